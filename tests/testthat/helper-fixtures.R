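# Shared fixtures and independent oracles for the test suite.

# Small-cohort simulation config used by the Monte-Carlo loops: simulated
# directly at the analysis rate with few channels so that epochs can be cut
# without the (deterministic, separately-tested) filtering stages.
fast_config <- function(channels = c("Cz", "Pz"),
                        lag_rad = seq(0, pi / 2, length.out = length(channels)),
                        fs_hz = 256, duration_s = 150,
                        zero_lag_gain = 2, noise_sd = 5, ...) {
  simulation_config(channel_labels = channels, eog_labels = character(),
                    fs_hz = fs_hz, duration_s = duration_s, lag_rad = lag_rad,
                    zero_lag_gain = zero_lag_gain, noise_sd = noise_sd, ...)
}

# Build a cross_spectrum_set directly from a trials x freqs matrix of
# imaginary parts (real parts zero), bypassing the FFT path.
cs_from_im <- function(im) {
  im <- as.matrix(im)
  structure(list(pair = c("a", "b"), freqs_hz = seq_len(ncol(im)),
                 values = 1i * im),
            class = "cross_spectrum_set")
}

# Literal double-sum oracle for the debiased squared-WPLI estimator.
dwpli2_brute <- function(im) {
  n <- length(im)
  num <- 0; den <- 0
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j != k) {
      num <- num + im[j] * im[k]
      den <- den + abs(im[j] * im[k])
    }
  }
  if (den == 0) 0 else num / den
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n1 + n2, n1) assignments of ranks to the first group (tie-free inputs).
wilcoxon_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_w <- apply(utils::combn(n1 + n2, n1), 2,
                 function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  p_le <- mean(all_w <= w_obs)
  p_ge <- mean(all_w >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Epoch set with given per-channel signal matrix replicated into trials.
epochs_from_matrix <- function(mat, fs_hz, n_trials = 1) {
  arr <- array(rep(mat, n_trials), dim = c(nrow(mat), ncol(mat), n_trials))
  epoch_set(arr, fs_hz, nrow(mat) / fs_hz, colnames(mat))
}
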