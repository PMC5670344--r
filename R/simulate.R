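#' Configuration for the synthetic resting-EEG cohort generator
#'
#' Bundles every knob of the generative model. The model: each scalp channel
#' carries a narrow-band oscillation at `f0_hz` whose phase is redrawn
#' uniformly every second (a common block phase), offset per channel by a
#' fixed lag `lag_rad[c]` plus von Mises jitter with concentration `kappa`.
#' Higher concentration means more consistent cross-channel phase lags and
#' therefore stronger lagged synchronization. On top of the oscillation each
#' channel receives (i) a shared broadband component added identically and
#' instantaneously to all scalp channels, mimicking volume conduction of a
#' common source, (ii) a low-frequency (< 4 Hz) ocular signal leaked into
#' scalp channels with fixed per-channel propagation factors and emitted
#' unmixed on the EOG channels, and (iii) independent Gaussian sensor noise.
#' Per-subject white-matter FA is linearly coupled to the subject's phase
#' concentration for one designated tract and pure baseline-plus-noise for
#' all others.
#'
#' @param n_per_group named integer vector `c(case = ..., control = ...)`;
#'   cohort arm sizes. Defaults to 15 cases vs 22 controls.
#' @param channel_labels scalp channel names.
#' @param eog_labels EOG channel names (zero, one or two).
#' @param fs_hz sampling rate in Hz; must exceed `2 * f0_hz`.
#' @param duration_s recording length in seconds; `duration_s * fs_hz` must be
#'   a whole number of samples and `duration_s` a whole number of 1-s blocks.
#' @param f0_hz carrier frequency of the coupled oscillation (default 32 Hz,
#'   inside the 25-40 Hz low-gamma band).
#' @param amp_uv carrier amplitude in microvolts.
#' @param lag_rad per-scalp-channel phase offsets delta_c in radians.
#' @param kappa_mean_by_group named vector of group means of the von Mises
#'   concentration (default `c(case = 0, control = 4)`).
#' @param kappa_sd between-subject SD of concentration (truncated at 0).
#' @param zero_lag_gain amplitude (microvolts per unit SD) of the shared
#'   instantaneous broadband component.
#' @param noise_sd independent sensor noise SD in microvolts.
#' @param eog_propagation per-scalp-channel ocular leakage factors.
#' @param eog_amp_uv SD of the ocular signal in microvolts.
#' @param fa_roi,fa_side designated tract whose FA tracks coupling strength.
#' @param fa_baseline optional data.frame (`roi`, `side`, `baseline_fa`)
#'   overriding [default_roi_vocabulary()].
#' @param fa_slope FA change per unit of (kappa - cohort mean kappa).
#' @param fa_noise_sd SD of FA measurement noise (>= 0).
#' @param artifact_rate fraction of 1-s blocks receiving an injected
#'   high-amplitude artifact (default 0; used to exercise trial rejection).
#' @param artifact_amp_uv amplitude of injected artifacts.
#' @param seed integer seed; cohort generation is bit-reproducible given the
#'   configuration and seed.
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [simulate_recording()], [simulate_cohort()], [expected_wpli()]
#' @export
simulation_config <- function(n_per_group = c(case = 15, control = 22),
                              channel_labels = c("Fz", "Cz", "Pz", "Oz", "C3", "C4"),
                              eog_labels = c("VEOGup", "VEOGdown"),
                              fs_hz = 2048,
                              duration_s = 150,
                              f0_hz = 32,
                              amp_uv = 10,
                              lag_rad = seq(0, 2, length.out = length(channel_labels)),
                              kappa_mean_by_group = c(case = 0, control = 4),
                              kappa_sd = 1,
                              zero_lag_gain = 2,
                              noise_sd = 5,
                              eog_propagation = NULL,
                              eog_amp_uv = 30,
                              fa_roi = "inferior_cerebellar_peduncle",
                              fa_side = "right",
                              fa_baseline = NULL,
                              fa_slope = 0.003,
                              fa_noise_sd = 0.004,
                              artifact_rate = 0,
                              artifact_amp_uv = 150,
                              seed = NULL) {
  if (is.null(eog_propagation)) {
    # frontal channels pick up more ocular activity than posterior ones
    base <- c(Fz = 0.15, Cz = 0.10, Pz = 0.06, Oz = 0.04, C3 = 0.08, C4 = 0.08)
    eog_propagation <- ifelse(channel_labels %in% names(base),
                              base[channel_labels], 0.08)
    names(eog_propagation) <- channel_labels
  }
  if (is.null(fa_baseline)) fa_baseline <- default_roi_vocabulary()
  cfg <- list(
    n_per_group = n_per_group, channel_labels = channel_labels,
    eog_labels = eog_labels, fs_hz = fs_hz, duration_s = duration_s,
    f0_hz = f0_hz, amp_uv = amp_uv, lag_rad = lag_rad,
    kappa_mean_by_group = kappa_mean_by_group, kappa_sd = kappa_sd,
    zero_lag_gain = zero_lag_gain, noise_sd = noise_sd,
    eog_propagation = eog_propagation, eog_amp_uv = eog_amp_uv,
    fa_roi = fa_roi, fa_side = fa_side, fa_baseline = fa_baseline,
    fa_slope = fa_slope, fa_noise_sd = fa_noise_sd,
    artifact_rate = artifact_rate, artifact_amp_uv = artifact_amp_uv,
    seed = seed
  )
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  num_fields <- c("fs_hz", "duration_s", "f0_hz", "amp_uv", "zero_lag_gain",
                  "noise_sd", "eog_amp_uv", "fa_slope", "fa_noise_sd",
                  "artifact_rate", "artifact_amp_uv")
  for (f in num_fields) {
    if (!all(is.finite(cfg[[f]]))) stop("non-finite value for `", f, "`")
  }
  if (!all(is.finite(cfg$lag_rad)) || !all(is.finite(cfg$kappa_mean_by_group)) ||
      !is.finite(cfg$kappa_sd)) {
    stop("non-finite simulation parameters")
  }
  if (cfg$fs_hz <= 2 * cfg$f0_hz) stop("fs_hz must exceed 2 * f0_hz")
  n <- cfg$duration_s * cfg$fs_hz
  if (abs(n - round(n)) > 1e-9) stop("duration_s * fs_hz must be integral")
  if (abs(cfg$duration_s - round(cfg$duration_s)) > 1e-9) {
    stop("duration_s must be a whole number of 1-s blocks")
  }
  if (any(cfg$kappa_mean_by_group < 0) || cfg$kappa_sd < 0) {
    stop("kappa parameters must be >= 0")
  }
  if (cfg$fa_noise_sd < 0) stop("fa_noise_sd must be >= 0")
  if (length(cfg$lag_rad) != length(cfg$channel_labels)) {
    stop("lag_rad must have one entry per scalp channel")
  }
  if (length(cfg$eog_propagation) != length(cfg$channel_labels)) {
    stop("eog_propagation must have one entry per scalp channel")
  }
  if (cfg$artifact_rate < 0 || cfg$artifact_rate > 1) {
    stop("artifact_rate must be in [0, 1]")
  }
  invisible(cfg)
}

# Von Mises sampler, Best & Fisher rejection algorithm. kappa may be 0
# (uniform) or Inf (point mass at the mean 0).
rvonmises <- function(n, kappa) {
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa)) return(rep(0, n))
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
    acc <- theta[ok]
    take <- min(length(acc), m)
    if (take > 0) out[(got + 1L):(got + take)] <- acc[seq_len(take)]
    got <- got + take
  }
  out
}

# Low-pass (< cutoff Hz) smoothed Gaussian process with unit variance,
# used as the ocular source e(t).
lowfreq_process <- function(n, fs_hz, cutoff_hz = 3) {
  x <- stats::rnorm(n)
  flt <- signal::butter(2, min(cutoff_hz / (fs_hz / 2), 0.99), type = "low")
  y <- signal::filtfilt(flt, x)
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s
}

#' Simulate one continuous multichannel recording
#'
#' Generates a single subject's recording under the block-phase von Mises
#' coupling model (see [simulation_config()]). For each consecutive 1-s block
#' a common phase is drawn uniformly; scalp channel `c` oscillates as
#' `amp_uv * cos(2*pi*f0*t + phi_block + lag_rad[c] + eta)`, with `eta` drawn
#' per block and channel from a von Mises(0, kappa) distribution. A shared
#' zero-lag broadband component, per-channel ocular leakage, and independent
#' Gaussian noise are added. EOG channels carry the ocular source itself
#' (unmixed, noiseless), so regression-based correction is exactly solvable.
#'
#' Draws come from R's global random number generator; seed with
#' [set.seed()] (or use [simulate_cohort()], which seeds from its config).
#'
#' @param config a [simulation_config()].
#' @param kappa von Mises concentration(s) (>= 0, may be `Inf` for
#'   deterministic lags); scalar, or one value per scalp channel so that a
#'   channel pair can mix a jitter-free reference channel with a jittered one.
#' @return A [continuous_recording()] with attribute `truth` (list with the
#'   kappa used and indices of artifact-injected blocks, if any).
#' @export
simulate_recording <- function(config, kappa) {
  validate_simulation_config(config)
  n_eeg <- length(config$channel_labels)
  if (!all(is.numeric(kappa)) || any(is.na(kappa)) || any(kappa < 0)) {
    stop("kappa must be numeric and >= 0")
  }
  kappa <- rep_len(kappa, n_eeg)
  fs <- config$fs_hz
  nblocks <- round(config$duration_s)
  block_len <- round(fs)
  n <- nblocks * block_len
  t <- (seq_len(n) - 1) / fs
  idx <- rep(seq_len(nblocks), each = block_len)

  phi <- stats::runif(nblocks, 0, 2 * pi)
  carrier_arg <- 2 * pi * config$f0_hz * t
  data <- matrix(0, nrow = n, ncol = n_eeg + length(config$eog_labels))
  for (c in seq_len(n_eeg)) {
    eta <- rvonmises(nblocks, kappa[c])
    phase <- phi + config$lag_rad[c] + eta
    data[, c] <- config$amp_uv * cos(carrier_arg + phase[idx])
  }
  if (config$zero_lag_gain != 0) {
    v <- stats::rnorm(n)
    data[, seq_len(n_eeg)] <- data[, seq_len(n_eeg)] + config$zero_lag_gain * v
  }
  n_eog <- length(config$eog_labels)
  if (n_eog > 0) {
    e <- config$eog_amp_uv * lowfreq_process(n, fs)
    for (c in seq_len(n_eeg)) {
      data[, c] <- data[, c] + config$eog_propagation[c] * e
    }
    # vertical EOG pair: opposite-polarity views of the same ocular source
    gains <- c(1, -0.6)[seq_len(n_eog)]
    for (k in seq_len(n_eog)) data[, n_eeg + k] <- gains[k] * e
  }
  if (config$noise_sd > 0) {
    data[, seq_len(n_eeg)] <- data[, seq_len(n_eeg)] +
      matrix(stats::rnorm(n * n_eeg, sd = config$noise_sd), nrow = n)
  }
  artifact_blocks <- integer(0)
  if (config$artifact_rate > 0) {
    n_art <- round(config$artifact_rate * nblocks)
    if (n_art > 0) {
      artifact_blocks <- sort(sample.int(nblocks, n_art))
      pulse_len <- max(1L, round(0.1 * fs))      # 100 ms square pulse
      offset <- round(0.4 * fs)                  # interior of the block
      for (b in artifact_blocks) {
        ch <- sample.int(n_eeg, 1L)
        s0 <- (b - 1L) * block_len + offset
        data[s0:(s0 + pulse_len - 1L), ch] <-
          data[s0:(s0 + pulse_len - 1L), ch] + config$artifact_amp_uv
      }
    }
  }
  rec <- continuous_recording(
    data, fs_hz = fs,
    labels = c(config$channel_labels, config$eog_labels),
    eog_labels = config$eog_labels
  )
  attr(rec, "truth") <- list(kappa = kappa, artifact_blocks = artifact_blocks)
  rec
}

#' Simulate a two-group cohort of recordings with linked FA tables
#'
#' Per subject, a phase-coupling concentration is drawn from the subject's
#' group distribution (normal, truncated at 0), a recording is generated with
#' [simulate_recording()], and per-ROI fractional anisotropy is generated as
#' baseline plus noise, with the designated tract additionally coupled
#' linearly to the subject's concentration:
#' `FA = baseline + fa_slope * (kappa_i - mean(kappa)) + N(0, fa_noise_sd)`.
#'
#' @param config a [simulation_config()]; `config$seed` (if non-NULL) seeds
#'   the single generator from which all draws flow, making the cohort
#'   bit-reproducible.
#' @return An object of class `synthetic_cohort`: list with `recordings`
#'   (named list of [continuous_recording()]), `metadata` (data.frame
#'   `subject_id`, `group`), `fa_table` (data.frame `subject_id`, `roi`,
#'   `side`, `fa`), and `truth` (per-subject kappa and the config).
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  if (length(config$n_per_group) != 2L || is.null(names(config$n_per_group))) {
    stop("n_per_group must be a named vector with two groups")
  }
  if (any(config$n_per_group < 2)) stop("need at least 2 subjects per group")
  if (!is.null(config$seed)) set.seed(config$seed)

  groups <- rep(names(config$n_per_group), config$n_per_group)
  ids <- unlist(lapply(names(config$n_per_group), function(g) {
    sprintf("%s%02d", g, seq_len(config$n_per_group[[g]]))
  }))
  mu <- config$kappa_mean_by_group[groups]
  # normal truncated below at 0, via inverse-CDF so one uniform per subject
  lo <- stats::pnorm(0, mean = mu, sd = config$kappa_sd)
  kappa <- if (config$kappa_sd == 0) as.numeric(mu) else {
    stats::qnorm(stats::runif(length(mu), lo, 1), mean = mu, sd = config$kappa_sd)
  }
  names(kappa) <- ids

  recordings <- vector("list", length(ids))
  names(recordings) <- ids
  for (i in seq_along(ids)) {
    recordings[[i]] <- simulate_recording(config, kappa[i])
  }

  vocab <- config$fa_baseline
  kbar <- mean(kappa)
  fa_rows <- lapply(seq_along(ids), function(i) {
    slope <- ifelse(vocab$roi == config$fa_roi & vocab$side == config$fa_side,
                    config$fa_slope, 0)
    fa <- vocab$baseline_fa + slope * (kappa[i] - kbar) +
      stats::rnorm(nrow(vocab), sd = config$fa_noise_sd)
    data.frame(subject_id = ids[i], roi = vocab$roi, side = vocab$side,
               fa = pmin(pmax(fa, 0), 1), stringsAsFactors = FALSE)
  })
  structure(
    list(
      recordings = recordings,
      metadata = data.frame(subject_id = ids, group = groups,
                            stringsAsFactors = FALSE),
      fa_table = do.call(rbind, fa_rows),
      truth = list(kappa = kappa, config = config)
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$metadata$group)
  cat(sprintf("<synthetic_cohort> %d subjects (%s)\n", nrow(x$metadata),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Population WPLI of the von Mises phase-lag model
#'
#' For a channel pair whose phase difference is `delta + eta` with
#' `eta ~ von Mises(0, kappa)`, the population weighted phase lag index is
#' `|E sin(delta + eta)| / E|sin(delta + eta)|` (amplitudes constant). Both
#' expectations are evaluated by adaptive quadrature to absolute tolerance
#' 1e-8. Serves as the recovery oracle for the simulator: estimates from the
#' single-jittered-channel configuration converge to this value (and the
#' debiased squared estimator to its square).
#'
#' @param kappa concentration (>= 0; `Inf` = deterministic lag).
#' @param delta mean phase lag in radians.
#' @return Population WPLI in `[0, 1]`.
#' @examples
#' expected_wpli(Inf, pi / 2)  # 1: perfectly consistent quarter-cycle lag
#' expected_wpli(5, 0)         # 0: phase difference symmetric about zero
#' @export
expected_wpli <- function(kappa, delta) {
  stopifnot(length(kappa) == 1L, length(delta) == 1L, kappa >= 0)
  if (!is.finite(kappa)) {
    return(if (sin(delta) == 0) 0 else 1)
  }
  # von Mises density written with scaled Bessel for large-kappa stability
  dens <- function(x) {
    exp(kappa * (cos(x) - 1)) /
      (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
  }
  num <- stats::integrate(function(x) sin(delta + x) * dens(x), -pi, pi,
                          abs.tol = 1e-10, rel.tol = 1e-10,
                          subdivisions = 400L)$value
  den <- stats::integrate(function(x) abs(sin(delta + x)) * dens(x), -pi, pi,
                          abs.tol = 1e-10, rel.tol = 1e-10,
                          subdivisions = 400L)$value
  if (den <= 1e-12) return(0)
  min(abs(num) / den, 1)
}
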