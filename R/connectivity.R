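#' Frequency band definition
#'
#' Inclusive integer frequency bounds in Hz. The defaults used throughout the
#' package are theta (4-7), alpha (8-13), beta (15-23) and low_gamma (25-40).
#'
#' @param name band name.
#' @param lo_hz,hi_hz inclusive integer bounds, `1 <= lo <= hi`.
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(name, lo_hz, hi_hz) {
  stopifnot(lo_hz >= 1, lo_hz <= hi_hz)
  structure(list(name = name, lo_hz = as.integer(lo_hz),
                 hi_hz = as.integer(hi_hz)),
            class = "band_definition")
}

#' Default analysis bands
#' @return Named list of [band_definition()]s: theta, alpha, beta, low_gamma.
#' @export
default_bands <- function() {
  list(
    theta = band_definition("theta", 4, 7),
    alpha = band_definition("alpha", 8, 13),
    beta = band_definition("beta", 15, 23),
    low_gamma = band_definition("low_gamma", 25, 40)
  )
}

# Complex Fourier coefficients of every retained epoch and channel at integer
# frequencies 1..fs/2 (rectangular window; with 1-s epochs the bin spacing is
# exactly 1 Hz). Returns freqs x channels x trials complex array; `rows`
# optionally restricts to a subset of the 1..fs/2 bins.
epoch_spectra <- function(epochs, rows = NULL) {
  len <- dim(epochs$epochs)[1]
  nch <- dim(epochs$epochs)[2]
  nf <- len %/% 2L
  if (is.null(rows)) rows <- seq_len(nf)
  n_keep <- sum(!epochs$rejected)
  x <- if (any(epochs$rejected)) {
    matrix(epochs$epochs[, , !epochs$rejected], nrow = len)
  } else {
    matrix(epochs$epochs, nrow = len)                # len x (nch * ntrial)
  }
  if (length(rows) <= 40L) {
    # few bins wanted: direct DFT by real matrix products beats a full FFT
    ang <- outer(0:(len - 1L), rows) * (2 * pi / len)
    sp_re <- crossprod(cos(ang), x)
    sp_im <- crossprod(sin(ang), x)
    sp <- complex(real = sp_re, imaginary = -sp_im)
  } else {
    sp <- stats::mvfft(x)[rows + 1L, , drop = FALSE]
  }
  array(sp, dim = c(length(rows), nch, n_keep),
        dimnames = list(NULL, epochs$labels, NULL))
}

freqs_of <- function(epochs) {
  len <- dim(epochs$epochs)[1]
  seq_len(len %/% 2L) / epochs$epoch_length_s
}

#' Per-epoch cross-spectra for one channel pair
#'
#' For each retained epoch, the discrete Fourier transform of each channel's
#' segment (rectangular window) is taken and the cross-spectrum
#' `S_j(f) = X_a(f) * Conj(X_b(f))` formed at integer frequencies
#' `1 .. fs/2` Hz. With 1-s epochs the frequency resolution is 1 Hz.
#'
#' @param epochs an [epoch_set()] with at least 2 retained trials.
#' @param pair character vector of two channel labels.
#' @return An object of class `cross_spectrum_set`: list with `pair`,
#'   `freqs_hz`, and `values` (trials x freqs complex matrix).
#' @export
epoch_cross_spectra <- function(epochs, pair) {
  stopifnot(inherits(epochs, "epoch_set"), length(pair) == 2L)
  if (!all(pair %in% epochs$labels)) {
    stop("unknown channel label(s): ",
         paste(setdiff(pair, epochs$labels), collapse = ", "))
  }
  if (n_retained(epochs) < 2L) stop("need at least 2 retained epochs")
  sp <- epoch_spectra(epochs)
  cross_spectrum_set(
    pair,
    freqs_of(epochs),
    t(sp[, pair[1], ] * Conj(sp[, pair[2], ]))
  )
}

cross_spectrum_set <- function(pair, freqs_hz, values) {
  values <- as.matrix(values)
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values)))) {
    stop("non-finite cross-spectral values")
  }
  structure(list(pair = pair, freqs_hz = freqs_hz, values = values),
            class = "cross_spectrum_set")
}

connectivity_spectrum <- function(pair, freqs_hz, measure, values) {
  structure(list(pair = pair, freqs_hz = freqs_hz, measure = measure,
                 values = as.numeric(values)),
            class = "connectivity_spectrum")
}

#' @export
print.connectivity_spectrum <- function(x, ...) {
  cat(sprintf("<connectivity_spectrum> %s %s-%s, %d bins (%g-%g Hz)\n",
              x$measure, x$pair[1], x$pair[2], length(x$freqs_hz),
              min(x$freqs_hz), max(x$freqs_hz)))
  invisible(x)
}

#' @export
plot.connectivity_spectrum <- function(x, ...) {
  graphics::plot(x$freqs_hz, x$values, type = "l", xlab = "frequency (Hz)",
                 ylab = x$measure,
                 main = paste(x$pair, collapse = " - "), ...)
  invisible(x)
}

# Shared kernel: per-frequency measures from the trials x freqs matrix of
# imaginary cross-spectrum values. The 0/0 case (all Im(S) = 0 at a bin,
# e.g. purely zero-lag coupling) is defined as 0 for all three measures.
measure_from_im <- function(imS, measure) {
  n <- nrow(imS)
  switch(
    measure,
    wpli = {
      den <- colSums(abs(imS))
      ifelse(den == 0, 0, abs(colSums(imS)) / den)
    },
    pli = abs(colMeans(sign(imS))),
    debiased_wpli_square = {
      if (n < 2L) stop("debiased WPLI-square needs at least 2 epochs")
      num <- colSums(imS)^2 - colSums(imS^2)
      den <- colSums(abs(imS))^2 - colSums(imS^2)
      ifelse(den == 0, 0, num / den)
    },
    stop("unknown measure: ", measure)
  )
}

#' Weighted phase lag index
#'
#' Per frequency, `|mean(Im S_j)| / mean(|Im S_j|)` over epochs: the
#' consistency of the lead/lag sign weighted by the magnitude of the
#' imaginary cross-spectrum. Ranges over `[0, 1]`; insensitive to purely
#' instantaneous (zero-lag) coupling, whose cross-spectrum is real.
#'
#' @param cs a [epoch_cross_spectra()] result.
#' @return A `connectivity_spectrum`.
#' @export
wpli <- function(cs) {
  stopifnot(inherits(cs, "cross_spectrum_set"))
  connectivity_spectrum(cs$pair, cs$freqs_hz, "wpli",
                        measure_from_im(Im(cs$values), "wpli"))
}

#' Phase lag index
#'
#' Per frequency, `|mean(sign(Im S_j))|`: the unweighted asymmetry of
#' phase-lead versus phase-lag epochs (`sign(0) = 0`).
#'
#' @inheritParams wpli
#' @return A `connectivity_spectrum`.
#' @export
pli <- function(cs) {
  stopifnot(inherits(cs, "cross_spectrum_set"))
  connectivity_spectrum(cs$pair, cs$freqs_hz, "pli",
                        measure_from_im(Im(cs$values), "pli"))
}

#' Debiased estimator of the squared WPLI
#'
#' Per frequency, the double sum over ordered epoch pairs `j != k`
#' `sum Im(S_j) Im(S_k) / sum |Im(S_j) Im(S_k)|`, computed in its algebraic
#' O(N) form `[(sum Im S)^2 - sum (Im S)^2] / [(sum |Im S|)^2 - sum (Im S)^2]`.
#' By excluding the diagonal terms the estimator is asymptotically unbiased
#' for the squared WPLI; it can be negative in finite samples (negative
#' values are deliberately not clipped — clipping would re-bias it and the
#' surrogate normalization downstream expects a signed statistic).
#'
#' @inheritParams wpli
#' @return A `connectivity_spectrum` with values in `[-1, 1]`.
#' @export
debiased_wpli_square <- function(cs) {
  stopifnot(inherits(cs, "cross_spectrum_set"))
  if (nrow(cs$values) < 2L) stop("debiased WPLI-square needs at least 2 epochs")
  connectivity_spectrum(cs$pair, cs$freqs_hz, "debiased_wpli_square",
                        measure_from_im(Im(cs$values), "debiased_wpli_square"))
}

#' Mean of a connectivity spectrum over a band
#'
#' Arithmetic mean of the per-frequency values over the integer bins
#' `lo_hz .. hi_hz` inclusive.
#'
#' @param spec a `connectivity_spectrum`.
#' @param band a [band_definition()] lying within the spectrum's range.
#' @return A single numeric value.
#' @export
band_average <- function(spec, band) {
  stopifnot(inherits(spec, "connectivity_spectrum"),
            inherits(band, "band_definition"))
  idx <- which(spec$freqs_hz >= band$lo_hz & spec$freqs_hz <= band$hi_hz)
  if (length(idx) == 0) stop("band ", band$name, " is empty for this spectrum")
  mean(spec$values[idx])
}

#' Connectivity for all channel pairs, band-averaged
#'
#' Computes the chosen measure for every unordered pair of scalp-EEG
#' channels, averages within each band, and also returns the across-pairs
#' mean per band (the "global" synchrony value).
#'
#' @param epochs an [epoch_set()] with at least 2 scalp channels.
#' @param measure one of `"debiased_wpli_square"` (default), `"wpli"`, `"pli"`.
#' @param bands named list of [band_definition()]s.
#' @param spectra if FALSE, skip the per-frequency table and evaluate only
#'   the bins inside the requested bands (faster for band summaries).
#' @return List with `pairs` (data.frame `channel_a`, `channel_b`, `band`,
#'   `measure`, `value`), `global` (data.frame `band`, `measure`, `value`),
#'   and `spectra` (data.frame `channel_a`, `channel_b`, `freq_hz`, `value`,
#'   or NULL).
#' @export
pairwise_connectivity <- function(epochs,
                                  measure = c("debiased_wpli_square", "wpli", "pli"),
                                  bands = default_bands(),
                                  spectra = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  measure <- match.arg(measure)
  chans <- eeg_labels(epochs)
  if (length(chans) < 2L) stop("need at least 2 scalp-EEG channels")
  if (n_retained(epochs) < 2L) stop("need at least 2 retained epochs")
  all_freqs <- freqs_of(epochs)
  band_idx_all <- lapply(bands, function(b) {
    idx <- which(all_freqs >= b$lo_hz & all_freqs <= b$hi_hz)
    if (length(idx) == 0) stop("band ", b$name, " outside spectrum range")
    idx
  })
  rows <- if (spectra) seq_along(all_freqs) else
    sort(unique(unlist(band_idx_all)))
  freqs <- all_freqs[rows]
  band_idx <- lapply(band_idx_all, function(idx) match(idx, rows))
  sp <- epoch_spectra(epochs, rows = rows)
  pairs <- utils::combn(chans, 2L)
  n_pairs <- ncol(pairs)
  spec_mat <- matrix(0, nrow = length(freqs), ncol = n_pairs)
  band_mat <- matrix(0, nrow = length(bands), ncol = n_pairs)
  for (k in seq_len(n_pairs)) {
    imS <- t(Im(sp[, pairs[1, k], ] * Conj(sp[, pairs[2, k], ])))
    vals <- measure_from_im(imS, measure)
    spec_mat[, k] <- vals
    band_mat[, k] <- vapply(band_idx, function(idx) mean(vals[idx]), 0)
  }
  pair_tbl <- data.frame(
    channel_a = rep(pairs[1, ], each = length(bands)),
    channel_b = rep(pairs[2, ], each = length(bands)),
    band = rep(names(bands), n_pairs),
    measure = measure,
    value = as.numeric(band_mat),
    stringsAsFactors = FALSE
  )
  global <- data.frame(band = names(bands), measure = measure,
                       value = rowMeans(band_mat), stringsAsFactors = FALSE,
                       row.names = NULL)
  spec_tbl <- if (spectra) {
    data.frame(
      channel_a = rep(pairs[1, ], each = length(freqs)),
      channel_b = rep(pairs[2, ], each = length(freqs)),
      freq_hz = rep(freqs, n_pairs),
      value = as.numeric(spec_mat),
      stringsAsFactors = FALSE
    )
  }
  list(pairs = pair_tbl, global = global, spectra = spec_tbl)
}

#' Global band synchrony of an epoch set
#'
#' Convenience statistic: the across-pairs mean of the band-averaged measure,
#' for a single band. This is the summary tested against surrogate nulls.
#'
#' @param epochs an [epoch_set()].
#' @param band a [band_definition()] (default low_gamma, 25-40 Hz).
#' @param measure connectivity measure (default debiased WPLI-square).
#' @return Single numeric value.
#' @export
global_band_synchrony <- function(epochs, band = default_bands()$low_gamma,
                                  measure = "debiased_wpli_square") {
  stopifnot(inherits(epochs, "epoch_set"))
  chans <- eeg_labels(epochs)
  if (length(chans) < 2L) stop("need at least 2 scalp-EEG channels")
  freqs <- freqs_of(epochs)
  idx <- which(freqs >= band$lo_hz & freqs <= band$hi_hz)
  if (length(idx) == 0) stop("band outside spectrum range")
  sp <- epoch_spectra(epochs, rows = idx)
  pairs <- utils::combn(chans, 2L)
  acc <- 0
  for (k in seq_len(ncol(pairs))) {
    imS <- t(Im(sp[, pairs[1, k], , drop = TRUE] *
                  Conj(sp[, pairs[2, k], , drop = TRUE])))
    if (is.null(dim(imS))) imS <- matrix(imS, ncol = length(idx))
    acc <- acc + mean(measure_from_im(imS, measure))
  }
  acc / ncol(pairs)
}
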