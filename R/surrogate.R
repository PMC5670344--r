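#' Channel-shuffled surrogate of an epoch set
#'
#' For each channel independently, all retained samples (concatenated across
#' retained epochs) are permuted uniformly at random and re-segmented into
#' the same epoch structure. The per-channel marginal amplitude distribution
#' is exactly preserved (same multiset of samples) while all temporal — and
#' hence all spectral and cross-channel phase — structure is destroyed,
#' which makes the surrogate a draw from the no-synchronization null.
#' Rejected trials are dropped before shuffling, so the surrogate is built
#' from exactly the epochs that enter the observed statistic.
#'
#' @param epochs an [epoch_set()] with at least 1 retained trial.
#' @return An [epoch_set()] of the retained trials with shuffled channels.
#' @export
shuffle_surrogate <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (n_retained(epochs) < 1L) stop("no retained epochs to shuffle")
  arr <- if (any(epochs$rejected)) {
    epochs$epochs[, , !epochs$rejected, drop = FALSE]
  } else {
    epochs$epochs
  }
  d <- dim(arr)
  n_tot <- d[1] * d[3]
  # concatenate each channel's retained samples, permute, re-segment
  m <- matrix(aperm(arr, c(1L, 3L, 2L)), nrow = n_tot)
  for (ch in seq_len(d[2])) m[, ch] <- m[sample.int(n_tot), ch]
  out <- epochs
  out$epochs <- aperm(array(m, dim = c(d[1], d[3], d[2])), c(1L, 3L, 2L))
  out$rejected <- rep(FALSE, d[3])
  out
}

#' Empirical null distribution of a synchrony statistic
#'
#' Repeatedly shuffles the epoch set with [shuffle_surrogate()] and
#' re-evaluates the statistic, building the subject's empirical null
#' distribution. Each replicate runs under its own deterministic seed derived
#' from `seed` by a counter, so the distribution is reproducible and
#' replicates could be computed independently.
#'
#' @param epochs an [epoch_set()].
#' @param statistic_fn function mapping an [epoch_set()] to a single number
#'   (default: global low-gamma debiased WPLI-square,
#'   [global_band_synchrony()]).
#' @param B number of surrogate replicates (default 1000; at least 100 is
#'   recommended when empirical p-values are wanted).
#' @param seed master integer seed.
#' @param statistic label stored with the distribution.
#' @return An object of class `null_distribution`: list with `values` (B
#'   surrogate statistics), `B`, `seed`, `statistic`.
#' @export
null_distribution <- function(epochs, statistic_fn = global_band_synchrony,
                              B = 1000, seed = 1L,
                              statistic = "global_low_gamma_dwpli2") {
  stopifnot(inherits(epochs, "epoch_set"))
  if (B < 1) stop("B must be >= 1")
  vals <- numeric(B)
  for (b in seq_len(B)) {
    set.seed(replicate_seed(seed, b))
    vals[b] <- statistic_fn(shuffle_surrogate(epochs))
  }
  if (!all(is.finite(vals))) stop("non-finite surrogate statistic")
  structure(list(values = vals, B = as.integer(B), seed = as.integer(seed),
                 statistic = statistic),
            class = "null_distribution")
}

# Deterministic per-replicate seed stream (Knuth multiplicative hash of the
# counter, folded into the 31-bit range R accepts).
replicate_seed <- function(seed, b) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(b) * 2654435761) %% 2147483647)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s: B = %d, mean = %.4g, sd = %.4g\n",
              x$statistic, x$B, mean(x$values), stats::sd(x$values)))
  invisible(x)
}

#' Empirical p-value against a surrogate null
#'
#' One-sided (greater) by default: `p = (1 + #{null >= observed}) / (1 + B)`,
#' the add-one permutation p-value, which is never zero and gives valid
#' coverage when observed and surrogates are exchangeable under the null.
#' The two-sided variant doubles the smaller tail (capped at 1).
#'
#' @param observed observed statistic value.
#' @param null a [null_distribution()].
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return p-value in `(0, 1]`.
#' @export
empirical_p <- function(observed, null, alternative = c("greater", "two.sided")) {
  stopifnot(inherits(null, "null_distribution"))
  alternative <- match.arg(alternative)
  if (null$B < 100) {
    warning("B < 100: empirical p-values are coarse")
  }
  B <- length(null$values)
  p_ge <- (1 + sum(null$values >= observed)) / (1 + B)
  if (alternative == "greater") return(p_ge)
  p_le <- (1 + sum(null$values <= observed)) / (1 + B)
  min(1, 2 * min(p_ge, p_le))
}

#' Normalize an observed statistic by its surrogate null
#'
#' Subtracts the null mean and divides by the null standard deviation
#' (sample SD, denominator B - 1), turning the per-subject statistic into a
#' z-score that accommodates individual differences under the null.
#'
#' @param observed observed statistic value.
#' @param null a [null_distribution()] with positive SD.
#' @return z-score.
#' @export
null_normalize <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  s <- stats::sd(null$values)
  if (!is.finite(s) || s == 0) {
    stop("null distribution of `", null$statistic, "` has zero SD")
  }
  (observed - mean(null$values)) / s
}

#' Null summary for one subject
#'
#' Convenience wrapper: computes the observed statistic, its null
#' distribution, empirical p and z in one call.
#'
#' @inheritParams null_distribution
#' @param subject_id identifier carried into the summary.
#' @return List with `subject_id`, `statistic`, `observed`, `B`, `null_mean`,
#'   `null_sd`, `p`, `z`, `seed`.
#' @export
null_summary <- function(epochs, statistic_fn = global_band_synchrony,
                         B = 1000, seed = 1L, subject_id = NA_character_,
                         statistic = "global_low_gamma_dwpli2") {
  obs <- statistic_fn(epochs)
  nd <- null_distribution(epochs, statistic_fn, B = B, seed = seed,
                          statistic = statistic)
  list(subject_id = subject_id, statistic = statistic, observed = obs,
       B = nd$B, null_mean = mean(nd$values), null_sd = stats::sd(nd$values),
       p = empirical_p(obs, nd), z = null_normalize(obs, nd), seed = nd$seed)
}
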