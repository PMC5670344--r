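#' Construct a continuous multichannel recording
#'
#' The basic container for a single subject's continuous EEG: an amplitude
#' matrix in microvolts with one column per channel, a sampling rate, and an
#' optional set of channel labels flagged as electro-oculogram (EOG) channels.
#' EOG channels ride along through the pipeline as regressors for ocular
#' artifact correction but are excluded from connectivity estimation and from
#' amplitude-based trial rejection.
#'
#' @param data numeric matrix, samples x channels, in microvolts.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param labels character vector of unique channel names; defaults to
#'   `colnames(data)`.
#' @param eog_labels subset of `labels` marking EOG channels (may be empty).
#' @return An object of class `continuous_recording` with fields `data`
#'   (samples x channels, column names = labels), `fs_hz`, `labels`,
#'   `eog_labels`.
#' @examples
#' x <- matrix(rnorm(512 * 2), ncol = 2, dimnames = list(NULL, c("Cz", "Pz")))
#' rec <- continuous_recording(x, fs_hz = 256)
#' @export
continuous_recording <- function(data, fs_hz, labels = colnames(data),
                                 eog_labels = character()) {
  data <- as.matrix(data)
  if (is.null(labels)) {
    stop("channel labels are required (supply `labels` or name the columns)")
  }
  if (length(labels) != ncol(data)) {
    stop("length(labels) must equal ncol(data)")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (!all(eog_labels %in% labels)) {
    stop("eog_labels must be a subset of labels")
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) || fs_hz <= 0) {
    stop("fs_hz must be a single positive finite number")
  }
  if (!all(is.finite(data))) stop("recording contains non-finite values")
  storage.mode(data) <- "double"
  colnames(data) <- labels
  structure(
    list(data = data, fs_hz = as.numeric(fs_hz),
         labels = as.character(labels), eog_labels = as.character(eog_labels)),
    class = "continuous_recording"
  )
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$fs_hz, nrow(x$data) / x$fs_hz))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  if (length(x$eog_labels)) {
    cat("  EOG:", paste(x$eog_labels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' EEG (non-EOG) channel labels of a recording or epoch set
#' @param x a `continuous_recording` or `epoch_set`.
#' @return character vector of scalp-EEG channel labels.
#' @export
eeg_labels <- function(x) setdiff(x$labels, x$eog_labels)

#' Construct a set of fixed-length epochs ("pseudotrials")
#'
#' Holds the segmented recording as a samples x channels x trials array plus
#' a per-trial rejection mask. Downstream estimators use only retained trials.
#'
#' @param epochs numeric array, samples x channels x trials, microvolts.
#' @param fs_hz sampling rate in Hz.
#' @param epoch_length_s epoch duration in seconds; `samples` must equal
#'   `fs_hz * epoch_length_s`.
#' @param labels channel labels (length = dim 2).
#' @param eog_labels subset of `labels` marking EOG channels.
#' @param rejected logical mask, one element per trial (TRUE = rejected).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, fs_hz, epoch_length_s, labels,
                      eog_labels = character(),
                      rejected = rep(FALSE, dim(epochs)[3])) {
  stopifnot(length(dim(epochs)) == 3L)
  if (dim(epochs)[1] != round(fs_hz * epoch_length_s)) {
    stop("samples per epoch must equal fs_hz * epoch_length_s")
  }
  if (dim(epochs)[2] != length(labels)) stop("labels must match channel dimension")
  if (length(rejected) != dim(epochs)[3]) stop("rejected mask must have one entry per trial")
  if (!all(eog_labels %in% labels)) stop("eog_labels must be a subset of labels")
  dimnames(epochs) <- list(NULL, labels, NULL)
  structure(
    list(epochs = epochs, fs_hz = as.numeric(fs_hz),
         epoch_length_s = as.numeric(epoch_length_s),
         labels = as.character(labels), eog_labels = as.character(eog_labels),
         rejected = as.logical(rejected)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials (%d retained) x %d channels x %d samples @ %g Hz\n",
              dim(x$epochs)[3], sum(!x$rejected), dim(x$epochs)[2],
              dim(x$epochs)[1], x$fs_hz))
  invisible(x)
}

#' Number of retained (non-rejected) trials
#' @param epochs an `epoch_set`.
#' @return integer count of retained trials.
#' @export
n_retained <- function(epochs) sum(!epochs$rejected)

# Subset an epoch set to its retained trials (mask reset to all-FALSE).
retained_epochs <- function(epochs) {
  keep <- !epochs$rejected
  epoch_set(epochs$epochs[, , keep, drop = FALSE], epochs$fs_hz,
            epochs$epoch_length_s, epochs$labels, epochs$eog_labels)
}
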