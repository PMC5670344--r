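#' Read a continuous recording from disk
#'
#' Two interchange formats are supported. `tsv`: a tab-separated file with a
#' header row of channel labels and one row per sample, plus a JSON sidecar
#' (same path with `.json` appended) carrying `fs_hz` and `eog_labels`;
#' lossless. `edf`: standard 16-bit European Data Format with per-signal
#' physical dimensions honoured (values returned in microvolts); quantized
#' to the 16-bit physical range.
#'
#' @param path file path.
#' @param format `"tsv"` or `"edf"` (default: guessed from the extension).
#' @return A [continuous_recording()].
#' @export
read_recording <- function(path, format = c("auto", "tsv", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format, tsv = read_recording_tsv(path), edf = read_recording_edf(path))
}

#' Write a continuous recording to disk
#'
#' @param rec a [continuous_recording()].
#' @param path output path.
#' @param format `"tsv"` (text, lossless, with JSON sidecar) or `"edf"`
#'   (16-bit binary; sampling rate must be an integer).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("tsv", "edf")) {
  format <- match.arg(format)
  switch(format,
         tsv = write_recording_tsv(rec, path),
         edf = write_recording_edf(rec, path))
  invisible(path)
}

read_recording_tsv <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar config: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs_hz)) stop("sidecar ", sidecar, " lacks fs_hz")
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  labels <- colnames(dat)
  if (anyDuplicated(labels)) stop("duplicate channel labels in ", path)
  continuous_recording(as.matrix(dat), fs_hz = meta$fs_hz, labels = labels,
                       eog_labels = as.character(meta$eog_labels %||% character()))
}

write_recording_tsv <- function(rec, path) {
  stopifnot(inherits(rec, "continuous_recording"))
  # 17 significant digits so the text round trip is bit-exact for doubles
  chr <- vapply(seq_len(ncol(rec$data)),
                function(j) sprintf("%.17g", rec$data[, j]),
                character(nrow(rec$data)))
  if (is.null(dim(chr))) chr <- matrix(chr, nrow = nrow(rec$data))
  colnames(chr) <- rec$labels
  utils::write.table(chr, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs_hz = rec$fs_hz, eog_labels = rec$eog_labels),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- Minimal EDF (16-bit) writer/reader ------------------------------------
# One data record per second; all signals in microvolts with a symmetric
# physical range covering the data. Header fields are fixed-width ASCII.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x)
  formatC(x, width = width, flag = "-")
}

write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "continuous_recording"))
  fs <- rec$fs_hz
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- ncol(rec$data)
  n_rec <- nrow(rec$data) %/% fs
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  pm <- max(1, ceiling(max(abs(rec$data))))
  dig_min <- -32768L; dig_max <- 32767L
  scale <- (2 * pm) / (dig_max - dig_min)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate 01-JAN-2000 X X X", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256L + ns * 256L, 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (lab in rec$labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(-pm, 8)
  for (i in seq_len(ns)) wr(pm, 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  dig <- round((rec$data - (-pm)) / scale) + dig_min
  dig <- pmin(pmax(dig, dig_min), dig_max)
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    block <- dig[((r - 1L) * fs + 1L):(r * fs), , drop = FALSE]
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("malformed EDF header in ", path, " (bad version)")
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header in ", path)
  if (header_bytes != 256L + ns * 256L) {
    stop("inconsistent EDF header size in ", path)
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  if (anyDuplicated(labels)) stop("duplicate channel labels in ", path)
  for (i in seq_len(ns)) rd(80)                  # transducer
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)                  # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)                  # reserved
  if (any(is.na(c(phys_min, phys_max, dig_min, dig_max, spr)))) {
    stop("malformed EDF signal headers in ", path)
  }
  if (length(unique(spr)) != 1L) {
    stop("inconsistent per-signal sampling rates in ", path)
  }
  fs <- spr[1] / rec_dur
  n <- n_rec * spr[1]
  data <- matrix(0, nrow = n, ncol = ns)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2L, endian = "little",
                     signed = TRUE)
      if (length(raw) < spr[s]) stop("truncated EDF data in ", path)
      phys <- phys_min[s] + (raw - dig_min[s]) *
        (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
      # convert to microvolts if the physical dimension is millivolts
      if (tolower(dims[s]) == "mv") phys <- phys * 1000
      data[((r - 1L) * spr[s] + 1L):(r * spr[s]), s] <- phys
    }
  }
  continuous_recording(data, fs_hz = fs, labels = labels)
}

#' Read and validate cohort metadata and FA tables
#'
#' @param cohort_csv CSV with columns `subject_id`, `group` and optional
#'   score columns; group labels must be `case`/`control`.
#' @param fa_csv CSV with columns `subject_id`, `roi`, `side`, `fa`.
#' @param strict_roi if TRUE (default), ROI names outside `roi_vocabulary`
#'   are an error; if FALSE, a warning.
#' @param roi_vocabulary data.frame with `roi`, `side` columns (default
#'   [default_roi_vocabulary()]).
#' @return List with `cohort` and `roi_table` data.frames.
#' @export
read_tables <- function(cohort_csv, fa_csv, strict_roi = TRUE,
                        roi_vocabulary = default_roi_vocabulary()) {
  cohort <- utils::read.csv(cohort_csv, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(cohort))) {
    stop(cohort_csv, ": required columns subject_id, group missing")
  }
  dup <- which(duplicated(cohort$subject_id))
  if (length(dup)) stop(cohort_csv, ": duplicate subject_id at row(s) ",
                        paste(dup, collapse = ", "))
  bad <- which(!cohort$group %in% c("case", "control") | is.na(cohort$group))
  if (length(bad)) stop(cohort_csv, ": unknown group label at row(s) ",
                        paste(bad, collapse = ", "))

  fa <- utils::read.csv(fa_csv, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "roi", "side", "fa") %in% names(fa))) {
    stop(fa_csv, ": required columns subject_id, roi, side, fa missing")
  }
  bad_fa <- which(!is.finite(fa$fa) | fa$fa < 0 | fa$fa > 1)
  if (length(bad_fa)) stop(fa_csv, ": fa outside [0, 1] at row(s) ",
                           paste(bad_fa, collapse = ", "))
  key <- paste(fa$subject_id, fa$roi, fa$side)
  dup <- which(duplicated(key))
  if (length(dup)) stop(fa_csv, ": duplicate (subject, roi, side) at row(s) ",
                        paste(dup, collapse = ", "))
  vocab_key <- paste(roi_vocabulary$roi, roi_vocabulary$side)
  unknown <- which(!paste(fa$roi, fa$side) %in% vocab_key)
  if (length(unknown)) {
    msg <- paste0(fa_csv, ": ROI outside vocabulary at row(s) ",
                  paste(utils::head(unknown, 10), collapse = ", "))
    if (strict_roi) stop(msg) else warning(msg)
  }
  list(cohort = cohort, roi_table = fa)
}

#' Write a synthetic cohort to disk
#'
#' One recording file per subject (TSV + sidecar, or EDF), plus
#' `cohort.csv` (subject_id, group), `fa.csv` (subject_id, roi, side, fa),
#' and `truth.json` with the per-subject generating concentrations.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param format `"tsv"` or `"edf"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("tsv", "edf")) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "tsv") ".tsv" else ".edf"
  for (id in names(cohort$recordings)) {
    write_recording(cohort$recordings[[id]], file.path(dir, paste0(id, ext)),
                    format = format)
  }
  utils::write.csv(cohort$metadata, file.path(dir, "cohort.csv"),
                   row.names = FALSE, quote = FALSE)
  fa_out <- cohort$fa_table
  fa_out$fa <- sprintf("%.17g", fa_out$fa)   # lossless text round trip
  utils::write.csv(fa_out, file.path(dir, "fa.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(kappa = as.list(cohort$truth$kappa)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
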