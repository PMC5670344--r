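#' Wilcoxon rank-sum test (two-sided)
#'
#' Thin wrapper over [stats::wilcox.test()] fixing this package's
#' conventions: the exact null distribution is used when the combined sample
#' size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return List with `statistic` (rank-sum W), `p_value`, `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (length(unique(c(x, y))) == 1L) {
    # fully tied data carry no ordering information
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                exact = FALSE))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Pooled-variance two-sample t statistic
#'
#' Computes the classic pooled two-sample t with `df = n1 + n2 - 2`, either
#' from summary statistics (means, SDs, group sizes) or from raw vectors
#' `x`, `y` (summaries computed first). The orientation is
#' `(mean2 - mean1) / SE`: with group 1 = cases and group 2 = controls, a
#' positive t means controls score higher.
#'
#' @param x,y optional raw group vectors (group 1, group 2).
#' @param mean1,sd1,n1 summary statistics of group 1 (cases).
#' @param mean2,sd2,n2 summary statistics of group 2 (controls).
#' @return List with `t`, `df`, `p_value` (two-sided).
#' @examples
#' two_sample_t_pooled(mean1 = 0, sd1 = 1, n1 = 10, mean2 = 1, sd2 = 1, n2 = 10)
#' @export
two_sample_t_pooled <- function(x = NULL, y = NULL,
                                mean1, sd1, n1, mean2, sd2, n2) {
  if (!is.null(x) || !is.null(y)) {
    if (is.null(x) || is.null(y)) stop("supply both raw vectors or neither")
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) stop("zero pooled variance")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean2 - mean1) / se
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the standard convention (sum of hypergeometric
#' probabilities of all tables, with the observed margins, whose point
#' probability does not exceed the observed table's), via
#' [stats::fisher.test()]. The hypergeometric point probability of the
#' observed table itself is also reported, since some published analyses
#' quote that quantity instead.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List with `p_two_sided`, `p_point`, `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(abs(tab - round(tab)) < 1e-9))
  tab <- round(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p_two_sided = 1, p_point = 1, odds_ratio = NA_real_))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  p_point <- stats::dhyper(tab[1, 1], rowSums(tab)[1], rowSums(tab)[2],
                           colSums(tab)[1])
  list(p_two_sided = ft$p.value, p_point = p_point,
       odds_ratio = unname(ft$estimate))
}

#' Pearson correlation with significance test
#'
#' Sample Pearson r on pairwise-complete observations. Significance by
#' default via the Student-t statistic `t = r * sqrt((n - 2) / (1 - r^2))`
#' with `df = n - 2` (two-sided); the Fisher-z variant
#' (`z = atanh(r) * sqrt(n - 3)`, standard-normal reference) is available
#' with `method = "fisher-z"`.
#'
#' @param x,y numeric vectors of equal length; pairs with missing values are
#'   dropped; at least 4 complete pairs required.
#' @param method `"t"` (default) or `"fisher-z"`.
#' @return List with `r`, `statistic`, `p_value`, `n`, `method`.
#' @export
pearson_corr_test <- function(x, y, method = c("t", "fisher-z")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y: correlation undefined")
  }
  r <- stats::cor(x, y)
  if (method == "t") {
    if (abs(r) >= 1) {
      stat <- sign(r) * Inf
      p <- 0
    } else {
      stat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(stat), df = n - 2)
    }
  } else {
    stat <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15)) * sqrt(n - 3)
    p <- 2 * stats::pnorm(-abs(stat))
  }
  list(r = r, statistic = stat, p_value = p, n = n, method = method)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down familywise-error correction: sort p ascending, multiply the
#' i-th smallest by `(m - i + 1)`, enforce a monotone cumulative maximum,
#' cap at 1, and return in the original order. Wrapper over
#' [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values, same order and length.
#' @export
holm_bonferroni <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  stopifnot(all(pvals > 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "holm")
}

#' Hierarchical band-then-pair group comparison
#'
#' Stage 1: for each band, a two-sided Wilcoxon rank-sum test comparing the
#' groups on the across-pairs band mean (the global synchrony), uncorrected.
#' Stage 2: for every band significant at `alpha`, per-pair Wilcoxon tests,
#' reported uncorrected by default (Holm adjustment across the pairs of a
#' band available via `adjust_pairs`). Subjects missing connectivity rows
#' are excluded with a warning.
#'
#' @param conn_table data.frame with columns `subject_id`, `channel_a`,
#'   `channel_b`, `band`, `value` (per-pair band-averaged connectivity, e.g.
#'   stacked [pairwise_connectivity()] `pairs` tables).
#' @param cohort data.frame with columns `subject_id`, `group` (two groups;
#'   by convention `case` and `control`).
#' @param alpha stage-1 significance level.
#' @param adjust_pairs if TRUE, add Holm-adjusted per-pair p-values.
#' @return An object of class `stats_report`: list with `stage1` (band-level
#'   data.frame), `stage2` (pair-level data.frame or NULL), `alpha`,
#'   `excluded` (subject ids).
#' @export
compare_groups <- function(conn_table, cohort, alpha = 0.05,
                           adjust_pairs = FALSE) {
  need <- c("subject_id", "channel_a", "channel_b", "band", "value")
  stopifnot(all(need %in% names(conn_table)),
            all(c("subject_id", "group") %in% names(cohort)))
  groups <- sort(unique(cohort$group))
  if (length(groups) != 2) stop("cohort must contain exactly two groups")
  missing_ids <- setdiff(cohort$subject_id, unique(conn_table$subject_id))
  if (length(missing_ids)) {
    warning("excluding subjects with no connectivity rows: ",
            paste(missing_ids, collapse = ", "))
    cohort <- cohort[!cohort$subject_id %in% missing_ids, ]
  }
  if (any(table(cohort$group) < 2)) stop("need >= 2 subjects per group")
  conn_table <- conn_table[conn_table$subject_id %in% cohort$subject_id, ]
  grp <- stats::setNames(cohort$group, cohort$subject_id)

  global <- stats::aggregate(value ~ subject_id + band, data = conn_table,
                             FUN = mean)
  bands <- unique(conn_table$band)
  stage1 <- do.call(rbind, lapply(bands, function(b) {
    gb <- global[global$band == b, ]
    g <- grp[gb$subject_id]
    wt <- wilcoxon_rank_sum(gb$value[g == groups[1]], gb$value[g == groups[2]])
    data.frame(band = b, statistic = wt$statistic, p_value = wt$p_value,
               significant = wt$p_value < alpha, stringsAsFactors = FALSE)
  }))
  sig_bands <- stage1$band[stage1$significant]
  stage2 <- NULL
  if (length(sig_bands)) {
    stage2 <- do.call(rbind, lapply(sig_bands, function(b) {
      sub <- conn_table[conn_table$band == b, ]
      pairs <- unique(sub[, c("channel_a", "channel_b")])
      rows <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
        pp <- sub[sub$channel_a == pairs$channel_a[k] &
                    sub$channel_b == pairs$channel_b[k], ]
        g <- grp[pp$subject_id]
        wt <- wilcoxon_rank_sum(pp$value[g == groups[1]],
                                pp$value[g == groups[2]])
        data.frame(band = b, channel_a = pairs$channel_a[k],
                   channel_b = pairs$channel_b[k], p_value = wt$p_value,
                   stringsAsFactors = FALSE)
      }))
      if (adjust_pairs) rows$p_adjusted <- holm_bonferroni(rows$p_value)
      rows
    }))
  }
  structure(list(stage1 = stage1, stage2 = stage2, alpha = alpha,
                 excluded = missing_ids),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("<stats_report> stage 1 (band-level):\n")
  print(x$stage1, row.names = FALSE)
  if (!is.null(x$stage2)) {
    cat("stage 2 (pair-level, uncorrected):\n")
    print(x$stage2, row.names = FALSE)
  }
  invisible(x)
}

#' Per-ROI group screening of fractional anisotropy
#'
#' For each (roi, side), a pooled two-sample t-test comparing FA between the
#' groups (orientation control minus case), with Holm-Bonferroni adjustment
#' across all tested ROI rows. ROIs with FA present for fewer than half the
#' subjects are excluded with a warning.
#'
#' @param roi_table data.frame `subject_id`, `roi`, `side`, `fa`.
#' @param cohort data.frame `subject_id`, `group` (groups `case`, `control`).
#' @return data.frame with one row per (roi, side): group means/SDs/ns, `t`,
#'   `df`, `p_value`, `p_adjusted`.
#' @export
fa_group_screen <- function(roi_table, cohort) {
  stopifnot(all(c("subject_id", "roi", "side", "fa") %in% names(roi_table)),
            all(c("subject_id", "group") %in% names(cohort)))
  grp <- stats::setNames(cohort$group, cohort$subject_id)
  roi_table <- roi_table[roi_table$subject_id %in% names(grp), ]
  n_subj <- length(unique(roi_table$subject_id))
  keys <- unique(roi_table[, c("roi", "side")])
  rows <- list()
  for (k in seq_len(nrow(keys))) {
    sub <- roi_table[roi_table$roi == keys$roi[k] &
                       roi_table$side == keys$side[k], ]
    if (nrow(sub) < n_subj / 2) {
      warning("ROI ", keys$roi[k], "/", keys$side[k],
              " missing for more than half of subjects; excluded")
      next
    }
    g <- grp[sub$subject_id]
    x <- sub$fa[g == "case"]; y <- sub$fa[g == "control"]
    if (length(x) < 2 || length(y) < 2) {
      warning("ROI ", keys$roi[k], "/", keys$side[k],
              ": fewer than 2 subjects in a group; excluded")
      next
    }
    tt <- two_sample_t_pooled(x = x, y = y)
    rows[[length(rows) + 1L]] <- data.frame(
      roi = keys$roi[k], side = keys$side[k],
      mean_case = mean(x), sd_case = stats::sd(x), n_case = length(x),
      mean_control = mean(y), sd_control = stats::sd(y), n_control = length(y),
      t = tt$t, df = tt$df, p_value = tt$p_value, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_bonferroni(out$p_value)
  out
}

#' Correlation between null-normalized synchrony and tract FA
#'
#' Pearson correlation, within one group, between each subject's
#' null-normalized global band synchrony (z-score from [null_normalize()])
#' and the FA of a selected tract.
#'
#' @param synchrony data.frame `subject_id`, `z` (normalized synchrony).
#' @param roi_table data.frame `subject_id`, `roi`, `side`, `fa`.
#' @param roi,side the tract to correlate against.
#' @param group group to restrict to (e.g. `"case"`).
#' @param cohort data.frame `subject_id`, `group`.
#' @param method passed to [pearson_corr_test()].
#' @return As [pearson_corr_test()].
#' @export
structure_function_correlation <- function(synchrony, roi_table, roi, side,
                                           group, cohort, method = "t") {
  stopifnot(all(c("subject_id", "z") %in% names(synchrony)))
  ids <- cohort$subject_id[cohort$group == group]
  fa <- roi_table[roi_table$roi == roi & roi_table$side == side &
                    roi_table$subject_id %in% ids, c("subject_id", "fa")]
  m <- merge(synchrony[synchrony$subject_id %in% ids, ], fa, by = "subject_id")
  if (nrow(m) < 4) stop("fewer than 4 subjects with both measures in group ", group)
  pearson_corr_test(m$z, m$fa, method = method)
}
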