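test_that("Wilcoxon rank-sum: exact path, tie handling, degenerate input", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_true(r$exact)
  expect_equal(r$p_value, 1 / 3)
  # same multiset in both groups
  r2 <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$p_value, 1)
  r3 <- wilcoxon_rank_sum(rep(5, 4), rep(5, 4))
  expect_equal(r3$p_value, 1)
  # exact path matches the enumeration oracle on random tie-free draws
  set.seed(51)
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    if (n1 + n2 > 12) next
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, wilcoxon_enum_p(x, y))
  }
})

test_that("Wilcoxon exact and approximate paths agree for moderate n", {
  set.seed(52)
  diffs <- replicate(100, {
    x <- rnorm(6); y <- rnorm(6)
    exact <- wilcoxon_rank_sum(x, y)$p_value
    approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    abs(exact - approx)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("pooled t agrees between summary and raw-vector forms", {
  r <- two_sample_t_pooled(mean1 = 0, sd1 = 1, n1 = 10,
                           mean2 = 1, sd2 = 1, n2 = 10)
  expect_equal(r$t, 1 / sqrt(2 / 10))
  expect_equal(r$df, 18)
  # equal means give t = 0
  expect_equal(two_sample_t_pooled(mean1 = 3, sd1 = 2, n1 = 8,
                                   mean2 = 3, sd2 = 1, n2 = 8)$t, 0)
  set.seed(53)
  x <- rnorm(12, 1, 2); y <- rnorm(15, 0.5, 1.5)
  raw <- two_sample_t_pooled(x = x, y = y)
  summ <- two_sample_t_pooled(mean1 = mean(x), sd1 = sd(x), n1 = length(x),
                              mean2 = mean(y), sd2 = sd(y), n2 = length(y))
  expect_equal(raw$t, summ$t, tolerance = 1e-12)
  expect_equal(raw$df, summ$df)
  # matches stats::t.test with var.equal = TRUE (orientation y - x)
  tt <- stats::t.test(y, x, var.equal = TRUE)
  expect_equal(raw$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(raw$p_value, tt$p.value, tolerance = 1e-12)
  expect_error(two_sample_t_pooled(mean1 = 1, sd1 = 0, n1 = 5,
                                   mean2 = 2, sd2 = 0, n2 = 5), "zero pooled")
})

test_that("Fisher 2x2: hand cases and hypergeometric completeness", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2))$p_two_sided, 1)
  r <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))
  expect_equal(r$p_two_sided, 2 / 252, tolerance = 1e-12)
  expect_equal(r$p_point, 1 / 252, tolerance = 1e-12)
  # degenerate margin
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2))$p_two_sided, 1)
  # point probabilities over all tables with the observed margins sum to 1
  set.seed(54)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    m <- rowSums(tab)[1]; n <- rowSums(tab)[2]; k <- colSums(tab)[1]
    a_range <- max(0, k - n):min(k, m)
    probs <- vapply(a_range, function(a) {
      fisher_exact_2x2(matrix(c(a, k - a, m - a, n - (k - a)), 2))$p_point
    }, 0)
    expect_lt(abs(sum(probs) - 1), 1e-12)
  }
})

test_that("Pearson correlation test handles exact, null and flagged variants", {
  x <- as.numeric(1:10)
  r1 <- pearson_corr_test(x, x)
  expect_equal(r1$r, 1)
  expect_lt(r1$p_value, 1e-12)
  # orthogonal mean-centred y: r = 0, p = 1
  y <- c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1)
  y <- y - mean(y)
  xc <- x - mean(x)
  y <- y - sum(y * xc) / sum(xc^2) * xc
  r0 <- pearson_corr_test(x, y)
  expect_equal(r0$r, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-9)
  # t form matches cor.test; fisher-z gives the documented statistic
  set.seed(55)
  a <- rnorm(12); b <- a + rnorm(12)
  ct <- stats::cor.test(a, b)
  rt <- pearson_corr_test(a, b)
  expect_equal(rt$r, unname(ct$estimate))
  expect_equal(rt$p_value, ct$p.value, tolerance = 1e-12)
  rz <- pearson_corr_test(a, b, method = "fisher-z")
  expect_equal(rz$statistic, atanh(rz$r) * sqrt(12 - 3))
  # pairwise-complete deletion
  a2 <- c(a, NA); b2 <- c(b, 1)
  expect_equal(pearson_corr_test(a2, b2)$n, 12)
  expect_error(pearson_corr_test(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson_corr_test(rnorm(3), rnorm(3)), "at least 4")
})

test_that("Holm-Bonferroni step-down adjustment", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_equal(holm_bonferroni(numeric(0)), numeric(0))
  set.seed(56)
  p <- runif(28)
  adj <- holm_bonferroni(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # adjustment preserves the ordering of the raw p-values
  expect_true(all(diff(adj[order(p)]) >= 0))
  # fully saturated lists are fixed points
  expect_true(all(holm_bonferroni(rep(1, 5)) == 1))
})

test_that("hierarchical band-then-pair comparison", {
  set.seed(57)
  bands <- c("theta", "alpha", "beta", "low_gamma")
  mk_table <- function(values_by_subject) {
    do.call(rbind, lapply(names(values_by_subject), function(id) {
      v <- values_by_subject[[id]]
      expand.grid(channel_a = "Cz", channel_b = c("Pz", "Fz"),
                  band = bands, stringsAsFactors = FALSE) |>
        transform(subject_id = id, value = v)
    }))
  }
  # identical groups (copied data): all stage-1 p = 1
  ids <- sprintf("s%02d", 1:8)
  vals <- stats::setNames(as.list(rep(0.3, 8)), ids)
  tab <- mk_table(vals)
  cohort <- data.frame(subject_id = ids, group = rep(c("case", "control"), 4))
  rep0 <- compare_groups(tab, cohort)
  expect_true(all(rep0$stage1$p_value == 1))
  expect_null(rep0$stage2)
  # a strong low-gamma-only effect triggers stage 2 for that band alone
  ids <- sprintf("s%02d", 1:20)
  cohort <- data.frame(subject_id = ids,
                       group = rep(c("case", "control"), each = 10))
  tab2 <- do.call(rbind, lapply(seq_along(ids), function(i) {
    g <- cohort$group[i]
    data.frame(subject_id = ids[i],
               channel_a = rep(c("Cz", "Cz", "Pz"), times = 4),
               channel_b = rep(c("Pz", "Fz", "Fz"), times = 4),
               band = rep(bands, each = 3),
               value = c(rnorm(9, 0, 0.01),
                         rnorm(3, ifelse(g == "control", 0.5, 0), 0.01)))
  }))
  rep2 <- compare_groups(tab2, cohort)
  expect_true(rep2$stage1$significant[rep2$stage1$band == "low_gamma"])
  expect_false(any(rep2$stage1$significant[rep2$stage1$band != "low_gamma"]))
  expect_equal(unique(rep2$stage2$band), "low_gamma")
  expect_equal(nrow(rep2$stage2), 3)
  expect_true(all(rep2$stage2$p_value < 0.05))
  # subjects without connectivity rows are excluded with a warning
  cohort3 <- rbind(cohort, data.frame(subject_id = "ghost", group = "case"))
  expect_warning(compare_groups(tab2, cohort3), "ghost")
})

test_that("stage-1 type-I error is near nominal under the null", {
  set.seed(58)
  bands <- c("theta", "alpha", "beta", "low_gamma")
  ids <- c(sprintf("case%02d", 1:15), sprintf("control%02d", 1:22))
  cohort <- data.frame(subject_id = ids,
                       group = rep(c("case", "control"), c(15, 22)))
  hits <- 0L; total <- 0L
  for (r in 1:500) {
    tab <- expand.grid(subject_id = ids, channel_a = "Cz", channel_b = "Pz",
                       band = bands, stringsAsFactors = FALSE)
    tab$value <- rnorm(nrow(tab))
    rep <- compare_groups(tab, cohort)
    hits <- hits + sum(rep$stage1$p_value < 0.05)
    total <- total + nrow(rep$stage1)
  }
  expect_gte(hits / total, 0.03)
  expect_lte(hits / total, 0.07)
})

test_that("FA screening tests every ROI row with Holm adjustment", {
  set.seed(59)
  vocab <- default_roi_vocabulary()
  ids <- c(sprintf("case%02d", 1:12), sprintf("control%02d", 1:17))
  cohort <- data.frame(subject_id = ids,
                       group = rep(c("case", "control"), c(12, 17)))
  roi_table <- do.call(rbind, lapply(ids, function(id) {
    data.frame(subject_id = id, roi = vocab$roi, side = vocab$side,
               fa = vocab$baseline_fa + rnorm(nrow(vocab), sd = 0.005))
  }))
  scr <- fa_group_screen(roi_table, cohort)
  expect_equal(nrow(scr), 28)
  expect_true(all(scr$p_adjusted >= scr$p_value))
  expect_equal(scr$df, rep(27, 28))
  # a strong one-ROI effect is detected as the smallest raw p nearly always
  hit <- 0L
  for (r in 1:30) {
    rt <- do.call(rbind, lapply(ids, function(id) {
      data.frame(subject_id = id, roi = vocab$roi, side = vocab$side,
                 fa = vocab$baseline_fa + rnorm(nrow(vocab), sd = 0.005))
    }))
    target <- rt$roi == "inferior_cerebellar_peduncle" & rt$side == "right" &
      grepl("^case", rt$subject_id)
    rt$fa[target] <- rt$fa[target] - 0.02
    scr2 <- fa_group_screen(rt, cohort)
    best <- which.min(scr2$p_value)
    hit <- hit + (scr2$roi[best] == "inferior_cerebellar_peduncle" &&
                    scr2$side[best] == "right")
  }
  expect_gte(hit / 30, 0.9)
})

test_that("structure-function correlation restricts to group and tract", {
  set.seed(60)
  ids <- sprintf("case%02d", 1:12)
  cohort <- data.frame(subject_id = c(ids, "control01", "control02"),
                       group = c(rep("case", 12), "control", "control"))
  z <- rnorm(12)
  synchrony <- data.frame(subject_id = ids, z = z)
  fa <- 0.28 + 0.01 * z + rnorm(12, sd = 0.002)
  roi_table <- rbind(
    data.frame(subject_id = ids, roi = "inferior_cerebellar_peduncle",
               side = "right", fa = fa),
    data.frame(subject_id = ids, roi = "fornix", side = "left",
               fa = rep(0.296, 12))
  )
  r <- structure_function_correlation(synchrony, roi_table,
                                      "inferior_cerebellar_peduncle", "right",
                                      "case", cohort)
  expect_equal(r$n, 12)
  expect_gt(r$r, 0.5)
  # constant FA: zero variance error propagated
  expect_error(
    structure_function_correlation(synchrony, roi_table, "fornix", "left",
                                   "case", cohort),
    "zero variance")
})
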