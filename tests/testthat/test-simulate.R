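test_that("expected_wpli matches closed-form endpoints", {
  expect_equal(expected_wpli(Inf, pi / 2), 1)
  expect_equal(expected_wpli(Inf, 0.3), 1)
  expect_equal(expected_wpli(Inf, 0), 0)
  for (k in c(0, 0.5, 2, 10)) expect_equal(expected_wpli(k, 0), 0)
  expect_equal(expected_wpli(0, pi / 2), 0)  # uniform phase difference
})

test_that("expected_wpli quadrature agrees with a Monte-Carlo sampling oracle", {
  set.seed(42)
  for (case in list(c(1, pi / 2), c(2, pi / 4), c(5, 1))) {
    kappa <- case[1]; delta <- case[2]
    eta <- wpliconn:::rvonmises(1e6, kappa)
    s <- sin(delta + eta)
    # MC estimate of |E s| / E |s| with batch-based standard error
    batches <- matrix(s, ncol = 100)
    ests <- abs(colMeans(batches)) / colMeans(abs(batches))
    mc <- abs(mean(s)) / mean(abs(s))
    se <- stats::sd(ests) / sqrt(ncol(batches))
    expect_lt(abs(expected_wpli(kappa, delta) - mc), 3 * se + 1e-6)
  }
})

test_that("von Mises sampler has the right circular moments", {
  set.seed(7)
  for (kappa in c(0.5, 2, 8)) {
    x <- wpliconn:::rvonmises(2e5, kappa)
    a1 <- besselI(kappa, 1) / besselI(kappa, 0)
    expect_lt(abs(mean(cos(x)) - a1), 4 / sqrt(2e5) + 3e-3)
    expect_lt(abs(mean(sin(x))), 4 / sqrt(2e5))
  }
  expect_identical(wpliconn:::rvonmises(5, Inf), rep(0, 5))
})

test_that("simulated recordings have the configured shape and stored truth", {
  cfg <- simulation_config(fs_hz = 512, duration_s = 10)
  set.seed(1)
  rec <- simulate_recording(cfg, 3)
  expect_s3_class(rec, "continuous_recording")
  expect_equal(nrow(rec$data), 512 * 10)
  expect_equal(rec$labels, c(cfg$channel_labels, cfg$eog_labels))
  expect_equal(attr(rec, "truth")$kappa, rep(3, 6))
  # same seed, same bits
  set.seed(99); a <- simulate_recording(cfg, 2)
  set.seed(99); b <- simulate_recording(cfg, 2)
  expect_identical(a$data, b$data)
})

test_that("EOG channels carry the ocular source unmixed, so regression removes it", {
  cfg <- simulation_config(fs_hz = 256, duration_s = 20, amp_uv = 0,
                           zero_lag_gain = 0, noise_sd = 0)
  set.seed(3)
  rec <- simulate_recording(cfg, 1)
  # scalp channels are pure leakage of e(t); residual after regression ~ 0
  corrected <- correct_eog(rec)
  for (ch in eeg_labels(rec)) {
    expect_lt(sqrt(mean(corrected$data[, ch]^2)),
              1e-8 * sqrt(mean(rec$data[, ch]^2) + 1e-30))
  }
  # the two EOG electrodes are opposite-polarity views of the same source
  expect_equal(cor(rec$data[, "VEOGup"], rec$data[, "VEOGdown"]), -1)
})

test_that("perfect quarter-cycle lag gives debiased WPLI-square of 1 at f0", {
  cfg <- fast_config(duration_s = 30, lag_rad = c(0, pi / 2),
                     zero_lag_gain = 0, noise_sd = 0)
  set.seed(11)
  rec <- simulate_recording(cfg, Inf)
  d <- debiased_wpli_square(epoch_cross_spectra(epoch(rec), c("Cz", "Pz")))
  expect_equal(d$values[d$freqs_hz == cfg$f0_hz], 1, tolerance = 1e-9)
})

test_that("independent phases (kappa = 0) give band synchrony centred at zero", {
  set.seed(21)
  cfg <- fast_config()
  vals <- replicate(200, {
    rec <- simulate_recording(cfg, 0)
    global_band_synchrony(epoch(rec))
  })
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("zero-lag common coupling is invisible to the lag-based measures", {
  set.seed(22)
  cfg <- fast_config(lag_rad = c(0, 0), zero_lag_gain = 3)
  vals <- replicate(150, {
    rec <- simulate_recording(cfg, Inf)   # deterministic identical phases
    global_band_synchrony(epoch(rec))
  })
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("cohorts have one FA row per subject and ROI, linked to stored truth", {
  cfg <- fast_config(duration_s = 2, n_per_group = c(case = 3, control = 4),
                     seed = 123)
  cohort <- simulate_cohort(cfg)
  expect_equal(nrow(cohort$metadata), 7)
  expect_equal(length(cohort$recordings), 7)
  vocab <- default_roi_vocabulary()
  expect_equal(nrow(cohort$fa_table), 7 * nrow(vocab))
  expect_equal(sort(unique(cohort$fa_table$subject_id)),
               sort(cohort$metadata$subject_id))
  expect_true(all(cohort$fa_table$fa >= 0 & cohort$fa_table$fa <= 1))
  expect_equal(names(cohort$truth$kappa), cohort$metadata$subject_id)
  expect_true(all(cohort$truth$kappa >= 0))
  # bit-reproducible given config + seed
  cohort2 <- simulate_cohort(cfg)
  expect_identical(cohort$fa_table, cohort2$fa_table)
  expect_identical(cohort$recordings[[1]]$data, cohort2$recordings[[1]]$data)
})

test_that("fa_slope = 0 decouples FA from the coupling strength", {
  cfg <- fast_config(duration_s = 2, n_per_group = c(case = 50, control = 50),
                     fa_slope = 0, seed = 5)
  cohort <- simulate_cohort(cfg)
  fa <- cohort$fa_table
  icp <- fa[fa$roi == "inferior_cerebellar_peduncle" & fa$side == "right", ]
  icp <- icp[match(names(cohort$truth$kappa), icp$subject_id), ]
  r <- cor(icp$fa, cohort$truth$kappa)
  expect_lt(abs(r), 3 / sqrt(nrow(icp)))  # 3 SE of a null correlation
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(fs_hz = 50, f0_hz = 32), "exceed")
  expect_error(simulation_config(duration_s = 10.5), "1-s blocks")
  expect_error(simulation_config(kappa_sd = -1), ">= 0")
  expect_error(simulation_config(fa_noise_sd = -0.1), ">= 0")
  expect_error(simulation_config(noise_sd = NaN), "non-finite")
  expect_error(simulate_recording(fast_config(duration_s = 2), -1), "kappa")
  expect_error(
    simulate_cohort(fast_config(duration_s = 2,
                                n_per_group = c(case = 1, control = 5))),
    "at least 2")
})
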