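test_that("SNR concentrates power where it is constructed to be", {
  withr::local_seed(3)
  fs <- 10
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  # 6 beats/min sinusoid with white noise 40 dB down
  x <- sin(2 * pi * 0.1 * t) + rnorm(length(t), sd = 0.01)
  expect_gt(bcg_snr(x, fs = fs)$snr, 10)

  # out-of-band tone: 20 beats/min
  y <- sin(2 * pi * (20 / 60) * t) + rnorm(length(t), sd = 0.01)
  expect_lt(bcg_snr(y, fs = fs)$snr, 0.2)

  # flat spectrum: expectation ~ band widths 4 / 52
  snrs <- replicate(5, bcg_snr(rnorm(length(t)), fs = fs)$snr)
  expect_true(all(abs(snrs - 4 / 52) / (4 / 52) < 0.5))

  # scale invariance
  r <- bcg_snr(x, fs = fs)
  r2 <- bcg_snr(1234 * x, fs = fs)
  expect_equal(r2$snr, r$snr, tolerance = 1e-10)

  expect_error(bcg_snr(rnorm(100), fs = 10), class = "accelbcg_resolution_error")
})

test_that("multi-window SNR weights windows by length", {
  withr::local_seed(9)
  fs <- 10
  t1 <- seq(0, 120 - 1 / fs, by = 1 / fs)
  t2 <- seq(0, 480 - 1 / fs, by = 1 / fs)
  w1 <- sin(2 * pi * 0.1 * t1) + rnorm(length(t1), sd = 0.05)
  w2 <- sin(2 * pi * 0.1 * t2) + rnorm(length(t2), sd = 0.05)
  r <- bcg_snr(list(w1, w2), fs = fs)
  expect_equal(r$n_windows, 2)
  expect_gt(r$snr, 10)
  # a short window below the resolution floor is dropped, not fatal
  r2 <- bcg_snr(list(w2, rnorm(100)), fs = fs)
  expect_equal(r2$n_windows, 1)
})

test_that("OLS equivalence recovers exact affine relations", {
  withr::local_seed(1)
  hr_e <- tibble::tibble(time_s = seq(5, 500, by = 5), hr_bpm = runif(100, 40, 60))
  same <- ols_equivalence(hr_e, hr_e, pairing_tol_s = 1)
  expect_equal(same$slope, 1, tolerance = 1e-10)
  expect_equal(same$intercept, 0, tolerance = 1e-8)
  expect_equal(same$mape_mean, 0, tolerance = 1e-10)
  expect_gt(same$p_slope_vs_1, 0.99)
  expect_gt(same$p_intercept_vs_0, 0.99)

  shifted <- dplyr::mutate(hr_e, hr_bpm = hr_bpm + 2)
  eq <- ols_equivalence(shifted, hr_e, pairing_tol_s = 1)
  expect_equal(eq$slope, 1, tolerance = 1e-10)
  expect_equal(eq$intercept, 2, tolerance = 1e-8)

  td <- tidy(eq)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$null.value, c(0, 1))
  expect_equal(glance(eq)$n, 100)

  expect_error(ols_equivalence(hr_e[1:2, ], hr_e[1:2, ], 1),
               class = "accelbcg_insufficient_data_error")
  const <- dplyr::mutate(hr_e, hr_bpm = 50)
  expect_error(ols_equivalence(const, const, 1), class = "accelbcg_degenerate_error")
})

test_that("OLS matches the closed-form normal-equation solution", {
  withr::local_seed(6)
  x <- runif(40, 30, 70)
  y <- 0.9 * x + 3 + rnorm(40)
  hr_e <- tibble::tibble(time_s = seq_along(x), hr_bpm = x)
  hr_b <- tibble::tibble(time_s = seq_along(x), hr_bpm = y)
  eq <- ols_equivalence(hr_b, hr_e, pairing_tol_s = 0.1)
  beta <- solve(crossprod(cbind(1, x)), crossprod(cbind(1, x), y))
  expect_equal(eq$intercept, beta[1], tolerance = 1e-10)
  expect_equal(eq$slope, beta[2], tolerance = 1e-10)
})

test_that("pairing drops unmatched intervals and respects the tolerance", {
  hr_b <- tibble::tibble(time_s = c(1, 2, 3, 50), hr_bpm = c(10, 20, 30, 40))
  hr_e <- tibble::tibble(time_s = c(1.1, 2.05, 3.4, 8), hr_bpm = c(11, 21, 31, 99))
  p <- accelbcg:::pair_nearest(hr_b, hr_e, tol_s = 0.5)
  expect_equal(nrow(p), 3)
  expect_equal(p$ecg, c(11, 21, 31))
  expect_equal(attr(p, "n_dropped"), 2)
})

test_that("Theil-Sen matches the brute-force pairwise-slope median", {
  expect_equal(theil_sen_trend(c(0, 0.5, 1), c(1, 2, 3))$slope, 2)
  expect_equal(theil_sen_trend(c(0, 0.5, 1), c(1, 2, 3))$intercept, 1)

  withr::local_seed(13)
  for (n in c(10, 50, 200)) {
    x <- runif(n)
    y <- 1.7 * x + rnorm(n, sd = 0.3)
    fit <- theil_sen_trend(x, y)
    expect_equal(fit$slope, oracle_theil_sen_slope(x, y), tolerance = 1e-12)
  }

  # robust to 30% gross outliers
  x <- runif(50)
  y <- x
  y[1:15] <- y[1:15] + 100
  fit <- theil_sen_trend(x, y)
  expect_gt(fit$slope, 0.8)
  expect_lt(fit$slope, 1.2)

  flat <- theil_sen_trend(runif(20), rep(5, 20))
  expect_equal(flat$slope, 0)
  expect_gte(flat$p_one_sided, 0.5)

  expect_error(theil_sen_trend(rep(1, 5), rnorm(5)), class = "accelbcg_degenerate_error")
  expect_error(theil_sen_trend(1:2, 1:2), class = "accelbcg_insufficient_data_error")
})

test_that("dive-phase profile pools normalized times across retained dives", {
  dives <- tibble::tibble(dive = 1:2,
                          start_s = c(0, 1000), end_s = c(600, 1600),
                          duration_s = 600, max_depth_m = 30, retained = TRUE)
  # exact ramp 4 -> 8 beats/min in each dive
  xs <- seq(0.05, 0.95, by = 0.1)
  hr <- tibble::tibble(time_s = c(xs * 600, 1000 + xs * 600),
                       hr_bpm = rep(4 + 4 * xs, 2))
  fit <- dive_phase_profile(dives, hr)
  expect_equal(fit$hr_start_bpm, 4, tolerance = 1e-9)
  expect_equal(fit$hr_end_bpm, 8, tolerance = 1e-9)
  expect_lt(fit$p_one_sided, 0.001)

  # two-point slope: (8.1 - 4.5) / 0.8
  one <- dives[1, ]
  hr2 <- tibble::tibble(time_s = c(0.1, 0.9, 0.5) * 600, hr_bpm = c(4.5, 8.1, 6.3))
  fit2 <- dive_phase_profile(one, hr2)
  expect_equal(fit2$slope, 4.5, tolerance = 1e-9)

  flat <- tibble::tibble(time_s = seq(50, 550, by = 50), hr_bpm = 6)
  fit3 <- dive_phase_profile(one, flat)
  expect_equal(fit3$slope, 0)
  expect_gt(fit3$p_one_sided, 0.05)

  none <- dplyr::mutate(dives, retained = FALSE)
  expect_error(dive_phase_profile(none, hr), class = "accelbcg_insufficient_data_error")
})
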