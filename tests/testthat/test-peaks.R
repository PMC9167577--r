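test_that("candidate extraction counts maxima of a slow sinusoid", {
  fs <- 400
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 0.5 * t)
  pk <- find_candidate_peaks(x, min_distance_s = 0.5, fs = fs)
  expect_equal(nrow(pk), 30) # maxima at 0.5 + 2k s on [0, 60)
  expect_equal(pk$time_s, seq(0.5, 58.5, by = 2), tolerance = 1e-3)

  ramp <- seq(0, 1, length.out = 1000)
  expect_equal(nrow(find_candidate_peaks(ramp, 0.5, fs = 100)), 0)
  flat <- rep(1, 1000)
  expect_equal(nrow(find_candidate_peaks(flat, 0.5, fs = 100)), 0)
})

test_that("greedy pruning keeps the higher of two close peaks", {
  fs <- 100
  x <- rep(0, 200)
  x[50] <- 1.0   # t = 0.49
  x[80] <- 1.5   # t = 0.79, 0.3 s away
  pk <- find_candidate_peaks(x, min_distance_s = 0.5, fs = fs)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$index, 80)
  # ties keep the earlier peak
  x[80] <- 1.0
  pk2 <- find_candidate_peaks(x, min_distance_s = 0.5, fs = fs)
  expect_equal(pk2$index, 50)
})

test_that("prominence follows the topographic definition", {
  x <- c(0, 3, 1, 5, 0)
  expect_equal(peak_prominence(x, 2), 2) # valley 1 toward higher neighbor 5
  expect_equal(peak_prominence(x, 4), 5) # global max: height above global min
  iso <- c(rep(0, 10), 4, rep(0, 10))
  expect_equal(peak_prominence(iso, 11), 4)
  expect_error(peak_prominence(x, 3), class = "accelbcg_parameter_error")
})

test_that("peak extraction and prominence match brute-force oracles exactly", {
  withr::local_seed(11)
  for (rep in 1:4) {
    n <- 5000
    fs <- 100
    x <- as.numeric(stats::filter(rnorm(n), rep(1 / 21, 21), sides = 2))
    x[is.na(x)] <- 0
    min_d <- 0.4
    pk <- find_candidate_peaks(x, min_distance_s = min_d, fs = fs)
    want <- oracle_candidate_peaks(x, min_sep = min_d * fs)
    expect_identical(pk$index, want)
    expect_identical(pk$height, x[want])
    expect_equal(pk$prominence,
                 vapply(want, function(i) oracle_prominence(x, i), numeric(1)),
                 tolerance = 1e-12)
  }
})

fake_peak_set <- function(height, prominence) {
  structure(tibble::tibble(time_s = seq_along(height), index = seq_along(height),
                           height = height, prominence = prominence),
            class = c("peak_set", "tbl_df", "tbl", "data.frame"),
            min_distance_s = 1, fs = 1)
}

test_that("clustering splits two separated clusters at a threshold between them", {
  withr::local_seed(5)
  # reference at (10, 10); low cluster at distance ~0.1, high at ~5
  d_low <- runif(20, 0.05, 0.15)
  d_high <- runif(20, 4.8, 5.2)
  d_low[1] <- 0 # the reference itself
  h <- 10 - c(d_low, d_high) / sqrt(2)
  p <- 10 - c(d_low, d_high) / sqrt(2)
  ps <- fake_peak_set(h, p)
  out <- cluster_peaks(ps)
  thr <- attr(out, "threshold")
  expect_false(attr(out, "degenerate"))
  expect_gt(thr, max(d_low))
  expect_lt(thr, min(d_high))
  expect_equal(sum(out$label == "major"), 20)
  expect_equal(out$distance[1], 0)
  expect_true(all(out$distance >= 0))
})

test_that("degenerate peak sets are labeled all-major", {
  two <- fake_peak_set(c(1, 2), c(1, 2))
  out <- cluster_peaks(two)
  expect_true(all(out$label == "major"))
  expect_identical(attr(out, "threshold"), Inf)
  expect_true(attr(out, "degenerate"))

  same <- fake_peak_set(rep(2, 10), rep(2, 10))
  out2 <- cluster_peaks(same)
  expect_true(all(out2$label == "major"))
  expect_true(attr(out2, "degenerate"))

  empty <- fake_peak_set(numeric(0), numeric(0))
  expect_equal(nrow(cluster_peaks(empty)), 0)
})

test_that("adding a far-away peak never flips existing majors", {
  withr::local_seed(8)
  base_d <- c(0, runif(14, 0, 0.2), runif(15, 8, 8.4)) # separation >> spread
  h <- 10 - base_d / sqrt(2)
  out1 <- cluster_peaks(fake_peak_set(h, h))
  major1 <- out1$label[1:15]
  h2 <- c(h, 10 - 12 / sqrt(2))
  out2 <- cluster_peaks(fake_peak_set(h2, h2))
  expect_identical(out2$label[1:15], major1)
  expect_true(all(out2$label[1:15] == "major"))
})

test_that("beats and instantaneous heart rate follow their definitions", {
  ps <- fake_peak_set(c(5, 1, 4, 2, 6, 3, 5, 1), rep(1, 8))
  ps$label <- rep(c("major", "minor"), 4)
  expect_equal(nrow(beats_from_peaks(ps)), 4)
  expect_equal(nrow(beats_from_peaks(fake_peak_set(numeric(0), numeric(0)))), 0)

  hr <- instantaneous_hr(tibble::tibble(time_s = c(0, 10, 20, 30)))
  expect_equal(hr$hr_bpm, c(6, 6, 6))
  expect_equal(hr$time_s, c(5, 15, 25))
  expect_equal(instantaneous_hr(tibble::tibble(time_s = c(0, 0.5)))$hr_bpm, 120)
  expect_equal(instantaneous_hr(tibble::tibble(time_s = c(0, 15, 22.5)))$hr_bpm, c(4, 8))
  expect_equal(nrow(instantaneous_hr(tibble::tibble(time_s = 3))), 0)
})

test_that("candidate counts are bounded by record duration", {
  for (seed in 1:3) {
    rec <- quick_sim(duration_s = 60, seed = seed)
    bc <- compute_bcg(rec$accel, bcg_config("killer_whale", axes_mode = "3d"))
    pk <- cluster_peaks(find_candidate_peaks(bc))
    beats <- beats_from_peaks(pk)
    expect_lte(nrow(beats), nrow(pk))
    expect_lte(nrow(pk), ceiling(60 / attr(pk, "min_distance_s")) + 1)
  }
})
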