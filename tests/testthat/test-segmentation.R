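trapezoid_depth <- function(times, dives, fs = 1) {
  # dives: list of c(start, end, depth); 20 s ramps inside each dive
  d <- rep(0, length(times))
  for (dv in dives) {
    sel <- times >= dv[1] & times <= dv[2]
    tt <- times[sel]
    ramp <- pmin(1, pmin((tt - dv[1]) / 20, (dv[2] - tt) / 20))
    d[sel] <- dv[3] * pmax(ramp, 0)
  }
  tag_series(tibble::tibble(time_s = times, depth_m = d), fs = fs, kind = "depth_m")
}

test_that("dive retention applies the >10 m and >5 min filters strictly", {
  t <- seq(0, 3000, by = 1)
  cases <- list(
    list(dv = c(100, 700, 30), retained = TRUE),   # 600 s to 30 m
    list(dv = c(100, 700, 8), retained = FALSE),   # too shallow
    list(dv = c(100, 220, 30), retained = FALSE))  # 120 s, too short
  for (cs in cases) {
    dives <- segment_dives(trapezoid_depth(t, list(cs$dv)))
    expect_equal(nrow(dives), 1)
    expect_identical(dives$retained, cs$retained)
    expect_equal(dives$max_depth_m, cs$dv[3])
  }
  expect_equal(nrow(segment_dives(trapezoid_depth(t, list()))), 0)
})

test_that("dive boundaries are interpolated at the 2 m crossing", {
  t <- seq(0, 1000, by = 1)
  dives <- segment_dives(trapezoid_depth(t, list(c(100, 700, 30))))
  # ramp is 1.5 m/s; 2 m crossing at 100 + 2/1.5 s
  expect_equal(dives$start_s, 100 + 2 / 1.5, tolerance = 0.01)
  expect_equal(dives$end_s, 700 - 2 / 1.5, tolerance = 0.01)
  expect_equal(dives$duration_s, dives$end_s - dives$start_s)
})

test_that("a profile with k qualifying dives yields exactly k retained segments", {
  t <- seq(0, 20000, by = 1)
  for (k in c(1, 3, 7, 10)) {
    dvs <- lapply(seq_len(k) - 1, function(i) c(200 + i * 800, 600 + i * 800, 25))
    # one disqualified shallow dip appended
    dvs <- c(dvs, list(c(200 + k * 800, 600 + k * 800, 5)))
    dives <- segment_dives(trapezoid_depth(t, dvs))
    expect_equal(sum(dives$retained), k)
    expect_equal(nrow(dives), k + 1)
    # dive intervals are disjoint and time-ordered
    expect_true(all(diff(dives$start_s) > 0))
    expect_true(all(dives$end_s[-nrow(dives)] <= dives$start_s[-1]))
  }
})

test_that("normalized dive time maps start to 0, end to 1", {
  dv <- tibble::tibble(start_s = 100, end_s = 700)
  expect_equal(normalize_dive_time(dv, 100), 0)
  expect_equal(normalize_dive_time(dv, 700), 1)
  expect_equal(normalize_dive_time(dv, 400), 0.5)
  expect_error(normalize_dive_time(dv, 800), class = "accelbcg_parameter_error")
})

make_gyro <- function(omega, fs) {
  tag_series(tibble::tibble(time_s = (seq_along(omega) - 1) / fs, sway = omega),
             fs = fs, units = "rad s-1")
}

test_that("a quiet record is one motionless window; constant stroking none", {
  fs <- 10
  quiet <- make_gyro(rep(0, 600 * fs), fs)
  w <- find_motionless(quiet, smooth_s = 5, min_dur_s = 60)
  expect_equal(nrow(w), 1)
  expect_gt(w$duration_s, 580) # covers (almost) the record

  t <- (seq_len(600 * fs) - 1) / fs
  stroking <- make_gyro(10 * sin(2 * pi * 0.25 * t), fs)
  w2 <- find_motionless(stroking, smooth_s = 5, threshold = 1, min_dur_s = 60)
  expect_equal(nrow(w2), 0)
})

test_that("alternating quiet/stroking segments are recovered within a smoothing window", {
  fs <- 10
  withr::local_seed(2)
  t <- seq(0, 900 - 1 / fs, by = 1 / fs)
  cycle <- t %% 180
  stroke <- cycle >= 120 # 120 s quiet, 60 s stroking
  omega <- 0.02 * rnorm(length(t)) + ifelse(stroke, sin(2 * pi * 0.25 * t), 0)
  w <- find_motionless(make_gyro(omega, fs), smooth_s = 5, min_dur_s = 60)
  expect_equal(nrow(w), 5)
  starts_true <- seq(0, 720, by = 180)
  # boundaries land within about one smoothing window (plus the deliberate
  # one-window trim) of the true quiet-segment edges
  expect_true(all(abs(w$start_s - starts_true) <= 2 * 5))
  expect_true(all(abs(w$end_s - (starts_true + 120)) <= 2 * 5))
  # windows never reach into a stroking burst by more than the smoothing window
  expect_true(all(w$end_s <= starts_true + 120 + 5))
  expect_true(all(w$start_s >= starts_true - 5))
})

test_that("stroking bursts in simulated dive records gate the windows", {
  cfg <- sim_config(fs = 50, duration_s = 3 * 260 + 40,
                    hr_profile = hr_dive_ramp(4, 8),
                    dive_profile = dive_square(depth_m = 25, dive_s = 220,
                                               surface_s = 40, n_dives = 3),
                    seed = 21)
  rec <- simulate_record(cfg)
  w <- find_motionless(rec$gyro, min_dur_s = 60)
  expect_equal(nrow(w), 3) # one quiet bottom phase per dive
  dives <- segment_dives(rec$depth)
  expect_equal(nrow(dives), 3)
  # every window lies inside a dive's bottom phase
  for (k in seq_len(nrow(w))) {
    inside <- any(w$start_s[k] >= dives$start_s & w$end_s[k] <= dives$end_s)
    expect_true(inside)
  }
})
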