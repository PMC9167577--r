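test_that("validation workflow: BCG heart rate is equivalent to the reference", {
  cfg <- sim_config(duration_s = 300, hr_profile = hr_constant(50),
                    hrv_sd = 0.05, seed = 11)
  rec <- simulate_record(cfg)
  v <- run_validation(rec$accel, rec$ecg_beats)
  eq <- v$equivalence
  expect_gt(eq$n, 100)
  # 95% CIs cover the identity line
  expect_lt(abs(eq$slope - 1), 2 * eq$slope_se)
  expect_lt(abs(eq$intercept), 2 * eq$intercept_se)
  expect_lt(eq$mape_mean, 5)
  expect_s3_class(autoplot(eq), "ggplot")

  expect_error(run_validation(rec$accel, tibble::tibble(time_s = numeric(0))),
               class = "accelbcg_insufficient_data_error")
})

test_that("validation artifacts are reproducible byte for byte", {
  cfg <- sim_config(fs = 200, duration_s = 120, hr_profile = hr_constant(45),
                    hrv_sd = 0.05, seed = 23)
  rec <- simulate_record(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_validation(rec$accel, rec$ecg_beats, out_dir = d1)
  run_validation(rec$accel, rec$ecg_beats, out_dir = d2)
  for (f in setdiff(list.files(d1), "manifest.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  m <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_named(m$files, setdiff(list.files(d1), "manifest.json"), ignore.order = TRUE)
})

field_rec <- function(fs = 100, n_dives = 3, seed = 31) {
  simulate_record(sim_config(
    fs = fs, duration_s = n_dives * 460 + 60,
    hr_profile = hr_dive_ramp(4, 8),
    dive_profile = dive_square(depth_m = 30, dive_s = 400, surface_s = 60,
                               n_dives = n_dives),
    seed = seed))
}

# Simulated packets ride at 5 Hz, so field analyses use a window matched to
# the waveform width (0.5 s) with the blue-whale band.
sim_field_config <- bcg_config("blue_whale", window_s = 0.5, axes_mode = "3d")

test_that("field workflow gates on dives and windows and fits the trend", {
  rec <- field_rec()
  f <- run_field(rec$accel, rec$gyro, rec$depth, config = sim_field_config)
  expect_equal(sum(f$dives$retained), 3)
  expect_equal(nrow(f$windows), 3)
  expect_gt(nrow(f$beats), 30)
  expect_s3_class(f$snr_1d, "bcg_snr")
  expect_s3_class(f$snr_3d, "bcg_snr")
  expect_false(is.null(f$trend))
  expect_gt(f$trend$slope, 0)
  expect_lt(f$trend$p_one_sided, 0.05)
  # heart rate is only ever measured inside motionless windows
  in_window <- vapply(f$hr$time_s, function(tt) {
    any(tt >= f$windows$start_s & tt <= f$windows$end_s)
  }, logical(1))
  expect_true(all(in_window))
})

test_that("field workflow diagnoses all-stroking and all-surface records", {
  rec <- simulate_record(sim_config(fs = 50, duration_s = 400, stroke_duty = 1,
                                    seed = 3))
  expect_error(run_field(rec$accel, rec$gyro, rec$depth),
               class = "accelbcg_no_windows_error")

  calm <- simulate_record(sim_config(fs = 50, duration_s = 400, seed = 5))
  f <- run_field(calm$accel, calm$gyro, calm$depth, config = sim_field_config)
  expect_equal(nrow(f$dives), 0)
  expect_null(f$trend)
  expect_match(paste(f$diagnostics, collapse = " "), "retained dives")
  expect_gt(nrow(f$hr), 0) # heart rate still measured in motionless windows
})

test_that("repeated field runs on the same record are idempotent", {
  rec <- field_rec(fs = 50, n_dives = 2, seed = 41)
  f1 <- run_field(rec$accel, rec$gyro, rec$depth, config = sim_field_config)
  f2 <- run_field(rec$accel, rec$gyro, rec$depth, config = sim_field_config)
  expect_identical(f1$beats, f2$beats)
  expect_identical(f1$snr_3d$snr, f2$snr_3d$snr)
  expect_identical(f1$trend$slope, f2$trend$slope)
})

test_that("result objects render tidy summaries and plots", {
  rec <- field_rec(fs = 100, n_dives = 2, seed = 41)
  f <- run_field(rec$accel, rec$gyro, rec$depth, config = sim_field_config)
  expect_s3_class(glance(f$snr_3d), "tbl_df")
  expect_s3_class(tidy(f$trend), "tbl_df")
  expect_s3_class(autoplot(f$trend), "ggplot")
  expect_s3_class(autoplot(f$snr_3d), "ggplot")
  expect_s3_class(plot_depth_profile(rec$depth, f$dives, f$windows), "ggplot")
  bc <- compute_bcg(rec$accel, bcg_config("killer_whale", axes_mode = "3d"),
                    fs = 100)
  expect_s3_class(autoplot(bc, beats = f$beats), "ggplot")
})
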