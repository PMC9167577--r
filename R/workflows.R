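# End-to-end workflows mirroring the two study designs: a controlled
# validation against reference ECG beats, and a field application gated by
# dive and motionless-period segmentation.

#' Controlled validation workflow: BCG versus reference ECG
#'
#' Runs the 1d pipeline on a motionless acceleration record, detects beats,
#' derives instantaneous heart rate, and tests equivalence against the
#' heart rate implied by reference ECG R-wave times.
#'
#' @param accel Acceleration [tag_series()].
#' @param ecg_beats Tibble of reference beat times (`time_s`).
#' @param config A [bcg_config()]; the killer-whale preset (0.5 s window,
#'   1-25 Hz band) by default.
#' @param out_dir Optional directory; when given, beats, heart rates, peak
#'   table, stage signals and a JSON run manifest are written there.
#' @param fs Sampling rate (Hz) if the series carries none.
#' @return A list of class `bcg_validation`: `equivalence`
#'   ([ols_equivalence()] result), `bcg`, `peaks`, `beats`, `hr_bcg`,
#'   `hr_ecg`, `config`.
#' @export
run_validation <- function(accel, ecg_beats, config = bcg_config("killer_whale"),
                           out_dir = NULL, fs = NULL) {
  if (!nrow(ecg_beats)) {
    abort("Reference ECG beat list is empty.", class = "accelbcg_insufficient_data_error")
  }
  fs <- series_fs(accel, fs)
  bcg <- compute_bcg(accel, config, fs = fs)
  peaks <- cluster_peaks(find_candidate_peaks(bcg))
  beats <- beats_from_peaks(peaks)
  hr_bcg <- instantaneous_hr(beats)
  hr_ecg <- instantaneous_hr(ecg_beats)
  eq <- ols_equivalence(hr_bcg, hr_ecg, pairing_tol_s = config$window_s)
  out <- structure(list(equivalence = eq, bcg = bcg, peaks = peaks,
                        beats = beats, hr_bcg = hr_bcg, hr_ecg = hr_ecg,
                        config = config),
                   class = "bcg_validation")
  if (!is.null(out_dir)) write_validation_artifacts(out, out_dir)
  out
}

#' @export
print.bcg_validation <- function(x, ...) {
  cat("<bcg_validation>\n")
  print(x$equivalence)
  invisible(x)
}

#' Field workflow: dive-gated BCG analysis
#'
#' The full field application: segment dives from depth, find motionless
#' windows from the gyroscope, construct 1d and 3d BCGs inside each window,
#' detect beats (3d BCG) per window, derive heart rate, compare the 1d and
#' 3d spectral SNRs, and fit the heart-rate trend over normalized dive
#' time.
#'
#' Heart rate is computed within windows only, so no inter-beat interval
#' spans a stroking gap. With no retained dives the trend is skipped (with
#' a diagnostic); with no motionless windows the run stops with an explicit
#' movement-artifact diagnostic.
#'
#' @param accel,gyro,depth Tag series for the three sensors.
#' @param config A [bcg_config()]; the blue-whale preset (2 s window,
#'   1-10 Hz band) by default. The 3d/1d comparison overrides `axes_mode`
#'   internally.
#' @param motionless Named list of overrides for [find_motionless()]
#'   (`axis`, `smooth_s`, `threshold`, `min_dur_s`).
#' @param snr_band_bpm,snr_max_bpm Signal band and spectrum ceiling for
#'   [bcg_snr()], in beats per minute.
#' @param out_dir Optional directory for CSV artifacts plus a JSON
#'   manifest.
#' @param fs Sampling rate (Hz) if the series carry none.
#' @return A list of class `bcg_field`: `dives`, `windows`, `snr_1d`,
#'   `snr_3d`, `beats`, `hr`, `trend` (NULL with a `diagnostics` entry when
#'   not computable), `config`.
#' @export
run_field <- function(accel, gyro, depth, config = bcg_config("blue_whale", axes_mode = "3d"),
                      motionless = list(), snr_band_bpm = c(4, 8),
                      snr_max_bpm = 60, out_dir = NULL, fs = NULL) {
  fs <- series_fs(accel, fs)
  diagnostics <- character(0)
  dives <- segment_dives(depth)
  windows <- do.call(find_motionless, c(list(gyro), motionless))
  if (!nrow(windows)) {
    abort(paste("No motionless windows found: body-movement artifacts mask the",
                "BCG everywhere in this record."),
          class = "accelbcg_no_windows_error")
  }
  min_len_s <- 4 * 60 / snr_band_bpm[1L]
  usable <- windows$duration_s >= min_len_s
  if (!any(usable)) {
    abort(sprintf("No motionless window reaches the %g s needed to resolve %g beats/min.",
                  min_len_s, snr_band_bpm[1L]), class = "accelbcg_resolution_error")
  }
  windows <- windows[usable, , drop = FALSE]

  cfg1 <- config; cfg1$axes_mode <- "1d"
  cfg3 <- config; cfg3$axes_mode <- "3d"
  per_window <- purrr::map(seq_len(nrow(windows)), function(k) {
    sel <- accel$time_s >= windows$start_s[k] & accel$time_s <= windows$end_s[k]
    seg <- tag_series(as.data.frame(accel)[sel, , drop = FALSE], fs = fs)
    b1 <- compute_bcg(seg, cfg1, fs = fs)
    b3 <- compute_bcg(seg, cfg3, fs = fs)
    beats <- beats_from_peaks(cluster_peaks(find_candidate_peaks(b3)))
    list(bcg_1d = b1, bcg_3d = b3, beats = beats,
         hr = instantaneous_hr(beats))
  })
  snr_1d <- bcg_snr(purrr::map(per_window, "bcg_1d"), fs = fs,
                    band_bpm = snr_band_bpm, max_bpm = snr_max_bpm, mode = "1d")
  snr_3d <- bcg_snr(purrr::map(per_window, "bcg_3d"), fs = fs,
                    band_bpm = snr_band_bpm, max_bpm = snr_max_bpm, mode = "3d")
  beats <- dplyr::bind_rows(purrr::map(per_window, "beats"))
  hr <- dplyr::arrange(dplyr::bind_rows(purrr::map(per_window, "hr")), .data$time_s)

  trend <- NULL
  if (!any(dives$retained)) {
    diagnostics <- c(diagnostics,
                     "no retained dives: heart-rate trend over dive time skipped")
  } else if (nrow(hr) < 3L) {
    diagnostics <- c(diagnostics, "fewer than 3 heart-rate points: trend skipped")
  } else {
    trend <- tryCatch(dive_phase_profile(dives, hr),
                      accelbcg_insufficient_data_error = function(e) {
                        diagnostics <<- c(diagnostics, conditionMessage(e))
                        NULL
                      })
  }
  out <- structure(list(dives = dives, windows = windows,
                        snr_1d = snr_1d, snr_3d = snr_3d,
                        beats = beats, hr = hr, trend = trend,
                        diagnostics = diagnostics, config = config),
                   class = "bcg_field")
  if (!is.null(out_dir)) write_field_artifacts(out, out_dir)
  out
}

#' @export
print.bcg_field <- function(x, ...) {
  cat(sprintf("<bcg_field: %d dives (%d retained), %d motionless windows, %d beats>\n",
              nrow(x$dives), sum(x$dives$retained), nrow(x$windows), nrow(x$beats)))
  cat(sprintf("  SNR: 1d %.3g, 3d %.3g\n", x$snr_1d$snr, x$snr_3d$snr))
  if (!is.null(x$trend)) print(x$trend)
  for (d in x$diagnostics) cat("  note:", d, "\n")
  invisible(x)
}

write_validation_artifacts <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_beats(x$beats, file.path(out_dir, "beats.csv"))
  write_hr(x$hr_bcg, file.path(out_dir, "hr_bcg.csv"))
  write_hr(x$hr_ecg, file.path(out_dir, "hr_ecg.csv"))
  write_csv15(as.data.frame(x$peaks), file.path(out_dir, "peaks.csv"))
  write_csv15(as.data.frame(x$bcg)[c("time_s", "bcg")], file.path(out_dir, "bcg.csv"))
  write_manifest(out_dir, x$config,
                 list(equivalence = c(glance(x$equivalence), tidy_wide(x$equivalence))))
}

write_field_artifacts <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_windows(x$dives, file.path(out_dir, "dives.csv"))
  write_windows(x$windows, file.path(out_dir, "motionless_windows.csv"))
  write_beats(x$beats, file.path(out_dir, "beats.csv"))
  write_hr(x$hr, file.path(out_dir, "hr.csv"))
  res <- list(snr_1d = x$snr_1d$snr, snr_3d = x$snr_3d$snr,
              diagnostics = x$diagnostics)
  if (!is.null(x$trend)) {
    res$trend <- list(slope = x$trend$slope, intercept = x$trend$intercept,
                      p_one_sided = x$trend$p_one_sided,
                      hr_start_bpm = x$trend$hr_start_bpm,
                      hr_end_bpm = x$trend$hr_end_bpm)
  }
  write_manifest(out_dir, x$config, res)
}

tidy_wide <- function(eq) {
  td <- tidy(eq)
  stats::setNames(as.list(td$estimate), td$term)
}

# Run manifest: config snapshot, package version, per-file digests of every
# artifact in the directory. Re-running on identical inputs must reproduce
# identical digests.
write_manifest <- function(out_dir, config, results) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  digests <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(digests) <- files
  jsonlite::write_json(
    list(package = "accelbcg",
         version = as.character(utils::packageVersion("accelbcg")),
         config = unclass(config),
         results = results,
         files = digests),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file.path(out_dir, "manifest.json"))
}
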