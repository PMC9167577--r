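# Behavioral gating: dives from the depth trace, motionless (stroke-free)
# windows from gyroscope rotational velocity. The BCG is only interpretable
# when body movement is not masking the recoil signal, so all field analyses
# run inside these windows.

#' Segment dives from a depth trace
#'
#' A dive is a maximal interval with depth strictly greater than
#' `surface_m` (default 2 m, positive-down). Start and end times are
#' refined by linear interpolation between the samples straddling the
#' surface threshold, giving sub-sample crossing times. A dive is flagged
#' `retained` when its maximum depth strictly exceeds `min_depth_m` and its
#' duration strictly exceeds `min_dur_s` (defaults: 10 m, 300 s).
#'
#' @param depth A depth [tag_series()] or data frame with `time_s` and
#'   `depth_m` columns (meters, positive-down).
#' @param surface_m Depth threshold defining submergence (m).
#' @param min_depth_m Minimum maximum-depth for a retained dive (m).
#' @param min_dur_s Minimum duration for a retained dive (s).
#' @param fs Sampling rate (Hz) if the series carries none.
#' @return Tibble with one row per dive: `dive`, `start_s`, `end_s`,
#'   `duration_s`, `max_depth_m`, `retained`. Zero rows when the animal
#'   never leaves the surface layer.
#' @export
segment_dives <- function(depth, surface_m = 2, min_depth_m = 10,
                          min_dur_s = 300, fs = NULL) {
  d <- depth[["depth_m"]] %||% signal_vector(depth)
  t <- depth$time_s
  wet <- d > surface_m
  empty <- tibble::tibble(dive = integer(0), start_s = numeric(0), end_s = numeric(0),
                          duration_s = numeric(0), max_depth_m = numeric(0),
                          retained = logical(0))
  if (!any(wet)) return(empty)
  r <- rle(wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  wet_runs <- which(r$values)
  cross <- function(i0, i1) {
    # linear interpolation of the surface_m crossing between samples i0, i1
    if (d[i1] == d[i0]) return(t[i1])
    t[i0] + (surface_m - d[i0]) / (d[i1] - d[i0]) * (t[i1] - t[i0])
  }
  out <- purrr::map_dfr(seq_along(wet_runs), function(k) {
    i <- wet_runs[k]
    s <- starts[i]; e <- ends[i]
    start_s <- if (s > 1L) cross(s - 1L, s) else t[s]
    end_s <- if (e < length(d)) cross(e, e + 1L) else t[e]
    tibble::tibble(dive = k, start_s = start_s, end_s = end_s,
                   duration_s = end_s - start_s,
                   max_depth_m = max(d[s:e]))
  })
  dplyr::mutate(out, retained = .data$max_depth_m > min_depth_m &
                  .data$duration_s > min_dur_s)
}

#' Normalized dive time
#'
#' Maps a time inside a dive to `[0, 1]`: 0 at the dive start, 1 at the end.
#'
#' @param dive A one-row dive tibble (or any list with `start_s`, `end_s`).
#' @param t Time(s) in seconds; must lie within the dive.
#' @return Numeric in `[0, 1]`, same length as `t`.
#' @export
normalize_dive_time <- function(dive, t) {
  if (any(t < dive$start_s - 1e-9 | t > dive$end_s + 1e-9)) {
    abort("`t` lies outside the dive.", class = "accelbcg_parameter_error")
  }
  pmin(1, pmax(0, (t - dive$start_s) / (dive$end_s - dive$start_s)))
}

#' Find motionless (stroke-free) windows from gyroscope data
#'
#' Fluke strokes register as large rotational velocity around the lateral
#' axis, on a sensor physically separate from the accelerometer. The lateral
#' rotational velocity is rectified and smoothed with a centered moving
#' average of `smooth_s`; maximal intervals where the smoothed envelope
#' stays below `threshold` for at least `min_dur_s` are returned, trimmed by
#' one smoothing window at each end so stroke energy blurred into the window
#' edges is excluded.
#'
#' The default threshold is record-relative with a physical cap:
#' `min(4 * q10, max_quiet_omega)`, where `q10` is the 10th percentile of
#' the smoothed envelope. The 10th percentile anchors the quiet-floor level
#' whatever the tag's noise figure, and the factor 4 provides headroom
#' above that floor while remaining far below stroking amplitudes, which
#' are typically one to two orders of magnitude larger. The cap resolves
#' the one case a purely record-relative rule cannot: a record that
#' strokes throughout has a uniformly high envelope, and without an
#' absolute ceiling its own 10th percentile would declare it quiet.
#' `max_quiet_omega` defaults to 0.1 rad/s — genuinely motionless large
#' animals stay well below it, fluke strokes well above; override it for
#' tags reporting deg/s. Pass an explicit `threshold` to bypass both.
#'
#' @param gyro A gyroscope [tag_series()] with the lateral axis present.
#' @param axis Name of the lateral-axis column (default `"sway"`).
#' @param smooth_s Envelope smoothing window (s).
#' @param threshold Rotational-velocity threshold in the gyro's units, or
#'   `NULL` for the record-relative default.
#' @param max_quiet_omega Absolute ceiling (same units as the gyro) on the
#'   default threshold; ignored when `threshold` is given.
#' @param min_dur_s Minimum window duration after trimming (s).
#' @param fs Sampling rate (Hz) if the series carries none.
#' @return Tibble with `window`, `start_s`, `end_s`, `duration_s`,
#'   `mean_abs_omega` (mean rectified rotational velocity inside the
#'   window). Zero rows when the record is never quiet long enough.
#' @export
find_motionless <- function(gyro, axis = "sway", smooth_s = 5,
                            threshold = NULL, min_dur_s = 60,
                            max_quiet_omega = 0.1, fs = NULL) {
  fs <- series_fs(gyro, fs)
  if (!axis %in% names(gyro)) {
    abort(sprintf("Axis `%s` not present in gyro series.", axis),
          class = "accelbcg_schema_error")
  }
  if (!is.null(threshold) && threshold <= 0) {
    abort("`threshold` must be > 0.", class = "accelbcg_parameter_error")
  }
  w <- abs(gyro[[axis]])
  m <- window_samples(smooth_s, fs, odd = TRUE)
  env <- sma_centered(w, m)
  threshold <- threshold %||%
    min(4 * quantile(env, 0.10, names = FALSE), max_quiet_omega)
  quiet <- env <= threshold
  empty <- tibble::tibble(window = integer(0), start_s = numeric(0),
                          end_s = numeric(0), duration_s = numeric(0),
                          mean_abs_omega = numeric(0))
  if (!any(quiet)) return(empty)
  t <- gyro$time_s
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- purrr::map_dfr(runs, function(i) {
    s0 <- t[starts[i]] + smooth_s  # trim stroke bleed-in at both ends
    e0 <- t[ends[i]] - smooth_s
    if (e0 - s0 < min_dur_s) return(NULL)
    sel <- t >= s0 & t <= e0
    tibble::tibble(start_s = s0, end_s = e0, duration_s = e0 - s0,
                   mean_abs_omega = mean(w[sel]))
  })
  if (!nrow(out)) return(empty)
  dplyr::mutate(out, window = dplyr::row_number(), .before = 1L)
}
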