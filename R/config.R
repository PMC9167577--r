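#' Pipeline configuration and species presets
#'
#' Bundles the tunable parameters of the BCG construction. Two presets
#' mirror the parameterizations used on real deployments:
#'
#' * `"killer_whale"`: 0.5 s windows (200 samples at 400 Hz), band-pass
#'   1-25 Hz — a smaller, faster-hearted animal.
#' * `"blue_whale"`: 2.0 s windows (800 samples at 400 Hz), band-pass
#'   1-10 Hz — larger bodies produce lower-magnitude, lower-frequency
#'   recoil, so a narrower band and longer smoothing window suit them.
#'
#' The 1 Hz lower corner de-trends the record; the upper corner removes
#' broadband noise above the beat wave packet (roughly 4-7 Hz in species
#' measured to date). `window_s` drives every windowed operation: the
#' Savitzky-Golay support, the triangular smoother, and the minimum peak
#' distance during beat detection.
#'
#' @param preset `"killer_whale"`, `"blue_whale"`, or `NULL` to start from
#'   the killer-whale values and override individually.
#' @param window_s Window length (s) for all windowed operations.
#' @param band_lo_hz,band_hi_hz Band-pass corner frequencies (Hz);
#'   `0 < band_lo_hz < band_hi_hz < fs/2` is checked at time of use.
#' @param butter_order Butterworth filter order (default 5).
#' @param sg_polyorder Savitzky-Golay polynomial order (default 4).
#' @param min_fs_hz Minimum recommended sampling rate; lower rates trigger a
#'   warning, not an error (default 50 Hz — twice the widest band's upper
#'   corner).
#' @param axes_mode `"1d"` (cranio-caudal/surge only) or `"3d"` (all axes).
#' @return A list of class `bcg_config`.
#' @examples
#' bcg_config("blue_whale", axes_mode = "3d")
#' @export
bcg_config <- function(preset = c("killer_whale", "blue_whale"),
                       window_s = NULL, band_lo_hz = NULL, band_hi_hz = NULL,
                       butter_order = 5L, sg_polyorder = 4L,
                       min_fs_hz = 50, axes_mode = c("1d", "3d")) {
  preset <- match.arg(preset)
  axes_mode <- match.arg(axes_mode)
  base <- switch(preset,
    killer_whale = list(window_s = 0.5, band_lo_hz = 1, band_hi_hz = 25),
    blue_whale   = list(window_s = 2.0, band_lo_hz = 1, band_hi_hz = 10))
  cfg <- list(
    preset = preset,
    window_s = window_s %||% base$window_s,
    band_lo_hz = band_lo_hz %||% base$band_lo_hz,
    band_hi_hz = band_hi_hz %||% base$band_hi_hz,
    butter_order = as.integer(butter_order),
    sg_polyorder = as.integer(sg_polyorder),
    min_fs_hz = min_fs_hz,
    axes_mode = axes_mode)
  if (cfg$window_s <= 0) abort("`window_s` must be > 0.", class = "accelbcg_parameter_error")
  if (cfg$band_lo_hz <= 0 || cfg$band_lo_hz >= cfg$band_hi_hz) {
    abort("Need 0 < band_lo_hz < band_hi_hz.", class = "accelbcg_parameter_error")
  }
  structure(cfg, class = "bcg_config")
}

#' @export
print.bcg_config <- function(x, ...) {
  cat(sprintf(paste0("<bcg_config: preset %s, window %.2g s, band [%g, %g] Hz, ",
                     "Butterworth order %d, SG order %d, axes %s>\n"),
              x$preset, x$window_s, x$band_lo_hz, x$band_hi_hz,
              x$butter_order, x$sg_polyorder, x$axes_mode))
  invisible(x)
}

# Validate a config against a concrete sampling rate at time of use.
check_config_fs <- function(cfg, fs) {
  if (cfg$band_hi_hz >= fs / 2) {
    abort(sprintf("Upper band corner %g Hz is not below Nyquist (%g Hz).",
                  cfg$band_hi_hz, fs / 2), class = "accelbcg_parameter_error")
  }
  n <- window_samples(cfg$window_s, fs, odd = TRUE)
  if (n < cfg$sg_polyorder + 2L) {
    abort(sprintf("Window of %d samples is too short for SG order %d.",
                  n, cfg$sg_polyorder), class = "accelbcg_parameter_error")
  }
  if (fs < cfg$min_fs_hz) {
    warn(sprintf("Sampling rate %g Hz is below the recommended %g Hz minimum.",
                 fs, cfg$min_fs_hz), class = "accelbcg_low_fs_warning")
  }
  invisible(cfg)
}
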