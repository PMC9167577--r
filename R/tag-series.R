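# Core tabular containers for regularly sampled tag sensor traces.
#
# A "tag series" is an ordinary tibble with a `time_s` column (seconds from
# record start; sample i sits at t0 + i/fs) plus one to three value columns,
# carrying `fs`, `t0`, `units` and (for single-channel series) `kind` as
# attributes. Every user-facing function accepts either a tag_series or a
# plain data frame with an explicit `fs` argument, so pipelines compose with
# the pipe without ceremony.

SCALAR_KINDS <- c("depth_m", "entropy", "bcg", "differenced", "filtered", "gyro", "accel")

#' Construct a regularly sampled tag series
#'
#' Wraps a data frame of sensor samples as a validated, regularly sampled
#' series. One to three value columns are allowed (e.g. `surge`, `sway`,
#' `heave` for animal-frame acceleration, or a single `depth_m` column).
#' A `time_s` column is generated from `fs` and `t0` when absent, and
#' checked for uniform spacing when present.
#'
#' @param data Data frame with one to three numeric value columns and
#'   optionally a `time_s` column.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds from record start.
#' @param units Free-text unit tag (e.g. `"g"`, `"m s-2"`, `"rad s-1"`).
#' @param kind For single-column series, one of
#'   `r paste0('\x60"', SCALAR_KINDS, '"\x60', collapse = ", ")`.
#' @param na_action How to treat non-finite samples: `"error"` (default)
#'   rejects the series; `"interpolate"` linearly fills runs of at most two
#'   consecutive missing samples and errors on longer gaps. Centered filters
#'   assume contiguous data, so silent pass-through is never allowed.
#'
#' @return A tibble of class `tag_series` with attributes `fs`, `t0`,
#'   `units` and `kind`.
#' @examples
#' tag_series(data.frame(surge = sin(1:100), sway = 0, heave = 0), fs = 50)
#' @export
tag_series <- function(data, fs, t0 = 0, units = NULL, kind = NULL,
                       na_action = c("error", "interpolate")) {
  na_action <- match.arg(na_action)
  stopifnot(is.data.frame(data))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).", class = "accelbcg_sampling_error")
  }
  data <- tibble::as_tibble(data)
  value_cols <- setdiff(names(data), "time_s")
  if (length(value_cols) < 1L || length(value_cols) > 3L) {
    abort("A tag series needs 1-3 value columns.", class = "accelbcg_schema_error")
  }
  if (anyDuplicated(value_cols)) {
    abort("Axis labels must be unique.", class = "accelbcg_schema_error")
  }
  n <- nrow(data)
  if (n < 1L) abort("A tag series needs at least one sample.", class = "accelbcg_schema_error")
  if ("time_s" %in% names(data)) {
    dt <- diff(data$time_s)
    if (n > 1L && any(abs(dt - 1 / fs) > 1e-6 / fs + 1e-9)) {
      abort("`time_s` is not uniformly spaced at 1/fs.", class = "accelbcg_sampling_error")
    }
    t0 <- data$time_s[1L]
  } else {
    data$time_s <- t0 + (seq_len(n) - 1L) / fs
  }
  data <- dplyr::relocate(data, "time_s")
  for (v in value_cols) {
    x <- data[[v]]
    if (!is.numeric(x)) {
      abort(sprintf("Column `%s` must be numeric.", v), class = "accelbcg_schema_error")
    }
    bad <- !is.finite(x)
    if (any(bad)) {
      if (na_action == "error") {
        abort(sprintf("Column `%s` has %d non-finite samples.", v, sum(bad)),
              class = "accelbcg_value_error")
      }
      data[[v]] <- interpolate_short_gaps(x, max_gap = 2L, col = v)
    }
  }
  if (length(value_cols) == 1L && !is.null(kind)) {
    kind <- match.arg(kind, SCALAR_KINDS)
  }
  structure(data,
            class = c("tag_series", "tbl_df", "tbl", "data.frame"),
            fs = fs, t0 = t0, units = units, kind = kind)
}

interpolate_short_gaps <- function(x, max_gap, col) {
  bad <- which(!is.finite(x))
  runs <- split(bad, cumsum(c(1L, diff(bad) != 1L)))
  for (r in runs) {
    if (length(r) > max_gap || min(r) == 1L || max(r) == length(x)) {
      abort(sprintf("Column `%s`: gap of %d non-finite samples cannot be interpolated.",
                    col, length(r)), class = "accelbcg_value_error")
    }
    lo <- min(r) - 1L; hi <- max(r) + 1L
    x[r] <- approx(c(lo, hi), x[c(lo, hi)], xout = r)$y
  }
  x
}

#' @export
print.tag_series <- function(x, ...) {
  cat(sprintf("<tag_series: %d samples @ %g Hz, axes: %s%s>\n",
              nrow(x), series_fs(x),
              paste(series_axes(x), collapse = "/"),
              if (!is.null(attr(x, "kind"))) paste0(", kind: ", attr(x, "kind")) else ""))
  NextMethod()
}

#' Sampling-rate and axis helpers
#'
#' `series_fs()` returns the sampling rate of a tag series (or the explicit
#' `fs` override); `series_axes()` returns its value-column names.
#'
#' @param x A `tag_series` or plain data frame.
#' @param fs Optional explicit sampling rate; required for plain data frames
#'   without an `fs` attribute.
#' @return `series_fs()` a number (Hz); `series_axes()` a character vector.
#' @export
series_fs <- function(x, fs = NULL) {
  out <- fs %||% attr(x, "fs")
  if (is.null(out)) {
    if (is.data.frame(x) && "time_s" %in% names(x) && nrow(x) > 1L) {
      out <- 1 / median(diff(x$time_s))
    } else {
      abort("Sampling rate unknown: pass `fs` or use tag_series().",
            class = "accelbcg_sampling_error")
    }
  }
  out
}

#' @rdname series_fs
#' @export
series_axes <- function(x) setdiff(names(x), "time_s")

#' Number of samples in an analysis window
#'
#' Converts a window length in seconds to a sample count,
#' `round(window_s * fs)`. Centered (symmetric) filters need odd support, so
#' `odd = TRUE` bumps an even count up by one.
#'
#' @param window_s Window length in seconds (> 0).
#' @param fs Sampling rate in Hz (> 0).
#' @param odd Force the count to be odd (used by the Savitzky-Golay and
#'   triangular smoothers).
#' @return Integer sample count (at least 1).
#' @examples
#' window_samples(0.5, 400) # 200
#' window_samples(2.0, 400) # 800
#' @export
window_samples <- function(window_s, fs, odd = FALSE) {
  stopifnot(window_s > 0, fs > 0)
  n <- max(1L, as.integer(round(window_s * fs)))
  if (odd && n %% 2L == 0L) n <- n + 1L
  n
}

#' Read a columnar tag-data CSV
#'
#' Reads a sensor trace from CSV with a declared column mapping and sampling
#' rate. The file needs a header row; a `time_s` column is optional and, if
#' mapped, is checked for uniform spacing.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz.
#' @param cols Named character vector mapping output axis names to file
#'   column names, e.g. `c(surge = "ax", sway = "ay", heave = "az")` or
#'   `c(depth_m = "p")`. Defaults to taking all file columns as-is.
#' @param min_fs_hz Below this sampling rate a diagnostic warning is issued:
#'   beat wave packets carry power up to roughly 7 Hz in species studied so
#'   far, so rates under about 50 Hz risk aliasing the waveform.
#' @inheritParams tag_series
#' @return A [tag_series()].
#' @export
read_tag_csv <- function(path, fs, cols = NULL, units = NULL, kind = NULL,
                         min_fs_hz = 50, na_action = "error") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path), class = "accelbcg_io_error")
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(cols)) {
    missing <- setdiff(unname(cols), names(raw))
    if (length(missing)) {
      abort(sprintf("Declared columns absent from %s: %s", basename(path),
                    paste(missing, collapse = ", ")), class = "accelbcg_schema_error")
    }
    raw <- raw[, unname(cols), drop = FALSE]
    names(raw) <- names(cols)
  }
  if (fs < min_fs_hz && !identical(attr(raw, "kind"), "depth_m") && !identical(kind, "depth_m")) {
    warn(sprintf(paste0("Sampling rate %g Hz is below the recommended minimum of %g Hz; ",
                        "beat waveforms may be aliased."), fs, min_fs_hz),
         class = "accelbcg_low_fs_warning")
  }
  tag_series(raw, fs = fs, units = units, kind = kind, na_action = na_action)
}

#' Write and read beat, heart-rate and window tables
#'
#' Plain-CSV persistence for the small result tables. Beat tables have a
#' `time_s` column; heart-rate tables add `hr_bpm`; window/dive tables are
#' written with whatever columns they carry. Round-trips are lossless to
#' full double precision (values are written with 15 significant digits).
#'
#' @param x A tibble (beats: `time_s`; heart rate: `time_s`, `hr_bpm`; or
#'   any interval table).
#' @param path Output CSV path.
#' @return `path`, invisibly (writers); a tibble (readers).
#' @export
write_beats <- function(x, path) {
  stopifnot("time_s" %in% names(x))
  if (is.unsorted(x$time_s, strictly = TRUE) && nrow(x) > 1L) {
    abort("Beat times must be strictly increasing.", class = "accelbcg_value_error")
  }
  write_csv15(x["time_s"], path)
}

#' @rdname write_beats
#' @export
read_beats <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"time_s" %in% names(out)) abort("Beat file lacks `time_s`.", class = "accelbcg_schema_error")
  tibble::as_tibble(out)
}

#' @rdname write_beats
#' @export
write_hr <- function(x, path) {
  stopifnot(all(c("time_s", "hr_bpm") %in% names(x)))
  write_csv15(x[c("time_s", "hr_bpm")], path)
}

#' @rdname write_beats
#' @export
read_hr <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_s", "hr_bpm") %in% names(out))) {
    abort("Heart-rate file needs `time_s` and `hr_bpm`.", class = "accelbcg_schema_error")
  }
  tibble::as_tibble(out)
}

#' @rdname write_beats
#' @export
write_windows <- function(x, path) write_csv15(x, path)

#' @rdname write_beats
#' @export
read_windows <- function(path) {
  tibble::as_tibble(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

# readr::write_csv drops no precision at 15 significant digits; enough for
# the >= 9 significant digit round-trip contract with headroom.
write_csv15 <- function(x, path) {
  out <- dplyr::mutate(tibble::as_tibble(x), dplyr::across(
    dplyr::where(is.numeric), ~ signif(.x, 15)))
  tryCatch(readr::write_csv(out, path, progress = FALSE),
           error = function(e) abort(conditionMessage(e), class = "accelbcg_io_error"))
  invisible(path)
}

#' Coverage of a record by a set of windows
#'
#' Total duration of a set of non-overlapping intervals as a percentage of
#' the record duration (e.g. motionless-period coverage of a deployment).
#'
#' @param windows Tibble with `start_s` and `end_s` columns, or a single
#'   total duration in seconds.
#' @param record_s Record duration in seconds.
#' @return Percentage in `[0, 100]`.
#' @examples
#' window_coverage_pct(76.9 * 60, record_s = 2 * 3600) # 64.1% of a 2 h record
#' @export
window_coverage_pct <- function(windows, record_s) {
  stopifnot(record_s > 0)
  total <- if (is.data.frame(windows)) {
    sum(windows$end_s - windows$start_s)
  } else {
    sum(windows)
  }
  100 * total / record_s
}
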