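# The four-stage BCG construction. Each stage is exported on its own so the
# intermediate signals (band-passed, differenced, entropy, BCG) can be
# inspected and saved; compute_bcg() composes them.

# Reflection padding keeps IIR/FIR edge transients out of the analysis span.
reflect_pad <- function(x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  if (npad < 1L) return(list(x = x, npad = 0L))
  left <- 2 * x[1L] - x[seq(npad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  list(x = c(left, x, right), npad = npad)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass forward and backward
#' ([signal::filtfilt()]) to each axis independently, so the filter
#' contributes no phase lag — beat timing is preserved, which downstream
#' comparison against ECG beat times depends on. The record is extended by
#' odd reflection before filtering to suppress edge transients.
#'
#' @param x A [tag_series()] or data frame with a `time_s` column and one to
#'   three axis columns.
#' @param lo,hi Pass-band corner frequencies in Hz; `lo < hi < fs/2`.
#' @param order Butterworth order of the underlying low/high-pass design
#'   (default 5).
#' @param fs Sampling rate (Hz); taken from the series attributes when
#'   omitted.
#' @return A series of the same shape and length, band-pass filtered.
#' @export
bcg_bandpass <- function(x, lo, hi, order = 5L, fs = NULL) {
  fs <- series_fs(x, fs)
  if (!(lo > 0 && lo < hi)) abort("Need 0 < lo < hi.", class = "accelbcg_parameter_error")
  if (hi >= fs / 2) {
    abort(sprintf("Upper corner %g Hz must be below Nyquist (%g Hz).", hi, fs / 2),
          class = "accelbcg_parameter_error")
  }
  n <- nrow(x)
  if (n <= 3L * order) {
    abort(sprintf("Signal of %d samples is too short for order-%d filtering.", n, order),
          class = "accelbcg_length_error")
  }
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  npad <- min(n - 1L, max(9L * order, as.integer(round(3 * fs / lo))))
  out <- x
  for (ax in series_axes(x)) {
    p <- reflect_pad(x[[ax]], npad)
    y <- signal::filtfilt(bf, p$x)
    out[[ax]] <- y[seq(p$npad + 1L, p$npad + n)]
  }
  out
}

#' Savitzky-Golay differencing
#'
#' Smoothed per-sample first difference of each axis: a local polynomial of
#' order `polyorder` is fitted over a centered window and its first
#' derivative evaluated at the center, in units per sample step (the
#' derivative is deliberately not divided by the sampling interval — the
#' output exaggerates peak structure rather than estimating jerk in
#' physical units). Applied to each axis independently.
#'
#' @inheritParams bcg_bandpass
#' @param window_n Odd window length in samples; must exceed `polyorder`.
#' @param polyorder Polynomial order (default 4).
#' @return A series of the same shape: the differenced signal.
#' @export
bcg_sg_difference <- function(x, window_n, polyorder = 4L, fs = NULL) {
  window_n <- as.integer(window_n)
  if (window_n %% 2L == 0L || window_n <= polyorder) {
    abort("`window_n` must be odd and greater than `polyorder`.",
          class = "accelbcg_parameter_error")
  }
  if (nrow(x) < window_n) {
    abort(sprintf("Signal of %d samples is shorter than the %d-sample window.",
                  nrow(x), window_n), class = "accelbcg_length_error")
  }
  out <- x
  n <- nrow(x)
  for (ax in series_axes(x)) {
    p <- reflect_pad(x[[ax]], (window_n - 1L) %/% 2L)
    y <- signal::sgolayfilt(p$x, p = polyorder, n = window_n, m = 1L, ts = 1)
    out[[ax]] <- y[seq(p$npad + 1L, p$npad + n)]
  }
  out
}

#' Shannon-entropy fusion of one or three axes
#'
#' Collapses the per-axis differenced signal into a single strictly
#' nonnegative trace: each axis is rescaled so its maximum absolute value
#' over the segment is 1 (an all-zero axis is left at zero), then
#' \deqn{H_i = -\sum_k |a_{ik}| \ln |a_{ik}|, \qquad 0\ln 0 := 0.}
#' The transform weights mid-amplitude samples most (its maximum is at
#' \eqn{|a| = 1/e}), which suppresses both the near-zero noise floor and
#' isolated full-scale spikes. Rescaling to at most 1 is what makes the sum
#' nonnegative, and it makes the whole pipeline invariant to the input's
#' amplitude units.
#'
#' @inheritParams bcg_bandpass
#' @param axes_mode `"1d"` uses the `surge` (cranio-caudal) axis only, and
#'   requires it to be present; `"3d"` sums over all available axes.
#' @return A single-channel series (`entropy` column) of the same length.
#' @export
bcg_entropy <- function(x, axes_mode = c("3d", "1d"), fs = NULL) {
  axes_mode <- match.arg(axes_mode)
  fs <- series_fs(x, fs)
  axes <- series_axes(x)
  if (axes_mode == "1d") {
    if (!"surge" %in% axes) {
      abort("1d mode needs a `surge` axis.", class = "accelbcg_schema_error")
    }
    axes <- "surge"
  }
  h <- numeric(nrow(x))
  for (ax in axes) {
    a <- abs(x[[ax]])
    m <- max(a)
    if (m > 0) {
      a <- a / m
      nz <- a > 0
      h[nz] <- h[nz] - a[nz] * log(a[nz])
    }
  }
  tag_series(tibble::tibble(time_s = x$time_s, entropy = h),
             fs = fs, kind = "entropy")
}

# Centered simple moving average with reflection padding; length m odd.
sma_centered <- function(x, m) {
  if (m <= 1L) return(x)
  n <- length(x)
  p <- reflect_pad(x, (m - 1L) %/% 2L)
  y <- stats::filter(p$x, rep(1 / m, m), sides = 2)
  as.numeric(y[seq(p$npad + 1L, p$npad + n)])
}

#' Triangular moving-average smoothing
#'
#' Two passes of a centered simple moving average, which is equivalent to a
#' single pass with triangular weights: the window center counts most, so
#' peaks and valleys survive smoothing better than under a flat average.
#' Each pass uses a window of `ceiling(window_n / 2)` samples (forced odd),
#' so the triangular kernel's total support is approximately `window_n`.
#' Nonnegative input stays nonnegative (all weights are positive).
#'
#' @inheritParams bcg_bandpass
#' @param window_n Odd nominal window length in samples.
#' @return A series of the same shape, smoothed.
#' @export
bcg_tma <- function(x, window_n, fs = NULL) {
  window_n <- as.integer(window_n)
  if (window_n < 1L || window_n %% 2L == 0L) {
    abort("`window_n` must be odd and >= 1.", class = "accelbcg_parameter_error")
  }
  m <- as.integer(ceiling(window_n / 2))
  if (m %% 2L == 0L) m <- m + 1L
  out <- x
  for (ax in series_axes(x)) out[[ax]] <- sma_centered(sma_centered(x[[ax]], m), m)
  out
}

#' Construct the ballistocardiogram
#'
#' Runs the four stages in order on animal-frame acceleration:
#' band-pass filter -> Savitzky-Golay differencing -> Shannon-entropy fusion
#' -> triangular smoothing. The result (the BCG) is a strictly nonnegative
#' trace, the same length and rate as the input, in which heart beats appear
#' as dominant local maxima. Because of the pre-entropy rescaling the BCG is
#' unchanged under any positive rescaling of the input (e.g. g versus
#' m s\eqn{^{-2}}), and its amplitude units are arbitrary — only relative
#' shape carries information.
#'
#' The first and last `window_s` seconds are influenced by the reflection
#' padding of the centered filters; they are marked by the logical `edge`
#' column so downstream users can weight them accordingly.
#'
#' @param x Acceleration [tag_series()] (axes `surge`, `sway`, `heave`; any
#'   subset including `surge` works in 1d mode).
#' @param config A [bcg_config()].
#' @param fs Sampling rate (Hz); from the series attributes when omitted.
#' @return A `bcg_signal`: a single-channel tag series with columns
#'   `time_s`, `bcg`, `edge`, carrying the config snapshot and the axes used
#'   as attributes.
#' @examples
#' rec <- simulate_record(sim_config(duration_s = 60, fs = 100, seed = 1))
#' bcg <- compute_bcg(rec$accel, bcg_config("blue_whale", axes_mode = "3d"))
#' @export
compute_bcg <- function(x, config = bcg_config(), fs = NULL) {
  fs <- series_fs(x, fs)
  check_config_fs(config, fs)
  n_win <- window_samples(config$window_s, fs, odd = TRUE)
  filt <- bcg_bandpass(x, config$band_lo_hz, config$band_hi_hz,
                       order = config$butter_order, fs = fs)
  diffd <- bcg_sg_difference(filt, n_win, polyorder = config$sg_polyorder, fs = fs)
  h <- bcg_entropy(diffd, axes_mode = config$axes_mode, fs = fs)
  sm <- bcg_tma(h, n_win, fs = fs)
  axes_used <- if (config$axes_mode == "1d") "surge" else series_axes(x)
  out <- tibble::tibble(
    time_s = x$time_s,
    bcg = pmax(sm$entropy, 0),
    edge = x$time_s < x$time_s[1L] + config$window_s |
      x$time_s > x$time_s[nrow(x)] - config$window_s)
  out <- tag_series(out[c("time_s", "bcg")], fs = fs, kind = "bcg")
  out$edge <- x$time_s < x$time_s[1L] + config$window_s |
    x$time_s > x$time_s[nrow(x)] - config$window_s
  structure(out, class = c("bcg_signal", class(out)),
            config = config, axes_used = axes_used)
}

#' @export
print.bcg_signal <- function(x, ...) {
  cat(sprintf("<bcg_signal: %d samples @ %g Hz, axes used: %s>\n",
              nrow(x), series_fs(x), paste(attr(x, "axes_used"), collapse = "/")))
  NextMethod()
}
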