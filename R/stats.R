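# Validation statistics: band-integrated spectral SNR of the BCG,
# OLS equivalence of BCG- against ECG-derived heart rate, and robust
# Theil-Sen regression of heart rate on normalized dive time.

#' Welch power spectral density
#'
#' Averaged modified periodogram: the (linearly detrended) signal is split
#' into Hann-tapered segments with 50% overlap, and per-segment one-sided
#' periodograms are averaged. Density scaling: the integral of the PSD over
#' frequency approximates the signal variance.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param nperseg Segment length in samples; defaults to
#'   `min(length(x), round(60 * fs))` so frequencies down to 1 cycle/min are
#'   resolved.
#' @param detrend Remove a per-segment linear trend before tapering.
#' @return Tibble with `freq_hz` (positive frequencies up to Nyquist) and
#'   `psd`.
#' @export
welch_psd <- function(x, fs, nperseg = NULL, detrend = TRUE) {
  n <- length(x)
  nperseg <- as.integer(nperseg %||% min(n, round(60 * fs)))
  nperseg <- min(nperseg, n)
  if (nperseg < 8L) abort("Segment too short for a PSD.", class = "accelbcg_length_error")
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))  # Hann
  u <- sum(w^2)
  acc <- numeric(nperseg %/% 2L)
  tt <- seq_len(nperseg)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    if (detrend) seg <- stats::lm.fit(cbind(1, tt), seg)$residuals
    X <- fft(seg * w)
    p <- (Mod(X)^2) / (fs * u)
    half <- p[2:(nperseg %/% 2L + 1L)] * 2
    if (nperseg %% 2L == 0L) half[length(half)] <- half[length(half)] / 2
    acc <- acc + half
  }
  psd <- acc / length(starts)
  tibble::tibble(freq_hz = (seq_len(nperseg %/% 2L)) * fs / nperseg, psd = psd)
}

# Trapezoidal integral of y(x) over [a, b], with linear interpolation at the
# band edges so the result does not depend on grid alignment.
band_integral <- function(x, y, a, b) {
  if (b <= a) return(0)
  a <- max(a, min(x)); b <- min(b, max(x))
  if (b <= a) return(0)
  inside <- x > a & x < b
  xs <- c(a, x[inside], b)
  ys <- c(approx(x, y, a)$y, y[inside], approx(x, y, b)$y)
  sum(diff(xs) * (head(ys, -1L) + tail(ys, -1L)) / 2)
}

#' Spectral signal-to-noise ratio of the BCG
#'
#' Quantifies how much of the BCG's spectral power sits where heart beats
#' are expected. Per analysis window, a Welch PSD is computed and its
#' frequency axis converted to cycles min\eqn{^{-1}} (`bpm = 60 * Hz`).
#' Signal is the integral over `band_bpm` (default 4-8 beats per minute,
#' the apneic heart-rate range of the largest divers); noise is the
#' integrated remainder from the lowest resolved frequency up to `max_bpm`
#' (default 60). Band powers are averaged across windows weighted by window
#' length, and the SNR is their ratio. The SNR is invariant to positive
#' rescaling of the BCG.
#'
#' @param windows A single numeric vector, a `bcg_signal`, or a list of
#'   either (one element per motionless window).
#' @param fs Sampling rate (Hz); required for bare vectors.
#' @param band_bpm Two-element signal band in beats per minute.
#' @param max_bpm Upper edge of the evaluated spectrum (beats per minute).
#' @param mode Optional label (`"1d"`/`"3d"`) carried into the result.
#' @param nperseg_s Welch segment length in seconds (default 60, the
#'   minimum usable window for a 4 beats-per-minute band edge).
#' @return A `bcg_snr` object: list with `snr`, `signal_power`,
#'   `noise_power`, `band_bpm`, `max_bpm`, `mode`, `n_windows`, and the
#'   pooled `psd` tibble (`freq_bpm`, `psd`) for plotting.
#' @export
bcg_snr <- function(windows, fs = NULL, band_bpm = c(4, 8), max_bpm = 60,
                    mode = NA_character_, nperseg_s = 60) {
  if (is.data.frame(windows) || is.numeric(windows)) windows <- list(windows)
  vecs <- lapply(windows, signal_vector)
  fs <- fs %||% series_fs(windows[[1L]])
  min_len_s <- 4 * 60 / band_bpm[1L]
  lens <- lengths(vecs)
  ok <- lens / fs >= min_len_s
  if (!any(ok)) {
    abort(sprintf(
      "No window reaches the minimum length of %g s (4 periods at %g beats/min).",
      min_len_s, band_bpm[1L]), class = "accelbcg_resolution_error")
  }
  vecs <- vecs[ok]; lens <- lens[ok]
  psds <- lapply(vecs, function(v) {
    welch_psd(v, fs, nperseg = min(length(v), round(nperseg_s * fs)))
  })
  pows <- purrr::map2_dfr(psds, as.numeric(lens), function(p, wlen) {
    f_bpm <- p$freq_hz * 60
    sig <- band_integral(f_bpm, p$psd, band_bpm[1L], band_bpm[2L])
    noi <- band_integral(f_bpm, p$psd, min(f_bpm), band_bpm[1L]) +
      band_integral(f_bpm, p$psd, band_bpm[2L], max_bpm)
    tibble::tibble(signal = sig, noise = noi, w = wlen)
  })
  signal_power <- sum(pows$signal * pows$w) / sum(pows$w)
  noise_power <- sum(pows$noise * pows$w) / sum(pows$w)
  # pooled PSD on the grid of the longest window, for plotting
  ref <- psds[[which.max(lens)]]
  pooled <- Reduce(`+`, purrr::map2(psds, as.numeric(lens), function(p, wlen) {
    wlen * approx(p$freq_hz, p$psd, ref$freq_hz, rule = 2)$y
  })) / sum(lens)
  structure(list(snr = signal_power / noise_power,
                 signal_power = signal_power, noise_power = noise_power,
                 band_bpm = band_bpm, max_bpm = max_bpm, mode = mode,
                 n_windows = length(vecs),
                 psd = tibble::tibble(freq_bpm = ref$freq_hz * 60, psd = pooled)),
            class = "bcg_snr")
}

#' @export
print.bcg_snr <- function(x, ...) {
  cat(sprintf("<bcg_snr%s: SNR %.3g over %d window(s); signal band [%g, %g] beats/min>\n",
              if (!is.na(x$mode)) paste0(" ", x$mode) else "", x$snr,
              x$n_windows, x$band_bpm[1L], x$band_bpm[2L]))
  invisible(x)
}

#' @method glance bcg_snr
#' @export
glance.bcg_snr <- function(x, ...) {
  tibble::tibble(snr = x$snr, signal_power = x$signal_power,
                 noise_power = x$noise_power, n_windows = x$n_windows,
                 mode = x$mode)
}

#' OLS equivalence of BCG- and ECG-derived heart rate
#'
#' Pairs the two instantaneous heart-rate series by nearest interval
#' midpoint within `pairing_tol_s` (one-to-one, closest first; unmatched
#' points are dropped and counted), regresses BCG rate on ECG rate by
#' ordinary least squares, and tests whether the intercept differs from 0
#' and the slope differs from 1 (two-sided t-tests). An equivalent method
#' should fail to reject both. The mean and standard deviation of the
#' absolute percent error complement the regression as an equivalence
#' measure.
#'
#' @param hr_bcg,hr_ecg Heart-rate tibbles (`time_s`, `hr_bpm`) from
#'   [instantaneous_hr()].
#' @param pairing_tol_s Maximum midpoint separation for a pair (s).
#' @return A `bcg_equivalence` object with the fitted `lm`, the paired
#'   observations, coefficient tests and error summaries. See [tidy()] and
#'   [glance()] methods.
#' @export
ols_equivalence <- function(hr_bcg, hr_ecg, pairing_tol_s = 0.5) {
  pairs <- pair_nearest(hr_bcg, hr_ecg, pairing_tol_s)
  n <- nrow(pairs)
  if (n < 3L) {
    abort(sprintf("Only %d paired observations; need at least 3.", n),
          class = "accelbcg_insufficient_data_error")
  }
  if (var(pairs$ecg) <= 1e-12 * mean(pairs$ecg)^2) {
    abort("ECG heart rate has zero variance; regression is degenerate.",
          class = "accelbcg_degenerate_error")
  }
  fit <- lm(bcg ~ ecg, data = pairs)
  sm <- suppressWarnings(summary(fit))$coefficients
  # a perfect fit has zero standard errors; the tests then carry no
  # evidence against their nulls (t := 0 when the estimate meets the null)
  eps <- 1e-8 * max(1, mean(abs(pairs$bcg)))
  tstat <- function(est, null, se) {
    if (abs(est - null) < eps) return(0)
    if (se == 0) return(Inf)
    (est - null) / se
  }
  p_slope <- 2 * pt(-abs(tstat(sm[2L, 1L], 1, sm[2L, 2L])), df = n - 2L)
  p_int <- 2 * pt(-abs(tstat(sm[1L, 1L], 0, sm[1L, 2L])), df = n - 2L)
  ape <- 100 * abs(pairs$bcg - pairs$ecg) / pairs$ecg
  structure(list(
    fit = fit, pairs = pairs, n = n,
    n_dropped = attr(pairs, "n_dropped"),
    intercept = sm[1L, 1L], intercept_se = sm[1L, 2L],
    slope = sm[2L, 1L], slope_se = sm[2L, 2L],
    p_intercept_vs_0 = p_int,
    p_slope_vs_1 = p_slope,
    mape_mean = mean(ape), mape_sd = sd(ape)),
    class = "bcg_equivalence")
}

pair_nearest <- function(hr_bcg, hr_ecg, tol_s) {
  tb <- hr_bcg$time_s; te <- hr_ecg$time_s
  cand <- tidyr::expand_grid(i = seq_along(tb), j = seq_along(te))
  cand$dt <- abs(tb[cand$i] - te[cand$j])
  cand <- dplyr::arrange(dplyr::filter(cand, .data$dt <= tol_s), .data$dt)
  used_i <- logical(length(tb)); used_j <- logical(length(te))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_i[i] && !used_j[j]) { keep[k] <- TRUE; used_i[i] <- TRUE; used_j[j] <- TRUE }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- tibble::tibble(time_s = tb[cand$i],
                        bcg = hr_bcg$hr_bpm[cand$i],
                        ecg = hr_ecg$hr_bpm[cand$j])
  out <- dplyr::arrange(out, .data$time_s)
  attr(out, "n_dropped") <- (length(tb) - nrow(out)) + (length(te) - nrow(out))
  out
}

#' @export
print.bcg_equivalence <- function(x, ...) {
  cat(sprintf(paste0("<bcg_equivalence: n = %d pairs>\n",
                     "  slope     %.3f +/- %.3f (p vs 1: %.3g)\n",
                     "  intercept %.3f +/- %.3f (p vs 0: %.3g)\n",
                     "  |error|   %.2f +/- %.2f %%\n"),
              x$n, x$slope, x$slope_se, x$p_slope_vs_1,
              x$intercept, x$intercept_se, x$p_intercept_vs_0,
              x$mape_mean, x$mape_sd))
  invisible(x)
}

#' @method tidy bcg_equivalence
#' @export
tidy.bcg_equivalence <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se),
    null.value = c(0, 1),
    statistic = c((x$intercept - 0) / x$intercept_se, (x$slope - 1) / x$slope_se),
    p.value = c(x$p_intercept_vs_0, x$p_slope_vs_1))
}

#' @method glance bcg_equivalence
#' @export
glance.bcg_equivalence <- function(x, ...) {
  tibble::tibble(n = x$n, n_dropped = x$n_dropped,
                 r.squared = suppressWarnings(summary(x$fit))$r.squared,
                 mape_mean = x$mape_mean, mape_sd = x$mape_sd)
}

#' Theil-Sen robust regression
#'
#' Slope = median of all pairwise slopes (pairs with tied `x` excluded);
#' intercept = median of `y - slope * x`. Robust to outliers (such as
#' premature beats in diving heart-rate profiles) and to heteroscedastic
#' noise. The one-sided p-value for a positive trend comes from the
#' Kendall rank-correlation test of `y` against `x`, the classical
#' companion test of the Theil-Sen slope.
#'
#' @param x Predictor (e.g. normalized dive time in `[0, 1]`).
#' @param y Response (e.g. instantaneous heart rate, beats per minute).
#' @param alternative Direction of the slope test (default `"greater"`).
#' @return A `bcg_trend` object: `slope`, `intercept`, `p_one_sided`, `n`.
#' @examples
#' theil_sen_trend(c(0, .5, 1), c(1, 2, 3)) # slope 2, intercept 1
#' @export
theil_sen_trend <- function(x, y, alternative = "greater") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("Need at least 3 points.", class = "accelbcg_insufficient_data_error")
  if (max(x) == min(x)) {
    abort("All `x` values identical; slope undefined.", class = "accelbcg_degenerate_error")
  }
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2L, ]] - x[ij[1L, ]]
  dy <- y[ij[2L, ]] - y[ij[1L, ]]
  slopes <- dy[dx != 0] / dx[dx != 0]
  slope <- median(slopes)
  intercept <- median(y - slope * x)
  p <- if (var(y) == 0) 0.5 else {
    suppressWarnings(cor.test(x, y, method = "kendall",
                              alternative = alternative, exact = FALSE)$p.value)
  }
  structure(list(slope = slope, intercept = intercept, p_one_sided = p,
                 n = n, alternative = alternative,
                 data = tibble::tibble(x = x, y = y)),
            class = "bcg_trend")
}

#' @export
print.bcg_trend <- function(x, ...) {
  cat(sprintf("<bcg_trend: slope %.3g, intercept %.3g, n = %d, one-sided p = %.3g>\n",
              x$slope, x$intercept, x$n, x$p_one_sided))
  if (!is.null(x$hr_start_bpm)) {
    cat(sprintf("  fitted heart rate: %.2f beats/min at dive start -> %.2f at dive end\n",
                x$hr_start_bpm, x$hr_end_bpm))
  }
  invisible(x)
}

#' @method tidy bcg_trend
#' @export
tidy.bcg_trend <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @method glance bcg_trend
#' @export
glance.bcg_trend <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 p_one_sided = x$p_one_sided, n = x$n,
                 hr_start_bpm = x$hr_start_bpm %||% NA_real_,
                 hr_end_bpm = x$hr_end_bpm %||% NA_real_)
}

#' Heart-rate trend over normalized dive time
#'
#' Assigns each instantaneous heart-rate point the normalized time of the
#' retained dive containing it (points outside retained dives are dropped),
#' pools all dives, and fits a Theil-Sen regression of heart rate on
#' normalized dive time. A positive slope is the classic signature of
#' diving bradycardia release: heart rate climbs toward the end of a dive.
#'
#' @param dives Dive table from [segment_dives()].
#' @param hr Heart-rate tibble (`time_s`, `hr_bpm`).
#' @param alternative Direction of the slope test (default `"greater"`).
#' @return A `bcg_trend` with extra fields `hr_start_bpm` and `hr_end_bpm`,
#'   the fitted heart rate at normalized times 0 and 1.
#' @export
dive_phase_profile <- function(dives, hr, alternative = "greater") {
  keep <- dives[dives$retained, , drop = FALSE]
  if (!nrow(keep)) {
    abort("No retained dives.", class = "accelbcg_insufficient_data_error")
  }
  pts <- purrr::map_dfr(seq_len(nrow(keep)), function(k) {
    dv <- keep[k, ]
    sel <- hr$time_s >= dv$start_s & hr$time_s <= dv$end_s
    if (!any(sel)) return(NULL)
    tibble::tibble(x = normalize_dive_time(dv, hr$time_s[sel]),
                   y = hr$hr_bpm[sel], dive = dv$dive)
  })
  if (is.null(pts) || nrow(pts) < 3L) {
    abort("Fewer than 3 heart-rate points inside retained dives.",
          class = "accelbcg_insufficient_data_error")
  }
  fit <- theil_sen_trend(pts$x, pts$y, alternative = alternative)
  fit$hr_start_bpm <- fit$intercept
  fit$hr_end_bpm <- fit$intercept + fit$slope
  fit$data <- pts
  fit
}
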