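# Candidate-peak extraction and major/minor separation in height-prominence
# space. The BCG contains one dominant local maximum per heart beat plus
# residual noise peaks; the two populations separate as two modes in the
# distribution of Euclidean distances from the highest peak.

# Indices of local maxima, plateau-aware: a plateau counts once (its first
# sample) and only when the signal rises into it and falls after it.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  # carry the previous non-zero slope through plateaus
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  filled <- s
  idx <- cumsum(nz)
  vals <- s[nz]
  filled[idx > 0] <- vals[idx[idx > 0]]
  cand <- which(diff(filled) == -2) + 1L
  # map plateau candidates back to the first sample of the plateau
  out <- vapply(cand, function(i) {
    j <- i
    while (j > 1L && x[j - 1L] == x[j]) j <- j - 1L
    j
  }, integer(1))
  unique(out)
}

#' Topographic prominence of a peak
#'
#' Height of a local maximum above the lowest valley separating it from
#' higher neighbors. On each side the signal is scanned outward until a
#' strictly higher sample (or the record edge) is met, tracking the minimum
#' along the way; the prominence is the peak height minus the higher of the
#' two side minima. Record edges act as higher neighbors, except for the
#' global maximum, whose prominence is its height above the global minimum.
#'
#' @param x Numeric signal, or a single-channel series/data frame.
#' @param index Sample index of a local maximum (1-based).
#' @return Prominence in signal units (>= 0).
#' @examples
#' peak_prominence(c(0, 3, 1, 5, 0), 2) # 2: valley 1 toward higher neighbor 5
#' @export
peak_prominence <- function(x, index) {
  x <- signal_vector(x)
  n <- length(x)
  h <- x[index]
  if ((index > 1L && x[index - 1L] > h) || (index < n && x[index + 1L] > h)) {
    abort(sprintf("Sample %d is not a local maximum.", index),
          class = "accelbcg_parameter_error")
  }
  side_min <- function(idx) {
    lo <- h
    hit_higher <- FALSE
    for (j in idx) {
      if (x[j] > h) { hit_higher <- TRUE; break }
      if (x[j] < lo) lo <- x[j]
    }
    list(min = lo, hit_higher = hit_higher)
  }
  left <- side_min(rev(seq_len(index - 1L)))
  right <- side_min(seq(index + 1L, length.out = n - index))
  if (!left$hit_higher && !right$hit_higher) {
    return(h - min(x)) # global maximum: height above the record's lowest point
  }
  h - max(left$min, right$min)
}

signal_vector <- function(x) {
  if (is.data.frame(x)) {
    col <- intersect(c("bcg", "entropy", series_axes(x)), names(x))[1L]
    x[[col]]
  } else {
    as.numeric(x)
  }
}

#' Extract candidate peaks from a BCG
#'
#' Finds all local maxima and greedily prunes them by descending height so
#' that surviving peaks are at least `min_distance_s` apart (equal heights
#' keep the earlier peak). Heights and topographic prominences are computed
#' for the survivors.
#'
#' @param bcg A [compute_bcg()] result, any single-channel series, or a
#'   numeric vector (then `fs` is required).
#' @param min_distance_s Minimum separation between retained peaks, in
#'   seconds. Defaults to the window length recorded in the BCG's config.
#' @param fs Sampling rate (Hz) if `bcg` carries none.
#' @return A `peak_set`: tibble with columns `time_s`, `index`, `height`,
#'   `prominence` (time-ordered), carrying `min_distance_s` as an attribute.
#'   A flat signal yields zero rows.
#' @export
find_candidate_peaks <- function(bcg, min_distance_s = NULL, fs = NULL) {
  if (is.numeric(bcg) && is.null(fs)) {
    abort("Pass `fs` when `bcg` is a bare vector.", class = "accelbcg_sampling_error")
  }
  fs <- if (is.numeric(bcg)) fs else series_fs(bcg, fs)
  cfg <- attr(bcg, "config")
  min_distance_s <- min_distance_s %||% cfg$window_s %||%
    abort("`min_distance_s` is required when the input carries no config.",
          class = "accelbcg_parameter_error")
  x <- signal_vector(bcg)
  t0 <- if (is.data.frame(bcg)) bcg$time_s[1L] else 0
  idx <- local_maxima(x)
  keep <- prune_by_distance(idx, x[idx], min_sep = min_distance_s * fs)
  idx <- idx[keep]
  prom <- vapply(idx, function(i) peak_prominence(x, i), numeric(1))
  out <- tibble::tibble(
    time_s = t0 + (idx - 1L) / fs,
    index = idx,
    height = x[idx],
    prominence = prom)
  structure(out, class = c("peak_set", class(out)),
            min_distance_s = min_distance_s, fs = fs)
}

# Greedy pruning: visit peaks by descending height (ties: earlier first);
# each surviving peak removes all others within min_sep samples.
prune_by_distance <- function(idx, heights, min_sep) {
  k <- length(idx)
  if (k == 0L) return(logical(0))
  ord <- order(-heights, idx)
  alive <- rep(TRUE, k)
  for (j in ord) {
    if (!alive[j]) next
    lo <- j; hi <- j
    while (lo > 1L && idx[j] - idx[lo - 1L] < min_sep) lo <- lo - 1L
    while (hi < k && idx[hi + 1L] - idx[j] < min_sep) hi <- hi + 1L
    if (lo < j) alive[seq(lo, j - 1L)] <- FALSE
    if (hi > j) alive[seq(j + 1L, hi)] <- FALSE
  }
  alive
}

#' Separate major (beat) from minor (noise) peaks
#'
#' Each peak's Euclidean distance from the highest peak is computed in raw
#' (height, prominence) coordinates — both share BCG units, so no rescaling
#' is applied. A Gaussian kernel density estimate of these distances
#' (Silverman bandwidth, 512 grid points over `[0, max distance]`) is
#' typically bimodal: a low-distance mode of beat peaks and a high-distance
#' mode of noise peaks. The threshold is placed at the deepest density
#' minimum between the two highest modes; peaks at or below it are labeled
#' `major`.
#'
#' Degenerate inputs — fewer than 3 peaks, zero spread, or a unimodal
#' density — yield all-major labels with an infinite threshold and
#' `degenerate = TRUE`, so downstream users know no rejection occurred.
#'
#' @param peaks A `peak_set` from [find_candidate_peaks()].
#' @return The peak set with added columns `distance` and `label`
#'   (`"major"`/`"minor"`), and attributes `threshold` and `degenerate`.
#' @export
cluster_peaks <- function(peaks) {
  n <- nrow(peaks)
  if (n == 0L) {
    out <- dplyr::mutate(peaks, distance = numeric(0), label = character(0))
    return(set_cluster_attrs(out, peaks, Inf, TRUE))
  }
  ref <- order(-peaks$height, peaks$time_s)[1L]
  d <- sqrt((peaks$height - peaks$height[ref])^2 +
              (peaks$prominence - peaks$prominence[ref])^2)
  thr <- Inf
  degenerate <- TRUE
  if (n >= 3L && max(d) > 0 && sd(d) > 0) {
    dens <- density(d, bw = "nrd0", n = 512L, from = 0, to = max(d))
    v <- density_split(dens$y, ok = function(idx) {
      # a mode must have at least two members to count as a cluster
      sum(d <= dens$x[idx]) >= 2L && sum(d > dens$x[idx]) >= 2L
    })
    if (!is.na(v)) {
      thr <- dens$x[v]
      degenerate <- FALSE
    }
  }
  out <- dplyr::mutate(peaks, distance = d,
                       label = ifelse(d <= thr, "major", "minor"))
  set_cluster_attrs(out, peaks, thr, degenerate)
}

# Index of the valley that best separates a bimodal density, or NA when no
# valley dips below `ratio` of the maximum density on both of its sides
# (i.e. the density is effectively unimodal). Evaluating every local
# minimum by its depth below the flanking maxima is robust to minor
# wiggles riding on the two main modes.
density_split <- function(y, ratio = 0.75, ok = function(idx) TRUE) {
  valleys <- local_maxima(-y)
  if (!length(valleys)) return(NA_integer_)
  best <- NA_integer_
  best_score <- -Inf
  for (v in valleys) {
    if (!ok(v)) next
    flank <- min(max(y[seq_len(v)]), max(y[seq(v, length(y))]))
    if (y[v] >= ratio * flank) next
    score <- flank - y[v]
    if (score > best_score) { best_score <- score; best <- v }
  }
  best
}

set_cluster_attrs <- function(out, peaks, thr, degenerate) {
  structure(out, class = c("peak_set", "tbl_df", "tbl", "data.frame"),
            min_distance_s = attr(peaks, "min_distance_s"),
            fs = attr(peaks, "fs"),
            threshold = thr, degenerate = degenerate)
}

#' Beat times from labeled peaks
#'
#' @param peaks A labeled `peak_set` from [cluster_peaks()] (an unlabeled
#'   set is accepted and treated as all-major).
#' @return Tibble with column `time_s`: ascending times of the major peaks.
#' @export
beats_from_peaks <- function(peaks) {
  keep <- if ("label" %in% names(peaks)) peaks$label == "major" else TRUE
  tibble::tibble(time_s = sort(peaks$time_s[keep]))
}

#' Instantaneous heart rate from beat times
#'
#' One rate per inter-beat interval: `hr_bpm = 60 / interval`, assigned to
#' the interval midpoint (an unbiased placement for trend fitting against
#' time).
#'
#' @param beats Tibble with a strictly increasing `time_s` column (>= 2
#'   rows for a non-empty result).
#' @return Tibble with `time_s` (interval midpoints) and `hr_bpm`; zero rows
#'   when fewer than two beats are supplied.
#' @examples
#' instantaneous_hr(data.frame(time_s = c(0, 15, 22.5)))  # 4 then 8 bpm
#' @export
instantaneous_hr <- function(beats) {
  t <- sort(beats$time_s)
  if (length(t) < 2L) return(tibble::tibble(time_s = numeric(0), hr_bpm = numeric(0)))
  iv <- diff(t)
  if (any(iv <= 0)) abort("Beat times must be strictly increasing.",
                          class = "accelbcg_value_error")
  tibble::tibble(time_s = head(t, -1L) + iv / 2, hr_bpm = 60 / iv)
}

#' Match detected beats against reference beat times
#'
#' Greedy one-to-one matching: detected beats are paired with the nearest
#' unused reference beat within `tol_s`. Reports recall (fraction of
#' reference beats recovered) and the false-detection fraction.
#'
#' @param detected,reference Tibbles with a `time_s` column.
#' @param tol_s Matching tolerance in seconds.
#' @return A one-row tibble: `n_ref`, `n_det`, `n_matched`, `recall`,
#'   `false_rate`, `mean_abs_err_s`.
#' @export
match_beats <- function(detected, reference, tol_s) {
  dt <- sort(detected$time_s); rt <- sort(reference$time_s)
  used <- rep(FALSE, length(rt))
  err <- numeric(0)
  n_match <- 0L
  for (d in dt) {
    if (!length(rt)) break
    j <- which(!used & abs(rt - d) <= tol_s)
    if (length(j)) {
      jbest <- j[which.min(abs(rt[j] - d))]
      used[jbest] <- TRUE
      n_match <- n_match + 1L
      err <- c(err, abs(rt[jbest] - d))
    }
  }
  tibble::tibble(
    n_ref = length(rt), n_det = length(dt), n_matched = n_match,
    recall = if (length(rt)) n_match / length(rt) else NA_real_,
    false_rate = if (length(dt)) (length(dt) - n_match) / length(dt) else NA_real_,
    mean_abs_err_s = if (n_match) mean(err) else NA_real_)
}
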