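# Independent brute-force oracles used to cross-check the optimized
# implementations. These deliberately share no code with R/.

# All local maxima by direct neighbour comparison (plateaus: first sample,
# requiring a rise before and a fall after).
oracle_local_maxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# O(n * k) greedy pruning by descending height, ties keep the earlier peak.
oracle_candidate_peaks <- function(x, min_sep) {
  idx <- oracle_local_maxima(x)
  ord <- idx[order(-x[idx], idx)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

# Topographic prominence straight from the definition.
oracle_prominence <- function(x, i) {
  n <- length(x)
  h <- x[i]
  left <- if (i > 1L) x[seq_len(i - 1L)] else numeric(0)
  right <- if (i < n) x[seq(i + 1L, n)] else numeric(0)
  side <- function(v) {
    higher <- which(v > h)
    if (!length(higher)) list(min = min(c(v, h)), open = TRUE)
    else list(min = min(v[seq_len(higher[1L] - 1L)], h), open = FALSE)
  }
  l <- side(rev(left)); r <- side(right)
  if (l$open && r$open) return(h - min(x))
  h - max(l$min, r$min)
}

# Two-pass centered simple moving average with odd window m and odd
# reflection padding, written as explicit loops over a padded vector.
oracle_two_pass_sma <- function(x, window_n) {
  m <- as.integer(ceiling(window_n / 2))
  if (m %% 2L == 0L) m <- m + 1L
  one_pass <- function(v) {
    n <- length(v)
    half <- (m - 1L) %/% 2L
    pad_l <- 2 * v[1L] - v[seq(half + 1L, 2L)]
    pad_r <- 2 * v[n] - v[seq(n - 1L, n - half)]
    vp <- c(pad_l, v, pad_r)
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- mean(vp[i:(i + m - 1L)])
    out
  }
  one_pass(one_pass(x))
}

# Median of all pairwise slopes by double loop.
oracle_theil_sen_slope <- function(x, y) {
  s <- c()
  n <- length(x)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (x[j] != x[i]) s <- c(s, (y[j] - y[i]) / (x[j] - x[i]))
  }
  median(s)
}

# Small helper: simulated record at reduced rate for fast unit tests.
quick_sim <- function(..., fs = 100, duration_s = 120, seed = 1) {
  simulate_record(sim_config(fs = fs, duration_s = duration_s, seed = seed, ...))
}
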