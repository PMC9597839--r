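# Independent brute-force oracles used to cross-check the implementation.

# Sort-and-slice band mean: explicitly ranks the non-missing values and
# averages those with rank-percentile 100*(i - 0.5)/n inside [lo, hi).
oracle_band_mean <- function(values, lo, hi) {
  v <- values[!is.na(values)]
  v <- v[order(v)]
  n <- length(v)
  selected <- c()
  for (i in seq_len(n)) {
    p <- 100 * (i - 0.5) / n
    if (p >= lo && p < hi) selected <- c(selected, v[i])
  }
  stopifnot(length(selected) > 0)
  mean(selected)
}

# Windowed-argmax peak finder: frame i is an onset when it is the earliest
# maximiser of the window [i-w, i+w] and some later in-window value is lower.
oracle_onsets <- function(v, fps, expected_rate) {
  n <- length(v)
  w <- ceiling(0.5 * fps * 60 / expected_rate)
  out <- c()
  for (i in seq_len(n)) {
    if (is.na(v[i])) next
    idx <- max(1, i - w):min(n, i + w)
    vals <- v[idx]
    if (all(is.na(vals))) next
    top <- max(vals, na.rm = TRUE)
    if (v[i] < top) next
    if (idx[which(vals == top)[1]] != i) next
    later <- idx[idx > i]
    if (!any(!is.na(v[later]) & v[later] < v[i])) next
    out <- c(out, i)
  }
  out
}

# Cohen's kappa from first principles on a plain matrix.
oracle_kappa <- function(m) {
  total <- sum(m)
  po <- sum(diag(m)) / total
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  (po - pe) / (1 - pe)
}

# A minimal valid trial with the given per-bodypart coordinate matrix.
make_trial <- function(parts, n = 60, circle = "CL", horse_id = "T",
                       fps = 30, ...) {
  series <- lapply(parts, function(p) {
    keypoint_series(p$x, p$y, if (is.null(p$lik)) rep(1, n) else p$lik)
  })
  trial_recording(horse_id = horse_id, circle = circle, series = series,
                  fps = fps, ...)
}
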