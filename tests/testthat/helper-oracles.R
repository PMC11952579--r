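# Independent brute-force oracles. These deliberately use plain loops and
# naive definitions, never the package's vectorized/compiled paths.

oracle_iff <- function(times_ms) {
  out_t <- integer(0); out_v <- numeric(0)
  if (length(times_ms) >= 2) {
    for (i in 2:length(times_ms)) {
      out_t <- c(out_t, times_ms[i])
      out_v <- c(out_v, 1000 / (times_ms[i] - times_ms[i - 1]))
    }
  }
  list(times_ms = out_t, iff_hz = out_v)
}

oracle_features <- function(times_ms, burst_gap_ms = 1000) {
  n <- length(times_ms)
  iff <- oracle_iff(times_ms)$iff_hz
  mean_iff <- if (length(iff)) sum(iff) / length(iff) else 0
  peak_iff <- 0
  for (v in iff) if (v > peak_iff) peak_iff <- v
  cv <- 0
  if (length(iff) >= 2 && mean_iff > 0) {
    ss <- 0
    for (v in iff) ss <- ss + (v - mean_iff)^2
    cv <- sqrt(ss / (length(iff) - 1)) / mean_iff
  }
  nb <- 0
  if (n >= 1) {
    nb <- 1
    if (n >= 2) for (i in 2:n)
      if (times_ms[i] - times_ms[i - 1] > burst_gap_ms) nb <- nb + 1
  }
  c(n_spikes = n, mean_iff_hz = mean_iff, peak_iff_hz = peak_iff,
    iff_cv = cv, n_bursts = nb)
}

oracle_max_1s <- function(times_ms, duration_ms, chunk_ms = 1000) {
  best <- 0
  for (s in 0:(duration_ms - chunk_ms)) {
    cnt <- sum(times_ms >= s & times_ms < s + chunk_ms)
    if (cnt > best) best <- cnt
  }
  best
}

# window metric values at a single start, from first principles
oracle_window_metric <- function(train, start, L, metric, bin_hz = 5) {
  t <- train$spike_times_ms
  inside <- t[t >= start & t < start + L]
  if (metric == "max_n_spikes") return(length(inside))
  if (metric == "max_mean_iff") {
    vals <- numeric(0)
    if (length(t) >= 2) for (i in 2:length(t)) {
      if (t[i - 1] >= start && t[i] <= start + L - 1)
        vals <- c(vals, 1000 / (t[i] - t[i - 1]))
    }
    return(if (length(vals)) mean(vals) else 0)
  }
  trace <- step_interpolate(compute_iff(train), train$duration_ms)
  w <- trace[(start + 1):(start + L)]
  if (metric == "max_iff_variation") {
    m <- mean(w)
    return(if (m > 0) sd(w) / m else 0)
  }
  if (metric == "max_iff_entropy") {
    cnt <- table(floor(w / bin_hz))
    p <- cnt / length(w)
    return(max(0, -sum(p * log(p))))
  }
  stop("bad metric")
}

oracle_argmax_start <- function(train, L, metric, bin_hz = 5) {
  starts <- 0:(train$duration_ms - L)
  vals <- vapply(starts, function(s)
    oracle_window_metric(train, s, L, metric, bin_hz), 0)
  # same tie rule as the contract: earliest start within tolerance of max
  m <- max(vals)
  starts[which(vals >= m - 1e-6 * max(1, abs(m)))[1]]
}

random_train <- function(duration_ms = 10000, max_rate_hz = 80, ...) {
  n <- rpois(1, max_rate_hz * duration_ms / 1000 * runif(1, 0.05, 1))
  n <- min(n, duration_ms)
  spike_train(sort(sample.int(duration_ms, n) - 1L),
              duration_ms = duration_ms, ...)
}

# independent oracle: quartic least squares via the normal equations on a
# Vandermonde matrix, then a dense 1 ms scan for max and 90% crossing
oracle_saturation <- function(lengths_ms, acc, fraction = 0.9) {
  w <- lengths_ms / 1000
  V <- outer(w, 0:4, `^`)
  beta <- solve(crossprod(V), crossprod(V, acc))
  grid <- seq(min(lengths_ms), max(lengths_ms)) / 1000
  yhat <- as.numeric(outer(grid, 0:4, `^`) %*% beta)
  imax <- which.max(yhat)
  thr <- fraction * yhat[imax]
  i <- imax
  while (i > 1 && yhat[i - 1] >= thr) i <- i - 1
  grid[i] * 1000
}

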