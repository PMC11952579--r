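#' Window length grid for segment analysis
#'
#' Lengths at 0.1 s steps from 0.1 s to 4 s and at 0.25 s steps from 4 s
#' to 10 s, deduplicated: 64 lengths in total.
#'
#' @return sorted integer vector of window lengths in ms.
#' @export
window_length_grid <- function() {
  unique(c(seq(100L, 4000L, by = 100L), seq(4000L, 10000L, by = 250L)))
}

#' Window-position metric names, in canonical order
#' @export
POSITION_METRICS <- c("first", "max_n_spikes", "max_mean_iff",
                      "max_iff_variation", "max_iff_entropy")

#' IFF histogram entropy
#'
#' Shannon entropy (natural log) of the empirical distribution of
#' step-interpolated IFF values over fixed-width bins; rates below
#' `bin_width_hz` (including silence) share the zero bin.
#'
#' @param values_hz step-IFF values within a window.
#' @param bin_width_hz histogram bin width, Hz (default 5).
#' @return non-negative entropy in nats; 0 for a constant (or all-zero)
#'   window.
#' @export
iff_entropy <- function(values_hz, bin_width_hz = 5) {
  if (!length(values_hz)) return(0)
  p <- tabulate(floor(values_hz / bin_width_hz) + 1L)
  p <- p[p > 0] / length(values_hz)
  max(0, -sum(p * log(p)))
}

# Metric trace over every candidate start for one (train, length):
# internal; relies on the compiled scans.
window_metric_scan <- function(train, length_ms, metric,
                               entropy_bin_hz = 5) {
  D <- train$duration_ms
  t <- train$spike_times_ms
  switch(metric,
    max_n_spikes = as.numeric(cpp_scan_counts(t, length_ms, D)),
    max_mean_iff = {
      n <- length(t)
      if (n < 2L) return(numeric(D - length_ms + 1L))
      cpp_scan_mean_iff(t[-n], t[-1L], 1000 / diff(t), length_ms, D)
    },
    max_iff_variation = cpp_scan_cv(step_interpolate(compute_iff(train), D),
                                    length_ms),
    max_iff_entropy = cpp_scan_entropy(
      step_interpolate(compute_iff(train), D), length_ms, entropy_bin_hz),
    stop("no scan for metric: ", metric))
}

#' Select the most informative segment of a spike train
#'
#' Slides a window of `length_ms` at 1 ms steps over the trial and returns
#' the start maximizing the position metric (`first` always returns start
#' 0). `max_mean_iff` averages only inter-spike intervals with both
#' spikes inside the window; `max_iff_variation` and `max_iff_entropy`
#' are computed from the step-interpolated IFF trace within the window.
#' Ties are broken toward the earliest start.
#'
#' @param train a [spike_train()].
#' @param length_ms window length, at most `duration_ms`.
#' @param metric one of `"first"`, `"max_n_spikes"`, `"max_mean_iff"`,
#'   `"max_iff_variation"`, `"max_iff_entropy"`.
#' @param entropy_bin_hz histogram bin width for the entropy metric.
#' @return list of class `segment`: `start_ms`, `length_ms`, `metric`,
#'   `trial_id`.
#' @export
select_segment <- function(train, length_ms,
                           metric = POSITION_METRICS,
                           entropy_bin_hz = 5) {
  metric <- match.arg(metric)
  length_ms <- as.integer(length_ms)
  stopifnot(length_ms >= 1L, length_ms <= train$duration_ms)
  start <- if (metric == "first" || length_ms == train$duration_ms) {
    0L
  } else {
    v <- window_metric_scan(train, length_ms, metric, entropy_bin_hz)
    # earliest start attaining the maximum, with a small relative
    # tolerance so exact ties are not broken by floating-point noise in
    # the sliding scans
    m <- max(v)
    which(v >= m - 1e-6 * max(1, abs(m)))[1L] - 1L
  }
  structure(list(start_ms = as.integer(start), length_ms = length_ms,
                 metric = metric, trial_id = train$trial_id),
            class = "segment")
}

#' Extract a segment's binary vector
#'
#' @param train a [spike_train()].
#' @param segment a `segment` from [select_segment()].
#' @return 0/1 integer vector of length `segment$length_ms`.
#' @export
segment_binary <- function(train, segment) {
  binarize(train)[(segment$start_ms + 1L):(segment$start_ms + segment$length_ms)]
}

#' Enumerate all segment variants of a dataset
#'
#' For every trial, every combination of window length and position
#' metric: with the full 64-length grid and all five metrics, 320 segment
#' options per trial.
#'
#' @param dataset a [spike_dataset()].
#' @param lengths_ms window lengths (default [window_length_grid()]).
#' @param metrics position metrics (default all five).
#' @return data.frame: `trial_id`, `metric`, `length_ms`, `start_ms`.
#' @export
segment_dataset <- function(dataset, lengths_ms = window_length_grid(),
                            metrics = POSITION_METRICS) {
  grid <- expand.grid(trial_id = names(dataset$trials), metric = metrics,
                      length_ms = lengths_ms, stringsAsFactors = FALSE)
  grid$start_ms <- mapply(function(id, m, L) {
    select_segment(dataset$trials[[id]], L, m)$start_ms
  }, grid$trial_id, grid$metric, grid$length_ms)
  grid[order(grid$trial_id, grid$metric, grid$length_ms), , drop = FALSE]
}

#' CNN accuracy for every (metric, window length) combination
#'
#' The window-position comparison protocol: for each metric and length,
#' segments are selected per trial, binarized (one CNN input size per
#' window length) and classified with repeated stratified CV (default 2
#' repeats).
#'
#' @param dataset a [spike_dataset()] restricted to one subtype.
#' @param lengths_ms,metrics grids to evaluate.
#' @param cv a [cv_spec()] (default 2 repeats of 5 folds).
#' @param spec optional [cnn_spec()] template (input length is adapted per
#'   window length).
#' @return data.frame `subtype,metric,length_ms,repeat_,accuracy` with one
#'   row per CV repeat.
#' @export
window_accuracy_table <- function(dataset, lengths_ms = window_length_grid(),
                                  metrics = POSITION_METRICS,
                                  cv = cv_spec(n_repeats = 2L), spec = NULL) {
  dataset <- sort_dataset(dataset)
  info <- dataset_info(dataset)
  stopifnot(length(unique(info$subtype)) == 1L)
  y <- factor(info$expression,
              levels = intersect(EXPRESSIONS, unique(info$expression)))
  out <- list()
  for (L in lengths_ms) {
    for (m in metrics) {
      X <- t(vapply(dataset$trials, function(tr) {
        segment_binary(tr, select_segment(tr, L, m))
      }, integer(L)))
      rep_ <- run_cv(X, y, cv, classifier = "cnn", cnn = spec)
      out[[length(out) + 1L]] <- data.frame(
        subtype = info$subtype[1L], metric = m, length_ms = L,
        repeat_ = seq_along(rep_$per_repeat_accuracies),
        accuracy = rep_$per_repeat_accuracies, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Direct implementation of the step-up rule: sorted p-values are scaled
#' by `m/i` and a running minimum from the largest p down enforces
#' monotonicity.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pairwise comparison of window-position metrics
#'
#' Two-sided Mann-Whitney U tests on the per-length mean accuracies of
#' each metric pair, with Benjamini-Hochberg correction across the 10
#' pairs.
#'
#' @param acc_table output of [window_accuracy_table()] (or same schema).
#' @return list with `metric_means` (mean accuracy per metric across all
#'   lengths) and `pairs` (data.frame `metric_a,metric_b,statistic,
#'   p_value,p_adj`).
#' @export
compare_window_metrics <- function(acc_table) {
  per_len <- aggregate(accuracy ~ metric + length_ms, acc_table, mean)
  metrics <- unique(per_len$metric)
  means <- vapply(metrics, function(m)
    mean(per_len$accuracy[per_len$metric == m]), 0)
  cmb <- utils::combn(metrics, 2L)
  rows <- apply(cmb, 2L, function(pr) {
    a <- per_len$accuracy[per_len$metric == pr[1L]]
    b <- per_len$accuracy[per_len$metric == pr[2L]]
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    data.frame(metric_a = pr[1L], metric_b = pr[2L],
               statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  pairs$p_adj <- bh_adjust(pairs$p_value)
  list(metric_means = means, pairs = pairs)
}
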