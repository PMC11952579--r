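#' Saturation window length from an accuracy curve
#'
#' Fits a fourth-order polynomial (ordinary least squares on raw
#' polynomial terms) to mean classification accuracy as a function of
#' window length, takes the fitted maximum over the grid's span (scanned
#' at 1 ms resolution), and returns the smallest length at which the
#' fitted curve reaches 90% of that maximum and stays at or above the
#' threshold through the location of the fitted maximum. The "stays
#' above" clause discards spurious early crossings from polynomial
#' wiggle.
#'
#' @param lengths_ms window lengths (>= 6 distinct values).
#' @param accuracies mean accuracy at each length, in `[0, 1]`.
#' @param fraction saturation fraction of the fitted maximum (default
#'   0.9).
#' @return list of class `saturation_result`: `saturation_length_ms`,
#'   `coefficients` (degree 0..4), `fitted_max`, `fitted_argmax_ms`,
#'   `threshold`, plus the raw maximum for reference.
#' @export
fit_saturation <- function(lengths_ms, accuracies, fraction = 0.9) {
  if (length(lengths_ms) != length(accuracies))
    stop("lengths and accuracies differ in length")
  if (length(unique(lengths_ms)) < 6L)
    stop("need at least 6 distinct window lengths")
  if (any(!is.finite(accuracies)))
    stop("non-finite accuracies")
  # scale lengths to seconds for conditioning of the raw quartic
  w <- lengths_ms / 1000
  fit <- lm(accuracies ~ poly(w, 4, raw = TRUE))
  beta <- unname(coef(fit))
  grid <- seq(min(lengths_ms), max(lengths_ms), by = 1) / 1000
  yhat <- beta[1] + beta[2] * grid + beta[3] * grid^2 +
    beta[4] * grid^3 + beta[5] * grid^4
  imax <- which.max(yhat)
  thr <- fraction * yhat[imax]
  # smallest scan index whose fitted value stays >= thr through imax
  above <- yhat[seq_len(imax)] >= thr
  runs <- rle(rev(above))   # trailing TRUE run ending at imax
  first_ok <- imax - runs$lengths[1L] + 1L
  structure(list(
    saturation_length_ms = grid[first_ok] * 1000,
    coefficients = beta,
    fitted_max = yhat[imax],
    fitted_argmax_ms = grid[imax] * 1000,
    threshold = thr,
    raw_max = max(accuracies)),
    class = "saturation_result")
}

#' @export
print.saturation_result <- function(x, ...) {
  cat(sprintf("<saturation: %.0f ms (90%% of fitted max %.3f at %.0f ms)>\n",
              x$saturation_length_ms, x$fitted_max, x$fitted_argmax_ms))
  invisible(x)
}

#' Pick the two best window-position metrics
#'
#' The two metrics with the highest mean accuracy across all window
#' lengths; ties break in the canonical metric order (`first`,
#' `max_n_spikes`, `max_mean_iff`, `max_iff_variation`,
#' `max_iff_entropy`).
#'
#' @param metric_means named numeric vector of per-metric mean accuracies
#'   (e.g. `compare_window_metrics(...)$metric_means`).
#' @return character vector of length 2.
#' @export
best_two_metrics <- function(metric_means) {
  nm <- names(metric_means)
  stopifnot(!is.null(nm), length(metric_means) >= 2L)
  canon <- match(nm, POSITION_METRICS)
  nm[order(-metric_means, canon)][1:2]
}

#' Accuracy curve over window lengths for the best two metrics
#'
#' Runs the window-length protocol (default 7 CV repeats) restricted to
#' the two best position metrics and averages their accuracies per
#' length, optionally within one expression (one-vs-rest accuracy for
#' that expression's trials).
#'
#' @param acc_table long accuracy table from [window_accuracy_table()]
#'   run with the chosen metrics and repeats.
#' @param metrics the two metrics to average over (default: best two by
#'   mean accuracy in the table).
#' @return list of class `accuracy_curve`: `lengths_ms`, `accuracies`,
#'   `metrics`.
#' @export
accuracy_curve <- function(acc_table, metrics = NULL) {
  if (is.null(metrics)) {
    mm <- vapply(split(acc_table$accuracy, acc_table$metric), mean, 0)
    metrics <- best_two_metrics(mm)
  }
  sub <- acc_table[acc_table$metric %in% metrics, , drop = FALSE]
  agg <- aggregate(accuracy ~ length_ms, sub, mean)
  agg <- agg[order(agg$length_ms), ]
  structure(list(lengths_ms = agg$length_ms, accuracies = agg$accuracy,
                 metrics = metrics),
            class = "accuracy_curve")
}
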