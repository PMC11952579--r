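#' Cross-validation specification
#'
#' Repeated stratified k-fold protocol used throughout: 20 repeats for
#' full-train expression/gesture classification, 2 for the window-metric
#' comparison, 7 for the window-length accuracy curves and 5 for the
#' jitter analysis.
#'
#' @param n_folds number of folds (default 5).
#' @param n_repeats number of repeats.
#' @param stratified stratify folds on the class label (default `TRUE`).
#' @param seed integer seed controlling the fold draws.
#' @return list of class `cv_spec`.
#' @export
cv_spec <- function(n_folds = 5L, n_repeats = 20L, stratified = TRUE,
                    seed = 1L) {
  stopifnot(n_folds >= 2L, n_repeats >= 1L)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_spec")
}

#' Stratified fold assignment
#'
#' Shuffles indices within each class and deals them round-robin, so
#' per-fold class counts differ by at most one trial. With `groups`,
#' whole groups (e.g. units) are dealt instead of single trials.
#'
#' @param y factor of class labels.
#' @param n_folds number of folds.
#' @param stratified stratify on `y`; otherwise a plain shuffle is dealt.
#' @param groups optional grouping vector; trials sharing a group land in
#'   one fold.
#' @return integer fold id per observation, in `1:n_folds`. Uses the
#'   current R RNG stream.
#' @export
make_folds <- function(y, n_folds = 5L, stratified = TRUE, groups = NULL) {
  n <- length(y)
  fold <- integer(n)
  if (!is.null(groups)) {
    g <- unique(groups)
    gf <- sample(rep_len(seq_len(n_folds), length(g)))
    fold <- gf[match(groups, g)]
    return(fold)
  }
  if (stratified) {
    for (cl in levels(factor(y))) {
      idx <- which(y == cl)
      if (length(idx) < n_folds)
        stop("class '", cl, "' has ", length(idx), " trials < ", n_folds,
             " folds")
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds),
                                                    length(idx))
    }
  } else {
    fold <- sample(rep_len(seq_len(n_folds), n))
  }
  fold
}

#' Confusion matrix from label pairs
#'
#' @param truth,pred factors over the same class set.
#' @param normalize row-normalize (rows = true class) so each row sums
#'   to 1; rows with no observations are left at 0.
#' @return square matrix, classes in `levels(truth)` order.
#' @export
confusion_matrix <- function(truth, pred, normalize = TRUE) {
  if (!identical(levels(truth), levels(pred)))
    stop("truth and pred must share the same class set")
  m <- table(truth = truth, pred = pred)
  m <- matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m))
  if (normalize) {
    rs <- rowSums(m)
    nz <- rs > 0
    m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  }
  m
}

#' Pool classification reports into one confusion matrix
#'
#' @param reports list of `classification_report`s over the same classes.
#' @param percent return percentages (default) rather than proportions.
#' @return row-normalized pooled confusion matrix.
#' @export
pooled_confusion <- function(reports, percent = TRUE) {
  cls <- lapply(reports, function(r) colnames(r$confusion_counts))
  if (length(unique(vapply(cls, paste, "", collapse = "|"))) != 1L)
    stop("reports have mismatched class sets")
  counts <- Reduce(`+`, lapply(reports, `[[`, "confusion_counts"))
  rs <- rowSums(counts)
  nz <- rs > 0
  counts[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
  if (percent) counts * 100 else counts
}

#' Run a repeated stratified cross-validation
#'
#' The generic CV harness behind both classifiers. Within each repeat the
#' held-out predictions of all folds are pooled into one accuracy; the
#' reported `mean_accuracy` is the average of the per-repeat accuracies.
#' Feature classifiers z-score each column using training-fold statistics
#' only.
#'
#' @param X numeric matrix: `n x 5` features (`classifier = "svm"`) or
#'   `n x duration_ms` binary spike trains (`classifier = "cnn"`).
#' @param y factor of class labels, length `n`.
#' @param cv a [cv_spec()].
#' @param classifier `"svm"` or `"cnn"`.
#' @param cnn a [cnn_spec()] when `classifier = "cnn"`.
#' @param groups optional grouping vector passed to [make_folds()].
#' @param test_transform optional `function(X_test, repeat, fold)` applied
#'   to held-out inputs before prediction (used by the jitter protocol).
#' @return object of class `classification_report`: `mean_accuracy`,
#'   `per_repeat_accuracies`, row-stochastic `confusion` (pooled over all
#'   held-out predictions), raw `confusion_counts`, per-prediction table
#'   `predictions`, and the specs and seed used.
#' @export
run_cv <- function(X, y, cv = cv_spec(), classifier = c("svm", "cnn"),
                   cnn = NULL, groups = NULL, test_transform = NULL) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(cv, "cv_spec"), nrow(X) == length(y))
  y <- droplevels(factor(y))
  k <- nlevels(y)
  if (k < 2L) stop("need at least 2 classes")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  per_repeat <- numeric(cv$n_repeats)
  counts <- matrix(0, k, k, dimnames = list(levels(y), levels(y)))
  pred_rows <- vector("list", cv$n_repeats * cv$n_folds)
  pi_ <- 0L
  for (r in seq_len(cv$n_repeats)) {
    set.seed(cv$seed + 7919L * r)
    fold <- make_folds(y, cv$n_folds, cv$stratified, groups)
    correct <- 0L; total <- 0L
    for (f in seq_len(cv$n_folds)) {
      tr <- fold != f; te <- fold == f
      if (!any(te)) next
      Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      if (!is.null(test_transform)) Xte <- test_transform(Xte, r, f)
      if (classifier == "svm") {
        model <- svm_linear_fit(Xtr, y[tr])
        pred <- svm_linear_predict(model, Xte, levels(y))
      } else {
        model <- cnn_fit(Xtr, y[tr], spec = cnn,
                         seed = cv$seed + 104729L * r + 1299709L * f)
        pred <- cnn_predict_class(model, Xte, levels(y))
      }
      correct <- correct + sum(pred == y[te])
      total <- total + sum(te)
      counts <- counts + confusion_matrix(y[te], pred, normalize = FALSE)
      pi_ <- pi_ + 1L
      pred_rows[[pi_]] <- data.frame(repeat_ = r, fold = f,
                                     index = which(te),
                                     truth = as.character(y[te]),
                                     pred = as.character(pred),
                                     stringsAsFactors = FALSE)
    }
    per_repeat[r] <- correct / total
  }
  rs <- rowSums(counts); nz <- rs > 0
  conf <- counts
  conf[nz, ] <- conf[nz, , drop = FALSE] / rs[nz]
  structure(list(mean_accuracy = mean(per_repeat),
                 per_repeat_accuracies = per_repeat,
                 confusion = conf, confusion_counts = counts,
                 predictions = do.call(rbind, pred_rows[seq_len(pi_)]),
                 classifier = classifier, cv = cv, cnn = cnn,
                 classes = levels(y)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report: %s, %d classes, mean accuracy %.1f%% (sd %.1f%%) over %d repeats>\n",
              x$classifier, length(x$classes), 100 * x$mean_accuracy,
              100 * sd(x$per_repeat_accuracies), length(x$per_repeat_accuracies)))
  invisible(x)
}
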