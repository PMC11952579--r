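# Linear support-vector machine, one-vs-rest, squared hinge loss.
#
# The feature space is tiny (five aggregate firing features), so the
# primal objective 0.5*||w||^2 + C * sum_i max(0, 1 - y_i f(x_i))^2 is
# minimized directly with BFGS and an analytic gradient; the squared hinge
# makes the objective differentiable. Deterministic (zero init, no
# stochastic steps). Features are z-scored with training statistics inside
# the fit, so cross-validation never leaks test-fold scale.

svm_binary_fit <- function(X, ypm, C = 1) {
  d <- ncol(X)
  obj <- function(par) {
    w <- par[1:d]; b <- par[d + 1L]
    m <- 1 - ypm * (X %*% w + b)
    h <- pmax(m, 0)
    0.5 * sum(w^2) + C * sum(h^2)
  }
  grad <- function(par) {
    w <- par[1:d]; b <- par[d + 1L]
    m <- as.numeric(1 - ypm * (X %*% w + b))
    h <- pmax(m, 0)
    gcoef <- -2 * C * h * ypm
    c(w + as.numeric(crossprod(X, gcoef)), sum(gcoef))
  }
  fit <- optim(numeric(d + 1L), obj, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  fit$par
}

#' Fit a linear SVM (one-vs-rest, squared hinge)
#'
#' @param X numeric feature matrix (rows = trials).
#' @param y factor of class labels.
#' @param C margin regularization constant (default 1, held fixed).
#' @return list of class `svm_linear` with per-class weight vectors and
#'   the training z-scoring statistics.
#' @export
svm_linear_fit <- function(X, y, C = 1) {
  y <- droplevels(factor(y))
  mu <- colMeans(X)
  sdev <- apply(X, 2L, sd)
  sdev[sdev < 1e-12] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdev, "/")
  W <- vapply(levels(y), function(cl) {
    svm_binary_fit(Z, ifelse(y == cl, 1, -1), C = C)
  }, numeric(ncol(X) + 1L))
  structure(list(W = W, mu = mu, sd = sdev, classes = levels(y), C = C),
            class = "svm_linear")
}

#' Predict classes with a fitted linear SVM
#'
#' @param model an `svm_linear` fit.
#' @param X feature matrix.
#' @param levels_out factor levels for the returned predictions (default:
#'   the model's training classes).
#' @return factor of predicted classes (argmax one-vs-rest score).
#' @export
svm_linear_predict <- function(model, X, levels_out = model$classes) {
  Z <- sweep(sweep(X, 2L, model$mu), 2L, model$sd, "/")
  d <- nrow(model$W) - 1L
  scores <- Z %*% model$W[1:d, , drop = FALSE] +
    matrix(model$W[d + 1L, ], nrow(Z), ncol(model$W), byrow = TRUE)
  factor(model$classes[max.col(scores, ties.method = "first")],
         levels = levels_out)
}

#' Rate-coding expression classification
#'
#' Linear SVM on the five firing features of one afferent subtype under
#' repeated stratified cross-validation.
#'
#' @param dataset a [spike_dataset()] (restricted to one subtype, or pass
#'   `subtype`).
#' @param subtype optional subtype filter.
#' @param cv a [cv_spec()].
#' @param group_by_unit keep each unit's trials in one fold.
#' @return a `classification_report`.
#' @export
train_eval_svm <- function(dataset, subtype = NULL, cv = cv_spec(),
                           group_by_unit = FALSE) {
  if (!is.null(subtype)) dataset <- filter_dataset(dataset, subtype = subtype)
  dataset <- sort_dataset(dataset)
  ft <- feature_table(dataset)
  if (length(unique(ft$subtype)) > 1L)
    stop("dataset spans multiple subtypes; pass subtype=")
  y <- factor(ft$expression, levels = intersect(EXPRESSIONS,
                                                unique(ft$expression)))
  run_cv(as.matrix(ft[, FEATURE_COLS]), y, cv, classifier = "svm",
         groups = if (group_by_unit) ft$unit_id else NULL)
}
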