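test_that("stratified folds partition trials with balanced classes", {
  set.seed(16)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    counts <- sample(5:20, k, replace = TRUE)
    y <- factor(rep(letters[1:k], counts))
    fold <- make_folds(y, n_folds = 5L)
    expect_length(fold, length(y))
    expect_true(all(fold %in% 1:5))
    # every trial in exactly one fold is implied by fold being a vector;
    # check per-fold class counts are within 1 of each other
    for (cl in levels(y)) {
      tab <- tabulate(fold[y == cl], nbins = 5)
      expect_lte(diff(range(tab)), 1L)
    }
  }
})

test_that("grouped folds keep a unit's trials together", {
  set.seed(17)
  y <- factor(rep(c("a", "b"), each = 30))
  groups <- rep(sprintf("u%d", 1:10), each = 6)
  fold <- make_folds(y, 5L, groups = groups)
  expect_true(all(tapply(fold, groups, function(f) length(unique(f))) == 1L))
})

test_that("confusion matrices are row-stochastic and tally correctly", {
  truth <- factor(c("a", "a", "b", "b", "c"), levels = c("a", "b", "c"))
  pred <- factor(c("a", "b", "b", "b", "a"), levels = c("a", "b", "c"))
  cm <- confusion_matrix(truth, pred)
  expect_equal(rowSums(cm), c(a = 1, b = 1, c = 1))
  expect_equal(cm["a", ], c(a = 0.5, b = 0.5, c = 0))
  expect_equal(cm["c", ], c(a = 1, b = 0, c = 0))
  raw <- confusion_matrix(truth, pred, normalize = FALSE)
  expect_equal(sum(raw), 5)
  expect_error(confusion_matrix(factor("a"), factor("b")), "class set")
})

test_that("pooled confusion reduces to identity / uniform in edge cases", {
  mk <- function(truth, pred) {
    counts <- confusion_matrix(truth, pred, normalize = FALSE)
    structure(list(confusion_counts = counts), class = "classification_report")
  }
  y <- factor(rep(c("a", "b"), each = 10))
  perfect <- pooled_confusion(list(mk(y, y), mk(y, y)), percent = FALSE)
  expect_equal(perfect, diag(2), ignore_attr = TRUE)

  set.seed(18)
  yy <- factor(rep(c("a", "b"), each = 4000))
  chance <- pooled_confusion(list(mk(yy, sample(yy))), percent = TRUE)
  expect_equal(as.numeric(chance), rep(50, 4), tolerance = 0.12)
})

test_that("linear SVM achieves 100% on class-unique constant features", {
  X <- rbind(matrix(0, 10, 5), matrix(5, 10, 5), matrix(-5, 10, 5))
  y <- factor(rep(c("a", "b", "c"), each = 10))
  rep_ <- run_cv(X, y, cv_spec(n_repeats = 2L, seed = 5L), classifier = "svm")
  expect_equal(rep_$mean_accuracy, 1)
})

test_that("svm fit/predict interface round-trips labels", {
  set.seed(19)
  X <- rbind(matrix(rnorm(50, 0), 10), matrix(rnorm(50, 3), 10))
  y <- factor(rep(c("lo", "hi"), each = 10), levels = c("lo", "hi"))
  m <- svm_linear_fit(X, y)
  pred <- svm_linear_predict(m, X)
  expect_gte(mean(pred == y), 0.9)
  expect_identical(levels(pred), levels(droplevels(y)))
})

test_that("CNN learns a trivially separable temporal pattern", {
  # class A: burst early; class B: burst late
  set.seed(20)
  mk <- function(pos) {
    x <- numeric(2000)
    x[pos + sample(0:199, 60)] <- 1
    x
  }
  X <- rbind(t(replicate(12, mk(100))), t(replicate(12, mk(1500))))
  y <- factor(rep(c("early", "late"), each = 12))
  m <- cnn_fit(X, y, spec = cnn_spec(input_len = 2000L, max_epochs = 40L),
               seed = 3L)
  pred <- cnn_predict_class(m, X)
  expect_gte(mean(pred == y), 0.95)
  p <- cnn_predict_proba(m, X)
  expect_equal(rowSums(p), rep(1, 24), tolerance = 1e-9)
})

test_that("CNN training is deterministic given the seed", {
  set.seed(21)
  X <- matrix(rbinom(20 * 500, 1, 0.02), 20, 500)
  y <- factor(rep(c("a", "b"), each = 10))
  sp <- cnn_spec(input_len = 500L, max_epochs = 5L)
  m1 <- cnn_fit(X, y, sp, seed = 9L)
  m2 <- cnn_fit(X, y, sp, seed = 9L)
  expect_identical(m1$W, m2$W)
  expect_identical(cnn_predict_proba(m1, X), cnn_predict_proba(m2, X))
})

test_that("accuracy is invariant to trial ordering in the dataset", {
  ds <- fixture_dataset(subtypes = "SA-II")
  rev_ds <- spike_dataset(rev(ds$trials), provenance = ds$provenance)
  cv <- cv_spec(n_repeats = 2L, seed = 6L)
  expect_identical(train_eval_svm(ds, cv = cv)$mean_accuracy,
                   train_eval_svm(rev_ds, cv = cv)$mean_accuracy)
})

test_that("report confusion rows sum to one over observed classes", {
  ds <- fixture_dataset(subtypes = "SA-II")
  rep_ <- train_eval_svm(ds, cv = cv_spec(n_repeats = 2L, seed = 7L))
  expect_equal(rowSums(rep_$confusion), rep(1, 6), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_identical(rep_$classes, EXPRESSIONS)
})
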