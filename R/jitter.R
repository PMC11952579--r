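#' Add Gaussian spike-timing jitter
#'
#' Each spike time is perturbed independently by zero-mean Gaussian noise
#' of SD `sd_ms`, rounded to the 1 ms grid and clipped into
#' `[0, duration-1]` (clipping, not deletion, so timing noise is not
#' confounded with rate loss). Bin collisions are re-assigned to the
#' nearest free bin, so the spike count is always preserved. `sd_ms = 0`
#' returns the train unchanged.
#'
#' @param train a [spike_train()].
#' @param sd_ms noise standard deviation in ms.
#' @return a jittered [spike_train()] with the same labels. Uses the
#'   current R RNG stream.
#' @export
add_jitter <- function(train, sd_ms) {
  stopifnot(inherits(train, "spike_train"), sd_ms >= 0)
  if (sd_ms == 0 || !length(train$spike_times_ms)) return(train)
  t2 <- round(train$spike_times_ms + rnorm(length(train$spike_times_ms),
                                           0, sd_ms))
  t2 <- pmin(pmax(t2, 0), train$duration_ms - 1L)
  t2 <- resolve_collisions(t2, train$duration_ms)
  spike_train(t2, duration_ms = train$duration_ms, unit_id = train$unit_id,
              subtype = train$subtype, expression = train$expression,
              trial_id = train$trial_id)
}

#' Jitter protocol specification
#'
#' @param sd_grid_ms noise SD grid (default 0 to 100 ms in 5 ms steps).
#' @param n_noise_sets independent noise realizations per SD level
#'   (default 10).
#' @param cv a [cv_spec()] (default 5 repeats of 5 folds).
#' @param seed base seed for the noise substreams.
#' @return list of class `jitter_spec`.
#' @export
jitter_spec <- function(sd_grid_ms = seq(0, 100, by = 5), n_noise_sets = 10L,
                        cv = cv_spec(n_repeats = 5L), seed = 1L) {
  stopifnot(all(sd_grid_ms >= 0), n_noise_sets >= 1L)
  structure(list(sd_grid_ms = sd_grid_ms,
                 n_noise_sets = as.integer(n_noise_sets),
                 cv = cv, seed = as.integer(seed)),
            class = "jitter_spec")
}

#' Spike-timing noise sensitivity of the temporal-coding classifier
#'
#' Trains the CNN per cross-validation split on clean (noise-free)
#' training folds, then evaluates each held-out fold repeatedly with
#' Gaussian spike-timing jitter at every SD level, using
#' `n_noise_sets` independent noise realizations per level (a single
#' no-noise evaluation at SD 0, which reproduces the clean baseline
#' exactly). Each noise cell is seeded as a deterministic function of
#' (base seed, SD index, set index, repeat, fold).
#'
#' @param dataset a [spike_dataset()] restricted to one subtype.
#' @param jspec a [jitter_spec()].
#' @param spec optional [cnn_spec()].
#' @return list of class `jitter_result`: `accuracy` (data.frame
#'   `subtype,expression,sd_ms,accuracy`, averaged over repeats, folds
#'   and noise sets; expression `"overall"` rows give the pooled
#'   accuracy), `confusion` (list of 6x6 row-stochastic matrices per SD),
#'   and `clean_report` (the SD-0 `classification_report`).
#' @export
jitter_protocol <- function(dataset, jspec = jitter_spec(), spec = NULL) {
  dataset <- sort_dataset(dataset)
  info <- dataset_info(dataset)
  stopifnot(length(unique(info$subtype)) == 1L)
  subtype <- info$subtype[1L]
  X <- binary_matrix(dataset)
  y <- factor(info$expression,
              levels = intersect(EXPRESSIONS, unique(info$expression)))
  k <- nlevels(y)
  cv <- jspec$cv
  nsd <- length(jspec$sd_grid_ms)
  correct <- array(0, c(nsd, k))     # per (sd, expression) correct counts
  total <- array(0, c(nsd, k))
  counts <- array(0, c(nsd, k, k))   # per-sd confusion counts
  clean_counts <- matrix(0, k, k, dimnames = list(levels(y), levels(y)))
  clean_per_repeat <- numeric(cv$n_repeats)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (r in seq_len(cv$n_repeats)) {
    set.seed(cv$seed + 7919L * r)
    fold <- make_folds(y, cv$n_folds, cv$stratified)
    rep_correct <- 0L; rep_total <- 0L
    for (f in seq_len(cv$n_folds)) {
      tr <- fold != f; te <- which(fold == f)
      model <- cnn_fit(X[tr, , drop = FALSE], y[tr],
                       spec = spec,
                       seed = cv$seed + 104729L * r + 1299709L * f)
      trains_te <- dataset$trials[te]
      for (si in seq_len(nsd)) {
        sd_ms <- jspec$sd_grid_ms[si]
        nsets <- if (sd_ms == 0) 1L else jspec$n_noise_sets
        for (set in seq_len(nsets)) {
          if (sd_ms == 0) {
            Xte <- X[te, , drop = FALSE]
          } else {
            set.seed((jspec$seed + 13L * si + 269L * set + 7919L * r +
                        104729L * f) %% 2147483647L)
            Xte <- t(vapply(trains_te, function(tt)
              binarize(add_jitter(tt, sd_ms)),
              integer(dataset$duration_ms)))
          }
          pred <- cnn_predict_class(model, Xte, levels(y))
          ok <- pred == y[te]
          for (cl in seq_len(k)) {
            m <- as.integer(y[te]) == cl
            correct[si, cl] <- correct[si, cl] + sum(ok[m])
            total[si, cl] <- total[si, cl] + sum(m)
          }
          counts[si, , ] <- counts[si, , ] +
            confusion_matrix(y[te], pred, normalize = FALSE)
          if (sd_ms == 0) {
            rep_correct <- rep_correct + sum(ok)
            rep_total <- rep_total + length(ok)
            clean_counts <- clean_counts +
              confusion_matrix(y[te], pred, normalize = FALSE)
          }
        }
      }
    }
    clean_per_repeat[r] <- rep_correct / rep_total
  }
  acc_rows <- list()
  for (si in seq_len(nsd)) {
    acc_rows[[length(acc_rows) + 1L]] <- data.frame(
      subtype = subtype, expression = c(levels(y), "overall"),
      sd_ms = jspec$sd_grid_ms[si],
      accuracy = c(correct[si, ] / pmax(total[si, ], 1),
                   sum(correct[si, ]) / sum(total[si, ])),
      stringsAsFactors = FALSE)
  }
  confusion <- lapply(seq_len(nsd), function(si) {
    m <- counts[si, , ]
    dimnames(m) <- list(levels(y), levels(y))
    rs <- rowSums(m); nz <- rs > 0
    m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
    m
  })
  names(confusion) <- as.character(jspec$sd_grid_ms)
  rs <- rowSums(clean_counts); nz <- rs > 0
  clean_conf <- clean_counts
  clean_conf[nz, ] <- clean_conf[nz, , drop = FALSE] / rs[nz]
  clean_report <- structure(
    list(mean_accuracy = mean(clean_per_repeat),
         per_repeat_accuracies = clean_per_repeat,
         confusion = clean_conf, confusion_counts = clean_counts,
         predictions = NULL, classifier = "cnn", cv = cv, cnn = spec,
         classes = levels(y)),
    class = "classification_report")
  structure(list(accuracy = do.call(rbind, acc_rows), confusion = confusion,
                 clean_report = clean_report, jspec = jspec,
                 subtype = subtype),
            class = "jitter_result")
}
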