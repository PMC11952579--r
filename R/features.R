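#' Aggregate rate-coding firing features
#'
#' Extracts the five features used for rate-coding classification from a
#' full-trial spike train: total spike count, mean IFF, peak IFF, IFF
#' variation (coefficient of variation of the IFF values) and burst count
#' (maximal spike groups separated by inter-spike intervals > 1 s).
#'
#' Degenerate trains are total: fewer than 2 spikes give mean/peak IFF 0,
#' fewer than 3 spikes give IFF variation 0, an empty train has 0 bursts
#' and a non-empty train with no gap > 1 s has 1 burst.
#'
#' @param train a [spike_train()].
#' @param burst_gap_ms ISI threshold separating bursts (default 1000).
#' @return named numeric vector `n_spikes`, `mean_iff_hz`, `peak_iff_hz`,
#'   `iff_cv`, `n_bursts`.
#' @export
extract_features <- function(train, burst_gap_ms = 1000) {
  stopifnot(inherits(train, "spike_train"))
  t <- train$spike_times_ms
  n <- length(t)
  iff <- compute_iff(train)$iff_hz
  mean_iff <- if (length(iff)) mean(iff) else 0
  peak_iff <- if (length(iff)) max(iff) else 0
  cv <- if (length(iff) >= 2L && mean_iff > 0) sd(iff) / mean_iff else 0
  nb <- if (n == 0L) 0L else sum(diff(t) > burst_gap_ms) + 1L
  c(n_spikes = n, mean_iff_hz = mean_iff, peak_iff_hz = peak_iff,
    iff_cv = cv, n_bursts = as.numeric(nb))
}

#' Maximum spike count in any 1 s chunk
#'
#' Highest spike count over all 1000 ms windows slid at 1 ms steps within
#' the trial; used to characterize gesture responses while avoiding long
#' non-contact gaps.
#'
#' @param train a [spike_train()].
#' @param chunk_ms window length (default 1000).
#' @return integer count.
#' @export
max_1s_spike_count <- function(train, chunk_ms = 1000L) {
  stopifnot(inherits(train, "spike_train"))
  t <- train$spike_times_ms
  if (!length(t)) return(0L)
  chunk_ms <- min(as.integer(chunk_ms), train$duration_ms)
  # the count as a function of window start changes only at spike times,
  # so scanning spike-anchored starts (clamped to the last valid start)
  # attains the maximum of the full 1 ms scan
  starts <- unique(pmin(t, train$duration_ms - chunk_ms))
  counts <- findInterval(starts + chunk_ms - 0.5, t) -
    findInterval(starts - 0.5, t)
  max(counts)
}

#' Dataset-level feature table
#'
#' @param dataset a [spike_dataset()].
#' @return data.frame: trial metadata plus the five features and
#'   `max_1s_count`.
#' @export
feature_table <- function(dataset) {
  info <- dataset_info(dataset)
  fx <- t(vapply(dataset$trials, extract_features, numeric(5)))
  info$n_spikes <- NULL
  cbind(info,
        as.data.frame(fx),
        max_1s_count = vapply(dataset$trials, max_1s_spike_count, 0L),
        stringsAsFactors = FALSE)
}

FEATURE_COLS <- c("n_spikes", "mean_iff_hz", "peak_iff_hz", "iff_cv",
                  "n_bursts")

#' Map expressions to elementary touch gestures
#'
#' attention and happiness are tapping; calming and love are stroking;
#' sadness is holding; gratitude (mixed tapping and holding) maps to `NA`
#' and is excluded from gesture-level analyses.
#'
#' @param expression character vector of expression labels.
#' @return character vector of `"tapping"`, `"stroking"`, `"holding"` or
#'   `NA`.
#' @export
gesture_label <- function(expression) {
  map <- c(attention = "tapping", happiness = "tapping",
           calming = "stroking", love = "stroking",
           sadness = "holding", gratitude = NA_character_)
  unname(map[expression])
}

#' Gesture classification from firing features
#'
#' Per-subtype linear SVM on the five firing features, classifying the
#' three elementary gestures (gratitude excluded) under repeated
#' stratified five-fold cross-validation.
#'
#' @param dataset a [spike_dataset()].
#' @param subtype subtype to analyse (required if the dataset holds more
#'   than one).
#' @param cv a [cv_spec()] (default: 5 folds, 20 repeats).
#' @param group_by_unit if `TRUE`, folds keep all trials of a unit
#'   together (leakage-controlled variant); default stratifies on the
#'   class label only.
#' @return a `classification_report` (see [run_cv()]).
#' @export
classify_gestures <- function(dataset, subtype = NULL,
                              cv = cv_spec(n_repeats = 20L),
                              group_by_unit = FALSE) {
  if (!is.null(subtype)) dataset <- filter_dataset(dataset, subtype = subtype)
  dataset <- sort_dataset(dataset)
  ft <- feature_table(dataset)
  ft$gesture <- gesture_label(ft$expression)
  ft <- ft[!is.na(ft$gesture), , drop = FALSE]
  if (length(unique(ft$gesture)) < 2L)
    stop("need at least 2 gesture classes after excluding gratitude")
  X <- as.matrix(ft[, FEATURE_COLS])
  y <- factor(ft$gesture, levels = c("tapping", "stroking", "holding"))
  y <- droplevels(y)
  run_cv(X, y, cv, classifier = "svm",
         groups = if (group_by_unit) ft$unit_id else NULL)
}
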