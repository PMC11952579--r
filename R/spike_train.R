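#' @useDynLib touchcode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd rnorm runif optim wilcox.test lm coef predict aggregate
#' @importFrom utils head tail
NULL

#' Label sets
#'
#' `AFFERENT_SUBTYPES`: the six retained afferent subtypes.
#' `EXPRESSIONS`: the six standardized touch expressions.
#' @export
AFFERENT_SUBTYPES <- c("Field", "HFA", "FA-II", "SA-II", "CT", "MS")

#' @rdname AFFERENT_SUBTYPES
#' @export
EXPRESSIONS <- c("attention", "happiness", "calming", "love", "gratitude",
                 "sadness")

#' Single-trial spike train
#'
#' Constructs a validated spike train: the spike times (integer milliseconds
#' since trial onset, strictly increasing, half-open coordinate convention
#' `[0, duration_ms)`) of one afferent unit during one touch-expression trial.
#'
#' @param spike_times_ms integer vector of spike times in ms; must be strictly
#'   increasing and lie in `[0, duration_ms)`.
#' @param duration_ms trial duration in ms (default 10000: trials are cropped
#'   to the first 10 s at 1 ms resolution).
#' @param unit_id character scalar identifying the afferent unit.
#' @param subtype afferent subtype, one of `"Field"`, `"HFA"`, `"FA-II"`,
#'   `"SA-II"`, `"CT"`, `"MS"`, or `NA` for unlabeled use.
#' @param expression touch expression label, one of `"attention"`,
#'   `"happiness"`, `"calming"`, `"love"`, `"gratitude"`, `"sadness"`, or `NA`.
#' @param trial_id character scalar; unique within a dataset.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(spike_times_ms = integer(), duration_ms = 10000L,
                        unit_id = NA_character_, subtype = NA_character_,
                        expression = NA_character_, trial_id = NA_character_) {
  spike_times_ms <- as.integer(spike_times_ms)
  duration_ms <- as.integer(duration_ms)
  if (length(duration_ms) != 1L || is.na(duration_ms) || duration_ms <= 0L)
    stop("duration_ms must be a single positive integer")
  if (anyNA(spike_times_ms))
    stop("spike times contain NA (trial ", trial_id, ")")
  if (length(spike_times_ms) && (min(spike_times_ms) < 0L ||
                                 max(spike_times_ms) >= duration_ms))
    stop("spike times out of range [0, ", duration_ms, ") in trial ",
         trial_id)
  if (is.unsorted(spike_times_ms, strictly = TRUE))
    stop("spike times not strictly increasing in trial ", trial_id,
         " (resolve ties with resolve_collisions() before construction)")
  if (!is.na(subtype) && !subtype %in% AFFERENT_SUBTYPES)
    stop("unknown subtype '", subtype, "' in trial ", trial_id)
  if (!is.na(expression) && !expression %in% EXPRESSIONS)
    stop("unknown expression '", expression, "' in trial ", trial_id)
  structure(
    list(spike_times_ms = spike_times_ms, duration_ms = duration_ms,
         unit_id = as.character(unit_id), subtype = as.character(subtype),
         expression = as.character(expression),
         trial_id = as.character(trial_id)),
    class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s: %d spikes / %d ms, unit %s, %s, %s>\n",
              x$trial_id, length(x$spike_times_ms), x$duration_ms,
              x$unit_id, x$subtype, x$expression))
  invisible(x)
}

#' Resolve spike-time bin collisions
#'
#' Re-assigns spikes that fall into an already occupied 1 ms bin to the
#' nearest free bin (ties broken toward the earlier bin), preserving the
#' spike count. Used when loading quantized data and after timing jitter.
#'
#' @param times_ms integer spike times, sorted, possibly with duplicates.
#' @param duration_ms trial duration in ms.
#' @return strictly increasing integer vector of the same length.
#' @export
resolve_collisions <- function(times_ms, duration_ms) {
  times_ms <- as.integer(sort(times_ms))
  duration_ms <- as.integer(duration_ms)
  if (length(times_ms) > duration_ms)
    stop("more spikes than 1 ms bins: cannot resolve collisions")
  if (!anyDuplicated(times_ms)) return(times_ms)
  occupied <- logical(duration_ms)
  out <- integer(length(times_ms))
  for (i in seq_along(times_ms)) {
    t <- times_ms[i]
    if (!occupied[t + 1L]) {
      out[i] <- t
    } else {
      d <- 1L
      repeat {
        lo <- t - d
        hi <- t + d
        if (lo >= 0L && !occupied[lo + 1L]) { out[i] <- lo; break }
        if (hi < duration_ms && !occupied[hi + 1L]) { out[i] <- hi; break }
        d <- d + 1L
      }
    }
    occupied[out[i] + 1L] <- TRUE
  }
  sort(out)
}

#' Instantaneous firing frequency series
#'
#' IFF is defined at each spike from the second onward as the reciprocal of
#' the interval to the previous spike, in Hz. A train with fewer than two
#' spikes yields an empty series.
#'
#' @param train a [spike_train()].
#' @return list of class `iff_series` with `times_ms` (spike times from the
#'   second spike on) and `iff_hz`.
#' @export
compute_iff <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  t <- train$spike_times_ms
  if (length(t) < 2L) {
    return(structure(list(times_ms = integer(), iff_hz = numeric()),
                     class = "iff_series"))
  }
  structure(list(times_ms = t[-1L], iff_hz = 1000 / diff(t)),
            class = "iff_series")
}

#' Step-interpolated IFF trace
#'
#' Expands an IFF series onto the uniform 1 ms grid as a piecewise-constant
#' trace: zero before the second spike, then the IFF value of spike i (its
#' backward inter-spike interval) held on `[t_i, t_{i+1})`, with the last
#' value held to trial end (hold-forward convention).
#'
#' @param iff an `iff_series` from [compute_iff()].
#' @param duration_ms length of the output grid in ms.
#' @return numeric vector of length `duration_ms`, in Hz.
#' @export
step_interpolate <- function(iff, duration_ms) {
  stopifnot(inherits(iff, "iff_series"))
  duration_ms <- as.integer(duration_ms)
  out <- numeric(duration_ms)
  n <- length(iff$times_ms)
  if (n == 0L) return(out)
  if (max(iff$times_ms) >= duration_ms)
    stop("duration_ms must exceed the last spike time")
  starts <- iff$times_ms
  ends <- c(starts[-1L], duration_ms)   # half-open segment ends
  for (i in seq_len(n)) {
    out[(starts[i] + 1L):ends[i]] <- iff$iff_hz[i]
  }
  out
}

#' Binarize a spike train
#'
#' @param train a [spike_train()].
#' @return integer 0/1 vector of length `duration_ms`; element `t+1` is 1
#'   iff a spike occupies bin `t`.
#' @export
binarize <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  v <- integer(train$duration_ms)
  v[unique(train$spike_times_ms) + 1L] <- 1L
  v
}

#' Labeled spike-train dataset
#'
#' @param trials list of [spike_train()] objects sharing `duration_ms`;
#'   trial ids must be unique.
#' @param provenance free-text provenance (file path or generator config
#'   hash).
#' @return object of class `spike_dataset`.
#' @export
spike_dataset <- function(trials, provenance = "") {
  stopifnot(is.list(trials), all(vapply(trials, inherits, TRUE, "spike_train")))
  ids <- vapply(trials, `[[`, "", "trial_id")
  if (anyDuplicated(ids)) stop("duplicate trial_id: ",
                               ids[duplicated(ids)][1L])
  durs <- vapply(trials, `[[`, 0L, "duration_ms")
  if (length(unique(durs)) > 1L)
    stop("all trials in a dataset must share duration_ms")
  names(trials) <- ids
  structure(list(trials = trials,
                 duration_ms = if (length(durs)) unname(durs[1L]) else 10000L,
                 provenance = provenance),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  st <- vapply(x$trials, `[[`, "", "subtype")
  ex <- vapply(x$trials, `[[`, "", "expression")
  cat(sprintf("<spike_dataset: %d trials, %d ms, %d subtypes x %d expressions>\n",
              length(x$trials), x$duration_ms,
              length(unique(st[!is.na(st)])),
              length(unique(ex[!is.na(ex)]))))
  invisible(x)
}

#' @export
length.spike_dataset <- function(x) length(x$trials)

#' Subset a dataset by labels
#'
#' @param dataset a [spike_dataset()].
#' @param subtype,expression optional label filters.
#' @return a [spike_dataset()] with the matching trials.
#' @export
filter_dataset <- function(dataset, subtype = NULL, expression = NULL) {
  stopifnot(inherits(dataset, "spike_dataset"))
  keep <- rep(TRUE, length(dataset$trials))
  if (!is.null(subtype))
    keep <- keep & vapply(dataset$trials, `[[`, "", "subtype") %in% subtype
  if (!is.null(expression))
    keep <- keep & vapply(dataset$trials, `[[`, "", "expression") %in% expression
  spike_dataset(dataset$trials[keep], provenance = dataset$provenance)
}

# canonical trial order (by trial_id) so that every CV-based analysis is
# invariant to the order of trials in the input file
sort_dataset <- function(dataset) {
  spike_dataset(dataset$trials[order(names(dataset$trials), method = "radix")],
                provenance = dataset$provenance)
}

#' Dataset trial metadata
#'
#' @param dataset a [spike_dataset()].
#' @return data.frame with one row per trial: `trial_id`, `unit_id`,
#'   `subtype`, `expression`, `n_spikes`.
#' @export
dataset_info <- function(dataset) {
  stopifnot(inherits(dataset, "spike_dataset"))
  data.frame(
    trial_id = vapply(dataset$trials, `[[`, "", "trial_id"),
    unit_id = vapply(dataset$trials, `[[`, "", "unit_id"),
    subtype = vapply(dataset$trials, `[[`, "", "subtype"),
    expression = vapply(dataset$trials, `[[`, "", "expression"),
    n_spikes = vapply(dataset$trials, function(tr) length(tr$spike_times_ms),
                      0L),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Read / write a spike-train dataset as long-format CSV
#'
#' The canonical interchange format is a long CSV with header
#' `trial_id,unit_id,subtype,expression,spike_time_ms`, one row per spike;
#' a trial with zero spikes appears once with an empty `spike_time_ms`
#' field. An optional JSON sidecar (`<path>.meta.json`) carries
#' `duration_ms` and provenance.
#'
#' @param path CSV file path.
#' @param duration_ms trial duration used when no sidecar is present.
#' @return [read_dataset()] returns a [spike_dataset()];
#'   [write_dataset()] returns `path` invisibly.
#' @export
read_dataset <- function(path, duration_ms = 10000L) {
  meta_path <- paste0(path, ".meta.json")
  provenance <- path
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!is.null(meta$duration_ms)) duration_ms <- as.integer(meta$duration_ms)
    if (!is.null(meta$provenance)) provenance <- meta$provenance
  }
  dt <- data.table::fread(path, colClasses = list(
    character = c("trial_id", "unit_id", "subtype", "expression")),
    na.strings = c("", "NA"))
  req <- c("trial_id", "unit_id", "subtype", "expression", "spike_time_ms")
  if (!all(req %in% names(dt)))
    stop("CSV must have columns: ", paste(req, collapse = ","))
  trials <- lapply(split(dt, by = "trial_id", sorted = FALSE), function(g) {
    st <- g$spike_time_ms[!is.na(g$spike_time_ms)]
    st <- resolve_collisions(st, duration_ms)
    spike_train(st, duration_ms = duration_ms,
                unit_id = g$unit_id[1L], subtype = g$subtype[1L],
                expression = g$expression[1L], trial_id = g$trial_id[1L])
  })
  spike_dataset(trials, provenance = provenance)
}

#' @rdname read_dataset
#' @param dataset a [spike_dataset()].
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spike_dataset"))
  rows <- lapply(dataset$trials, function(tr) {
    n <- length(tr$spike_times_ms)
    data.table::data.table(
      trial_id = tr$trial_id, unit_id = tr$unit_id, subtype = tr$subtype,
      expression = tr$expression,
      spike_time_ms = if (n) tr$spike_times_ms else NA_integer_)
  })
  data.table::fwrite(data.table::rbindlist(rows), path, na = "")
  jsonlite::write_json(
    list(duration_ms = dataset$duration_ms,
         provenance = dataset$provenance),
    paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
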