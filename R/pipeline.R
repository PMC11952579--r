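# Pipeline orchestration: YAML config in, CSV/JSON artifacts out. Every
# artifact directory carries the resolved config and its hash plus the
# root seed, so a run is reproducible from its artifacts alone.

# polynomial rolling hash (mod 2^31-1) of the serialized config; hex
# string. A fingerprint for provenance, not a cryptographic hash.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default pipeline run configuration
#'
#' @param seed root seed; every stage derives its substream from it.
#' @param generator [generator_config()] arguments as a list.
#' @param stages character vector of stages to run, in order, from
#'   `simulate`, `features`, `classify_gestures`, `classify_svm`,
#'   `classify_cnn`, `windows`, `saturate`, `jitter`.
#' @param subtypes subtypes to analyse.
#' @param cv_repeats named list of repeat counts per protocol.
#' @param window_lengths,window_metrics grids for the `windows` stage.
#' @param jitter_sd_grid,jitter_noise_sets jitter stage parameters.
#' @return nested list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       generator = list(n_units_per_subtype = 2L,
                                        n_trials_per_unit_per_expression = 3L),
                       stages = c("simulate", "features", "classify_svm"),
                       subtypes = AFFERENT_SUBTYPES,
                       cv_repeats = list(classify = 20L, windows = 2L,
                                         curves = 7L, jitter = 5L),
                       window_lengths = window_length_grid(),
                       window_metrics = POSITION_METRICS,
                       jitter_sd_grid = seq(0, 100, by = 5),
                       jitter_noise_sets = 10L) {
  structure(list(seed = as.integer(seed), generator = generator,
                 stages = stages, subtypes = subtypes,
                 cv_repeats = cv_repeats, window_lengths = window_lengths,
                 window_metrics = window_metrics,
                 jitter_sd_grid = jitter_sd_grid,
                 jitter_noise_sets = as.integer(jitter_noise_sets)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  do.call(run_config, args)
}

#' Execute the analysis pipeline
#'
#' Runs the configured stages in order -- simulate, features, gesture and
#' expression classification (SVM and CNN), window-metric comparison,
#' saturation fitting, jitter analysis -- writing each stage's artifact
#' (CSV or JSON, schema documented per stage function) under `out_dir`
#' together with the resolved config (`config.yaml`), its hash and the
#' seed. Stage dependencies are checked: `saturate` requires the
#' `windows` accuracy table.
#'
#' @param config a [run_config()] (or YAML path).
#' @param out_dir output directory, created if missing.
#' @param dataset optional pre-loaded [spike_dataset()]; otherwise the
#'   `simulate` stage must come first.
#' @param verbose print per-stage wall time.
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config = run_config(), out_dir, dataset = NULL,
                         verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(config))
  yaml::write_yaml(c(unclass(config), list(config_hash = hash)),
                   file.path(out_dir, "config.yaml"))
  results <- list(config_hash = hash)
  say <- function(stage, t0) if (verbose)
    message(sprintf("[%s] %.1fs (seed %d, config %s)", stage,
                    as.numeric(Sys.time()) - t0, config$seed, hash))
  for (stage in config$stages) {
    t0 <- as.numeric(Sys.time())
    switch(stage,
      simulate = {
        gc_args <- config$generator
        gc_args$seed <- config$seed
        dataset <- generate_dataset(do.call(generator_config, gc_args),
                                    subtypes = config$subtypes)
        write_dataset(dataset, file.path(out_dir, "dataset.csv"))
      },
      features = {
        if (is.null(dataset)) stop("features: missing dataset artifact ",
                                   "(run simulate first or pass dataset=)")
        ft <- feature_table(dataset)
        results$features <- ft
        data.table::fwrite(ft, file.path(out_dir, "features.csv"))
      },
      classify_gestures = {
        if (is.null(dataset)) stop("classify_gestures: missing dataset")
        reps <- lapply(config$subtypes, function(s)
          classify_gestures(dataset, subtype = s,
                            cv = cv_spec(n_repeats = config$cv_repeats$classify,
                                         seed = config$seed)))
        names(reps) <- config$subtypes
        results$gestures <- reps
        write_report_json(reps, file.path(out_dir, "gestures.json"),
                          hash, config$seed)
      },
      classify_svm = ,
      classify_cnn = {
        if (is.null(dataset)) stop(stage, ": missing dataset")
        fun <- if (stage == "classify_svm") train_eval_svm else train_eval_cnn
        reps <- lapply(config$subtypes, function(s)
          fun(dataset, subtype = s,
              cv = cv_spec(n_repeats = config$cv_repeats$classify,
                           seed = config$seed)))
        names(reps) <- config$subtypes
        results[[stage]] <- reps
        write_report_json(reps, file.path(out_dir, paste0(stage, ".json")),
                          hash, config$seed)
      },
      windows = {
        if (is.null(dataset)) stop("windows: missing dataset")
        tabs <- lapply(config$subtypes, function(s)
          window_accuracy_table(filter_dataset(dataset, subtype = s),
                                lengths_ms = config$window_lengths,
                                metrics = config$window_metrics,
                                cv = cv_spec(n_repeats = config$cv_repeats$windows,
                                             seed = config$seed)))
        results$windows <- do.call(rbind, tabs)
        data.table::fwrite(results$windows,
                           file.path(out_dir, "window_accuracy.csv"))
      },
      saturate = {
        if (is.null(results$windows)) {
          p <- file.path(out_dir, "window_accuracy.csv")
          if (!file.exists(p))
            stop("saturate: missing window accuracy table ",
                 "(run the windows stage first)")
          results$windows <- as.data.frame(data.table::fread(p))
        }
        sat <- lapply(split(results$windows, results$windows$subtype),
                      function(tab) {
          crv <- accuracy_curve(tab)
          fit_saturation(crv$lengths_ms, crv$accuracies)
        })
        results$saturation <- sat
        out <- data.frame(subtype = names(sat),
                          saturation_ms = vapply(sat, `[[`, 0,
                                                 "saturation_length_ms"),
                          fitted_max = vapply(sat, `[[`, 0, "fitted_max"))
        data.table::fwrite(out, file.path(out_dir, "saturation.csv"))
        jsonlite::write_json(
          lapply(sat, function(s) s[c("coefficients", "fitted_max",
                                      "saturation_length_ms")]),
          file.path(out_dir, "saturation_fits.json"), auto_unbox = TRUE,
          digits = NA)
      },
      jitter = {
        if (is.null(dataset)) stop("jitter: missing dataset")
        jres <- lapply(config$subtypes, function(s)
          jitter_protocol(filter_dataset(dataset, subtype = s),
                          jitter_spec(sd_grid_ms = config$jitter_sd_grid,
                                      n_noise_sets = config$jitter_noise_sets,
                                      cv = cv_spec(n_repeats = config$cv_repeats$jitter,
                                                   seed = config$seed),
                                      seed = config$seed)))
        names(jres) <- config$subtypes
        results$jitter <- jres
        data.table::fwrite(
          do.call(rbind, lapply(jres, `[[`, "accuracy")),
          file.path(out_dir, "jitter_accuracy.csv"))
      },
      stop("unknown stage: ", stage)
    )
    say(stage, t0)
  }
  invisible(results)
}

write_report_json <- function(reports, path, hash, seed) {
  jsonlite::write_json(lapply(reports, function(r) list(
    mean_accuracy = r$mean_accuracy,
    per_repeat_accuracies = r$per_repeat_accuracies,
    confusion = r$confusion, classes = r$classes,
    config_hash = hash, seed = seed)),
    path, auto_unbox = TRUE, digits = NA)
}
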