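#' Assemble a full pipeline configuration
#'
#' One object drives the whole experiment: phantom cohort generation,
#' patient-level splitting, GLCM extraction, CNN and random-forest training,
#' and evaluation. All stage seeds are derived deterministically from the
#' single root `seed`, so a configuration reproduces its results exactly.
#'
#' @param seed Root RNG seed.
#' @param n_patients Synthetic patients in the cohort.
#' @param fractions Patient-level split fractions (train, validation, test).
#' @param n_levels Gray levels / GLCM dimension.
#' @param symmetric,normalize GLCM options (see [glcm_stack()]).
#' @param epochs,batch_size,lr CNN training settings (see [cnn_config()]).
#' @param n_trees Random-forest size.
#' @param bootstrap_b Bootstrap resamples for AUC CIs.
#' @param phantom Optional full [phantom_config()] overriding `n_patients`.
#' @return Nested list of class `vt_run_config`.
#' @export
run_config <- function(seed = 1L, n_patients = 400L,
                       fractions = c(train = 0.6, validation = 0.1, test = 0.3),
                       n_levels = 64L, symmetric = FALSE, normalize = TRUE,
                       epochs = 200L, batch_size = 10L, lr = 1e-5,
                       n_trees = 50L, bootstrap_b = 1000L, phantom = NULL) {
  seed <- as.integer(seed)
  if (is.null(phantom))
    phantom <- phantom_config(n_patients = n_patients, seed = seed)
  structure(list(
    seed = seed, phantom = phantom, fractions = fractions,
    glcm = list(n_levels = as.integer(n_levels), symmetric = symmetric,
                normalize = normalize),
    cnn = cnn_config(epochs = epochs, batch_size = batch_size, lr = lr,
                     n_levels = n_levels, seed = seed + 2L),
    rf = list(n_trees = as.integer(n_trees), seed = seed + 3L),
    bootstrap_b = as.integer(bootstrap_b)), class = "vt_run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; unknown keys raise
#' a validation error naming them. A `--seed` style override can be passed
#' through `seed`.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's value.
#' @return A `vt_run_config`.
#' @export
load_run_config <- function(path, seed = NULL) {
  if (!file.exists(path)) abort(sprintf("missing config file: %s", path))
  raw <- yaml::read_yaml(path) %||% list()
  known <- setdiff(names(formals(run_config)), "phantom")
  bad <- setdiff(names(raw), c(known, "phantom"))
  if (length(bad) > 0)
    abort(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  if (!is.null(raw$phantom)) {
    ph <- raw$phantom
    raw$phantom <- do.call(phantom_config, ph)
  }
  if (!is.null(raw$fractions)) raw$fractions <- unlist(raw$fractions)
  do.call(run_config, raw)
}

#' Run the full phantom experiment end to end
#'
#' Generates the cohort, assigns patient-level splits, extracts GLCM stacks,
#' computes Haralick features, trains the CNN (with validation-AUC
#' checkpoint selection) and the random-forest baseline, scores the test
#' split with both plus the PI-RADS rule, and evaluates everything with the
#' paired-comparison suite. Re-running with an identical configuration
#' reproduces every artifact byte for byte.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, records / features /
#'   predictions CSVs, the evaluation JSON, ROC curves and sidecars are
#'   written there.
#' @param quiet Suppress progress messages.
#' @return List of class `vt_run`: `records`, `features`, `cnn`, `rf`,
#'   `predictions`, `eval`, `timing`, `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "vt_run_config"))
  timing <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- force(expr)
    dt <- proc.time()[3] - t0
    timing[[name]] <<- dt
    if (!quiet) message(sprintf("[voltexture] %-12s %7.1fs (seed %d)", name,
                                dt, config$seed))
    res
  }

  cohort <- stage("generate", generate_cohort(config$phantom))
  records <- stage("split", split_cohort(cohort$records, config$fractions,
                                         seed = config$seed + 1L))
  stacks <- stage("extract", extract_stacks(
    cohort, n_levels = config$glcm$n_levels,
    normalize = config$glcm$normalize, symmetric = config$glcm$symmetric))
  features <- stage("features", feature_table(stacks, records))

  idx <- split(seq_len(nrow(records)), records$split)
  need <- c("train", "validation", "test")
  if (!all(need %in% names(idx))) abort("cohort is missing a split")
  sub <- function(i) stacks[records$lesion_id[i]]

  cnn <- stage("train_cnn", train_cnn(
    sub(idx$train), records$label[idx$train], sub(idx$validation),
    records$label[idx$validation], config$cnn))
  rf <- stage("train_rf", train_rf(features[idx$train, ],
                                   n_trees = config$rf$n_trees,
                                   seed = config$rf$seed))

  test_records <- records[idx$test, ]
  predictions <- stage("predict", dplyr::bind_rows(
    mutate(predict(cnn, sub(idx$test)), model = "textured_cnn"),
    mutate(predict(rf, features[idx$test, ]), model = "textured_rf"),
    mutate(pirads_cla(test_records), model = "pirads_cla")))

  eval <- stage("evaluate", evaluate_models(
    predictions, test_records, baseline = "pirads_cla",
    bootstrap_b = config$bootstrap_b, seed = config$seed + 4L))

  run <- structure(list(records = records, features = features, cnn = cnn,
                        rf = rf, predictions = predictions, eval = eval,
                        timing = tibble(stage = names(timing),
                                        seconds = unlist(timing, use.names = FALSE)),
                        config = config), class = "vt_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write the artifacts of a pipeline run
#'
#' @param run A `vt_run` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$records, file.path(out_dir, "records.csv"))
  readr::write_csv(run$features, file.path(out_dir, "features.csv"))
  readr::write_csv(run$predictions[, c("lesion_id", "score", "model")],
                   file.path(out_dir, "predictions.csv"))
  roc <- attr(run$eval, "roc")
  roc_tbl <- dplyr::bind_rows(lapply(names(roc), function(m)
    mutate(roc[[m]], model = m)))
  readr::write_csv(roc_tbl, file.path(out_dir, "roc_curves.csv"))
  saveRDS(run$cnn, file.path(out_dir, "cnn.rds"))
  saveRDS(run$rf, file.path(out_dir, "rf.rds"))
  write_eval_json(run$eval, file.path(out_dir, "eval.json"),
                  config = run$config)
  write_sidecar(file.path(out_dir, "run.json"), run$config)
  invisible(out_dir)
}

#' @export
print.vt_run <- function(x, ...) {
  overall <- x$eval[x$eval$group == "all" & x$eval$evaluable, ]
  cat(sprintf("<vt_run> %d lesions; test AUCs:\n", nrow(x$records)))
  if (nrow(overall) == 0) cat("  (test split not evaluable)\n")
  for (i in seq_len(nrow(overall)))
    cat(sprintf("  %-14s %.3f [%.3f, %.3f]\n", overall$model[i],
                overall$auc[i], overall$auc_lo[i], overall$auc_hi[i]))
  invisible(x)
}

#' @export
tidy.vt_run <- function(x, ...) as_tibble(x$eval)

#' @export
glance.vt_run <- function(x, ...) glance(x$eval)
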