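#' Default configuration of the three-arm training-strategy experiment
#'
#' The three arms differ only in how the shared training cohort is
#' turned into a training set:
#' \describe{
#'   \item{Unbal_NoCons}{conventional augmentation (each image augmented
#'     `conv_copies` times plus the original), no consolidations.}
#'   \item{Bal_NoCons}{balanced augmentation by per-category integer
#'     factors, no consolidations.}
#'   \item{Bal_Cons}{balanced augmentation, then artificial
#'     consolidations on every training image.}
#' }
#' Both test cohorts (with and without consolidations) are shared by all
#' arms; the with-consolidation cohort receives phantom consolidations
#' from a held-out seed stream. Desk-scale defaults: 200 training
#' phantoms at 64 x 64, 30 + 10 test phantoms, a depth-3 U-Net.
#'
#' @param n_train training phantoms.
#' @param n_test_nocons,n_test_cons test phantoms without/with
#'   consolidations.
#' @param matrix_size phantom grid side.
#' @param arms subset of the three arm names to run.
#' @param balanced_target per-category target for balanced augmentation;
#'   `NULL` uses the largest category count.
#' @param conv_copies augmented copies per image in the conventional arm.
#' @param ap_fraction,bssfp_fraction cohort category mix.
#' @param train a [unet_config()].
#' @param consolidation a [consolidation_params()].
#' @param transform a [transform_params()].
#' @param postprocess a [postprocess_params()].
#' @param calibrate_threshold grid-search the contour threshold per arm
#'   on validation phantoms (see [calibrate_threshold()]).
#' @param seed master seed; all stage seeds derive from it.
#' @return an `ExperimentConfig` list.
#' @export
experiment_config <- function(n_train = 200L, n_test_nocons = 30L,
                              n_test_cons = 10L, matrix_size = 64L,
                              arms = c("Unbal_NoCons", "Bal_NoCons", "Bal_Cons"),
                              balanced_target = NULL, conv_copies = 10L,
                              ap_fraction = 0.2, bssfp_fraction = 0.5,
                              train = unet_config(input_size = matrix_size,
                                                  depth = 3L,
                                                  base_channels = 8L,
                                                  batch_size = 16L,
                                                  max_epochs = 25L,
                                                  early_stop_patience = 5L),
                              consolidation = consolidation_params(),
                              transform = transform_params(),
                              postprocess = postprocess_params(),
                              calibrate_threshold = TRUE,
                              seed = 1L) {
  arms <- match.arg(arms, several.ok = TRUE)
  structure(list(n_train = as.integer(n_train),
                 n_test_nocons = as.integer(n_test_nocons),
                 n_test_cons = as.integer(n_test_cons),
                 matrix_size = as.integer(matrix_size),
                 arms = arms,
                 balanced_target = balanced_target,
                 conv_copies = as.integer(conv_copies),
                 ap_fraction = ap_fraction,
                 bssfp_fraction = bssfp_fraction,
                 train = train, consolidation = consolidation,
                 transform = transform, postprocess = postprocess,
                 calibrate_threshold = isTRUE(calibrate_threshold),
                 seed = as.integer(seed)),
            class = "ExperimentConfig")
}

add_labels <- function(records, width_px = 6L) {
  lapply(records, function(r) {
    r$label <- make_contour_label(r$mask, width_px)
    r
  })
}

build_arm_training_set <- function(arm, records, config) {
  seed_aug <- derive_seed(config$seed, paste0("augment_", arm))
  set <- switch(arm,
    Unbal_NoCons = build_training_set(records, "conventional",
                                      conv_copies = config$conv_copies,
                                      params = config$transform,
                                      seed = seed_aug),
    Bal_NoCons = ,
    Bal_Cons = {
      counts <- category_counts(records)
      target <- config$balanced_target %||% max(counts)
      plan <- compute_balancing_factors(counts, target)
      build_training_set(records, "balanced", plan = plan,
                         params = config$transform, seed = seed_aug)
    },
    stop("unknown arm: ", arm))
  if (arm == "Bal_Cons")
    set <- consolidate_dataset(set, config$consolidation,
                               seed = derive_seed(config$seed, "train_cons"))
  set
}

evaluate_arm <- function(arm, model, threshold, test_records, config) {
  pp <- config$postprocess
  pp$threshold <- threshold
  do.call(rbind, lapply(test_records, function(r) {
    prob <- predict_unet(model, r$image)
    pred <- postprocess_probability(prob, pp, spacing_mm = r$mask$spacing_mm)
    eval_record(pred, r$mask, spacing_mm = r$mask$spacing_mm,
                id = r$id, cohort = r$cohort, arm = arm)
  }))
}

#' Run the three-arm training-strategy experiment end to end
#'
#' Generates the training and test cohorts, builds each arm's training
#' set, trains one U-Net per arm, calibrates the contour threshold on
#' held-out validation phantoms, predicts and postprocesses the two
#' shared test cohorts and assembles the arm-comparison report. Every
#' stage seed derives from the master seed, so the run is fully
#' reproducible and the arms differ only in training strategy.
#'
#' @param config an [experiment_config()].
#' @param output_dir optional directory for CSV reports and histories.
#' @param verbose print stage progress.
#' @return list with `report` (from [evaluate_arms()]), `records`
#'   (per-image scores), `histories`, `thresholds`, `train_sizes` and
#'   `config`.
#' @export
run_experiment <- function(config = experiment_config(), output_dir = NULL,
                           verbose = interactive()) {
  say <- function(...) if (verbose) message(sprintf(...))
  ranges <- list(matrix_size = config$matrix_size,
                 ap_fraction = config$ap_fraction,
                 bssfp_fraction = config$bssfp_fraction)

  say("generating cohorts (train %d, test %d + %d)",
      config$n_train, config$n_test_nocons, config$n_test_cons)
  train_cohort <- add_labels(generate_cohort(
    config$n_train, ranges, seed = derive_seed(config$seed, "train_cohort")))
  test_nocons <- add_labels(generate_cohort(
    config$n_test_nocons, ranges, seed = derive_seed(config$seed, "test_nocons")))
  test_cons <- add_labels(generate_cohort(
    config$n_test_cons, ranges, seed = derive_seed(config$seed, "test_cons")))
  # held-out consolidation stream for the with-consolidation test cohort
  test_cons <- consolidate_dataset(test_cons, config$consolidation,
                                   seed = derive_seed(config$seed, "test_cons_regions"))
  for (i in seq_along(test_nocons)) test_nocons[[i]]$cohort <- "without_cons"
  for (i in seq_along(test_cons)) test_cons[[i]]$cohort <- "with_cons"
  test_records <- c(test_nocons, test_cons)

  # calibration phantoms: held out from training and test streams
  calib <- add_labels(generate_cohort(
    max(6L, round(config$n_train * 0.05)), ranges,
    seed = derive_seed(config$seed, "calibration")))
  calib_cons <- consolidate_dataset(calib, config$consolidation,
                                    seed = derive_seed(config$seed, "calib_regions"))

  all_scores <- list()
  histories <- list()
  thresholds <- list()
  train_sizes <- list()
  for (arm in config$arms) {
    say("arm %s: building training set", arm)
    set <- build_arm_training_set(arm, train_cohort, config)
    train_sizes[[arm]] <- length(set)
    say("arm %s: training on %d images", arm, length(set))
    cfg <- config$train
    cfg$seed <- derive_seed(config$seed, paste0("train_", arm))
    model <- build_unet(cfg)
    fit <- train_unet(model, records_to_dataset(set), cfg)
    histories[[arm]] <- fit$history
    th <- config$postprocess$threshold
    if (config$calibrate_threshold) {
      th <- calibrate_threshold(fit$model, c(calib, calib_cons),
                                params = config$postprocess)
      say("arm %s: calibrated threshold %.4g", arm, as.numeric(th))
    }
    thresholds[[arm]] <- as.numeric(th)
    say("arm %s: evaluating %d test images", arm, length(test_records))
    all_scores[[arm]] <- evaluate_arm(arm, fit$model, as.numeric(th),
                                      test_records, config)
  }
  scores <- do.call(rbind, all_scores)
  report <- evaluate_arms(scores)
  out <- list(report = report, records = scores, histories = histories,
              thresholds = thresholds, train_sizes = train_sizes,
              config = config)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(scores, file.path(output_dir, "scores.csv"),
                     row.names = FALSE)
    utils::write.csv(report$summary, file.path(output_dir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(report$comparisons))
      utils::write.csv(report$comparisons,
                       file.path(output_dir, "comparisons.csv"),
                       row.names = FALSE)
    for (arm in names(histories))
      utils::write.csv(histories[[arm]],
                       file.path(output_dir, sprintf("history_%s.csv", arm)),
                       row.names = FALSE)
    writeLines(format_arm_report(report),
               file.path(output_dir, "report.txt"))
    yaml::write_yaml(experiment_config_to_list(config),
                     file.path(output_dir, "config.yaml"))
  }
  out
}

# plain-list view of a config for YAML round-tripping
experiment_config_to_list <- function(config) {
  lapply(unclass(config), function(v) if (is.list(v)) unclass(v) else v)
}

#' Load an experiment configuration from YAML
#'
#' Unknown keys are rejected; nested sections `train`, `consolidation`,
#' `transform` and `postprocess` accept the fields of their respective
#' constructors.
#'
#' @param path YAML file.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- raw
  call_with_known <- function(fn, values)
    do.call(fn, values[intersect(names(values), names(formals(fn)))])
  if (!is.null(raw$train)) args$train <- call_with_known(unet_config, raw$train)
  if (!is.null(raw$consolidation))
    args$consolidation <- call_with_known(consolidation_params, raw$consolidation)
  if (!is.null(raw$transform))
    args$transform <- call_with_known(transform_params, raw$transform)
  if (!is.null(raw$postprocess))
    args$postprocess <- call_with_known(postprocess_params, raw$postprocess)
  do.call(experiment_config, args)
}
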