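#' Run a baseline predictor through cross-validation
#'
#' For every fold of `assignment`, fits `predictor_factory` on that fold's
#' training pairs (role `train`; validation pairs are held out of fitting
#' so blind guarantees extend to them) and scores the fold's test pairs.
#' Test predictions are pooled across folds with their fold index, so both
#' pooled and fold-level metrics can be computed downstream.
#'
#' @param dataset a [triplet_dataset()].
#' @param assignment a `fold_assignment` built from `dataset`.
#' @param predictor_factory function taking a training `triplet_dataset`
#'   and returning a `drp_predictor` (e.g. [drug_mean_predictor]).
#' @return A `cv_result`: list with `predictions` (tibble `cell_id`,
#'   `drug_id`, `fold`, `response`, `predicted`), `dataset`, `assignment`.
#' @export
cross_validate <- function(dataset, assignment, predictor_factory) {
  records <- as_tibble(as.data.frame(dataset))
  key <- paste(records$cell_id, records$drug_id, sep = "\r")
  a <- assignment$assignment
  a_key <- paste(a$cell_id, a$drug_id, sep = "\r")
  pieces <- lapply(seq_len(assignment$k) - 1L, function(f) {
    in_fold <- a$fold == f
    train_keys <- a_key[in_fold & a$role == "train"]
    test_keys <- a_key[in_fold & a$role == "test"]
    if (length(test_keys) == 0) return(NULL)
    train_ds <- restore_triplets(records[key %in% train_keys, , drop = FALSE],
                                 dataset)
    predictor <- predictor_factory(train_ds)
    test_tab <- records[key %in% test_keys, , drop = FALSE]
    preds <- predict_pairs(predictor, test_tab)
    tibble(cell_id = test_tab$cell_id, drug_id = test_tab$drug_id,
           fold = f, response = test_tab$response,
           predicted = preds$predicted)
  })
  structure(list(predictions = bind_rows(pieces),
                 dataset = dataset, assignment = assignment),
            class = "cv_result")
}

#' Metrics for a cross-validation run
#'
#' Computes fold-level overall metrics (then their mean across folds, the
#' way benchmark tables report "average SCC"), pooled overall metrics over
#' all test predictions, and pooled per-drug metrics.
#'
#' @param cv a `cv_result` from [cross_validate()].
#' @param min_pairs per-drug scoring floor, see [per_drug_metrics()].
#' @param scc_threshold threshold for the per-drug exceedance summary.
#' @return list with `per_fold` (tibble of fold-level overall metrics),
#'   `fold_mean` (named means across folds), `pooled` (a
#'   [metric_report()] over the pooled predictions).
#' @export
cv_metrics <- function(cv, min_pairs = 3, scc_threshold = 0.5) {
  preds <- cv$predictions
  truth_all <- restore_triplets(
    as_tibble(as.data.frame(cv$dataset)), cv$dataset)
  per_fold <- bind_rows(lapply(sort(unique(preds$fold)), function(f) {
    sub <- preds[preds$fold == f, , drop = FALSE]
    b <- metric_block(sub$response, sub$predicted)
    tibble(fold = f, n_pairs = nrow(sub),
           pcc = b$pcc, scc = b$scc, rmse = b$rmse, mae = b$mae, r2 = b$r2)
  }))
  pooled_pred <- prediction_table(preds[c("cell_id", "drug_id", "predicted")])
  list(per_fold = per_fold,
       fold_mean = colMeans(per_fold[c("pcc", "scc", "rmse", "mae", "r2")],
                            na.rm = TRUE),
       pooled = metric_report(truth_all, pooled_pred,
                              min_pairs = min_pairs,
                              scc_threshold = scc_threshold))
}

predictor_factories <- function() {
  list(drug_mean = drug_mean_predictor, additive = additive_predictor)
}

#' Run a configured evaluation pipeline
#'
#' Orchestrates the standard workflow — simulate a screen, split it, run a
#' baseline through cross-validation, evaluate, and write plot data — from
#' a single configuration, writing every artifact plus a JSON manifest
#' into `out_dir`. Re-running with an identical config reproduces
#' byte-identical CSV outputs.
#'
#' The config is a named list (or path to a JSON file) with blocks:
#' \preformatted{
#' {
#'   "out_dir": "run1",
#'   "seed": 42,
#'   "simulate": {"n_cells": 50, "n_drugs": 20, "sigma_drug": 2, ...},
#'   "split":    {"strategy": "cell_blind", "k": 5, "validation_fraction": 0},
#'   "evaluate": {"predictor": "drug_mean", "min_pairs": 3,
#'                "scc_threshold": 0.5},
#'   "plot":     {"waterfall": true}
#' }
#' }
#' Alternatively `input` (path to a triplet CSV) plus `response_type`
#' replaces the `simulate` block. Stage parameters default sensibly;
#' unknown predictor names and missing input files are config errors
#' raised before any stage runs.
#'
#' @param config named list or JSON file path.
#' @return the run manifest (named list), invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_drp("config file '%s' not found", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop_drp("config must be a list or a JSON file path")
  out_dir <- config$out_dir %||% stop_drp("config error: key 'out_dir' is required")
  seed <- as.integer(config$seed %||% 1L)

  # -- validate everything before running any stage ------------------------
  if (!is.null(config$input) && !file.exists(config$input)) {
    stop_drp("config error: input file '%s' does not exist", config$input)
  }
  if (is.null(config$input) && is.null(config$simulate)) {
    stop_drp("config error: need either 'input' or a 'simulate' block")
  }
  eval_cfg <- config$evaluate %||% list()
  predictor_name <- eval_cfg$predictor %||% "drug_mean"
  factories <- predictor_factories()
  if (!predictor_name %in% names(factories)) {
    stop_drp("config error: unknown predictor '%s' (available: %s)",
             predictor_name, paste(names(factories), collapse = ", "))
  }
  split_cfg <- config$split %||% list()
  strategy <- split_cfg$strategy %||% "random"
  if (!strategy %in% c("random", "cell_blind", "drug_blind",
                       "completely_blind", "cancer_type_blind")) {
    stop_drp("config error: unknown split strategy '%s'", strategy)
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, stages = list())
  log_stage <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(stage = stage, params = params,
                                      seed = seed, files = files)
    message(sprintf("[%s] wrote %s", stage, paste(files, collapse = ", ")))
  }

  # -- stage: data ---------------------------------------------------------
  if (!is.null(config$input)) {
    dataset <- read_triplets(config$input,
                             response_type = config$response_type %||% "ln_ic50")
    latents <- NULL
    log_stage("input", list(path = config$input), character(0))
  } else {
    sim_cfg <- config$simulate
    sim_cfg$seed <- sim_cfg$seed %||% seed
    sc <- do.call(screen_config, sim_cfg)
    sim <- generate_screen(sc)
    dataset <- sim$dataset
    latents <- sim$latents
    truth_path <- file.path(out_dir, "truth.csv")
    write_triplets(dataset, truth_path)
    log_stage("simulate", unclass(sc), "truth.csv")
  }

  # -- stage: split --------------------------------------------------------
  spec <- split_spec(strategy = strategy,
                     k = split_cfg$k %||% 5L,
                     seed = split_cfg$seed %||% seed,
                     validation_fraction = split_cfg$validation_fraction %||% 0)
  assignment <- split_dataset(dataset, spec)
  verification <- verify_assignment(dataset, assignment)
  if (!all_checks_pass(verification)) {
    stop_drp("stage 'split' failed: assignment violates its own guarantees")
  }
  assign_path <- file.path(out_dir, "assignment.csv")
  readr::write_csv(assignment_table(assignment, expand_train = TRUE),
                   assign_path, progress = FALSE)
  log_stage("split", unclass(spec), "assignment.csv")

  # -- stage: evaluate -----------------------------------------------------
  cv <- cross_validate(dataset, assignment, factories[[predictor_name]])
  mets <- cv_metrics(cv,
                     min_pairs = eval_cfg$min_pairs %||% 3,
                     scc_threshold = eval_cfg$scc_threshold %||% 0.5)
  overall_path <- file.path(out_dir, "overall_metrics.csv")
  per_drug_path <- file.path(out_dir, "per_drug_metrics.csv")
  per_cell_path <- file.path(out_dir, "per_cell_metrics.csv")
  readr::write_csv(mets$per_fold, overall_path, progress = FALSE)
  readr::write_csv(mets$pooled$per_drug, per_drug_path, progress = FALSE)
  readr::write_csv(mets$pooled$per_cell, per_cell_path, progress = FALSE)
  log_stage("evaluate",
            list(predictor = predictor_name,
                 min_pairs = eval_cfg$min_pairs %||% 3),
            c("overall_metrics.csv", "per_drug_metrics.csv",
              "per_cell_metrics.csv"))

  # -- stage: plot ---------------------------------------------------------
  plot_cfg <- config$plot %||% list()
  if (isTRUE(plot_cfg$waterfall %||% TRUE)) {
    wf <- plot_waterfall(mets$pooled$per_drug,
                         threshold = eval_cfg$scc_threshold %||% 0.5)
    wf_data <- attr(wf, "plot_data")$bars
    wf_data$threshold <- attr(wf, "plot_data")$threshold
    wf_data$fraction_above <- attr(wf, "plot_data")$fraction_above
    wf_data_path <- file.path(out_dir, "waterfall_data.csv")
    readr::write_csv(wf_data, wf_data_path, progress = FALSE)
    files <- "waterfall_data.csv"
    # image output is best-effort: the data table above is the testable artifact
    png_ok <- tryCatch({
      ggplot2::ggsave(file.path(out_dir, "waterfall.png"), wf,
                      width = 7, height = 4, dpi = 120)
      TRUE
    }, error = function(e) FALSE)
    if (png_ok) files <- c(files, "waterfall.png")
    log_stage("plot", list(waterfall = TRUE), files)
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
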