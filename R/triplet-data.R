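#' Triplet response datasets
#'
#' A triplet dataset is the field's canonical S = \{cell, drug, response\}
#' structure: one row per measured (cell line, drug) pair with a single
#' numeric response, plus an optional `cancer_type` annotation per cell.
#' Cells and drugs are opaque string identifiers; the framework never looks
#' inside them. The object is a tibble subclass carrying the dataset's
#' response type and name as attributes.
#'
#' Response types and their range constraints:
#' * `ln_ic50` — natural-log IC50 on an arbitrary (dataset-specific) scale;
#'   any finite real.
#' * `audrc`, `aadrc`, `normalized` — must lie in \[0, 1\].
#' * `binary` — must be 0 or 1.
#'
#' @param records data frame with columns `cell_id`, `drug_id`, `response`
#'   and optionally `cancer_type`. At most one row per (cell, drug) pair;
#'   use [read_triplets()] for replicate aggregation.
#' @param response_type one of `"ln_ic50"`, `"audrc"`, `"aadrc"`,
#'   `"normalized"`, `"binary"`.
#' @param name label used in reports and cross-dataset matrices.
#' @return A `triplet_dataset` (tibble subclass).
#' @examples
#' triplet_dataset(
#'   data.frame(cell_id = c("C1", "C2"), drug_id = "D1",
#'              response = c(0.2, 0.8)),
#'   response_type = "audrc", name = "toy"
#' )
#' @export
triplet_dataset <- function(records,
                            response_type = c("ln_ic50", "audrc", "aadrc",
                                              "normalized", "binary"),
                            name = "dataset") {
  response_type <- match.arg(response_type)
  records <- as_tibble(records)
  required <- c("cell_id", "drug_id", "response")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop_drp("triplet records are missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  records$cell_id <- as.character(records$cell_id)
  records$drug_id <- as.character(records$drug_id)
  records$response <- as.numeric(records$response)
  keep <- c(required, intersect("cancer_type", names(records)))
  records <- records[keep]

  if (nrow(records) > 0) {
    if (any(!nzchar(records$cell_id)) || any(is.na(records$cell_id)) ||
        any(!nzchar(records$drug_id)) || any(is.na(records$drug_id))) {
      stop_drp("cell_id and drug_id must be non-empty strings")
    }
    if (any(!is.finite(records$response))) {
      stop_drp("responses must be finite")
    }
    if (anyDuplicated(paste(records$cell_id, records$drug_id, sep = "\r"))) {
      stop_drp("duplicate (cell_id, drug_id) pairs; aggregate replicates first")
    }
    if (response_type %in% c("audrc", "aadrc", "normalized") &&
        any(records$response < 0 | records$response > 1)) {
      stop_drp("%s responses must lie in [0, 1]", response_type)
    }
    if (response_type == "binary" && !all(records$response %in% c(0, 1))) {
      stop_drp("binary responses must be 0 or 1")
    }
  }

  structure(records,
            class = c("triplet_dataset", class(tibble())),
            response_type = response_type,
            dataset_name = name)
}

#' @rdname triplet_dataset
#' @param x a `triplet_dataset`.
#' @export
response_type <- function(x) attr(x, "response_type", exact = TRUE)

#' @rdname triplet_dataset
#' @export
dataset_name <- function(x) attr(x, "dataset_name", exact = TRUE)

#' @export
print.triplet_dataset <- function(x, ...) {
  cat(sprintf("<triplet_dataset '%s'> %d pairs, %d cells, %d drugs, response = %s\n",
              dataset_name(x), nrow(x),
              length(unique(x$cell_id)), length(unique(x$drug_id)),
              response_type(x)))
  NextMethod()
}

# rebuild a triplet_dataset after tibble surgery (tibble verbs strip attrs)
restore_triplets <- function(records, template, response_type = NULL) {
  triplet_dataset(records,
                  response_type = response_type %||% response_type(template),
                  name = dataset_name(template))
}

read_delim_auto <- function(path) {
  # columns come in as character: numeric conversion goes through base R's
  # correctly-rounded strtod so write/read round-trips are exact to the bit
  ct <- readr::cols(.default = readr::col_character())
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::read_tsv(path, col_types = ct, progress = FALSE)
  } else {
    readr::read_csv(path, col_types = ct, progress = FALSE)
  }
}

#' Read a triplet response table
#'
#' Reads delimited text (`.csv` comma, `.tsv` tab) with header columns
#' `cell_id`, `drug_id`, `response` and optional `cancer_type`, collapses
#' replicate rows for the same (cell, drug) pair, and returns a validated
#' [triplet_dataset()]. Row order follows first occurrence. The number of
#' rows collapsed by aggregation is reported via `message()`.
#'
#' @param path file path; delimiter inferred from the extension.
#' @param response_type see [triplet_dataset()].
#' @param aggregate how to collapse replicate pairs: `"median"` (default,
#'   robust to outlier wells), `"mean"`, or `"error"` to refuse duplicates.
#' @param name dataset label; defaults to the file name.
#' @return A `triplet_dataset`.
#' @export
read_triplets <- function(path,
                          response_type = c("ln_ic50", "audrc", "aadrc",
                                            "normalized", "binary"),
                          aggregate = c("median", "mean", "error"),
                          name = NULL) {
  response_type <- match.arg(response_type)
  aggregate <- match.arg(aggregate)
  raw <- read_delim_auto(path)
  required <- c("cell_id", "drug_id", "response")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_drp("file '%s' is missing required column(s): %s",
             path, paste(missing_cols, collapse = ", "))
  }
  resp_chr <- as.character(raw$response)
  resp_num <- suppressWarnings(as.numeric(resp_chr))
  bad <- which(is.na(resp_num) & !is.na(resp_chr))
  if (length(bad) > 0) {
    stop_drp("non-numeric response at data row %d of '%s' ('%s')",
             bad[1], path, resp_chr[bad[1]])
  }
  raw$response <- resp_num

  records <- aggregate_replicates(raw, aggregate = aggregate)
  triplet_dataset(records, response_type = response_type,
                  name = name %||% basename(path))
}

# collapse replicate (cell, drug) rows; first-occurrence order is preserved
# regardless of input row order so aggregation is permutation-invariant up to
# the ordering rule
aggregate_replicates <- function(records, aggregate = c("median", "mean", "error")) {
  aggregate <- match.arg(aggregate)
  key <- paste(records$cell_id, records$drug_id, sep = "\r")
  if (!anyDuplicated(key)) return(records)
  if (aggregate == "error") {
    dup <- key[duplicated(key)][1]
    stop_drp("duplicate (cell_id, drug_id) pair present: %s",
             gsub("\r", " / ", dup))
  }
  fun <- if (aggregate == "median") stats::median else mean
  first_idx <- which(!duplicated(key))
  agg_val <- vapply(split(records$response, key)[key[first_idx]],
                    fun, numeric(1))
  out <- records[first_idx, , drop = FALSE]
  out$response <- unname(agg_val)
  message(sprintf("aggregated %d replicate row(s) into %d pair(s) (%s)",
                  nrow(records) - nrow(out), nrow(out), aggregate))
  out
}

#' Write a triplet dataset
#'
#' Serializes with full numeric precision so that
#' `read_triplets(write_triplets(x))` reproduces `x`'s records exactly.
#' An empty dataset yields a header-only file.
#'
#' @param dataset a [triplet_dataset()].
#' @param path output path; `.tsv` writes tab-delimited, anything else comma.
#' @return `path`, invisibly.
#' @export
write_triplets <- function(dataset, path) {
  tab <- as_tibble(as.data.frame(dataset))
  # 17 significant digits guarantee binary round-trip of doubles
  tab$response <- sprintf("%.17g", tab$response)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(tab, path, progress = FALSE)
  } else {
    readr::write_csv(tab, path, progress = FALSE)
  }
  invisible(path)
}

#' Dose-response experiments
#'
#' One experiment is a set of viability measurements (fraction of control)
#' for a single cell-drug pair across increasing drug concentrations.
#' Concentrations are stored in molar units, strictly positive, sorted
#' ascending and unique; at least 4 points are required (a four-parameter
#' fit needs four). Viabilities may exceed 1 on input (control-normalized
#' assays can); clamping happens only inside AUDRC integration.
#'
#' @param experiment_id,cell_id,drug_id identifiers.
#' @param concentrations positive molar concentrations.
#' @param viabilities viability values, same length as `concentrations`.
#' @return A `dose_response_experiment` object.
#' @export
dose_response_experiment <- function(experiment_id, cell_id, drug_id,
                                     concentrations, viabilities) {
  concentrations <- as.numeric(concentrations)
  viabilities <- as.numeric(viabilities)
  if (length(concentrations) != length(viabilities)) {
    stop_drp("concentrations and viabilities must have the same length")
  }
  if (length(concentrations) < 4) {
    stop_drp("experiment '%s' has %d point(s); >= 4 required",
             experiment_id, length(concentrations))
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop_drp("concentrations must be finite and strictly positive")
  }
  ord <- order(concentrations)
  concentrations <- concentrations[ord]
  viabilities <- viabilities[ord]
  if (anyDuplicated(concentrations)) {
    stop_drp("duplicate concentrations in experiment '%s'", experiment_id)
  }
  structure(
    list(experiment_id = as.character(experiment_id),
         cell_id = as.character(cell_id),
         drug_id = as.character(drug_id),
         concentrations = concentrations,
         viabilities = viabilities),
    class = "dose_response_experiment"
  )
}

#' @export
print.dose_response_experiment <- function(x, ...) {
  cat(sprintf("<dose_response_experiment '%s'> %s x %s, %d points, [%.3g, %.3g] M\n",
              x$experiment_id, x$cell_id, x$drug_id,
              length(x$concentrations),
              min(x$concentrations), max(x$concentrations)))
  invisible(x)
}

#' Read raw dose-response tables
#'
#' Long-format delimited text with columns `experiment_id`, `cell_id`,
#' `drug_id`, `concentration`, `viability`. Rows are grouped by
#' `experiment_id`; concentrations are converted to molar and sorted
#' ascending (viabilities reordered in lockstep). Experiments with fewer
#' than 4 points are excluded with a warning.
#'
#' @param path file path (`.csv`/`.tsv`).
#' @param concentration_unit unit of the `concentration` column.
#' @return list of [dose_response_experiment()] objects.
#' @export
read_dose_response <- function(path,
                               concentration_unit = c("molar", "micromolar",
                                                      "nanomolar")) {
  concentration_unit <- match.arg(concentration_unit)
  scale <- c(molar = 1, micromolar = 1e-6, nanomolar = 1e-9)[[concentration_unit]]
  raw <- read_delim_auto(path)
  required <- c("experiment_id", "cell_id", "drug_id", "concentration", "viability")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_drp("file '%s' is missing required column(s): %s",
             path, paste(missing_cols, collapse = ", "))
  }
  conc <- suppressWarnings(as.numeric(as.character(raw$concentration)))
  bad <- which(!is.finite(conc) | conc <= 0)
  if (length(bad) > 0) {
    stop_drp("non-positive or non-numeric concentration at data row %d of '%s'",
             bad[1], path)
  }
  raw$concentration <- conc * scale
  raw$viability <- as.numeric(raw$viability)

  groups <- split(seq_len(nrow(raw)), as.character(raw$experiment_id))
  # keep first-appearance order of experiments
  groups <- groups[unique(as.character(raw$experiment_id))]
  too_small <- names(groups)[lengths(groups) < 4]
  if (length(too_small) > 0) {
    warn_drp("excluded %d experiment(s) with < 4 points: %s",
             length(too_small), paste(too_small, collapse = ", "))
    groups <- groups[lengths(groups) >= 4]
  }
  lapply(names(groups), function(eid) {
    idx <- groups[[eid]]
    dose_response_experiment(
      experiment_id = eid,
      cell_id = raw$cell_id[idx[1]],
      drug_id = raw$drug_id[idx[1]],
      concentrations = raw$concentration[idx],
      viabilities = raw$viability[idx]
    )
  })
}

#' Prediction tables
#'
#' Model outputs to be scored: one finite predicted value per (cell, drug)
#' pair. A thin validated tibble.
#'
#' @param entries data frame with columns `cell_id`, `drug_id`, `predicted`.
#' @return tibble with class `prediction_table`.
#' @export
prediction_table <- function(entries) {
  entries <- as_tibble(entries)
  required <- c("cell_id", "drug_id", "predicted")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    stop_drp("prediction table is missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  entries$cell_id <- as.character(entries$cell_id)
  entries$drug_id <- as.character(entries$drug_id)
  entries$predicted <- as.numeric(entries$predicted)
  if (any(!is.finite(entries$predicted))) {
    stop_drp("predicted values must be finite")
  }
  if (anyDuplicated(paste(entries$cell_id, entries$drug_id, sep = "\r"))) {
    stop_drp("duplicate (cell_id, drug_id) pair in prediction table")
  }
  structure(entries[required],
            class = c("prediction_table", class(tibble())))
}

#' Pair coverage of a screen
#'
#' Fraction of the cells-by-drugs grid that is unmeasured. Useful as a
#' one-line sanity report for curated screens: e.g. 107,446 records over
#' 561 cell lines and 238 drugs leaves 19.5% of the grid unmeasured.
#'
#' @param dataset a [triplet_dataset()], or `NULL` if counts are given.
#' @param n_records,n_cells,n_drugs explicit counts (override `dataset`).
#' @return list with `n_records`, `n_cells`, `n_drugs`, `n_possible`,
#'   `measured_fraction`, `unmeasured_fraction`, `unmeasured_pct`.
#' @export
coverage_report <- function(dataset = NULL, n_records = NULL, n_cells = NULL,
                            n_drugs = NULL) {
  if (!is.null(dataset)) {
    n_records <- n_records %||% nrow(dataset)
    n_cells <- n_cells %||% length(unique(dataset$cell_id))
    n_drugs <- n_drugs %||% length(unique(dataset$drug_id))
  }
  if (is.null(n_records) || is.null(n_cells) || is.null(n_drugs)) {
    stop_drp("supply a dataset or all of n_records, n_cells, n_drugs")
  }
  n_possible <- as.numeric(n_cells) * as.numeric(n_drugs)
  if (n_records > n_possible) {
    stop_drp("n_records (%d) exceeds the %d-pair grid", n_records, n_possible)
  }
  measured <- n_records / n_possible
  list(n_records = n_records, n_cells = n_cells, n_drugs = n_drugs,
       n_possible = n_possible,
       measured_fraction = measured,
       unmeasured_fraction = 1 - measured,
       unmeasured_pct = 100 * (1 - measured))
}
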