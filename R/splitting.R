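#' Cross-validation split specification
#'
#' Describes one K-fold partitioning scheme. Five strategies are supported,
#' each a proxy for a different generalization question:
#' * `random` — drug-cell pairs dealt into K folds (mixed-set / leave-pairs-out);
#'   the optimistic baseline.
#' * `cell_blind` — cell lines dealt into K groups; test cells never appear
#'   in training (new-patient proxy).
#' * `drug_blind` — drugs dealt into K groups (new-compound proxy).
#' * `completely_blind` — cells *and* drugs grouped; fold f tests the
#'   cell-group-f x drug-group-f block, trains on the complementary block,
#'   and explicitly discards the mixed pairs.
#' * `cancer_type_blind` — all cells of one cancer type share a fold
#'   (greedy balancing by cell count).
#'
#' @param strategy one of the five strategy names.
#' @param k number of folds (>= 2); must not exceed the number of
#'   splittable units for the strategy.
#' @param seed integer seed; identical (dataset, spec) gives identical
#'   assignments.
#' @param validation_fraction fraction in \[0, 0.5) carved from each fold's
#'   training side for model selection. For blind strategies the carve-out
#'   is taken at the entity level so blindness guarantees extend to the
#'   validation set.
#' @return A `split_spec` list.
#' @export
split_spec <- function(strategy = c("random", "cell_blind", "drug_blind",
                                    "completely_blind", "cancer_type_blind"),
                       k = 5L, seed = 1L, validation_fraction = 0) {
  strategy <- match.arg(strategy)
  k <- as.integer(k)
  if (is.na(k) || k < 2) stop_drp("k must be an integer >= 2")
  if (!(validation_fraction >= 0 && validation_fraction < 0.5)) {
    stop_drp("validation_fraction must lie in [0, 0.5)")
  }
  structure(list(strategy = strategy, k = k, seed = as.integer(seed),
                 validation_fraction = validation_fraction),
            class = "split_spec")
}

new_fold_assignment <- function(assignment, spec, n_pairs, notes = list()) {
  structure(list(assignment = assignment, strategy = spec$strategy,
                 k = spec$k, seed = spec$seed,
                 validation_fraction = spec$validation_fraction,
                 n_pairs = n_pairs, notes = notes),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  tab <- table(x$assignment$role[x$assignment$fold == 0])
  cat(sprintf("<fold_assignment> strategy=%s k=%d seed=%d, %d pairs (fold 0: %s)\n",
              x$strategy, x$k, x$seed, x$n_pairs,
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

# deal shuffled items round-robin into k groups -> integer group id 0..k-1,
# group sizes differing by at most 1
deal_into_folds <- function(items, k) {
  g <- integer(length(items))
  g[sample.int(length(items))] <- rep(seq_len(k) - 1L, length.out = length(items))
  g
}

# expand a per-fold role assignment into the long (pair, fold, role) table
build_long <- function(records, role_by_fold, k) {
  bind_rows(lapply(seq_len(k) - 1L, function(f) {
    tibble(cell_id = records$cell_id, drug_id = records$drug_id,
           fold = f, role = role_by_fold[[f + 1L]])
  }))
}

#' Split drug-cell pairs at random
#'
#' Pairs are shuffled with the seeded RNG and dealt into `k` folds whose
#' sizes differ by at most 1. Fold f's test set is group f; the remaining
#' pairs are training, minus a seeded validation carve-out of
#' `validation_fraction` of the training pairs.
#'
#' @param dataset a [triplet_dataset()].
#' @param spec a [split_spec()] (its `strategy` field is ignored here).
#' @return A `fold_assignment` whose `$assignment` tibble has one row per
#'   (pair, fold) with `role` in train/validation/test.
#' @export
split_random <- function(dataset, spec) {
  n <- nrow(dataset)
  if (n == 0) stop_drp("dataset is empty")
  if (spec$k > n) stop_drp("k = %d exceeds the %d available pairs", spec$k, n)
  records <- as_tibble(as.data.frame(dataset))
  roles <- with_seed(spec$seed, {
    fold_of <- deal_into_folds(seq_len(n), spec$k)
    lapply(seq_len(spec$k) - 1L, function(f) {
      role <- ifelse(fold_of == f, "test", "train")
      train_idx <- which(role == "train")
      nv <- floor(spec$validation_fraction * length(train_idx))
      if (nv > 0) role[sample(train_idx, nv)] <- "validation"
      role
    })
  })
  spec$strategy <- "random"
  new_fold_assignment(build_long(records, roles, spec$k), spec, n)
}

split_entity_blind <- function(dataset, spec, unit = c("cell", "drug")) {
  unit <- match.arg(unit)
  col <- paste0(unit, "_id")
  records <- as_tibble(as.data.frame(dataset))
  entities <- unique(records[[col]])
  if (spec$k > length(entities)) {
    stop_drp("k = %d exceeds the %d distinct %ss", spec$k, length(entities), unit)
  }
  roles <- with_seed(spec$seed, {
    group_of <- deal_into_folds(entities, spec$k)
    names(group_of) <- entities
    lapply(seq_len(spec$k) - 1L, function(f) {
      test_entities <- entities[group_of == f]
      train_entities <- entities[group_of != f]
      nv <- floor(spec$validation_fraction * length(train_entities))
      val_entities <- if (nv > 0) sample(train_entities, nv) else character(0)
      role <- rep("train", nrow(records))
      role[records[[col]] %in% val_entities] <- "validation"
      role[records[[col]] %in% test_entities] <- "test"
      role
    })
  })
  new_fold_assignment(build_long(records, roles, spec$k), spec, nrow(records))
}

#' Cell-blind K-fold split
#'
#' Distinct cells are dealt into `k` seeded groups balanced by cell count
#' (group sizes differ by at most one cell); fold f's test pairs are all
#' pairs whose cell is in group f. For every fold, test cells and
#' train/validation cells are disjoint. `k` equal to the number of cells
#' gives leave-one-cell-line-out.
#'
#' @inheritParams split_random
#' @return A `fold_assignment`.
#' @export
split_cell_blind <- function(dataset, spec) {
  spec$strategy <- "cell_blind"
  split_entity_blind(dataset, spec, "cell")
}

#' Drug-blind K-fold split
#'
#' Symmetric to [split_cell_blind()] with drugs as the unit; `k` equal to
#' the number of drugs gives leave-one-drug-out.
#'
#' @inheritParams split_random
#' @return A `fold_assignment`.
#' @export
split_drug_blind <- function(dataset, spec) {
  spec$strategy <- "drug_blind"
  split_entity_blind(dataset, spec, "drug")
}

#' Completely-blind (disjoint-set) K-fold split
#'
#' Cells are dealt into `k` groups and drugs into `k` groups (seeded).
#' Fold f tests the measured pairs in cell-group f x drug-group f and
#' trains on measured pairs whose cell *and* drug are both outside group f;
#' pairs mixing the two sides get `role = "discarded"` for that fold, so
#' the coverage cost of the strategy is explicit. On a full n x m grid the
#' k test blocks jointly cover ~1/k of all pairs and each fold's training
#' block is ~((k-1)/k)^2 of the grid.
#'
#' @inheritParams split_random
#' @return A `fold_assignment` (roles include `discarded`).
#' @export
split_completely_blind <- function(dataset, spec) {
  records <- as_tibble(as.data.frame(dataset))
  cells <- unique(records$cell_id)
  drugs <- unique(records$drug_id)
  if (spec$k > length(cells)) {
    stop_drp("k = %d exceeds the %d distinct cells", spec$k, length(cells))
  }
  if (spec$k > length(drugs)) {
    stop_drp("k = %d exceeds the %d distinct drugs", spec$k, length(drugs))
  }
  roles <- with_seed(spec$seed, {
    cell_group <- deal_into_folds(cells, spec$k); names(cell_group) <- cells
    drug_group <- deal_into_folds(drugs, spec$k); names(drug_group) <- drugs
    cg <- cell_group[records$cell_id]
    dg <- drug_group[records$drug_id]
    lapply(seq_len(spec$k) - 1L, function(f) {
      role <- rep("discarded", nrow(records))
      role[cg == f & dg == f] <- "test"
      role[cg != f & dg != f] <- "train"
      train_cells <- cells[cell_group != f]
      nv <- floor(spec$validation_fraction * length(train_cells))
      if (nv > 0) {
        val_cells <- sample(train_cells, nv)
        role[role == "train" & records$cell_id %in% val_cells] <- "validation"
      }
      role
    })
  })
  spec$strategy <- "completely_blind"
  new_fold_assignment(build_long(records, roles, spec$k), spec, nrow(records))
}

#' Cancer-type-blind K-fold split
#'
#' All cells of one cancer type share a fold. Types are assigned by seeded
#' greedy balancing on cell counts: types sorted by size (largest first,
#' ties broken by a seeded shuffle) are placed one at a time into the fold
#' currently holding the fewest cells. Cells with a missing cancer type are
#' excluded from every fold (`role = "discarded"`) and counted in the
#' assignment's notes.
#'
#' @inheritParams split_random
#' @return A `fold_assignment`.
#' @export
split_cancer_type_blind <- function(dataset, spec) {
  records <- as_tibble(as.data.frame(dataset))
  if (!"cancer_type" %in% names(records)) {
    stop_drp("cancer_type_blind splitting requires a cancer_type column")
  }
  cell_type <- records$cancer_type[!duplicated(records$cell_id)]
  names(cell_type) <- records$cell_id[!duplicated(records$cell_id)]
  known <- !is.na(cell_type) & nzchar(cell_type)
  excluded_cells <- names(cell_type)[!known]
  types <- unique(cell_type[known])
  if (spec$k > length(types)) {
    stop_drp("k = %d exceeds the %d distinct cancer types", spec$k, length(types))
  }
  sizes <- vapply(types, function(tp) sum(cell_type[known] == tp), integer(1))

  roles <- with_seed(spec$seed, {
    ord <- sample.int(length(types))              # seeded tie-break
    ord <- ord[order(-sizes[ord])]                # then largest first (stable)
    fold_cells <- integer(spec$k)
    type_fold <- integer(length(types)); names(type_fold) <- types
    for (i in ord) {
      f <- which.min(fold_cells)                  # ties -> lowest fold index
      type_fold[types[i]] <- f - 1L
      fold_cells[f] <- fold_cells[f] + sizes[i]
    }
    pair_type <- cell_type[records$cell_id]
    pair_fold <- ifelse(is.na(pair_type) | !nzchar(pair_type),
                        NA_integer_, type_fold[pair_type])
    lapply(seq_len(spec$k) - 1L, function(f) {
      role <- rep("train", nrow(records))
      role[is.na(pair_fold)] <- "discarded"
      role[!is.na(pair_fold) & pair_fold == f] <- "test"
      train_types <- types[type_fold != f]
      nv <- floor(spec$validation_fraction * length(train_types))
      if (nv > 0) {
        val_types <- sample(train_types, nv)
        role[role == "train" & pair_type %in% val_types] <- "validation"
      }
      role
    })
  })
  if (length(excluded_cells) > 0) {
    message(sprintf("cancer_type_blind: excluded %d cell(s) with missing cancer type",
                    length(excluded_cells)))
  }
  spec$strategy <- "cancer_type_blind"
  new_fold_assignment(build_long(records, roles, spec$k), spec, nrow(records),
                      notes = list(excluded_cells = excluded_cells))
}

#' Split a dataset under a named strategy
#'
#' Dispatches to the strategy-specific splitter named in `spec$strategy`.
#'
#' @inheritParams split_random
#' @return A `fold_assignment`.
#' @export
split_dataset <- function(dataset, spec) {
  switch(spec$strategy,
         random = split_random(dataset, spec),
         cell_blind = split_cell_blind(dataset, spec),
         drug_blind = split_drug_blind(dataset, spec),
         completely_blind = split_completely_blind(dataset, spec),
         cancer_type_blind = split_cancer_type_blind(dataset, spec),
         stop_drp("unknown strategy '%s'", spec$strategy))
}

#' Verify a fold assignment's guarantees
#'
#' Makes each strategy's promises machine-checkable. Checks (applied only
#' where applicable to `strategy`):
#' * `pair_coverage` — every measured pair is test in exactly one fold
#'   (at most one for completely-blind and for cells excluded under
#'   cancer-type-blind).
#' * `fold_balance` — test-unit counts per fold differ by at most 1
#'   (pairs for random, entities for cell/drug/completely-blind).
#' * `cell_disjointness` / `drug_disjointness` — per fold, no test entity
#'   occurs in any train or validation pair.
#' * `type_cohesion` — each cancer type's cells are test in one fold only.
#'
#' @param dataset the dataset the assignment was built from.
#' @param assignment a `fold_assignment`.
#' @param strategy strategy whose rules to check; defaults to the
#'   assignment's own.
#' @return A `split_verification`: tibble with columns `check`,
#'   `applicable`, `pass`, `detail`; attribute `all_pass`.
#' @export
verify_assignment <- function(dataset, assignment,
                              strategy = assignment$strategy) {
  a <- assignment$assignment
  k <- assignment$k
  records <- as_tibble(as.data.frame(dataset))
  key <- function(tab) paste(tab$cell_id, tab$drug_id, sep = "\r")
  pair_keys <- key(records)
  res <- list()
  add <- function(check, applicable, pass = NA, detail = "") {
    res[[length(res) + 1]] <<- tibble(check = check, applicable = applicable,
                                      pass = pass, detail = detail)
  }

  test_rows <- a[a$role == "test", , drop = FALSE]
  test_count <- table(factor(key(test_rows), levels = unique(pair_keys)))
  exact_once <- strategy %in% c("random", "cell_blind", "drug_blind")
  if (strategy == "cancer_type_blind") {
    excluded <- assignment$notes$excluded_cells %||% character(0)
    coverable <- !(records$cell_id %in% excluded)
  } else {
    coverable <- rep(TRUE, nrow(records))
  }
  over <- sum(test_count > 1)
  missed <- sum(test_count[coverable] == 0)
  cov_pass <- over == 0 &&
    (if (exact_once || strategy == "cancer_type_blind") missed == 0 else TRUE)
  add("pair_coverage", TRUE, cov_pass,
      sprintf("%d pair(s) tested more than once; %d coverable pair(s) never tested",
              over, missed))

  balance_counts <- switch(
    strategy,
    random = vapply(seq_len(k) - 1L, function(f)
      sum(test_rows$fold == f), integer(1)),
    cell_blind = vapply(seq_len(k) - 1L, function(f)
      length(unique(test_rows$cell_id[test_rows$fold == f])), integer(1)),
    drug_blind = vapply(seq_len(k) - 1L, function(f)
      length(unique(test_rows$drug_id[test_rows$fold == f])), integer(1)),
    completely_blind = NULL,
    cancer_type_blind = NULL)
  if (strategy == "completely_blind") {
    # both entity partitions must be balanced; measure on the group level
    cell_counts <- vapply(seq_len(k) - 1L, function(f)
      length(unique(test_rows$cell_id[test_rows$fold == f])), integer(1))
    drug_counts <- vapply(seq_len(k) - 1L, function(f)
      length(unique(test_rows$drug_id[test_rows$fold == f])), integer(1))
    # sparse data can hide entities from the test block, so balance is
    # reported, not enforced
    add("fold_balance", FALSE, NA,
        sprintf("test cells/fold: %s; test drugs/fold: %s",
                paste(cell_counts, collapse = ","),
                paste(drug_counts, collapse = ",")))
  } else if (is.null(balance_counts)) {
    add("fold_balance", FALSE, NA, "greedy type balancing; no <=1 guarantee")
  } else {
    spread <- diff(range(balance_counts))
    add("fold_balance", TRUE, spread <= 1,
        sprintf("per-fold unit counts: %s",
                paste(balance_counts, collapse = ",")))
  }

  check_disjoint <- function(col, label) {
    offenders <- character(0)
    for (f in seq_len(k) - 1L) {
      te <- unique(a[[col]][a$fold == f & a$role == "test"])
      tr <- unique(a[[col]][a$fold == f & a$role %in% c("train", "validation")])
      offenders <- c(offenders, intersect(te, tr))
    }
    offenders <- unique(offenders)
    add(label, TRUE, length(offenders) == 0,
        if (length(offenders) == 0) "" else
          sprintf("leaking %s(s): %s", sub("_.*", "", label),
                  paste(head(offenders, 5), collapse = ", ")))
  }
  if (strategy %in% c("cell_blind", "completely_blind", "cancer_type_blind")) {
    check_disjoint("cell_id", "cell_disjointness")
  } else {
    add("cell_disjointness", FALSE)
  }
  if (strategy %in% c("drug_blind", "completely_blind")) {
    check_disjoint("drug_id", "drug_disjointness")
  } else {
    add("drug_disjointness", FALSE)
  }

  if (strategy == "cancer_type_blind" && "cancer_type" %in% names(records)) {
    type_of <- records$cancer_type[match(test_rows$cell_id, records$cell_id)]
    folds_per_type <- tapply(test_rows$fold, type_of,
                             function(f) length(unique(f)))
    bad <- names(folds_per_type)[folds_per_type > 1]
    add("type_cohesion", TRUE, length(bad) == 0,
        if (length(bad) == 0) "" else
          sprintf("type(s) split across folds: %s", paste(bad, collapse = ", ")))
  } else {
    add("type_cohesion", FALSE)
  }

  out <- bind_rows(res)
  structure(out, class = c("split_verification", class(out)),
            all_pass = all(out$pass[out$applicable], na.rm = TRUE))
}

#' @rdname verify_assignment
#' @param verification a `split_verification`.
#' @export
all_checks_pass <- function(verification) {
  isTRUE(attr(verification, "all_pass", exact = TRUE))
}

#' Export a fold assignment as a flat table
#'
#' One row per (pair, fold) for roles test and validation (train membership
#' is derivable as the complement); set `expand_train = TRUE` to
#' materialize train and discarded rows too.
#'
#' @param assignment a `fold_assignment`.
#' @param expand_train include train/discarded rows.
#' @return tibble with columns `cell_id`, `drug_id`, `fold`, `role`.
#' @export
assignment_table <- function(assignment, expand_train = FALSE) {
  a <- assignment$assignment
  if (!expand_train) a <- a[a$role %in% c("test", "validation"), , drop = FALSE]
  as_tibble(a)
}
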