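#' Canonicalize cell/drug identifiers
#'
#' Uppercases and strips every non-alphanumeric character, so "MCF-7",
#' "mcf7" and "MCF 7" all map to "MCF7". Full identifier resolution
#' (Cellosaurus etc.) is deliberately out of scope.
#'
#' @param x character vector of raw identifiers.
#' @return canonical identifiers.
#' @export
canonicalize_id <- function(x) {
  toupper(gsub("[^A-Za-z0-9]", "", x))
}

apply_alias <- function(ids, alias) {
  if (is.null(alias)) return(ids)
  alias <- as_tibble(alias)
  if (!all(c("raw", "canonical") %in% names(alias))) {
    stop_drp("alias tables need columns raw, canonical")
  }
  conflict <- tapply(alias$canonical, alias$raw,
                     function(v) length(unique(v)))
  bad <- names(conflict)[conflict > 1]
  if (length(bad) > 0) {
    stop_drp("alias table maps raw id(s) to multiple canonical ids: %s",
             paste(bad, collapse = ", "))
  }
  hit <- match(ids, alias$raw)
  ifelse(is.na(hit), ids, alias$canonical[hit])
}

#' Match cell-drug pairs between two datasets
#'
#' Inner join on canonical (cell, drug) identifiers after applying optional
#' alias maps (tibbles with columns `raw`, `canonical`) and
#' case-insensitive, punctuation-stripped canonicalization. Refuses to
#' match datasets of differing response type unless `allow_mixed = TRUE`
#' (Spearman's rank invariance makes mixed comparison defensible, but it
#' must be explicit).
#'
#' @param a,b [triplet_dataset()] objects.
#' @param cell_map,drug_map optional alias tables applied before
#'   canonicalization.
#' @param allow_mixed permit differing response types.
#' @return list with aligned value vectors `values_a`, `values_b`, matched
#'   pair count `n`, and `n_unmatched_a`, `n_unmatched_b`.
#' @export
match_pairs <- function(a, b, cell_map = NULL, drug_map = NULL,
                        allow_mixed = FALSE) {
  if (!allow_mixed && !identical(response_type(a), response_type(b))) {
    stop_drp("response types differ (%s vs %s); pass allow_mixed = TRUE to override",
             response_type(a), response_type(b))
  }
  canon <- function(d) {
    tab <- as_tibble(as.data.frame(d))
    tibble(cell = canonicalize_id(apply_alias(tab$cell_id, cell_map)),
           drug = canonicalize_id(apply_alias(tab$drug_id, drug_map)),
           value = tab$response)
  }
  ta <- canon(a); tb <- canon(b)
  joined <- inner_join(ta, tb, by = c("cell", "drug"),
                       suffix = c("_a", "_b"), relationship = "many-to-many")
  key_a <- paste(ta$cell, ta$drug, sep = "\r")
  key_b <- paste(tb$cell, tb$drug, sep = "\r")
  list(values_a = joined$value_a, values_b = joined$value_b,
       n = nrow(joined),
       n_unmatched_a = sum(!(key_a %in% key_b)),
       n_unmatched_b = sum(!(key_b %in% key_a)))
}

#' Cross-dataset Spearman matrix
#'
#' For every pair of datasets, the Spearman correlation of responses over
#' their matched (cell, drug) pairs, together with the matched-pair count
#' — the standard picture of how well public screens agree with each
#' other. Correlations with fewer than `min_overlap` matched pairs are
#' reported as `NA` (the count is still reported). The diagonal holds each
#' dataset's self-correlation (1 whenever it has >= 2 pairs with variance)
#' and its own pair count.
#'
#' @param datasets list of [triplet_dataset()] objects (names taken from
#'   their `dataset_name`).
#' @param min_overlap minimum matched pairs before a correlation is
#'   reported (default 10).
#' @param allow_mixed permit differing response types across datasets.
#' @return A `cross_dataset_matrix`: list with `dataset_names`, `scc`
#'   (matrix, `NA` markers where undefined), `n_overlap` (matrix of
#'   counts).
#' @export
cross_dataset_matrix <- function(datasets, min_overlap = 10,
                                 allow_mixed = FALSE) {
  if (length(datasets) < 2) stop_drp("need >= 2 datasets")
  nm <- vapply(datasets, dataset_name, character(1))
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  p <- length(datasets)
  scc <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  n_ov <- matrix(0L, p, p, dimnames = list(nm, nm))
  for (i in seq_len(p)) {
    for (j in i:p) {
      m <- match_pairs(datasets[[i]], datasets[[j]], allow_mixed = allow_mixed)
      n_ov[i, j] <- n_ov[j, i] <- m$n
      if (m$n >= min_overlap &&
          stats::sd(m$values_a) > 0 && stats::sd(m$values_b) > 0) {
        scc[i, j] <- scc[j, i] <- stats::cor(m$values_a, m$values_b,
                                             method = "spearman")
      }
    }
  }
  structure(list(dataset_names = nm, scc = scc, n_overlap = n_ov,
                 min_overlap = min_overlap),
            class = "cross_dataset_matrix")
}

#' @export
print.cross_dataset_matrix <- function(x, ...) {
  cat(sprintf("<cross_dataset_matrix> %d datasets (min_overlap = %d)\n",
              length(x$dataset_names), x$min_overlap))
  print(round(x$scc, 3))
  invisible(x)
}
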