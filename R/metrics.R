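#' Match truth and prediction pairs
#'
#' Inner join of a truth dataset and a prediction table on
#' (cell_id, drug_id). Unmatched pairs on either side are counted.
#' @noRd
join_truth_pred <- function(truth, pred) {
  t_tab <- as_tibble(as.data.frame(truth))[c("cell_id", "drug_id", "response")]
  p_tab <- as_tibble(as.data.frame(pred))[c("cell_id", "drug_id", "predicted")]
  joined <- inner_join(t_tab, p_tab, by = c("cell_id", "drug_id"))
  list(joined = joined,
       n_unmatched_truth = nrow(t_tab) - nrow(joined),
       n_unmatched_pred = nrow(p_tab) - nrow(joined))
}

metric_block <- function(y, yhat) {
  # correlations carry NA markers when either side has zero variance;
  # they are never reported as fabricated zeros
  const <- stats::sd(y) == 0 || stats::sd(yhat) == 0
  resid <- yhat - y
  ss_tot <- sum((y - mean(y))^2)
  list(pcc = if (const) NA_real_ else stats::cor(y, yhat, method = "pearson"),
       scc = if (const) NA_real_ else stats::cor(y, yhat, method = "spearman"),
       rmse = sqrt(mean(resid^2)),
       mae = mean(abs(resid)),
       r2 = if (ss_tot == 0) NA_real_ else 1 - sum(resid^2) / ss_tot)
}

#' Overall regression metrics
#'
#' Scores a prediction table against a truth dataset over the inner join
#' of (cell, drug) pairs. PCC is Pearson correlation, SCC Spearman with
#' average-rank tie handling, RMSE/MAE the usual error norms, and
#' R^2 = 1 - SS_res / SS_tot. Zero-variance truth or predictions yield
#' `NA` correlation markers.
#'
#' @param truth a [triplet_dataset()].
#' @param pred a [prediction_table()] (or data frame with the same columns).
#' @return list with `pcc`, `scc`, `rmse`, `mae`, `r2`, `n_pairs`,
#'   `n_unmatched_truth`, `n_unmatched_pred`.
#' @export
overall_metrics <- function(truth, pred) {
  m <- join_truth_pred(truth, pred)
  if (nrow(m$joined) < 2) {
    stop_drp("need >= 2 matched (cell, drug) pairs; got %d", nrow(m$joined))
  }
  c(metric_block(m$joined$response, m$joined$predicted),
    list(n_pairs = nrow(m$joined),
         n_unmatched_truth = m$n_unmatched_truth,
         n_unmatched_pred = m$n_unmatched_pred))
}

per_entity_metrics <- function(truth, pred, entity_col, min_pairs = 3) {
  m <- join_truth_pred(truth, pred)
  joined <- m$joined
  if (nrow(joined) == 0) {
    out <- tibble(entity = character(), n_pairs = integer(),
                  pcc = numeric(), scc = numeric(), rmse = numeric())
    names(out)[1] <- entity_col
    return(out)
  }
  groups <- split(seq_len(nrow(joined)), joined[[entity_col]])
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (length(idx) < min_pairs) {
      return(tibble(entity = g, n_pairs = length(idx),
                    pcc = NA_real_, scc = NA_real_, rmse = NA_real_))
    }
    b <- metric_block(joined$response[idx], joined$predicted[idx])
    tibble(entity = g, n_pairs = length(idx),
           pcc = b$pcc, scc = b$scc, rmse = b$rmse)
  })
  out <- bind_rows(rows)
  names(out)[1] <- entity_col
  out[order(match(out[[entity_col]], unique(joined[[entity_col]]))), ]
}

#' Per-drug and per-cell metrics
#'
#' The clinically relevant view: metrics computed within each drug's (or
#' cell's) matched pairs only, so within-entity *ranking* ability is
#' visible rather than masked by between-entity potency differences.
#' Entities with fewer than `min_pairs` matched pairs (default 3 — a
#' Spearman on 2 points is always +/-1) are reported with their pair count
#' and `NA` metric markers.
#'
#' @inheritParams overall_metrics
#' @param min_pairs minimum matched pairs for an entity to be scored.
#' @return tibble with columns `drug_id` (resp. `cell_id`), `n_pairs`,
#'   `pcc`, `scc`, `rmse`.
#' @export
per_drug_metrics <- function(truth, pred, min_pairs = 3) {
  per_entity_metrics(truth, pred, "drug_id", min_pairs)
}

#' @rdname per_drug_metrics
#' @export
per_cell_metrics <- function(truth, pred, min_pairs = 3) {
  per_entity_metrics(truth, pred, "cell_id", min_pairs)
}

#' Fraction of entities above a metric threshold
#'
#' The waterfall-plot summary: the fraction of scorable entities whose
#' metric is *strictly* greater than `threshold`. Unscorable entities
#' (`NA` markers) are excluded from the denominator and counted
#' separately.
#'
#' @param per_entity_table output of [per_drug_metrics()] or
#'   [per_cell_metrics()].
#' @param metric column name to summarize (default `"scc"`).
#' @param threshold cutoff (default 0.5).
#' @return list with `fraction` (NA if nothing is scorable), `n_above`,
#'   `n_scorable`, `n_unscorable`.
#' @export
fraction_above <- function(per_entity_table, metric = "scc", threshold = 0.5) {
  vals <- per_entity_table[[metric]]
  if (is.null(vals)) stop_drp("no metric column '%s'", metric)
  scorable <- !is.na(vals)
  list(fraction = if (any(scorable)) mean(vals[scorable] > threshold) else NA_real_,
       n_above = sum(vals[scorable] > threshold),
       n_scorable = sum(scorable),
       n_unscorable = sum(!scorable))
}

auroc_rank <- function(y, score) {
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)                       # average ranks handle ties
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

auprc_ap <- function(y, score) {
  n1 <- sum(y)
  if (n1 == 0 || sum(!y) == 0) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  y <- y[ord]; score <- score[ord]
  # process tied-score blocks together so the curve is threshold-wise
  blocks <- rle(score)$lengths
  ends <- cumsum(blocks)
  tp <- cumsum(y)[ends]
  pos_seen <- ends
  prec <- tp / pos_seen
  recall <- tp / n1
  prev_recall <- c(0, head(recall, -1))
  sum((recall - prev_recall) * prec)
}

#' Binary classification metrics
#'
#' Scores binary sensitivity calls against continuous scores. Calls are
#' restricted to sensitive/resistant; `"undefined"` calls are excluded and
#' counted. Threshold metrics use `score >= threshold` as a positive
#' prediction; AUROC and AUPRC are threshold-free (rank-based Mann-Whitney
#' and blockwise average precision). The diagnostic odds ratio
#' `(TP*TN)/(FP*FN)` uses the Haldane 0.5 continuity correction when any
#' contingency cell is zero. Single-class truth yields `NA` AUROC/AUPRC.
#'
#' @param truth_calls tibble with `cell_id`, `drug_id`, `call` (output of
#'   [binarize()]).
#' @param scores a [prediction_table()]; higher score = more likely
#'   positive.
#' @param positive_label which call counts as positive (default
#'   `"sensitive"`).
#' @param threshold score cutoff for the contingency metrics.
#' @return list with `acc`, `sen`, `spc`, `pre`, `f1`, `fpr`, `gm`,
#'   `mcc`, `auroc`, `auprc`, `dor`, the contingency counts `tp`, `fn`,
#'   `fp`, `tn`, and `n_undefined_excluded`.
#' @export
binary_metrics <- function(truth_calls, scores,
                           positive_label = c("sensitive", "resistant"),
                           threshold = 0.5) {
  positive_label <- match.arg(positive_label)
  calls <- as_tibble(truth_calls)
  n_undef <- sum(calls$call == "undefined")
  calls <- calls[calls$call != "undefined", , drop = FALSE]
  p_tab <- as_tibble(as.data.frame(scores))[c("cell_id", "drug_id", "predicted")]
  joined <- inner_join(calls, p_tab, by = c("cell_id", "drug_id"))
  if (nrow(joined) < 2) stop_drp("need >= 2 matched labelled pairs")
  y <- joined$call == positive_label
  score <- joined$predicted
  pred_pos <- score >= threshold
  tp <- sum(pred_pos & y);  fn <- sum(!pred_pos & y)
  fp <- sum(pred_pos & !y); tn <- sum(!pred_pos & !y)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sen <- safe_div(tp, tp + fn)
  spc <- safe_div(tn, tn + fp)
  pre <- safe_div(tp, tp + fp)
  f1 <- if (is.na(pre) || is.na(sen) || (pre + sen) == 0) NA_real_ else
    2 * pre * sen / (pre + sen)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  hald <- if (any(c(tp, fn, fp, tn) == 0)) 0.5 else 0
  dor <- ((tp + hald) * (tn + hald)) / ((fp + hald) * (fn + hald))
  list(acc = (tp + tn) / (tp + tn + fp + fn),
       sen = sen, spc = spc, pre = pre, f1 = f1,
       fpr = if (is.na(spc)) NA_real_ else 1 - spc,
       gm = if (is.na(sen) || is.na(spc)) NA_real_ else sqrt(sen * spc),
       mcc = mcc,
       auroc = auroc_rank(y, score),
       auprc = auprc_ap(y, score),
       dor = dor,
       tp = tp, fn = fn, fp = fp, tn = tn,
       n_undefined_excluded = n_undef)
}

#' Full metric report
#'
#' Bundles overall, per-drug and per-cell tables plus the waterfall
#' summary into one object.
#'
#' @inheritParams per_drug_metrics
#' @param scc_threshold threshold for the per-drug SCC exceedance summary.
#' @return A `metric_report` list with elements `overall`, `per_drug`,
#'   `per_cell`, `summary`.
#' @export
metric_report <- function(truth, pred, min_pairs = 3, scc_threshold = 0.5) {
  per_drug <- per_drug_metrics(truth, pred, min_pairs)
  per_cell <- per_cell_metrics(truth, pred, min_pairs)
  structure(
    list(overall = overall_metrics(truth, pred),
         per_drug = per_drug,
         per_cell = per_cell,
         summary = c(fraction_above(per_drug, "scc", scc_threshold),
                     list(scc_threshold = scc_threshold))),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf("<metric_report> n=%d  PCC=%.3f SCC=%.3f RMSE=%.3f MAE=%.3f R2=%.3f\n",
              o$n_pairs, o$pcc, o$scc, o$rmse, o$mae, o$r2))
  s <- x$summary
  cat(sprintf("  per-drug: %d scorable, %d unscorable; %.0f%% with SCC > %.2f\n",
              s$n_scorable, s$n_unscorable, 100 * s$fraction, s$scc_threshold))
  invisible(x)
}
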