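#' Reference baseline predictors
#'
#' Simple predictors used to probe an evaluation protocol rather than to
#' win it:
#'
#' * `drug_mean_predictor(train)` predicts each drug's training-mean
#'   response for every requested pair (grand mean for unseen drugs).
#'   It is the canonical pathology baseline: on a screen dominated by drug
#'   main effects it achieves a spectacular *overall* correlation while
#'   carrying zero information about which cells respond to which drug.
#' * `additive_predictor(train)` adds training cell-mean offsets on top
#'   (grand mean + drug offset + cell offset, 0 offset for unseen
#'   entities). Under entity-blind splits it loses exactly the offset of
#'   the held-out entity type, reproducing the random >= cell-blind >=
#'   drug-blind degradation pattern when drug effects outweigh cell
#'   effects.
#' * `oracle_predictor(latents, noise_sd_pred, seed)` predicts the
#'   noiseless generative response plus controllable Gaussian noise — an
#'   upper-bound reference whose per-drug SCC can be tuned continuously
#'   from ~1 downward for waterfall-plot testing.
#'
#' All predictors are `drp_predictor` objects; score pairs with
#' [predict_pairs()].
#'
#' @param train a [triplet_dataset()] of training pairs.
#' @return A `drp_predictor`.
#' @name baseline-predictors
NULL

new_predictor <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "drp_predictor")
}

#' @export
print.drp_predictor <- function(x, ...) {
  cat(sprintf("<drp_predictor: %s>\n", x$kind))
  invisible(x)
}

#' @rdname baseline-predictors
#' @export
drug_mean_predictor <- function(train) {
  if (nrow(train) == 0) stop_drp("training data is empty")
  tab <- as_tibble(as.data.frame(train))
  means <- tapply(tab$response, tab$drug_id, mean)
  new_predictor("drug_mean",
                list(drug_means = means, grand_mean = mean(tab$response)))
}

#' @rdname baseline-predictors
#' @export
additive_predictor <- function(train) {
  if (nrow(train) == 0) stop_drp("training data is empty")
  tab <- as_tibble(as.data.frame(train))
  mu <- mean(tab$response)
  new_predictor("additive",
                list(grand_mean = mu,
                     drug_offsets = tapply(tab$response, tab$drug_id, mean) - mu,
                     cell_offsets = tapply(tab$response, tab$cell_id, mean) - mu))
}

#' @rdname baseline-predictors
#' @param latents the `latents` element returned by [generate_screen()].
#' @param noise_sd_pred sd of the noise added to the noiseless truth.
#' @param seed seed for the prediction noise (deterministic per call).
#' @export
oracle_predictor <- function(latents, noise_sd_pred = 0, seed = 1L) {
  new_predictor("oracle",
                list(grid = latents$grid, noise_sd_pred = noise_sd_pred,
                     seed = as.integer(seed)))
}

#' Score pairs with a predictor
#'
#' @param predictor a `drp_predictor`.
#' @param pairs data frame with columns `cell_id`, `drug_id` (extra
#'   columns ignored).
#' @return A [prediction_table()] in the same pair order.
#' @export
predict_pairs <- function(predictor, pairs) {
  pairs <- as_tibble(as.data.frame(pairs))[c("cell_id", "drug_id")]
  predicted <- switch(
    predictor$kind,
    drug_mean = {
      hit <- predictor$drug_means[pairs$drug_id]
      ifelse(is.na(hit), predictor$grand_mean, hit)
    },
    additive = {
      d_off <- predictor$drug_offsets[pairs$drug_id]
      c_off <- predictor$cell_offsets[pairs$cell_id]
      predictor$grand_mean +
        ifelse(is.na(d_off), 0, d_off) + ifelse(is.na(c_off), 0, c_off)
    },
    oracle = {
      idx <- match(paste(pairs$cell_id, pairs$drug_id, sep = "\r"),
                   paste(predictor$grid$cell_id, predictor$grid$drug_id,
                         sep = "\r"))
      if (anyNA(idx)) stop_drp("oracle_predictor: pair(s) outside the generated grid")
      base <- predictor$grid$noiseless[idx]
      if (predictor$noise_sd_pred > 0) {
        base + with_seed(predictor$seed,
                         stats::rnorm(length(base), 0, predictor$noise_sd_pred))
      } else base
    },
    stop_drp("unknown predictor kind '%s'", predictor$kind))
  prediction_table(tibble(cell_id = pairs$cell_id, drug_id = pairs$drug_id,
                          predicted = unname(predicted)))
}
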