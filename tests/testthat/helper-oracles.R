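# Independent brute-force oracles: explicit-formula implementations kept
# deliberately separate from the package's code paths.

pearson_bf <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

rank_avg_bf <- function(x) {
  # average ranks by explicit enumeration
  sapply(seq_along(x), function(i) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    less + (ties + 1) / 2
  })
}

spearman_bf <- function(x, y) pearson_bf(rank_avg_bf(x), rank_avg_bf(y))

rmse_bf <- function(y, yhat) sqrt(sum((yhat - y)^2) / length(y))

mcc_bf <- function(tp, fn, fp, tn) {
  (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
}

auroc_bf <- function(y, score) {
  # pairwise probability a positive outranks a negative; ties count 1/2
  pos <- score[y]; neg <- score[!y]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# dense trapezoid oracle for AUDRC on a clamped 4PL curve
audrc_trapz_bf <- function(upper, lower, inflection, hill,
                           cmin = 1e-10, cmax = 1e-4, n = 10001) {
  x <- seq(log10(cmin), log10(cmax), length.out = n)
  f <- pmin(1, pmax(0, fourpl(10^x, upper, lower, inflection, hill)))
  h <- diff(x)
  sum(h * (f[-n] + f[-1]) / 2) / (log10(cmax) - log10(cmin))
}

# percentile by explicit linear interpolation (quantile type 7 semantics)
pctile_bf <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

make_fit <- function(upper, lower, inflection, hill) {
  structure(list(upper = upper, lower = lower, inflection = inflection,
                 hill = hill, converged = TRUE, rss = 0, n_points = 9,
                 non_identifiable = FALSE),
            class = "fourpl_fit")
}

# small fully crossed dataset fixture
toy_grid <- function(n_cells, n_drugs, response_fn = function(c, d) c + d,
                     types = NULL, name = "toy",
                     response_type = "ln_ic50") {
  cells <- sprintf("C%02d", seq_len(n_cells))
  drugs <- sprintf("D%02d", seq_len(n_drugs))
  tab <- expand.grid(cell_id = cells, drug_id = drugs,
                     stringsAsFactors = FALSE)
  tab$response <- mapply(response_fn,
                         match(tab$cell_id, cells), match(tab$drug_id, drugs))
  if (!is.null(types)) tab$cancer_type <- types[match(tab$cell_id, cells)]
  triplet_dataset(tab, response_type = response_type, name = name)
}

identity_predictions <- function(dataset) {
  prediction_table(data.frame(cell_id = dataset$cell_id,
                              drug_id = dataset$drug_id,
                              predicted = dataset$response))
}
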