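#' Synthetic screen configuration
#'
#' The generative model for a synthetic drug screen is an additive
#' Gaussian ANOVA on the cells-by-drugs grid:
#' \deqn{r_{cd} = \mu + \alpha_d + \beta_c + \gamma_{cd} + \epsilon_{cd}}
#' with independent zero-mean Gaussian drug main effects (sd
#' `sigma_drug`), cell main effects (`sigma_cell`), drug-cell interactions
#' (`sigma_interaction`) and measurement noise (`sigma_noise`). A seeded
#' `missing_fraction` of pairs is deleted uniformly at random, emulating
#' the sparsity of curated public screens (the default 0.195 mirrors a
#' curated GDSC panel in which 19.5% of the cell-drug grid is
#' unmeasured). Cancer types are assigned to cells round-robin.
#'
#' This is the minimal structure that exhibits the field's evaluation
#' pathology: when `sigma_drug` dominates, a predictor that only knows
#' each drug's mean response scores a spectacular overall correlation
#' while being useless at ranking cells within any drug.
#'
#' @param n_cells,n_drugs grid dimensions.
#' @param n_types number of cancer types (round-robin over cells).
#' @param sigma_drug,sigma_cell,sigma_interaction,sigma_noise effect sds
#'   (at least one must be positive).
#' @param grand_mean baseline response.
#' @param missing_fraction fraction of pairs deleted, in \[0, 1).
#' @param seed integer seed; all randomness flows from it.
#' @return A `screen_config` list.
#' @export
screen_config <- function(n_cells = 50, n_drugs = 20, n_types = 5,
                          sigma_drug = 1, sigma_cell = 0.5,
                          sigma_interaction = 0.5, sigma_noise = 0.25,
                          grand_mean = 0, missing_fraction = 0.195,
                          seed = 1L) {
  if (n_cells < 1 || n_drugs < 1) stop_drp("n_cells and n_drugs must be >= 1")
  if (n_types < 1 || n_types > n_cells) {
    stop_drp("n_types must lie in [1, n_cells]")
  }
  sigmas <- c(sigma_drug, sigma_cell, sigma_interaction, sigma_noise)
  if (any(sigmas < 0)) stop_drp("sigmas must be >= 0")
  if (all(sigmas == 0)) stop_drp("at least one sigma must be > 0")
  if (!(missing_fraction >= 0 && missing_fraction < 1)) {
    stop_drp("missing_fraction must lie in [0, 1)")
  }
  structure(list(n_cells = as.integer(n_cells), n_drugs = as.integer(n_drugs),
                 n_types = as.integer(n_types),
                 sigma_drug = sigma_drug, sigma_cell = sigma_cell,
                 sigma_interaction = sigma_interaction,
                 sigma_noise = sigma_noise, grand_mean = grand_mean,
                 missing_fraction = missing_fraction, seed = as.integer(seed)),
            class = "screen_config")
}

#' Generate a synthetic screen with known ground truth
#'
#' Draws one screen from the model described in [screen_config()]. The
#' latent effects are returned alongside the observed dataset so tests
#' can use the generator itself as the oracle.
#'
#' @param config a [screen_config()].
#' @return list with:
#' * `dataset` — a [triplet_dataset()] of the observed (non-missing)
#'   pairs, with `cancer_type` attached;
#' * `latents` — list holding `alpha` (named drug effects), `beta`
#'   (named cell effects), `grid` (full-grid tibble with `noiseless`,
#'   `response` and `measured` columns) and the `config`.
#' @export
generate_screen <- function(config) {
  nc <- config$n_cells; nd <- config$n_drugs
  cells <- sprintf("CELL%03d", seq_len(nc))
  drugs <- sprintf("DRUG%03d", seq_len(nd))
  types <- sprintf("TYPE%02d", ((seq_len(nc) - 1L) %% config$n_types) + 1L)
  draws <- with_seed(config$seed, {
    list(alpha = stats::rnorm(nd, 0, config$sigma_drug),
         beta = stats::rnorm(nc, 0, config$sigma_cell),
         gamma = stats::rnorm(nc * nd, 0, config$sigma_interaction),
         eps = stats::rnorm(nc * nd, 0, config$sigma_noise),
         keep = stats::runif(nc * nd) >= config$missing_fraction)
  })
  names(draws$alpha) <- drugs
  names(draws$beta) <- cells
  # grid in cell-major order: cell varies slowest, drug fastest
  grid <- tibble(
    cell_id = rep(cells, each = nd),
    drug_id = rep(drugs, times = nc),
    cancer_type = rep(types, each = nd),
    noiseless = config$grand_mean +
      rep(draws$alpha, times = nc) + rep(draws$beta, each = nd) + draws$gamma,
    measured = draws$keep
  )
  grid$response <- grid$noiseless + draws$eps
  observed <- grid[grid$measured,
                   c("cell_id", "drug_id", "response", "cancer_type")]
  dataset <- triplet_dataset(observed, response_type = "ln_ic50",
                             name = sprintf("synthetic_screen_seed%d", config$seed))
  list(dataset = dataset,
       latents = list(alpha = draws$alpha, beta = draws$beta,
                      grid = grid, config = config))
}

#' Synthetic dose-response curve set configuration
#'
#' Each experiment samples a known 4PL curve on a log-spaced concentration
#' grid (default 9 points over the standard 100 pM - 100 uM window —
#' robust sigmoid fitting typically uses 8-10 concentrations) and adds
#' Gaussian viability noise, clipped at 0 below. Generating parameters
#' are drawn from uniform priors.
#'
#' @param n_experiments number of curves.
#' @param n_points concentrations per curve (>= 4).
#' @param cmin,cmax concentration window, molar.
#' @param upper_range,lower_range,log10_inflection_range,hill_range
#'   uniform priors for the generating 4PL parameters.
#' @param noise_sd viability noise sd.
#' @param seed integer seed.
#' @return A `curve_set_config` list.
#' @export
curve_set_config <- function(n_experiments = 20, n_points = 9,
                             cmin = 1e-10, cmax = 1e-4,
                             upper_range = c(0.9, 1.1),
                             lower_range = c(0, 0.2),
                             log10_inflection_range = c(-9, -5),
                             hill_range = c(0.5, 3),
                             noise_sd = 0.02, seed = 1L) {
  if (n_points < 4) stop_drp("n_points must be >= 4")
  if (!(cmin > 0 && cmax > cmin)) stop_drp("need 0 < cmin < cmax")
  if (hill_range[1] <= 0) stop_drp("hill prior must be positive")
  structure(list(n_experiments = as.integer(n_experiments),
                 n_points = as.integer(n_points), cmin = cmin, cmax = cmax,
                 upper_range = upper_range, lower_range = lower_range,
                 log10_inflection_range = log10_inflection_range,
                 hill_range = hill_range, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "curve_set_config")
}

#' Generate synthetic dose-response experiments
#'
#' @param config a [curve_set_config()].
#' @return list with `experiments` (list of [dose_response_experiment()])
#'   and `params` (tibble of generating parameters, one row per
#'   experiment: `experiment_id`, `upper`, `lower`, `inflection`, `hill`).
#' @export
generate_curves <- function(config) {
  conc <- 10^seq(log10(config$cmin), log10(config$cmax),
                 length.out = config$n_points)
  runif2 <- function(n, r) stats::runif(n, r[1], r[2])
  out <- with_seed(config$seed, {
    params <- tibble(
      experiment_id = sprintf("EXP%04d", seq_len(config$n_experiments)),
      cell_id = sprintf("CELL%03d", seq_len(config$n_experiments)),
      drug_id = "DRUG001",
      upper = runif2(config$n_experiments, config$upper_range),
      lower = runif2(config$n_experiments, config$lower_range),
      inflection = 10^runif2(config$n_experiments, config$log10_inflection_range),
      hill = runif2(config$n_experiments, config$hill_range))
    experiments <- lapply(seq_len(config$n_experiments), function(i) {
      v <- fourpl(conc, params$upper[i], params$lower[i],
                  params$inflection[i], params$hill[i])
      if (config$noise_sd > 0) {
        v <- pmax(0, v + stats::rnorm(length(v), 0, config$noise_sd))
      }
      dose_response_experiment(params$experiment_id[i], params$cell_id[i],
                               params$drug_id[i], conc, v)
    })
    list(experiments = experiments, params = params)
  })
  out
}
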