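# drpval

Standardized validation tooling for **drug response prediction (DRP)** —
models that predict how sensitive a cancer model (cell line, organoid, PDX)
is to a compound from a triplet dataset S = {cell, drug, response}.

Two evaluation practices routinely inflate reported DRP performance:

1. **Random cross-validation only.** Randomly splitting cell–drug *pairs*
   leaves every cell line and every drug represented in training, so the
   score says nothing about new patients or new compounds. `drpval` builds
   K-fold partitions under five strategies — `random`, `cell_blind`,
   `drug_blind`, `completely_blind` (disjoint cells *and* drugs, with
   explicit accounting of the pairs each fold must discard), and
   `cancer_type_blind` — and every assignment can be machine-verified
   (`verify_assignment()`): test/train entity disjointness, pair coverage,
   fold balance, type cohesion.
2. **Overall metrics only.** A model that merely learns each drug's average
   potency gets a spectacular overall Pearson correlation while being unable
   to rank cell lines *within* any drug — the clinically relevant task.
   `drpval` reports metrics overall **and** per drug / per cell
   (PCC, SCC, RMSE, MAE, R²; ACC/SEN/SPC/PRE/F1/FPR/GM/MCC/AUROC/AUPRC and
   the diagnostic odds ratio for binarized calls), plus waterfall summaries
   such as the fraction of drugs with SCC > 0.5.

Around those two pillars the package provides:

* **Dose–response standardization.** Raw viability curves are fitted with
  the four-parameter logistic model
  `f(c) = d + (a − d) / (1 + (c/e)^h)` and summarized by the area under the
  fitted curve over a *fixed* window (default 100 pM–100 µM, six orders of
  magnitude), normalized to [0, 1]:
  `AUDRC = ∫ clamp(f(10^x), 0, 1) dx / (log10 cmax − log10 cmin)`.
  Unlike the legacy per-experiment trapezoid
  (`audrc_trapezoid_experimental()`, provided for contrast), identical
  curves measured over different concentration ranges get identical scores.
  Absolute IC50, AADRC = 1 − AUDRC, per-drug/per-cell normalization and
  percentile binarization (sensitive ≤ P25 / resistant ≥ P75 / undefined
  between) are included.
* **Cross-dataset harmonization.** `cross_dataset_matrix()` matches
  cell–drug pairs across screens (canonicalized identifiers + optional alias
  tables) and reports the pairwise Spearman matrix with matched-pair counts,
  with a heatmap renderer.
* **A synthetic screen generator.** `generate_screen()` draws from an
  additive Gaussian model r_cd = µ + α_d + β_c + γ_cd + ε_cd with
  configurable variance components, missingness and cancer types, returning
  the latent effects so every claim in the package is testable against known
  ground truth — no downloads required. `generate_curves()` does the same
  for 4PL viability curves.
* **Baselines and orchestration.** Drug-mean, additive-effects and
  noisy-oracle reference predictors; `cross_validate()` / `cv_metrics()`;
  `run_pipeline()` to drive simulate → split → evaluate → plot from one JSON
  config with a reproducible manifest; ggplot2 diagnostics
  (`plot_per_drug_scatter()`, `plot_waterfall()`,
  `plot_cross_dataset_heatmap()`).

## Worked example

```r
library(drpval)

# simulate a small screen with known ground truth
sim <- generate_screen(screen_config(n_cells = 40, n_drugs = 15, seed = 7))
sim$dataset
#> <triplet_dataset 'synthetic_screen_seed7'> 478 pairs, 40 cells, 15 drugs, response = ln_ic50

# cell-blind five-fold split with machine-checked guarantees
spec <- split_spec("cell_blind", k = 5, seed = 7)
assignment <- split_cell_blind(sim$dataset, spec)
all_checks_pass(verify_assignment(sim$dataset, assignment))
#> [1] TRUE

# run the drug-mean baseline through CV and score it
cv <- cross_validate(sim$dataset, assignment, drug_mean_predictor)
mets <- cv_metrics(cv)
round(mets$fold_mean, 3)
#>   pcc   scc  rmse   mae    r2
#> 0.895 0.887 0.691 0.573 0.791
mets$pooled
#> <metric_report> n=478  PCC=0.890 SCC=0.873 RMSE=0.696 MAE=0.575 R2=0.791
#>   per-drug: 15 scorable, 0 unscorable; 0% with SCC > 0.50
```

Read the two lines together: the drug-mean baseline — which knows *nothing*
about individual cell lines — reaches an overall PCC of 0.89 on a
cell-blind split, yet **zero** of the 15 drugs clear a per-drug SCC of 0.5.
That gap is exactly the failure mode per-drug evaluation exists to expose.

```r
# standardized dose-response summary for one fitted curve
conc <- 10^seq(-10, -4, length.out = 9)
viab <- fourpl(conc, upper = 1, lower = 0.05, inflection = 2e-7, hill = 1.3)
fit <- fit_4pl(dose_response_experiment("E1", "MCF7", "lapatinib", conc, viab))
c(audrc = audrc(fit), aadrc = aadrc(fit), ic50_nM = absolute_ic50(fit) * 1e9)
#>       audrc       aadrc     ic50_nM
#>   0.5726494   0.4273506 216.8842752
```

AUDRC 0.57 means the drug leaves ~57% of the viability "area" intact across
the standardized window; the absolute IC50 (curve crossing 50% viability,
217 nM) sits slightly above the 200 nM inflection because the lower
asymptote is 0.05, not 0.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the package's main computation from scratch against the installed
package — simulating dose–response curves and fitting them, generating a
synthetic screen, building verified random / cell-blind / drug-blind
partitions, scoring a trained additive baseline under each, and correlating
a technical-replicate screen pair — logging a summary of each stage and
writing the results JSON to `--out`. All randomness derives from `--seed`.

## File formats

* Triplets: CSV/TSV with header `cell_id,drug_id,response[,cancer_type]`.
* Raw dose–response: `experiment_id,cell_id,drug_id,concentration,viability`
  (concentration unit declared at read time; molar internally).
* Predictions: `cell_id,drug_id,predicted`.
* Fold assignments: `cell_id,drug_id,fold,role`.

See the methods vignette (`vignettes/drp-validation.Rmd`) for the models,
numerical choices, and known limitations.
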