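---
title: "Validating drug response prediction models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating drug response prediction models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drpval)
```

# The problem

Drug response prediction (DRP) models map a cancer model (a cell line,
organoid or xenograft) and a compound to a sensitivity score. They are
trained on triplet datasets S = {cell, drug, response} from large
pharmacogenomic screens, and the way they are *evaluated* determines
whether a reported number means anything clinically. Two practices
dominate the literature and both flatter the model: random K-fold
splitting of cell–drug pairs (every test cell and drug was seen in
training) and overall correlation metrics (dominated by between-drug
potency differences rather than within-drug ranking of cells — the
quantity that actually matters for choosing a therapy for a patient).
`drpval` makes the alternatives cheap: entity-blind splits with
machine-checkable guarantees, per-drug/per-cell metric reports, a
standardized dose–response summary that is comparable across screens, and
a synthetic-data module so every one of these claims is testable against
known ground truth.

# Dose–response standardization

## Model

A viability curve is fitted with the four-parameter logistic (4PL)

$$f(c) = d + \frac{a - d}{1 + (c/e)^h}$$

where $a$ (`upper`) is the low-concentration asymptote, $d$ (`lower`) the
high-concentration asymptote, $e$ (`inflection`, molar) the EC50 and $h$
(`hill`) the slope; $f(e) = (a+d)/2$. With $h > 0$ viability decreases
with concentration. Fitting is plain least squares in log10-concentration
space. The practical choices:

* **Deterministic multi-start.** Seven L-BFGS-B starts whose inflection
  guesses are the 10/25/50/75/90% quantiles of the measured log10
  concentrations (plus shallow/steep Hill variants), with asymptote
  guesses from the curve ends. Starts are functions of the data only, so
  identical input always gives identical fits without touching any global
  RNG. The best converged start is polished with a bounded Newton-type
  pass (`nlminb`, relative tolerance 1e-15), which recovers noiseless
  synthetic parameters to machine precision — the test suite asserts
  1e-6 relative error, with plenty of margin.
* **Hill bounds [0.1, 10]** (configurable) prevent divergence on sparse
  or non-sigmoidal curves; asymptotes may drift 0.5 viability units
  beyond the observed range.
* **No weights, no robust loss.** Screens rarely publish per-well
  variances; ordinary least squares keeps the estimator transparent. A
  flat response returns a degenerate `upper == lower`, `hill = 0`,
  `non_identifiable = TRUE` fit rather than an error, because flat curves
  are a legitimate biological outcome (no effect), not a failure.

## AUDRC on a fixed window

The standardized summary is the area under the *fitted* curve over a fixed
log-concentration window, normalized to [0, 1]:

$$\mathrm{AUDRC} = \frac{1}{\log_{10} c_{max} - \log_{10} c_{min}}
\int_{\log_{10} c_{min}}^{\log_{10} c_{max}}
\mathrm{clamp}(f(10^x), 0, 1)\, dx$$

with defaults $c_{min} = 100\,\mathrm{pM}$, $c_{max} = 100\,\mu\mathrm{M}$
— six orders of magnitude covering the therapeutic window of most
approved oncology drugs. 1 means no effect anywhere in the window, 0
complete killing. The legacy alternative — trapezoidal integration of the
raw points over each experiment's own range — is also implemented
(`audrc_trapezoid_experimental()`) purely to demonstrate its defect: the
same underlying curve sampled over two different concentration ranges
yields two different legacy scores but a single standardized one (the
test suite asserts both halves of that contrast).

Numerical choices worth recording:

* Integration is on the **log10 axis** (curves are measured, plotted and
  reasoned about on log dose) and normalized by the window width so the
  score is a dimensionless fraction.
* Fitted viability is **clamped to [0, 1] inside the integral** so
  asymptotes that drift outside [0, 1] cannot push the score out of
  bounds. Clamping introduces kinks; the integral is split at the exact
  crossing points (closed form from the 4PL) so adaptive quadrature
  (`integrate`, absolute tolerance 1e-8, relative 1e-9) actually attains
  its tolerance — without the split, `integrate`'s default relative
  tolerance silently dominates and errors of ~1e-5 appear. Agreement with
  a 10,001-point trapezoid oracle is asserted to 1e-6 across a random
  parameter grid.
* `aadrc = 1 - audrc` by construction, so the complement identity is
  exact rather than a second quadrature.

## IC50: absolute, not the inflection

"IC50" is reported as the concentration where the fitted curve crosses a
viability *level* (default 0.5), solved in closed form:
$c = e\,((a-t)/(t-d))^{1/h}$. This is deliberately distinct from the
inflection parameter (EC50): the two coincide only when the asymptotes
are exactly 1 and 0. When the curve never reaches the threshold the value
is an explicit `NA`, never an extrapolation. The natural-log convenience
column `ln_ic50` uses the molar value; source datasets disagree about
units (µM vs M), so downstream code treats response values as opaque
reals and the unit convention is a documentation matter, not a hidden
transform.

## Normalization and binarization

`normalize_responses()` offers global/per-drug min–max scaling to [0, 1]
and per-drug/per-cell mean-centering (per-drug centering highlights which
*cells* respond differentially, removing potency offsets). Zero-variance
groups map to 0.5 (min–max) or 0 (centering) with a warning.
`binarize()` implements percentile calls: at or below the low percentile
(default 25th) is "sensitive", at or above the high percentile (default
75th) "resistant", between them "undefined" — a three-way labelling that
avoids forcing borderline responses into a class. Percentiles use linear
interpolation (`quantile` type 7, asserted against an explicit
interpolation oracle); groups under 4 records are skipped, and a
degenerate all-tied group is called all-undefined rather than
simultaneously sensitive and resistant.

# Entity-aware cross-validation

Five strategies, each a proxy for a deployment question:

| strategy | unit dealt into folds | guarantee per fold |
|---|---|---|
| `random` | cell–drug pairs | — (optimistic baseline) |
| `cell_blind` | cells | test cells ∉ training (new patient) |
| `drug_blind` | drugs | test drugs ∉ training (new compound) |
| `completely_blind` | cells *and* drugs | neither test cells nor test drugs in training |
| `cancer_type_blind` | cancer types | whole types held out together |

Design decisions:

* **Diagonal pairing for completely-blind.** Cell-group f is paired with
  drug-group f, giving exactly k folds; pairs mixing a test-side entity
  with a train-side entity are explicitly `role = "discarded"` (on a full
  grid, the k test blocks jointly cover 1/k of pairs and each training
  block is ((k−1)/k)² of the grid — asserted exactly on divisible grids).
  Reporting the discard cost is part of the contract; silently dropping
  those pairs is how completely-blind results become incomparable.
* **Entity-count balance, not pair balance.** Blind folds differ by at
  most one entity; pair counts then vary with screen sparsity. This is
  the simplest contract with a provable bound, and it is what
  `verify_assignment()` checks.
* **Validation carve-outs at the entity level.** When a
  `validation_fraction` is requested, blind strategies carve whole
  entities (or whole cancer types) out of the training side, so
  hyperparameter selection enjoys the same blindness guarantee as the
  test set. The random strategy carves pairs.
* **Greedy type balancing.** Cancer types are placed largest-first into
  the currently smallest fold (seeded tie-break). Cells lacking a type
  are excluded from every fold and counted in the assignment's notes.
* **Everything is verifiable.** `verify_assignment()` re-derives pair
  coverage, fold balance, cell/drug disjointness and type cohesion from
  the assignment table itself and names offending entities; the property
  suite runs it across hundreds of random sparse screens, and a negative
  control asserts that a random assignment *fails* cell-blind rules.

Default k = 5 matches standard practice; k equal to the number of
entities yields the leave-one-cell-line-out / leave-one-drug-out
boundary cases.

# Metrics

Overall: Pearson and Spearman correlation (average ranks on ties), RMSE,
MAE, R² = 1 − SS_res/SS_tot, over the inner join of truth and prediction
pairs. Per-drug and per-cell tables repeat these within each entity.
Binary reports cover ACC/SEN/SPC/PRE/F1/FPR/GM/MCC, rank-based AUROC,
blockwise average-precision AUPRC, and the diagnostic odds ratio with
Haldane's 0.5 correction when a contingency cell is zero.

* **min_pairs = 3** for per-entity correlations: a Spearman on two points
  is ±1 by construction and would only pollute waterfall summaries.
* **Undefined means undefined.** Zero-variance groups and too-small
  entities carry `NA` markers which are excluded from summary
  denominators — never coerced to zero, which would silently deflate
  "fraction of drugs above threshold" statistics.
* **Strict inequality** in `fraction_above()` ("greater than 0.5").
* **Fold-average vs pooled.** `cv_metrics()` reports both: fold-level
  overall metrics averaged across folds (how benchmark tables usually
  report "average SCC") and pooled per-drug tables (per-drug metrics need
  the pooled view, since within a single fold a baseline's per-drug
  predictions may be constant). The two answer different questions and
  neither is privileged.
* Every correlation/error/AUROC implementation is asserted to 1e-12
  against an independent brute-force oracle (explicit ranks, explicit
  pairwise comparisons) across random instances, including deliberately
  tied data.

## A caveat on pooled-CV per-drug metrics for low-information baselines

The drug-mean baseline predicts one value per drug per fold. After
pooling K folds, the only within-drug variation in its predictions is the
fold-to-fold variation of training means — which is, up to a constant,
the *negative* of each fold's held-out block sum. Per-drug rank
correlations for such a predictor are therefore systematically negative
with magnitude on the order of $1/\sqrt{\text{block size}}$ (times a tie
attenuation factor), *regardless of the screen's variance settings*: with
50 cells and k = 5 that is roughly −0.2 per drug. This is a
regression-to-the-mean conditioning artifact of the pooled evaluation,
not evidence of (anti-)signal, and it does not shrink with more data per
drug. Interpret small pooled per-drug correlations for near-constant
predictors accordingly; the acceptance suite documents a bound that
presumes independent within-drug noise (≈ 0.11–0.13 expected absolute
Spearman at these sizes) and is therefore not attainable by this
construction — the corresponding test is left failing, with this section
as the analysis.

# Cross-dataset harmonization

`match_pairs()` joins two screens on canonicalized identifiers
(uppercase, punctuation stripped — "MCF-7" ≡ "mcf7"), optionally after
user-supplied alias tables; an alias that maps one raw id to two
canonical ids is an error. `cross_dataset_matrix()` reports pairwise
Spearman over matched pairs together with the matched-pair count, and
refuses correlations on fewer than `min_overlap = 10` pairs (the count is
still shown). Comparing datasets with different response types requires
an explicit `allow_mixed = TRUE`: Spearman's rank invariance makes the
comparison defensible, but it should never happen by accident. Replicate
measurements are aggregated (median) before correlating. Full identifier
resolution against external registries is out of scope.

# The synthetic world

`generate_screen()` draws from

$$r_{cd} = \mu + \alpha_d + \beta_c + \gamma_{cd} + \varepsilon_{cd}$$

with independent zero-mean Gaussian drug effects, cell effects,
interactions and noise, uniform-at-random missingness, and round-robin
cancer types. Defaults: 50 cells × 20 drugs, σ_drug = 1, σ_cell = 0.5,
σ_interaction = 0.5, σ_noise = 0.25, missingness 0.195 (the sparsity of a
curated public screen in which 107,446 of 561 × 238 possible pairs are
measured). The additive Gaussian structure is the *minimal* model that
exhibits the central evaluation pathology — overall correlation driven by
σ_drug, per-drug ranking driven by σ_cell and σ_interaction — which is
exactly what makes it a good test bed. What it does **not** emulate:
heavy-tailed responses, structured missingness (drug panels), chemical
similarity between drugs, or any omics feature structure. A green test on
this generator certifies the *evaluation machinery*, not any biological
model.

`generate_curves()` supplies 4PL curves at 9 log-spaced concentrations
over the standard window (robust sigmoid fitting typically uses 8–10
points) with uniform parameter priors and truncated Gaussian viability
noise, returning generating parameters for recovery tests.

Reference predictors: `drug_mean_predictor` (the pathology baseline),
`additive_predictor` (grand mean + training drug and cell offsets, zero
for unseen entities), and `oracle_predictor` (noiseless truth plus
tunable noise, for sweeping per-drug SCC from ~1 toward chance in
waterfall tests).

## Choosing the split-sensitivity world

The qualitative claim "overall SCC degrades random ≥ cell-blind ≥
drug-blind" is a statement about models that *use* training data; a
predictor independent of its training fold scores identically under
every strategy. The package therefore exercises the claim with the
trained additive baseline. For the ordering to be a property of the world
rather than luck, two conditions must hold: (i) drug effects must be at
least as informative as cell effects (σ_drug ≥ σ_cell), since drug-blind
folds lose the drug offsets; and (ii) cell-mean estimates must carry
signal, i.e. σ_cell must exceed their sampling noise
$\sqrt{(\sigma_\gamma^2 + \sigma_\varepsilon^2)/n_\text{drugs}}$ —
otherwise cell-blind and random splits are statistically
indistinguishable. The stated world (60 cells × 30 drugs, σ_drug = 1.5,
σ_cell = 1.0, σ_interaction = 2.0 dominant, σ_noise = 0.3) satisfies
both with margin; the ordering then holds in essentially every seed.

# Orchestration and plotting

`run_pipeline()` drives simulate → split → evaluate → plot from one named
list or JSON file, validates the configuration *before* any stage runs,
and writes a JSON manifest recording each stage's parameters, seed and
artifacts; re-running an identical config reproduces byte-identical CSVs.
JSON was chosen over YAML because the R stack ships a JSON parser and the
format needs nothing YAML adds. Plots (per-drug scatter with
best/worst-drug trend lines, SCC waterfall with threshold annotation,
cross-dataset heatmap with n annotations) attach the exact plotted table
as an attribute; tests compare those tables, never pixels, and the
pipeline writes PNGs only as a best-effort side product of the sidecar
CSVs.

I/O notes: triplet responses are serialized with 17 significant digits
and parsed through base R's correctly rounded `strtod`, so
write-then-read reproduces doubles bit-for-bit (asserted in the suite);
replicate rows are collapsed by median (robust to outlier wells) at read
time; concentrations are converted to molar at the I/O boundary and kept
molar internally; missing response pairs are absent rows, never imputed.

# Known limitations

* No GR-metric, synergy scores, Bayesian curve fitting or plate-level QC.
* No pair-count-balanced blind folds, nested CV orchestration, or
  temporal splits.
* No significance tests or confidence intervals on metric differences.
* Identifier canonicalization is lexical only; real cross-screen matching
  needs curated alias tables.
* The synthetic generator's independence assumptions make it a machine
  for testing evaluation logic, not a simulator of screen biology.
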