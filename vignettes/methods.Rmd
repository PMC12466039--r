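---
title: "Methods: the two-stage human pharmacokinetics model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-stage human pharmacokinetics model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the estimation
procedure, the evaluation protocol, the synthetic-data generator, and
the numerical choices made in `pkcascade`. Code chunks are shown but
not evaluated: the worked example in the README runs the same pipeline
end to end.

## The prediction problem

Given a compound's structure (a SMILES string), the package predicts
five human intravenous pharmacokinetic parameters:

| endpoint | meaning                                 | unit      | modelling scale |
|----------|-----------------------------------------|-----------|-----------------|
| VDss     | steady-state volume of distribution     | L/kg      | log10           |
| CL       | total plasma clearance                  | mL/min/kg | log10           |
| t_half   | elimination half-life                   | h         | log10           |
| fu       | fraction unbound in plasma              | 0–1       | raw             |
| MRT      | mean residence time                     | h         | log10           |

All endpoints except `fu` are strictly positive and right-skewed, so
they are modelled after a decadic log transform; `fu` is bounded in
(0, 1] and modelled on the raw scale with a `1e-4` floor applied
before any fold-error division.

## Data curation

`curate_pk_data()` applies, in order:

1. **SMILES standardization** — RDKit cleanup, normalization, largest
   organic fragment (removes counter-ions such as `.Cl`), canonical
   tautomer, then a deterministic rule-based protonation at pH 7.4
   (carboxylic/sulfonic/phosphonic acids and tetrazoles deprotonated;
   aliphatic amines, amidines and guanidines protonated). The
   transformation is idempotent: standardizing a standardized SMILES
   is a no-op.
2. **Invalid values to missing** — `fu` outside (0, 1], non-positive
   values of the log-modelled endpoints.
3. **Duplicate merging** — records sharing a standardized SMILES are
   merged by the per-endpoint median.
4. **Molecular-weight filter** — compounds above
   `mean(MW) + 1.5 * sd(MW)` are removed. The threshold is computed
   *after* merging, so repeated measurements of one compound do not
   weight the threshold; only an upper filter is applied because the
   small-molecule lower tail is legitimate chemistry.
5. **Log transform** of all endpoints except `fu`.

The result is a `pk_dataset` tibble (one row per unique standardized
compound) carrying a curation report: counts of unparsable records,
invalidated values, merged duplicates, the MW threshold, and the final
annotation sparsity.

## Features

* **Morgan fingerprints**: radius 2, folded to 2048 bits. Feature
  selection keeps bits with variance ≥ 0.05 across the training
  compounds.
* **Physicochemical descriptors**: RDKit's full 2D descriptor set
  (210 descriptors). Selection drops descriptors with any missing
  value, then variance < 0.05, then applies a greedy left-to-right
  correlation filter at |r| threshold 0.95 on the *signed* correlation
  (two perfectly anti-correlated descriptors are both kept; they are
  not redundant for a tree ensemble in the presence of interactions —
  an explicit, documented choice; `use_abs_cor = TRUE` is available).
* **Predicted animal pharmacokinetics**: the nine Stage-1 model
  outputs (`VDss`, `CL`, `fu` for rat, dog, monkey), on the modelling
  scales (log10 for VDss/CL, raw clipped [1e-4, 1] for fu).

Feature selection and scaling (centre/scale to unit variance) are fit
on each model's full modelling subset before cross-validation
splitting. This follows the published protocol for this model family;
it leaks marginal feature statistics (not labels) into the folds, and
is retained deliberately for fidelity rather than corrected.

## Stage 1: animal models

For each species, compounds annotated for at least one of that
species' endpoints define the species subset, on which a feature
recipe (selected fingerprint bits + selected descriptors) is fit. Each
of the nine (species × endpoint) Random Forest models is selected by
nested cross-validation (below) and refit on all annotated compounds.

## Stage 2: human models

`predict_animal_features()` runs the nine Stage-1 models on every
human-set compound; the 9-vector of predictions becomes a feature
block. Ten feature combinations are defined:

1. fingerprints; 2. descriptors; 3. predicted animal; 4. fingerprints
+ descriptors; 5. fingerprints + predicted animal; 6. descriptors +
predicted animal; 7. all three; 8. animal block with *measured* animal
values overlaid where available; 9. all three with the overlay; 10. a
mean-predictor baseline run through the identical cross-validation
loop.

Combination 7 is the released model: combinations 8 and 9 score better
in cross-validation, but measured animal data are unavailable for new
compounds, so they serve as diagnostics only. Fold assignments are
identical across combinations (same sample size and seed), making
per-fold comparisons paired; `paired_gmfe_test()` formalizes them.

## Nested cross-validation

`nested_cv()` runs `n_repeats` (default 5) repetitions of an
`n_outer`-fold split (default 5). On each outer-training portion an
`n_inner`-fold (default 4) grid search selects Random Forest
hyperparameters; the selected model is refit on the outer-training
portion and evaluated on the held-out fold. Defaults of the grid
(`default_rf_grid()`):

* `num_trees`: 100, 250, 500
* `max_depth`: 8, 12, unlimited (`0`)
* `min_node`: 1, 3, 5
* `mtry`: square-root heuristic or 0.3 × p

The **inner selection score is the natural-scale GMFE** (geometric
mean fold error), not RMSE: GMFE is the quantity the field reports and
optimizing the reported quantity end to end avoids a selection
mismatch. The final released model reuses the hyperparameters of the
best evaluation fold (lowest GMFE; ties broken toward fewer trees,
then shallower depth) and is refit on all data — a deliberately
simple, documented rule. Every stochastic component (fold assignments,
forest seeds) is pre-drawn from the single `cv_config()` seed, so a
run is a pure function of `(x, y, config)`.

## Evaluation metrics

With predictions `f` and observations `y` on the natural scale:

* fold error `FE = max(f/y, y/f)`; percentage within 2-, 3-, 5-fold
  (boundary inclusive); median fold error;
* `GMFE = 10^mean(|log10 FE|)` — always ≥ 1. The *signed* companion,
  `ALB = mean(log10(f/y))`, is exposed separately
  (`alb_signed()`); defining GMFE with the absolute value is what
  makes reported values ≥ 1, and the two statistics answer different
  questions (accuracy vs. directional bias);
* bias = `median(f − y)` on the natural scale;
* RMSE and R² on the modelling (log) scale.

`pk_metrics()` applies the scale contract automatically.

## Uncertainty and applicability domain

For the released (combination 7) models, each evaluation fold yields
(mean 5-nearest-neighbour Tanimoto similarity to that fold's training
compounds, fold error) pairs. Pairs below `mean − 1.5·sd` of the
similarity distribution are discarded as unsupported extrapolation,
and similarities are binned at two decimals (the resolution at which
the similarity → error relation is resolvable with these sample
sizes; finer bins would be fit to noise). A kernel ridge regression
with an RBF + white-noise kernel — the closed form
`(K + (λ + σ²) I) α = y` — is fit to the binned means, with
lengthscale, ridge and noise chosen by 10-fold cross-validated R² over
a log-spaced grid.

At prediction time, a query compound's mean 5-NN similarity to the
training set gives an estimated fold error (clipped ≥ 1, since a fold
error below 1 is meaningless), a prediction range
`[pred / FE, pred × FE]`, and an applicability-domain alert when the
similarity is *strictly* below 0.25 (a similarity of exactly 0.25 does
not alert; the boundary convention is tested).

## Synthetic-data generator

`generate_pk_data()` produces a seeded synthetic study with known
ground truth, built from a bundled pool of drug-like SMILES plus a
deterministic combinatorial scaffold expansion. On the log10 scale,

```
endpoint = location + scale * (sqrt(f_s) * structural
                               + sqrt(f_l) * latent
                               + sqrt(1 - f_s - f_l) * noise)
```

where `structural` is a z-scored linear combination of seven
continuous RDKit descriptors (per endpoint family), `latent` is a
shared per-compound variable *not* derivable from structure, `f_s =
signal_fraction` (default 0.55) and `f_l = cross_species_weight`
(default 0.15). `fu` passes through a decadic logistic link. Raw
tables additionally contain duplicated records with jittered values
and `.Cl` salt forms, so the generator exercises the curation
protocol, not just the models.

Default sizes (1283 human / 371 animal compounds, 300 shared,
per-endpoint missingness matching the curated study conditions the
package emulates) reproduce the intended study shape. Tests and the
acceptance script run smaller studies (e.g. 120–200 human compounds,
1–2 repeats × 3 folds, a 2–4-row grid); these problem sizes are the
package's own choice, selected so the full suite runs in minutes on
one CPU while keeping every code path exercised at realistic
sparsity.

**What passing the synthetic tests shows** — and does not show. The
generator's structural signal is linear in descriptors, so it
demonstrates that the pipeline *recovers signal it is built to carry*:
richer feature blocks beat fingerprints alone, the mean baseline
scores R² ≤ 0 out of fold, cross-validation does not leak, the
fold-error curve decreases with similarity, and the AD alert fires at
the documented threshold. It does *not* demonstrate real-world
predictive accuracy on measured pharmacokinetics; reproducing the
published dataset statistics and performance requires the original
curated tables, which are not redistributable with the package (the
acceptance tests document the expected file layout under
`inst/extdata/supplementary/`).

## Numerical choices

* All randomness flows from a single integer seed per object
  (`cv_config()`, `synthetic_pk_spec()`); derived seeds are drawn
  once, up front, below 2³¹.
* Forests run single-threaded (`num.threads = 1`) for bit
  reproducibility.
* Kernel ridge uses `solve()` on an n×n system; n here is the number
  of similarity bins (≤ 101), so conditioning is a non-issue once the
  white-noise term is on the diagonal.
* Tanimoto similarity is computed by matrix algebra
  (`A Bᵀ / (|A| + |B| − A Bᵀ)`), with the empty–empty fingerprint pair
  defined as similarity 0.
* `max_depth = 0` encodes "unlimited" and sorts as deepest in
  tie-breaking.

## Limitations

* The protonation step is a compact SMARTS rule set, not a full pKa
  model; unusual ionizable groups keep their input state.
* The descriptor block is RDKit's 2D set; retained-descriptor counts
  are not comparable to pipelines built on other descriptor software.
* Stage-2 accuracy is bounded by Stage-1 accuracy for the animal
  block; with sparse animal data the predicted-animal features can be
  weak.
* The fold-error estimator extrapolates poorly outside the similarity
  range seen in cross-validation; the AD alert is a coarse guard, not
  a calibrated confidence interval.
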