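# pkcascade

Predicting human intravenous pharmacokinetics from chemical structure
with a two-stage, cross-species Random Forest cascade.

## The science

Before a drug candidate is first dosed in humans, its human
pharmacokinetic (PK) parameters must be anticipated from preclinical
data. Five parameters drive dose selection:

* **VDss** — steady-state volume of distribution (L/kg)
* **CL** — total plasma clearance (mL/min/kg)
* **t½** — elimination half-life (h)
* **fu** — fraction unbound in plasma (0–1)
* **MRT** — mean residence time (h)

Animal PK (rat, dog, monkey) carries real information about human PK,
but measured animal data only exist for compounds that have already
been synthesized and dosed. The idea implemented here is a **cascade**:

1. **Stage 1** trains nine Random Forest models — VDss, CL and fu for
   each of rat, dog and monkey — on structural features (Morgan
   fingerprints, radius 2 / 2048 bits, plus 2D physicochemical
   descriptors).
2. **Stage 2** runs those nine models on every human-dataset compound
   and injects the *predicted* animal parameters as nine extra
   features into the five human-endpoint models.

Because the animal features are themselves predictions from structure,
the final models need nothing but a SMILES string at prediction time,
yet they inherit part of the cross-species signal. All endpoints
except fu are modelled on the decadic log scale; fu stays on the raw
(0, 1] scale.

Around the core model the package provides:

* the full **curation protocol**: SMILES standardization (largest
  fragment, canonical tautomer, rule-based pH 7.4 protonation),
  invalid-value handling, duplicate merging by median, a
  mean + 1.5·SD molecular-weight filter, and log transforms
  (`curate_pk_data()`);
* **feature selection** (variance and correlation filters,
  `fit_feature_recipe()`);
* **repeated nested cross-validation** with grid-search
  hyperparameter selection scored by natural-scale geometric mean
  fold error (`nested_cv()`, `cv_config()`);
* the **fold-error metric panel** — 2/3/5-fold percentages, MFE,
  GMFE, signed ALB, bias, RMSE, R² with the scale contract applied
  automatically (`pk_metrics()`);
* a similarity-based **uncertainty estimate**: a kernel ridge
  regression maps mean 5-nearest-neighbour Tanimoto similarity to an
  expected fold error, with an applicability-domain alert below
  similarity 0.25 (`fit_fold_error_model()`, `estimate_fold_error()`);
* **chemical-space diagnostics** (`similarity_profile()`,
  `cross_species_regression()`, `pca_projection()`,
  `clearance_strata()`);
* a first-class **synthetic-data generator** with known ground truth
  (`synthetic_pk_spec()`, `generate_pk_data()`), used throughout the
  test suite;
* a **command-line interface** (`inst/cli/pkcascade`) covering
  curation, training, and batch prediction.

Chemistry primitives (standardization, fingerprints, descriptors) are
delegated to Python RDKit through a bundled helper; `python` with
RDKit must be on the PATH (or set `options(pkcascade.python = ...)`).

See `vignettes/methods.Rmd` for the full methods description.

## Worked example

A complete run on a small synthetic study (about a minute on one CPU):

```r
library(pkcascade)

spec <- synthetic_pk_spec(n_human = 140, n_animal = 110, n_overlap = 45,
                          sparsity_animal = c(rat = 0.10, dog = 0.20,
                                              monkey = 0.30),
                          seed = 101)
data <- generate_curated_pk_data(spec)
data$human
#> <pk_dataset: human, 127 compounds, 5 endpoints, sparsity 6.6%>
#> # A tibble: 127 × 7
#>    std_smiles                mol_weight    VDss     CL  t_half      fu    MRT
#>  1 CC(=O)NCCCS(=O)(=O)[O-]         180.  0.792   1.81  -0.123   0.532   0.126
#>  2 CC(=O)Nc1ccc(C)cc1              149. -1.38    0.677  0.0662  0.129   0.249
#>  3 CC(=O)Nc1ccc(C)cn1              150.  0.946  NA      0.829   0.506   1.39
#>  # ... 124 more rows

cfg <- cv_config(n_repeats = 2, n_outer = 3, n_inner = 3,
                 grid = small_rf_grid(), seed = 202)

am <- train_animal_models(data$animal, cfg)
tidy(am)
#> # A tibble: 9 × 12
#>   endpoint species     n n_folds median_r2 median_gmfe median_pct2
#> 1 VDss     rat        81       6     0.338        2.62        50
#> 2 CL       rat        92       6     0.312        2.28        44.2
#> 3 fu       rat        95       6     0.376        2.15        66.7
#> 4 VDss     dog        77       6     0.373        2.27        47.1
#> 5 CL       dog        83       6     0.436        2.12        57.1
#> 6 fu       dog        77       6     0.286        2.48        56.8
#> 7 VDss     monkey     69       6     0.418        2.39        43.5
#> 8 CL       monkey     67       6     0.456        2.26        47.7
#> 9 fu       monkey     70       6     0.360        2.85        51.1

hm <- train_human_models(data$human, am, config = cfg,
                         combos = c(1, 7, 10),
                         endpoints = c("VDss", "fu"),
                         real_animal = data$animal)
tidy(hm)
#> # A tibble: 6 × 13
#>   endpoint combo_id label                              n median_r2 median_gmfe
#> 1 VDss            1 morgan                           127   0.301          2.69
#> 2 VDss            7 morgan+descriptors+animal_pred   127   0.398          2.53
#> 3 VDss           10 mean_baseline                    127  -0.00901        3.23
#> 4 fu              1 morgan                            89  -0.0170         3.36
#> 5 fu              7 morgan+descriptors+animal_pred    89   0.0463         3.32
#> 6 fu             10 mean_baseline                     89  -0.0540         3.64
```

The full feature set (combination 7) beats fingerprints alone
(combination 1), and the mean-predictor baseline sits at R² ≈ 0, as
it must out of fold. Prediction takes raw SMILES and returns natural
units with an estimated fold error and applicability-domain alert:

```r
predict_human(c("CCN(CC)CCNC(=O)c1ccc(N)cc1",
                "CC(C)Cc1ccc(cc1)C(C)C(=O)O"), hm)
#> # A tibble: 4 × 11
#>   std_smiles                     endpoint unit   prediction fold_error
#> 1 CC[NH+](CC)CCNC(=O)c1ccc(N)cc1 VDss     "L/kg"      0.517       3.09
#> 2 CC[NH+](CC)CCNC(=O)c1ccc(N)cc1 fu       ""          0.301       7.02
#> 3 CC(C)Cc1ccc(C(C)C(=O)[O-])cc1  VDss     "L/kg"      1.01        3.09
#> 4 CC(C)Cc1ccc(C(C)C(=O)[O-])cc1  fu       ""          0.357      10.9
#>   range_low range_high similarity_5nn ad_alert
#> 1    0.167        1.60          0.394 FALSE
#> 2    0.0430       1             0.385 FALSE
#> 3    0.328        3.13          0.501 FALSE
#> 4    0.0328       1             0.323 FALSE
```

`autoplot()` methods are available for cross-validation objects and
fold-error models; `plot_combo_comparison()` and
`plot_chemical_space()` cover the study-level figures.

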