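# pathopred

Structure-aware pathogenicity classification of missense variants in
hereditary-cancer gene panels.

Clinical gene panels for hereditary cancer syndromes return large numbers of
missense variants of uncertain significance (VUS): single-residue
substitutions with too little evidence to call pathogenic or benign. This
package implements a complete, offline-testable framework for building
panel-specific variant effect classifiers that combine evolutionary
conservation with structural context from AlphaFold2-style predicted models,
and for using such classifiers — together with external predictors — to
propose computational reclassifications of VUS. It is aimed at
computational biologists building or evaluating variant effect predictors.

## What it computes

For each missense variant (protein `P`, position `i`, wild-type residue
`wt`, variant residue `var`) the package derives a feature vector from
three sources:

* **Conservation** — a PSIC (position-specific independent counts) profile
  from a multiple sequence alignment: sequences are greedily clustered at
  62% identity, each cluster contributes one independent count per column,
  and the smoothed log-odds score is
  `score(i, a) = ln[(c(i, a) + w·q_a) / ((n_eff(i) + w)·q_a)]`
  with background `q` and pseudo-count weight `w = 1`. The model sees
  `score(i, wt)`, `score(i, var)` and
  `ΔPSIC = score(i, wt) − score(i, var)` — large positive ΔPSIC marks a
  disruptive substitution at a conserved site.
* **Structure** — per-residue pLDDT (read from the B-factor column of the
  predicted model, AF2 convention), solvent accessible surface area by the
  Shrake–Rupley method (probe 1.4 Å, deterministic Fibonacci point
  lattice), and relative accessibility
  `rASA = SASA / maxASA(residue type)` using the Tien et al. (2013)
  theoretical maxima.
* **Substitution chemistry** — BLOSUM62 score, Kyte–Doolittle hydropathy
  and Zamyatnin volume deltas, Chou–Fasman helix/sheet/turn propensities
  and background amino-acid frequencies for both residues; optionally
  gene-level features (protein length, GO term count) in the "full"
  schema, whose contribution is measured by an ablation against the
  "reduced" schema.

Random-forest and gradient-boosting classifiers are trained under nested
cross-validation (stratified 5-fold outer loop for performance estimation,
3-fold inner loop driving a TPE-style Bayesian search, 150 trials per
fold by default) and explained with exact interventional tree-Shapley
attributions. Evaluation reports AUROC (rank/Mann–Whitney form with tie
correction), F1, MCC, precision, recall and accuracy with 1000-resample
percentile bootstrap intervals (single-class resamples excluded and
counted), benchmarks external predictor score tables tool-by-tool, and
stratifies successes/failures by pLDDT, ΔPSIC and SASA. Finally, a
consensus rule averages the classifier's score with normalized external
predictor scores and reassigns a variant as likely pathogenic when the
mean exceeds 0.95, or likely benign below 0.05 (strict inequalities).

A fully synthetic fixture generator (sequences, helical toy structures
with pLDDT profiles, alignments with controlled conservation, labeled
variant tables with planted effects, binormal comparator scores) makes
every stage testable without network access or real data.

## Worked example

```r
library(pathopred)
library(dplyr)

cfg <- synthetic_config(seed = 1, n_proteins = 12, length_range = c(60, 90),
                        n_variants = 400, msa_depth = 30)
fix <- generate_fixture(cfg, tempfile("demo_"))

features <- fixture_features(fix, schema = "full", n_points = 240)
pool <- filter(features, label %in% c("PATHOGENIC", "BENIGN"))
split <- split_train_test(pool, test_fraction = 0.2, seed = 1)
#> <labeled_split> train: 320, test: 80 (test_fraction = 0.2, seed = 1)

model <- fit_final(split$train, "rf", list(num_trees = 300), seed = 1)
compute_metrics(split$test$label, predict_proba(model, split$test))
#> # A tibble: 1 × 7
#>   auroc    f1 precision recall   mcc accuracy     n
#>   <dbl> <dbl>     <dbl>  <dbl> <dbl>    <dbl> <int>
#> 1 0.994 0.975     0.975  0.975  0.95    0.975    80

sh <- shap_importance(model, split$train[1:50, ], split$test[1:40, ])
head(tidy(sh), 5)
#> # A tibble: 5 × 2
#>   feature    mean_abs_shap
#>   <chr>              <dbl>
#> 1 psic_wt          0.0208
#> 2 rasa             0.0152
#> 3 blosum62         0.0138
#> 4 delta_psic       0.0115
#> 5 psic_var         0.00755
```

The held-out AUROC of 0.994 reflects the strong class structure planted by
the generator (pathogenic variants at conserved, buried, high-pLDDT
positions); the Shapley ranking recovers exactly the planted signal
carriers — conservation (`psic_wt`, `delta_psic`), burial (`rasa`) and
substitution severity (`blosum62`).

`nested_cv()` gives the honest version of the same estimate (no
hyperparameter leakage), `benchmark_comparators()` scores external
predictor tables against the same truth labels, and
`consensus_reclassify()` applies the mean-score rule to VUS. `run_pipeline()`
chains all stages from one config; `inst/cli/pathopred.R` exposes the same
stages from a shell.

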