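---
title: "Methods: structure-aware missense pathogenicity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-aware missense pathogenicity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `pathopred`, in the spirit of a methods section: what
each stage computes, what it assumes, and where a design was genuinely
open, why the shipped choice was made.

## Problem setting

The package classifies missense variants in a panel of proteins as
pathogenic or benign, from protein-level annotations only: a harmonized
clinical label (ClinVar-style free text collapsed to
PATHOGENIC/BENIGN/VUS/CONFLICTING, with an explicit UNKNOWN sentinel for
out-of-vocabulary strings), a protein sequence, a predicted structure
with per-residue confidence, and a multiple sequence alignment. Variants
whose annotated wild-type residue disagrees with the sequence at the
annotated position are treated as mapping failures and dropped with a
count, mirroring the silent exclusions of typical curation pipelines but
keeping them auditable.

## Conservation: the PSIC profile

Published descriptions of position-specific independent counts leave the
weighting scheme under-specified, so the package fixes one concrete,
fully documented variant and exposes every constant:

* sequences are clustered greedily at `clustering_identity = 0.62`
  (identity = matching residues over columns where either row is
  ungapped, compared against cluster representatives in input order);
* at each column every cluster contributes **one** independent count,
  split equally over the residues its members show there (gap members
  contribute nothing; a cluster that is all-gap at a column contributes
  no count at all);
* counts are smoothed with a background pseudo-count of weight
  `pseudo_weight = 1` and converted to natural-log odds
  `ln(f/q)` against the background `q`.

The background defaults to the pooled residue frequencies of the
alignment (Laplace-smoothed), falling back to uniform when the alignment
has fewer than 100 residue cells — a pooled estimate from a tiny
alignment would be dominated by sampling noise. Columns with no usable
residues keep zero scores and are flagged rather than producing
infinities. Two consequences worth knowing: exact duplicate rows
collapse into a single count (the redundancy correction the method
exists for), and a single-sequence "alignment" yields a well-defined,
mildly informative profile.

`ΔPSIC` is defined as `score(wt) − score(var)`, so a disruptive
substitution at a conserved position is *positive*. The sign convention
is arbitrary in principle; this orientation makes the feature increase
with damage, which reads naturally in attribution plots.

## Structural features

Structures are parsed with bio3d from PDB or mmCIF, under the AlphaFold2
conventions: complete single-chain coverage (a chain break is an error
naming the missing indices, not a warning) and per-residue pLDDT stored
in the B-factor field, read from the C-alpha atom. B-factors outside
[0, 100] are rejected as "not a pLDDT channel" to catch experimental
structures passed in by mistake.

SASA uses Shrake–Rupley directly rather than wrapping an external DSSP
binary: each atom's sphere is expanded by the probe radius (default
1.4 Å, water) and covered with a deterministic Fibonacci lattice
(default `n_points = 960`, below 10 points is an error). Determinism was
the deciding factor: a golden-angle lattice makes SASA a pure function
of coordinates, so fixtures can assert exact values. A relative
tolerance of 1e-9 on the occlusion test makes exactly coincident spheres
fully occlude each other instead of depending on floating-point
round-off. Van der Waals radii are a small element-keyed table
(C 1.7, N 1.55, O 1.52, S 1.8, H 1.2, P 1.8 Å), editable alongside the
other scale tables in `inst/extdata/scales.json`.

rASA divides residue SASA by the Tien et al. (2013) *theoretical*
maximum for the residue type. With theoretical maxima, observed ratios
slightly above 1 are legitimate; they are deliberately **not clamped**
(clamping would distort the upper tail of the feature distribution the
model learns) but values above 1.2 trigger a diagnostic message, since
they usually indicate geometry problems. Both raw SASA and rASA are
exposed: the model consumes rASA, failure-mode stratification uses SASA.

## Substitution features and scales

The feature families (hydrophobicity, volume, secondary-structure
propensity, residue frequency) admit many published scales; the package
ships Kyte–Doolittle hydropathy, Zamyatnin volumes, Chou–Fasman
propensities and BLOSUM62 background frequencies as editable JSON, with
deltas computed as `var − wt` (hence antisymmetric). The per-residue
frequency feature uses the fixed BLOSUM62 background table rather than
an alignment-derived estimate, so it is defined even for proteins with
shallow alignments; the alignment-derived alternative is already
captured by the PSIC features. The full schema appends two gene-level
features (protein length, GO term count, consumed as a plain integer
column — no ontology traversal); the reduced schema omits them, and
`ablation_compare()` runs both under byte-identical folds to price their
contribution.

## Model training

Both engines are standard tree ensembles (ranger random forest with
probability trees; xgboost gradient boosting with logistic objective,
`base_score = 0.5`, single-threaded for reproducibility). Nested
cross-validation separates estimation from selection: a stratified
`outer_k = 5` loop estimates performance; within each outer-training
fold a stratified `inner_k = 3` loop drives the hyperparameter search
with mean inner AUROC as the objective; the winner is refit on the outer
training fold and scored once on the outer test fold. Index bookkeeping
of the inner loop is retained on the result object so tests can verify
that no outer-test row is ever touched during selection.

The search spaces (random forest: 100–1000 trees, depth 3–30 or
unlimited, minimum node size 1–10, feature-subset rule sqrt/log2 or a
fraction in 0.3–1; gradient boosting: 100–1000 rounds, learning rate
log-uniform 1e-3–0.3, depth 2–10, row and column subsampling 0.5–1) are
declared as data and overridable per call. The optimizer is a
tree-structured Parzen estimator written for this package: startup
trials from the prior, then candidates drawn from a Gaussian-kernel
density over the best `gamma = 0.25` fraction of observed
configurations, scored by the good/bad log-density ratio. Any seeded
sequential model-based optimizer would satisfy the same contract; TPE
was chosen because it handles mixed integer/continuous/categorical
spaces without a surrogate-model dependency. The whole loop is a pure
function of the seed.

The decision threshold for binary calls is fixed at 0.5 — no calibration
is attempted, and the threshold is carried in the model bundle so a
deployment could change it explicitly.

## Attribution

`shap_importance()` computes *interventional* tree-Shapley values
exactly, against an explicit empirical background set. For each tree
leaf, the unique features on its root path are classified per
(foreground, background) pair as must-in, must-out, free or dead, and
the closed-form Shapley weight `k!·m!/(k+m+1)!` is accumulated — exact
in time linear in the number of leaves, no path-dependent
approximation. Attributions are on the probability scale for random
forests and the margin (log-odds) scale for gradient boosting, matching
each engine's natural additive output; local accuracy
(`base + Σφ = f(x)`) holds to floating-point precision. One numerical
subtlety: xgboost stores feature values and thresholds in float32, so
both sides of every split comparison are rounded to float32 before
comparing — without this, points that sit exactly on a learned threshold
are routed differently than the engine routes them. The unit tests pin
the implementation to a brute-force subset-enumeration oracle on small
models.

## Evaluation and benchmarking

AUROC uses the rank (Mann–Whitney) formulation with midrank tie
correction, so constant scores give exactly 0.5. Confusion-matrix
metrics define 0/0 as 0 (e.g. MCC with an empty margin), which keeps
degenerate calls finite and conservative. Bootstrap intervals are
percentile 2.5/97.5 over resamples drawn at the original size;
resamples missing a class are excluded and counted (`n_excluded`)
rather than silently contributing undefined metrics. The drawn index
matrix is attached to the result so the bookkeeping itself is testable.

Comparator tables arrive as long (variant, tool, score, call) data with
a per-tool manifest declaring orientation (`higher_is_damaging`) and
whether the tool produces binary calls; orientation handling is
explicit because upstream annotation frameworks invert scores like SIFT
invisibly. Missing scores are dropped per tool, never listwise, so each
tool is evaluated on its own coverage. Score-only tools get AUROC only.

Failure stratification counts, per variant, how many call-producing
comparators were correct, bins the counts in pairs (`[1-2]` … `[11-12]`
for twelve tools; a count of zero folds into the lowest band) and joins
the structural features for plotting.

## Consensus reclassification

Tool scores are first normalized to [0, 1]: bounded scores can pass
through min–max; unbounded scores (e.g. CADD-like) use midrank
percentiles, `rank/n` with ties as midranks — monotone, cohort-stable
and insensitive to outliers. The consensus mean over the configured
ensemble reassigns a variant only on *strict* threshold crossings
(mean > 0.95 or < 0.05); a mean exactly at a threshold stays
unchanged. By default every configured tool must have a score
(`min_tools = ensemble size`); mean-of-available is an explicit opt-in,
because averaging over fewer tools silently changes the evidence
standard. Reassignment is monotone in the thresholds, and summaries
cross-tabulate decisions by gene, prior label and review status with
conserved totals.

## The synthetic fixture generator

The generator emulates the statistical structure the classifier is
meant to exploit, not real biology: toy proteins whose ordered core is
an ideal alpha-helix (2.3 Å radius, 1.5 Å rise, side-chain sphere tucked
toward the axis, hence buried) and whose terminal ~15% segments are a
sparse extended arc far from the axis (hence exposed), with pLDDT high
in the core and low in the termini (`plddt_gap = 40` points around a
base of 70). The helical geometry was chosen over random coils because
burial is then deterministic and analytically checkable. Alignments
emit the query residue with a per-position conservation probability
(conserved positions 0.85–0.99, variable 0.10–0.40) and otherwise a
non-query substitution from the BLOSUM62 conditional distribution, so
homologs carry realistic conservative substitutions and `conservation`
is exactly the query-emission probability.

Pathogenic variants are planted preferentially at conserved, buried
positions with dissimilar substitutions, benign variants at the
opposite, with selection odds set by `conservation_gap = 0.9` and
`burial_gap = 0.8` (each gap is the difference between the two classes'
probabilities of landing on a marked position). Labels flip with
`label_noise = 0.02`, emulating curation error; an extra
`vus_fraction = 0.2` of variants is emitted as VUS/conflicting with the
latent label recorded only in the manifest. These defaults were
calibrated once so that a deliberately weak oracle — a depth-3 decision
tree on `delta_psic` and `rasa` alone — already separates the classes
with AUROC ≥ 0.9 at the default 2000 variants; the full models must
clear the same bar under nested CV without access to the manifest. The
default panel (60 proteins of 100–160 residues) keeps planted positions
plentiful relative to the number of variants drawn, so the selection
weights, not pool exhaustion, determine the planted structure.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: real fold geometry and contact
burial, alignment depth/phylogenetic correlation (rows are i.i.d. given
the conservation profile), gene-specific label composition, annotation
biases between panels, or correlated errors between external
predictors (comparator scores are conditionally independent binormal
draws squashed by the logistic map). Results on the fixture demonstrate
correctness of the machinery and recoverability of planted signal,
nothing more.

## Reproducibility and problem sizes

Every stochastic step takes an explicit integer seed and is a pure
function of it; derived seeds stay below 2^31. The test-suite and
acceptance-script problem sizes are the package's own choices, balancing
statistical resolution against desk-scale runtimes: SASA checks at 960
lattice points; feature extraction in bulk at 240 points (sampling error
well under the planted effects); nested CV on the 2000-variant default
fixture with 6 TPE trials per outer fold (the planted signal is strong
enough that the search saturates quickly; the 150-trial default remains
for real use); bootstrap coverage with 100 replicate cohorts of n = 600
at 1000 resamples. The pipeline writes every artifact under one run
directory with md5 checksums in a manifest; deterministic stages
reproduce identical checksums across runs.

## Known limitations

* PSIC clustering is greedy in input order; a different row order can,
  in edge cases, produce a different clustering (standard for this
  family of weighting schemes, and deterministic for a fixed input).
* Interventional SHAP scales with background × explain × leaves; it is
  meant for hundreds of rows against a modest background, not whole
  cohorts.
* The consensus rule is purely computational evidence; it assigns no
  ACMG/AMP evidence codes and must not be read as clinical
  classification.
* mmCIF parsing follows bio3d's reader; exotic multi-model or multimer
  files are out of scope, as is any secondary-structure assignment from
  geometry.
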