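---
title: "Predicting the metabolizing CYP isoform: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the metabolizing CYP isoform: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Five cytochrome P450 isoforms — CYP3A4, CYP2D6, CYP1A2, CYP2C9 and
CYP2C19 — carry out the phase-I oxidative metabolism of more than 90% of
therapeutic drugs. Knowing which isoform(s) metabolize a candidate
molecule matters early in drug development: it anticipates drug–drug
interactions, pharmacogenetic variability and clearance routes. `cypred`
implements a QSAR (quantitative structure–activity relationship)
pipeline for this five-class substrate-specificity problem: molecular
descriptors are computed from the 2D structure, pruned, and fed to
one-vs-rest support vector machines whose decision scores drive either a
single-label call (the best isoform) or a multi-label call (every
isoform whose score clears a calibrated threshold).

# The model

## One-vs-rest decomposition

Substrate specificity is a multi-class problem; an SVM is a binary
classifier. The pipeline therefore fits five binary models. For the
CYP3A4 model, CYP3A4 substrates are the positive examples and the
substrates of the other four isoforms are the negatives, and so on. All
five models share one descriptor subset, one imputation table (training
column means) and one z-scaler, all fitted on training data only.

Two decision rules sit on top of the five decision scores
("SVM scores") for a molecule:

* **Single-label**: the isoform with the highest score. Exact ties go to
  the earlier isoform in the canonical order (3A4, 2D6, 1A2, 2C9, 2C19).
* **Multi-label**: every isoform whose score is *strictly greater* than
  that model's calibrated default threshold. The set may be empty, which
  the prediction table flags explicitly.

## Threshold calibration

The default threshold of each binary model is the score cutoff at which
the model performs best by Matthews correlation coefficient (MCC), with
the difference between sensitivity and specificity as small as possible.
Because both goals cannot generally be optimized simultaneously, the
criterion is lexicographic: maximum MCC first, then minimum
|sensitivity − specificity|, then the smaller threshold. Candidate
thresholds are the midpoints between consecutive distinct sorted scores
plus two finite sentinels (one below the minimum — accept everything —
and the maximum itself — accept nothing under the strict rule); a finite
threshold is an invariant of the fitted model object. Calibration runs
on *out-of-fold* scores from an internal five-fold split of the training
set: resubstitution scores of a margin-maximizing classifier are
degenerate near the margin, which would push thresholds toward 0
regardless of the operating characteristics.

## Figures of merit

For one binary model with confusion counts TP, TN, FP, FN:

$$\mathrm{Sens} = \frac{TP}{TP+FN}\times 100,\quad
\mathrm{Spec} = \frac{TN}{TN+FP}\times 100,\quad
\mathrm{Acc} = \frac{TP+TN}{TP+TN+FP+FN}\times 100,$$

$$\mathrm{MCC} = \frac{TP\cdot TN - FP\cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.$$

MCC = 1 is a perfect prediction and 0 a random one; when any factor of
the denominator is zero the MCC is reported as 0, the random-prediction
convention. Reported percentages are rounded half-up to two decimals,
matching the conventions of the tables this pipeline reproduces.
Single-label performance is summarized by the *average accuracy*
(unweighted mean of the five per-isoform accuracies, each the percentage
of that isoform's substrates recovered) and the *overall accuracy*
(percentage of all molecules labeled correctly); the overall accuracy
equals the class-size-weighted mean of the per-isoform accuracies.

# Descriptors

The descriptor registry (`descriptor_sets()`) defines one set, `cmb2d`,
computed on an OpenBabel/ChemmineR backend: bulk physicochemical
properties (molecular weight, logP, topological polar surface area,
molar refractivity, hydrogen-bond donor/acceptor counts), fixed
per-element heavy-atom counts, ring and aromatic-ring counts, twelve
functional-group counts, and topological indices of the heavy-atom graph
(Wiener, Zagreb M1/M2, Randić connectivity, Balaban J, Kier kappa shape
indices, eccentric connectivity, rotatable-bond and branching counts).
The set is 1D/2D only — no conformer generation and no quantum-chemical
terms — and its column set is fixed by the registry, so matrices
computed from different inputs align. A descriptor that is undefined for
a molecule (e.g. distance-based indices of a disconnected salt, kappa
indices of a single-atom molecule) yields the missing marker `NA`, never
0: the downstream sparsity filter counts zeros, so conflating the two
would corrupt it.

# The filter cascade

Descriptor pruning applies four rules in a fixed order, each recorded in
a per-stage report:

1. **Missingness** — drop columns with *more than* 5% missing values
   (strict; exactly 5% is kept). Surviving missings are imputed later,
   at model time, with training means.
2. **Sparsity** — drop columns with *less than* 10% non-zero values
   among observed entries (strict; missing entries are excluded from the
   denominator).
3. **Pairwise correlation** — scan columns in order and drop the later
   column of any pair with |Pearson r| ≥ 0.90 (inclusive, on
   pairwise-complete observations). Zero-variance columns carry no
   defined correlation and are dropped with an explicit "zero variance"
   reason. Keep-earlier is the tie-break: deterministic and stable under
   column reordering of the survivors.
4. **Multicollinearity** — iteratively regress each surviving column on
   the others (complete-case rows, least squares with a ridge fallback
   for singular systems) and drop the column with the largest R² while
   that maximum exceeds 0.95 (strict). Ties at the maximum — exact
   linear dependences — drop the latest column, mirroring rule 3.

The interpretation of "multicollinearity > 0.95" as the R² of each
descriptor on the rest (equivalently VIF > 20) was a design choice; the
pairwise filter is run on |r| rather than signed r (configurable
threshold, absolute value fixed). The cascade is idempotent:
re-running it on its own output drops nothing.

# Wrapper feature selection

Two wrapper searches reduce the cascade's survivors to a compact model
subset:

* **Genetic algorithm** (`ga_select`): chromosomes are binary column
  masks constrained by repair to exactly `target_k` ones; tournament
  selection (size 2), uniform crossover (probability 0.8), per-bit swap
  mutation (0.02), elitism of the best chromosome, fitness caching, and
  one chromosome of the initial population seeded from the univariate
  F-statistic ranking. Population 50 and 100 generations by default —
  conventional GA settings, configurable.
* **Greedy stepwise** (`greedy_stepwise_select`): forward selection
  adding the fitness-maximizing column each step (ties to the earlier
  column), stopping at `target_k` or when no addition improves the
  current fitness.

The default fitness is the mean five-fold cross-validated MCC of the
one-vs-rest suite, averaged over isoforms, with per-fold train-mean
imputation and z-scaling; any `function(matrix, labels)` can be plugged
in. Wrapper fitnesses are estimates: when two informative columns of the
same class overlap in what they explain, subsets exchanging one of them
for a noise column can sit on a fitness plateau, so recovery of a
planted optimum is expected to be high but not guaranteed column-for-
column.

Because selection looks at the labels, descriptor subsets chosen on the
full data bias any subsequent cross-validation estimate upward (on pure
noise we observe inflations of 25+ accuracy points). `cross_validate()`
therefore accepts a `select_fun` argument that re-runs selection inside
every training fold, nesting it in the CV; unbiased accuracy claims in
the test suite use this form.

# Cross-validation

`cross_validate()` implements stratified five-fold CV (per-fold class
counts within one of proportional — with 19-member classes,
unstratified folds can lose a class entirely; an unstratified mode
remains available) and LOOCV (k = N). Out-of-fold single-label
predictions are pooled (micro aggregation) into per-isoform one-vs-rest
confusion counts and into the accuracy summaries. Fold assignment,
internal grid search and GA are all driven by explicit seeds; identical
seeds give bit-identical results.

# SVM training

Classifiers are soft-margin SVMs (libsvm via e1071). Per isoform, the
kernel and hyperparameters are chosen from a grid — C ∈ {0.1, 1, 10,
100}; RBF γ ∈ {0.001, 0.01, 0.1, 1}; polynomial degree ∈ {2, 3} — by
mean internal-CV MCC at the natural zero threshold, ties to the first
grid entry. Descriptors are z-scaled before training (kernel machines
are scale-sensitive; the scaler is fitted on training data only, so no
information leaks from evaluation folds). Decision-score orientation is
verified empirically after each fit — the mean score of positives must
exceed that of negatives, else the sign is flipped and stored — so "SVM
score" semantics never depend on libsvm's internal class ordering.
Saved model bundles are single JSON files (format-versioned; scaler,
imputation means, thresholds in the clear; classifiers as base64-encoded
serializations) whose integrity is checked on load. Thresholds from
training are reused as-is when a bundle is applied to new data; no
recalibration happens at prediction time.

# The synthetic-data generator

Real training data for this problem (curated single-isoform DrugBank
substrates) cannot be shipped, so `generate_table()` emulates its
structure: by default 226 molecules in classes of 111/47/29/20/19
(CYP3A4 … CYP2C19), two informative descriptors per class, 50 noise
descriptors, and planted pathological columns — five redundant affine
copies of informative columns (for the correlation rule), three ~5%
non-zero columns (sparsity rule) and three ~10%-missing columns
(missingness rule) — plus 1% uniform missingness elsewhere. Informative
columns are class-conditional Gaussians with unit within-class SD; the
`class_separation` parameter (default 6) is the distance between a
class's mean and the background in that class's informative *subspace*,
so the per-column shift is `class_separation / sqrt(m)` for `m`
informative columns per class. Splitting the shift this way also keeps
same-class informative columns below the |r| ≥ 0.9 filter (two columns
carrying the identical full-strength contrast would be mutually
correlated right at the threshold for the largest class, making cascade
behavior seed-dependent). An optional `multilabel_frac` gives molecules
a second label and moves them toward that class's mean in its
informative columns, emulating the multi-isoform substrates of an
independent evaluation set.

What the generator does *not* emulate: real descriptor marginals (heavy
tails, integer counts, block correlations), chemically induced
label noise, and any relationship between columns and actual chemistry.
Passing tests on synthetic data therefore demonstrates that the
machinery — filters, selection, training, calibration, evaluation —
behaves as specified on data with known ground truth, not that any
particular accuracy will be reached on real substrate data.

A matched-difficulty setting of `class_separation = 2` is used for the
class-imbalance studies: it lands CV accuracies in the 70–85% band
reported for models of this kind — imperfect but far from random — so
that class-size effects are visible. At that setting the mean
one-vs-rest MCC over replicates is ordered exactly by class size. The
two smallest classes (20 and 19 members) are statistically
indistinguishable from each other, however: their systematic MCC gap
(~0.004) is two orders of magnitude below the replicate SD (~0.17), so
which of the two is strictly worst in any single replicate is close to a
coin flip. Claims about "the smallest class" are therefore made at the
level of the two smallest classes, or of means over replicates.

# Numerical and degenerate-input choices

* MCC with a zero denominator factor → 0 (random-prediction convention).
* Percent rounding: half-up to 2 decimals at reporting boundaries;
  internal computations keep full precision.
* Threshold calibration with all scores identical returns that score.
* Zero-variance descriptors: dropped in the correlation stage with an
  explicit reason; if they reach the scaler, the scale factor falls back
  to 1 to avoid division by zero.
* Isoforms with fewer than two positive examples are skipped with a
  warning; wholly absent isoforms are logged.
* An argmax over uncalibrated one-vs-rest SVM scores is not
  prior-calibrated: on data with no class signal it spreads predictions
  across classes and scores *below* the majority-class rate (observed
  ~33% vs 49% majority on the default class sizes). Interpreting
  near-majority accuracy as "no information" would be wrong for this
  classifier family; the reliable no-signal diagnostics are the MCCs
  (≈ 0) and the monotone decline of accuracy with separation.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline at the
generator's default conditions (226 molecules, 71 descriptors before
filtering, GA with population 30 for 25 generations under the five-fold
MCC fitness) and the imbalance study on ten replicates of the
matched-difficulty setting; oracle equivalences sweep all ~194,000
confusion matrices with entries up to 20, 200 random threshold-
calibration instances, and exhaustive subset searches on 10–12 column
instances. These sizes were chosen to exercise every code path at the
study's stated conditions while keeping a complete run in the
low minutes on one CPU.

# Known limitations

* The descriptor set (~55 columns) is an open 1D/2D registry, not a
  reimplementation of any commercial or CDK descriptor list; descriptor-
  level parity with models built on those engines is out of scope.
* No structure standardization beyond parsing and canonicalization: salts,
  tautomers and charge states are taken as given.
* No probability calibration of scores; thresholds are MCC-optimal
  cutoffs, not posterior probabilities.
* Training requires single-label molecules; multi-label data are
  supported at evaluation and prediction time only.
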