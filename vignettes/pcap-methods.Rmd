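---
title: "Recovering missing sample metadata at a guaranteed precision: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering missing sample metadata at a guaranteed precision: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Public gene-expression repositories hold enormous numbers of profiled
samples whose clinical annotations — ancestry, receptor status, treatment
response, tissue site — are missing for a large fraction of samples.  A
dataset without the annotation a study needs is usually discarded.  Because
many such variables leave a strong multivariate footprint in the
transcriptome, they can often be predicted from the expression values
themselves, and the data rescued.

The catch is that a prediction used in place of a measurement must be
*right*; a downstream analysis does not benefit from doubling its sample
size with labels that are 80% accurate.  `pcapmeta` therefore treats the
problem as *selective* prediction: predict a label only for the subset of
samples where a chosen precision (say 90%) can be met, and abstain on the
rest.  The fraction of samples that survives this filter is the quantity
the package estimates and maximizes: **PCAP_x**, the Proportion of Cases
Accurately Predicted at x% precision.

## The calibration algorithm

All classifiers here emit a probability of the positive class (the
*minority* category of the variable, coded +1).  For a cutoff we use a
*percentile* of the predicted-probability distribution rather than an
absolute probability, which makes the cutoff transferable between datasets
whose probability scales differ.  The grid of candidate cutoffs is the
integer percentiles 50–99.

`estimate_pcap()` runs a nested, stratified cross-validation:

1. **Outer loop** (default 10 folds): hold out one fold as a test set.
2. **Inner loop** (default 10 folds) on the outer-training set: refit the
   entire pipeline (normalization, gene screen, RFE, optional SMOTE,
   hyperparameter tuning) on each inner-training split and score the inner
   validation fold.  For every percentile p in 50–99, compute precision
   and recall of the rule "predict +1 when the probability is at or above
   the p-th percentile of the validation fold's own probabilities".
3. **Cutoff selection**: a percentile is marked 1 in a fold when its
   precision there reaches the target x%.  The smallest percentile with
   the most marks across the k inner folds is selected (`P_i`), and the
   mean recall at `P_i` — over folds that contain at least one true
   positive — is recorded (`R_i`).
4. **Outer evaluation**: refit the pipeline on the whole outer-training
   set, apply `P_i` as a percentile of the outer-test probabilities, and
   record the precision actually achieved on unseen samples.

The PCAP_x estimate is the mean of the `R_i`; the deployment cutoff is the
mean of the `P_i` rounded to the nearest integer percentile.  Because
recall at a fixed percentile is non-increasing in the percentile, raising
the precision target can only move the selected cutoff up and the recall
down, which is why PCAP_95 ≤ PCAP_90 on shared folds — a property the test
suite checks over many seeds.

When no percentile reaches the target in any inner fold, the fold is
flagged *unattainable*, reported with cutoff 99, and contributes recall 0
to the PCAP mean: PCAP is a fraction of usable data, and an outer fold in
which the target cannot be met contributes none.  Note that the converse
flag is conservative in the other direction: a single lucky fold — for
instance the top validation sample happening to be a true positive —
counts as attainable, so on pure-noise data the flag fires in only a
fraction of folds even though the PCAP estimate itself collapses towards
zero.  The estimate, not the flag, is the quantity to trust.

### Model selection

A *model* is a full pipeline configuration (`model_spec()`): learning
algorithm × normalization × oversampling switch × gene-count mode.
`select_model()` estimates each candidate on identical folds and picks the
winner by the *median* of the per-fold criterion values — the median, not
the maximum, so that one lucky fold cannot promote an unstable candidate.
The criterion is per-fold PCAP_x by default; mean inner-validation F1 (at
a 0.5 threshold) and AUROC are available on the same folds for
comparison, so the cost of trying all three criteria is one nested CV per
candidate.

## Pipeline stages and their parameters

Stage order inside every training split: normalize → Welch screen → RFE →
SMOTE → tune/fit.  Each stage is fitted on training samples only; the
inner and outer validation folds are never oversampled and never
contribute to screening, feature selection or the quantile reference.

* **Normalization.**  Rank normalization replaces each sample's values by
  average-tied ranks rescaled by n(n+1)/2 × 10⁶, so every sample sums to
  one million and only the within-sample ordering survives; RPM rescales
  counts to a per-million sum; quantile normalization equalizes the
  per-sample distributions, and on validation/test samples uses the frozen
  training reference.  Rank and RPM are strictly per-sample, so applying
  them globally or per-split is equivalent.  The tie rule "average of the
  occupied rank positions" is the one reading under which ranks sum to
  n(n+1)/2, which the rescaling assumes; for quantile normalization, ties
  receive the mean of the reference values across the tied span.
* **Welch screen** (`alpha`, default 0.1): per-gene two-sample Welch
  t-test between the classes; genes with two-sided p below alpha become
  candidates.  Zero-variance genes are removed first (the statistic is
  undefined).  If nothing passes — possible on tiny degenerate splits —
  the 10 smallest p-values are used so the pipeline still yields a model,
  with a warning.
* **RFE** (`gene_mode`, `rfe_step` default 0.1): iteratively drop the
  least-important 10% of genes, importance being absolute coefficients
  for the lasso, impurity/gain for the tree ensembles, and squared-margin
  weights for the linear SVM.  `auto` mode records a 3-fold CV AUROC at
  every size up to 100 genes and returns the best-scoring set (ties favour
  the smaller set, and elimination floors at 2 genes because one-feature
  models cannot be fitted by every backend); `fixed-10`/`fixed-25` simply
  eliminate down to k genes.  CV scoring is skipped in fixed mode — the
  cross-validation only ever chooses the set *size*, which fixed mode
  pins.
* **SMOTE** (`smote_k`, default 5 neighbours): equalizes class counts by
  interpolating between minority samples and their nearest minority
  neighbours, in the selected-gene space (running it before selection
  would synthesize thousands of coordinates only to discard them).
* **Tuning** (`tuning_budget` = 10 draws, `tuning_folds` = 3): random
  search scored by mean CV AUROC, the package's headline ranking metric.
  The documented default spaces (`default_search_space()`): lasso lambda
  log-uniform 10⁻⁴–1 (above ~1 the L1 penalty yields the null model on
  data of this scale, so larger values only waste draws); random forest
  100–1000 trees, depth 2–10, mtry fraction 0.05–0.8; gradient boosting
  100–1000 rounds, depth 2–10, learning rate 0.01–0.3, subsample 0.5–1;
  SVM cost log-uniform 10⁻³–10³, linear or RBF kernel, gamma log-uniform
  10⁻³–10.  SVM probabilities come from the Platt sigmoid e1071 fits on
  training folds, which keeps them away from 0/1 even on separated data.

All randomness descends from one root seed, expanded deterministically per
stage, fold and draw; the same seed reproduces every fold assignment,
hyperparameter draw, SMOTE interpolation and therefore every number.

## Downstream reliability: DEG overlap experiments

Predicting a label is a means to an end; the package also measures whether
an analysis run *with* predicted labels reproduces the analysis run with
true ones.  Differential expression (per-gene Welch t-tests on
log2-transformed values, pseudocount 1) serves as the canonical example.

`fiveway_overlap_experiment()` rotates ten stratified folds through the
roles training set / evaluation set / "newly collected" set and compares
five DEG lists against a reference list from a fold-sized subsample of the
training data: evaluation-set truth, confident-subset predictions at two
precision targets, the new collection's truth, and permuted labels.  With
perfect probabilities the prediction arms must equal the truth arm
exactly; permutation must destroy the overlap — both are asserted in the
test suite.  Predicted groups use the two-sided rule: class −1 when the
probability lies in [0, c), class +1 in [1−c, 1], abstain between.  The
low interval is half-open — a probability exactly at c is *not* confident.
With a single model specification the two precision-target arms share one
fitted model (they differ only when a candidate grid is supplied for
per-arm selection); the two-sided cutoff c (default 0.25) is a separate,
explicit knob rather than being derived from the percentile cutoff, whose
one-sided design does not define a confident negative set.

`cutoff_sweep()` varies c from 0.05 to 0.5 over per-fold confident
subsets, reporting the percent overlap with the all-sample truth list,
the best c and its median overlap.  Small c buys accuracy at the price of
sample size; the sweep makes that trade-off measurable per variable.
Significance defaults to unadjusted p < 0.05 (mirroring plain
overlap-count designs; Benjamini–Hochberg is available via `adjust`), and
the overlap denominator is always the reference list.

## The synthetic-data generator

`synth_generate()` emulates the structure the pipeline faces on
repository data: log-normal expression (per-gene log2 baselines uniform
on 3–10), a binary sample attribute with class imbalance, a block of
informative genes whose log2 mean shifts in the minority class, per-sample
library-scale factors (uniform 0.5–2, so raw values are not comparable
across samples and normalization is load-bearing), and
missing-completely-at-random gaps in the metadata table.  The defaults —
600 samples, 2000 genes, 50 informative genes at a log2 fold change of
1.0, 25% minority, within-class noise SD 1.0, 20% missing — are the
standard study conditions used by the acceptance checks: a clearly
learnable but not trivial signal of the kind a well-predictable clinical
variable leaves in bulk expression data.

What the generator does *not* emulate: batch effects, platform transfer,
negative-binomial count noise, correlated gene modules, label noise, and
missingness that depends on the label.  Tests passing on this generator
show the machinery is correct and calibrated under its assumptions; they
do not certify performance on any particular real dataset, where the
bottleneck is usually how strongly the variable is encoded in expression
at all.

## Numerical choices and edge cases

* Percentiles use the linear-interpolation definition (R's `quantile`
  type 7) everywhere — calibration, deployment, and the test oracles.
* The selected percentile is applied to the evaluation set's *own*
  probability distribution (the literal percentile-as-cutoff reading);
  `predict_confident(threshold = "absolute")` instead freezes the
  probability value observed at that percentile during calibration, which
  is safer when the deployment cohort's class prevalence may differ.
  On near-degenerate probability distributions (e.g. a classifier that
  collapses to constant output) an interpolated threshold can fall at or
  below the probability mass and the rule then predicts everything — one
  reason tuning draws that yield null models are worth avoiding (see the
  lasso lambda bound above).
* Class-size ties in label encoding break lexicographically (the
  alphabetically smaller class becomes +1); cutoff-count ties take the
  smallest percentile; model-selection ties keep the earliest candidate;
  CV-score ties in auto RFE favour the smaller gene set.
* Folds are stratified everywhere; an estimate refuses to run when the
  smaller class cannot populate every fold.
* Inner folds with no positive validation samples are dropped from recall
  means; precision with an empty predicted set is reported as missing, and
  recall with no positives as 0.

## Problem sizes used by the checks

The unit tests run on matrices of tens of samples and a few hundred genes
so the whole suite stays fast; the acceptance checks use the generator
defaults above (five replicate datasets, a two-candidate model grid,
10×10 nested CV), 20-seed dominance and null-calibration simulations at
reduced size, and oracle-probability DEG experiments with 200 samples ×
300 genes.  These sizes are the package's own reproducibility
conditions; all of them are configurable at the function level.

## Known limitations

* Binary variables only; multi-class variables are reduced to their two
  most frequent values at encoding time.
* PCAP is defined here for precision; the cutoff-selection machinery is
  metric-agnostic in principle but v1 exposes precision only.
* The percentile-on-own-distribution rule assumes the deployment cohort's
  positive fraction resembles the calibration cohort's; a strong shift in
  prevalence shifts what a percentile means.
* DEG reliability experiments use t-tests on log2 values; count-model DE
  (negative binomial) is out of scope.
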