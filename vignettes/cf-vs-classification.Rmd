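---
title: "Collaborative filtering versus imputation-and-classification: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collaborative filtering versus imputation-and-classification: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfbench)
```

## The question the package answers

Recommender systems predict a user's missing item ratings from the
ratings of similar users. Recast clinically — patients as users,
discretized clinical features as items, the outcome as one more item —
user-based collaborative filtering (CF) becomes an outcome predictor that
handles missing data natively, with no imputation step. `cfbench`
provides a controlled harness for asking when, if ever, that recasting is
competitive with the traditional route of imputing the missing predictor
cells and fitting a classifier.

## The CF predictor

Ratings live in a patients × items integer matrix. Similarity between two
patients is the cosine of their rating vectors restricted to co-observed
items (the outcome item never enters the similarity, so training and test
pairs are scored identically). For a target patient the k most similar
training patients with *defined* similarity form the neighbourhood, and
an item is estimated as the similarity-weighted mean of its observed
values across the neighbourhood, with the weights renormalized over the
neighbours that actually observe the item.

Assumptions worth keeping in mind: similarity on level codes treats the
ordinal scale as interval; all items share one rating scale (hence the
discretization step below); and no row-centring is applied, so habitual
"high raters" are not adjusted for — appropriate for clinical
measurements, which are not preference ratings.

Because the weighted mean is continuous while items are discrete, a
decision rule is needed at the end. The package uses:

* predictor items — round half-up to the nearest admissible level;
* binary outcome — weighted mean of the 0/1 class codes thresholded at
  0.5, with an exact tie going to the training majority class;
* multiclass outcome — similarity-weighted vote, ties to the smallest
  class code.

Degenerate cases degrade gracefully rather than erroring, in a fixed
order: zero total weight with contributors present falls back to the
unweighted contributor mean; an item observed by no neighbour falls back
to the global training item mean (outcome: training majority class); a
patient with no defined similarity at all therefore still receives the
majority-class prediction. This matters at high missingness, where
empty co-observation sets become common; the harness consequently has no
hard ceiling on injectable missingness.

Ties in neighbourhood ranking are broken toward the lower row id, making
every prediction deterministic given the matrix.

## Discretization

CF needs a uniform ordinal scale, so continuous predictors are binned by
quantiles (linear interpolation between order statistics; right-closed
bins; ties to the lower level). The level count is the maximal level-set
size among categorical/ordinal predictors; an all-continuous table (the
synthetic case) uses the configured default of 4 levels. Cutpoints are
fitted on the training fold only and applied to the test fold — the
pipeline diagram of folds-then-discretization admits either reading, and
the per-fold choice avoids information leaking from test rows into the
binning; `fit_discretization(..., rows = )` exposes the whole-data
variant for sensitivity checks. To keep the comparison level, the
classifiers also operate on the discretized codes, even though they could
use the raw values.

## Missingness machinery

Two mechanisms are injected on top of fully observed predictors, never on
the response:

* **MCAR** removes exactly `round(rate · n · p)` cells uniformly over all
  predictor cells. Exact-count sampling without replacement (rather than
  per-cell Bernoulli) makes the printed rates exact and makes nesting
  constructible.
* **MAR** masks the target column (default the first predictor) in
  exactly the `ceiling(rate · n)` rows whose driver column (default the
  second predictor) is largest, i.e. a threshold at the empirical
  `1 − rate` quantile. The rule is deterministic given the table.

Severity levels are *cumulative*: each pattern's lower-severity mask is a
subset of its higher-severity masks, so increasing missingness degrades
the same cells further instead of resampling them. A `mcar_matched`
mechanism draws an MCAR mask with exactly the MAR mask's cell count,
spread over all predictors, for volume-fair MCAR/MAR comparisons.

One semantic choice deserves flagging: a MAR "rate" here is the fraction
of the *target column* missing, while an MCAR rate is matrix-wide. With
only one maskable column of five, a matrix-wide MAR reading could never
exceed 20%; the per-column reading keeps the full severity range
reachable, and the matched mechanism reconciles the two by cell count.

## Imputation strategies

All four imputers are fitted on the training fold only and applied to
test rows; observed cells are never altered.

* **Mean**: training-column mean of observed values, also used for test
  cells. Level-coded columns keep the unrounded mean by default (the
  classifiers accept numeric inputs); a rounding toggle exists.
* **kNN**: a missing cell takes the mean of its column over the k nearest
  rows (Euclidean distance on co-observed predictors after unit-variance
  scaling fitted on training); test rows draw neighbours from training
  rows only. k is selected by 3-fold cross-validation on the training
  fold over the grid {1, 3, 5, 10}, minimizing the downstream
  misclassification; logistic regression serves as the selection
  classifier because it is fast and deterministic, and the selection
  criterion — not the selection model — is what the contract fixes.
* **Forest proximity** (training rows only): column-median start, then
  iterative refinement by proximity-weighted means from a supervised
  forest, 5 iterations of 100 trees by default — deliberately smaller
  than the evaluation forests, since the imputation forest only supplies
  proximities. Test rows receive mean imputation instead, keeping the
  test-time procedure cheap and training-only.
* **Chained equations**: per-column conditional models (linear for
  numeric-coded columns, multinomial for categorical), Gibbs-style sweeps
  with a 10-sweep burn-in, m = 5 completed training sets from
  independently seeded chains. Imputed level-coded values are clamped to
  the observed level range. Test rows are completed by the final
  conditional models of each chain — initialized at training means, two
  passes to resolve cross-column dependence — without refitting. The
  burn-in length and the test-completion rule are package choices; the
  per-column conditional structure is the method's definition.

Predictions from the m completed datasets are pooled by averaging the
class-probability matrices before the argmax, which reduces to the
single-model path exactly when m = 1.

## Classifiers

Classification is delegated to standard fitters behind a thin contract:
probability vectors that sum to one, deterministic behaviour under a
seed, and (for forests) out-of-bag vote fractions per training row.
Logistic regression uses `glm` (binomial) or `nnet::multinom` for more
than two classes; random forests use `randomForest` with mtry = √p.
The forest default here is `ntree = 500`; `cv_options(ntree = 5000)`
reproduces the heavier reference setting at roughly tenfold cost, with
no change to the harness.

## The evaluation harness

Repeated K-fold cross-validation (K = 3, so two thirds train per fold)
with R repetitions (default 50). The fold assignment of a repetition is
fixed across missingness levels and mechanisms, so severity effects are
measured on identical splits; each repetition uses its own missingness
pattern. Fold assignment is simple random — stratification is available
(`cv_plan(stratify = TRUE)`) but off by default, since nothing in the
benchmarked procedure requires it.

Per condition the report stores misclassification, sensitivity,
specificity, Brier score, the OOB-vote Brier for forests, and the
Hosmer–Lemeshow statistic on deciles (groups with degenerate mean
probability are skipped with the degrees of freedom reduced; fewer than
three usable groups is an error, as the test then has no degrees of
freedom). The reported spread is the plain standard deviation across
fold-level values — not divided by √K — matching how the benchmark's
figures are conventionally drawn; a single record reports spread 0.

A failing method cell (for instance a single-class training fold handed
to a classifier) is recorded as failed and the run continues; the run
errors only if every cell fails.

## The synthetic generator

`sim_config()` encodes the simulated study conditions: p = 5 iid N(0,1)
predictors, latent response Y = Xβ + λε with β = (1, 1, 0.1, 0.1, 0.1)
and λ = 10⁻² (Var(Y) = ‖β‖² + λ² = 2.0301 analytically), dichotomized at
the sample mean; n = 300 for the balanced setting and n = 1000 for the
imbalanced ones. For imbalance the stated rule covers only the balanced
cut, so the package labels exactly `ceiling(rate · n)` of the largest
latent values as the (upper-tail) minority class — a deterministic
reconstruction that hits 20/25/30% minority exactly, flagged as such
rather than asserted as the original procedure. The noise stream is
seeded independently of the predictor stream.

What the generator does *not* emulate: mixed variable types, correlated
predictors, measurement error, informative (MNAR) missingness, and the
covariate structure of real clinical tables. Passing benchmarks on this
generator therefore demonstrate correctness of the machinery and the
qualitative method ordering under clean linear signal — not performance
on any particular clinical dataset, which should be assessed by loading
that dataset through `load_table()`.

## Numerical conventions

* Cosine similarities are clamped to [−1, 1]; undefined similarity
  (empty overlap or zero norm) is a first-class `NA`, not an error.
* A total similarity weight below 10⁻¹² counts as zero (unweighted-mean
  fallback).
* Quantiles use linear interpolation between order statistics throughout
  (discretization cutpoints and Hosmer–Lemeshow groups alike), with
  right-closed assignment so ties go to the lower bin.
* All randomness derives from integer seeds via a single multiplicative
  derivation chain, so a master seed reproduces every artifact
  bit-identically; RNG state is always restored after use.
* Selection rules break ties downward: smallest k, smallest class code,
  lowest row id.

## Problem sizes in the shipped checks

The test suite exercises the CF predictor against an independently
written direct implementation on 100 random matrices of up to 20 patients
and 6 items, verifies generator moments at n = 10⁵, and reruns the
simulated benchmark at n = 300 with R = 10 repetitions, 500-tree forests
and 10% missingness — sizes chosen so the full suite stays in the
minutes range while still exercising every code path end to end. The
full-scale configuration (R = 50, three severity levels, all eight
methods, 5000-tree forests) is a `experiment_config()` call away.

## Known limitations

* Similarity on ordinal codes inherits the discretization's information
  loss; CF performance is sensitive to the level count in ways the
  classifiers are not.
* The MAR mechanism masks a single target column; multi-column MAR
  dependencies are out of scope.
* Chained equations here use plain conditional draws, not predictive-mean
  matching or other multiple-imputation refinements.
* No statistical tests compare the methods' mean losses; the report
  deliberately stops at means and fold spreads.
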