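---
title: "Decoding current and prospective task relevance from simulated voxel patterns"
author: "mvdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding current and prospective task relevance from simulated voxel patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvdecode)
```

## The scientific problem

When people hold an object in working memory for a task they will perform
*later*, while first doing something else, the brain has to keep the
prospective memory from interfering with the current task. Multivariate
pattern analysis (MVPA) of object-selective visual cortex can ask how the
two are related: train a classifier to tell remembered object categories
apart when they are *currently* relevant and test it when the same
categories are *prospectively* relevant. Three outcomes are diagnostic:

* **above-chance** cross-relevance decoding: current and prospective
  representations share a format;
* **chance** decoding: the formats are unrelated;
* **below-chance** decoding: the formats are *systematically opposed* —
  voxels that are most active when a category is the current target are
  suppressed when the same category is a future target (an anti-correlated,
  sign-inverted code).

This package implements the full analysis chain needed to ask that question
— within-/cross-relevance decoding with the appropriate cross-validation,
cross-temporal generalization with cluster-corrected inference,
representational dissimilarity analysis (RSA), and repeated-measures group
statistics — together with a synthetic generator of region-of-interest (ROI)
voxel patterns in which the ground truth (signal amplitude, inversion,
display drive) is known and controllable. Every inferential claim the
package makes can therefore be checked against the generator that produced
the data.

## The generative model

A trial is described by its run, relevance condition
(current / prospective / irrelevant), object category (1..3), exemplar
(1..4) and a TR grid (15 TRs for the two-condition design, 16 for the
three-condition design; TR = 2 s). For voxel pattern $x$ at TR $t$ of a
trial in condition $c$ showing category $k$, exemplar $e$:

$$x(t) = a(c,t)\, s(c,t)\, P_{k,e} + b(c,t)\, P_k + \varepsilon$$

* $P_k$ is a unit-norm category prototype over voxels; $P_{k,e}$ adds
  exemplar jitter with expected norm `exemplarJitterSd` (default 0.3, i.e.
  within-category exemplar correlations of roughly 0.9 — high, as expected
  for exemplars of a visually homogeneous category).
* $a(c,t) \ge 0$ is the **amplitude schedule**: how strongly the remembered
  category is encoded in condition $c$ at TR $t$.
* $s(c,t) \in [-1, 1]$ is the **inversion coefficient**: $s = -1$ flips the
  sign of the category pattern, the generative formalization of an
  anti-correlated prospective code. It is the single knob the package's
  central hypothesis tests manipulate.
* $b(c,t) \ge 0$ is the **display drive**: the bottom-up response to the
  trial's own category when it is physically on screen (during encoding and
  during the search that displays that category). Unrelated search displays
  (the other task's stimuli) carry no category information about the
  remembered item and are therefore not modelled separately.
* $\varepsilon$ is i.i.d. Gaussian noise per voxel (`noiseSd`, default 1),
  optionally AR(1) across TRs (default coefficient 0.3, a mild temporal
  autocorrelation typical of fast event-related t-patterns; the marginal
  sd is preserved).

### Default schedules: the simulated study conditions

`defaultSchedules()` fixes the trial phases after a ~4 s haemodynamic lag.
For the 16-TR design the analysis windows (`defaultIntervals()`) are Delay
= TRs 5–7, Search 1 = TRs 9–11, Search 2 = TRs 13–15, covering the task's
8-s epochs; the exact indices are configuration because no canonical values
exist for them. The default amplitudes (in units of the noise sd) encode
the qualitative structure the analyses are meant to recover:

* **current**: strong delay code (1.5), strongest during its own search
  (2.0 plus display drive 1.0), weak inverted tail afterwards;
* **prospective**: moderate delay code (1.0), *inverted* moderate code
  during Search 1 (0.8 with $s=-1$ — the re-emerging, anti-correlated
  prospective representation), strong upright code during Search 2 when it
  becomes the current target (1.8 plus display drive);
* **irrelevant**: moderate delay code (0.9) that vanishes once the cue
  renders the item irrelevant ($a = 0$ from Search 1 on).

In the 15-TR two-condition design the no-longer-relevant current item is
also inverted during Search 2, mirroring the prospective item during
Search 1. Effect sizes in pattern space are free parameters of the
simulation — they are this package's choices of a realistic regime (group
effects of the sizes the decoders detect reliably at 20+ simulated
subjects), not estimates of any empirical quantity.

### The haemodynamic path

`simulateTPatterns()` emits the model above directly as "t-values".
`simulateBoldGlm()` instead synthesizes per-voxel BOLD time series — the
per-TR neural amplitudes convolved with a double-gamma HRF (peak 6 s,
undershoot 16 s, ratio 1/6; configurable) — adds noise, and fits the
standard per-trial GLM in which **every TR of the trial is one boxcar
regressor** (16 regressors for 16-TR trials), returning $t = \beta / SE$
per voxel per TR. The acquisition window extends a configurable number of
rest TRs (default 6) past the trial so the model keeps residual degrees of
freedom. The finite-impulse-response design matrix is ill-conditioned in
the way such per-TR models always are, so the GLM path is noisier than the
direct path at equal `noiseSd`; at low noise the two agree per signal TR
(correlation > 0.9), which the test suite verifies.

## Decoding

`fitOvrLogistic()` is a one-vs-rest logistic regression (one binary
iteratively-reweighted-least-squares fit per category, iteration cap 5000,
prediction by argmax of the class scores, ties to the lowest category
index). A small L2 ridge (1e-4) on the weights — not the intercept — keeps
the optimum finite on separable data; a step-halving line search keeps the
penalized deviance monotone, which plain Newton steps do not guarantee.
Features (t-values) are used as-is; per-fold standardization is available
behind the `standardize` flag but off by default.

Two cross-validation schemes cover the two designs:

* `loroWithin()`: standard leave-one-run-out within one relevance
  condition. Valid when runs are category-balanced within condition.
* `balancedLoro()`: the modified scheme for 9-run designs where per-run
  category counts within a condition are a rotation of (2,1,1). Each
  training fold then holds 32 trials with counts (10,11,11); for each of
  11 repetitions one surplus trial of each 11-count category is excluded
  (every surplus trial exactly once), leaving 30 training trials, 10 per
  category, and 9 × 11 = 99 fits per TR. Scores are **balanced accuracies**
  (per-class accuracy averaged over classes), which makes the null
  expectation exactly 1/3 regardless of how a label-blind classifier
  distributes its predictions. This matters: plain accuracy under plain
  leave-one-run-out is biased *below* chance on these folds, because the
  training imbalance anti-correlates with the test-run composition.

`crossRelevance()` trains on all trials of one condition and tests on all
trials of another, in both directions, and averages the two — train and
test sets are disjoint by construction, so no run splitting is required
(a leave-one-run-out variant is available behind `runSplit = TRUE` for
sensitivity analysis). `decodeTimecourse()` applies a scheme per TR;
`crossTemporalMatrix()` trains at every TR and tests at every other,
keeping the scheme's folds so the matrix diagonal equals the timecourse.

## Cluster-based permutation inference

`clusterPermutation2d()` tests a group of train × test TR matrices against
chance: per-cell one-sample t, cluster formation among 4-connected
supra-threshold cells (8-connectivity available), cluster mass = summed t,
and a max-mass null built by subject-wise sign flips of the deviations from
chance. Monte-Carlo p-values use the +1 correction so they are never 0;
when $2^n$ does not exceed the requested permutation count the test
enumerates all sign assignments exactly instead of sampling. Two-sided
testing runs two one-sided tests (positive and negative clusters), each
formed at half the cluster-forming level and evaluated at half the
corrected level. The cluster-forming threshold and the corrected level are
deliberately independent knobs (both default 0.05). Cells with zero
variance across subjects cannot carry a t statistic and are excluded from
cluster formation with a warning.

## Representational dissimilarity analysis

`computeRdm()` correlates the per-combination (category × exemplar ×
relevance) mean patterns with Spearman's rank correlation (average ranks on
ties) and stores $1 - \rho$; for the two-condition design at 3 categories ×
4 exemplars this is the 24 × 24 matrix. Two aggregation conventions are
implemented because the natural-sounding one is infeasible: a 12-trial run
of a 24-combination design contains at most half the combinations, and over
8 runs many *pairs* of combinations never co-occur within any run, so
strict per-run RDM averaging leaves structurally empty cells. The default
(`runAverage = "pooled"`) therefore averages each combination's pattern
across the runs in which it occurs and correlates once per TR; the per-run
mode (`"per_run"`) is available and errors informatively on the first
empty pair. Interval RDMs average the per-TR RDMs over the interval's three
TRs.

`rankTransform()` re-expresses an RDM by the rank of each cell among the
upper-triangle cells, scaled to [0, 1] (all-equal inputs collapse to 0.5
by convention). `classicalMds()` is Torgerson scaling via double-centering
and spectral decomposition — deterministic, closed-form, negative
eigenvalues truncated.

`sameVsDiffContrast()` restricts an RDM to cells crossing two relevance
levels and compares the 3 same-category blocks (48 cells) with the 6
different-category blocks (96 cells). On the `fisher` scale each
contributing cell's underlying $\rho$ is variance-stabilized first and the
dissimilarity taken as $-\mathrm{atanh}(\rho)$: the transform is applied to
$\rho$ rather than to $1-\rho$ (whose range [0, 2] exceeds the transform's
domain) so the statistic stays defined while preserving the intended
monotone relation. A negative same-minus-different difference means
category structure is preserved across relevance; under an inverted
prospective code the difference turns positive during search — same-category
pairs become the *most* dissimilar cells.

## Group statistics

`pairedT()` is the paired/one-sample t with Cohen's
$d = \bar{x}_{\mathrm{diff}} / s_{\mathrm{diff}}$. Comparisons of
within-relevance decoding against chance are one-tailed (that scheme cannot
meaningfully fall below chance); everything else, including all
cross-relevance tests, is two-tailed. `rmAnovaOneway()` decomposes a
complete subjects × conditions table (condition, subject, error sums of
squares), reports partial eta squared
$SS_{\mathrm{cond}} / (SS_{\mathrm{cond}} + SS_{\mathrm{err}})$, and
estimates the Greenhouse–Geisser $\varepsilon$ from the double-centered
covariance matrix; by default the correction is applied automatically when
$\varepsilon < 0.75$ (a common working rule; configurable to always/never).
`withinSubjectSem()` uses the Cousineau subject-centering with the Morey
$\sqrt{C/(C-1)}$ bias factor. `perTrUncorrected()` provides the per-TR
p < 0.05 uncorrected significance masks that accompany decoding
timecourses, and `roiMeanTimecourse()` the mean ROI response per TR with
within-subject error bars.

## Orchestration and reproducibility

`runConfig()` / `validateConfig()` / `runPipeline()` bundle the stages:
simulate n subjects, decode the configured schemes at the configured TRs,
average over intervals, test against chance, run the condition ANOVA when
three within-relevance schemes are present, and compute interval RDM
contrasts per cross pair. The master seed deterministically derives
per-subject sub-seeds (all below $2^{31}$); re-running a config reproduces
every number exactly, and `outDir` gets tidy CSVs plus a JSON manifest.
Configs load from YAML or JSON (`readConfig()`), datasets persist as plain
CSV + JSON sidecars (`writePatternDataset()`), and real per-TR t-maps can
be ingested from a 4-D NIfTI plus a TSV trial table (`readNiftiPatterns()`,
requires RNifti).

## Numerical choices and degenerate inputs

* IRLS stops on a coefficient step below 1e-8 or a relative deviance change
  below 1e-10; non-convergence at the iteration cap warns and returns the
  current iterate.
* Argmax ties in prediction go to the lowest category index (determinism).
* Spearman ties receive average ranks; $\rho$ is clamped away from ±1
  before $\mathrm{atanh}$.
* Zero-noise input to the GLM path is an error (t undefined), as are
  rank-deficient trial design matrices and zero residual variance.
* Permutation p-values are never 0 (+1 correction / exhaustive counts).
* An all-equal off-diagonal RDM rank-transforms to 0.5 everywhere.
* Infeasible balance requests (trials per run not divisible by the number
  of conditions; run counts that cannot equalize condition × category
  totals) are configuration errors, raised before any data are simulated.

## What the simulation does and does not establish

The generator emulates: the two trial-design geometries (8 × 12 and 9 × 12
runs × trials; 15/16 TRs), per-run condition balance with the rotated
(2,1,1) category imbalance, category-selective patterns with exemplar
structure shared across relevance, relevance- and phase-dependent gain and
inversion, display-evoked drive, and Gaussian (optionally AR(1)) noise. It
does **not** emulate spatial voxel correlations, physiological or motion
artifacts, between-subject variability in effect size (subjects differ
only by seed), or any exemplar-specific inversion. Passing tests therefore
show that the analysis chain recovers the intended signatures from data
that contain them and stays calibrated on data that do not — they are
statements about the inference machinery, not about any empirical brain.

Problem sizes in the test suite are chosen for tight, reliable checks at
desk scale: 20 simulated subjects for group-level signatures, 40 voxels per
ROI for signal datasets, 20 for null calibrations, 200 replicates for the
family-wise error check (binomial 3σ tolerance), and exhaustive sign-flip
enumeration whenever $2^n$ is within the permutation budget.
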