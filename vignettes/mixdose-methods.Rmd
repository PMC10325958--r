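---
title: "Methods: biodosimetry of mixed neutron + photon exposures by biomarker integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biodosimetry of mixed neutron + photon exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixdose)
```

## The problem and the model

A realistic large-scale radiation exposure is a mixture of photons and
neutrons, and the neutron share — which differs between individuals with
distance and shielding — matters biologically because neutrons deposit
energy more densely per Gy than photons. `mixdose` reconstructs both the
magnitude and the composition of such exposures from panels of
radiation-responsive biomarkers: qRT-PCR transcript signals (cycle
thresholds, C_T), serum and urine metabolite intensities, and
flow-cytometry blood cell counts.

The central modelling assumption is that every biomarker responds to a
single scalar damage burden, the *photon-equivalent dose*

$$D_{PE}(\mathrm{RBE}) = D_P + \mathrm{RBE}\times D_N,$$

where RBE is the neutron relative biological effectiveness. Because the
true RBE plausibly differs between biomarkers, the package estimates a
*correlation-weighted compromise*: `estimateRbe()` scans a dense RBE grid
and keeps the value maximising

$$\sum_i \operatorname{cor}\!\big(D_{PE}(\mathrm{RBE}),\, S_i\big)^2 ,$$

the sum over biomarkers of squared Pearson correlations between the
candidate dose scale and each signal $S_i$. Squaring lets positively and
negatively responding biomarkers contribute alike, and weights each
biomarker by how tightly it tracks the candidate scale. The assumptions to
keep in mind: each biomarker is (after transformation) approximately
*linear* in $D_{PE}$ over the observed range, and the same RBE applies to
every sample. Blood counts therefore enter this objective on their ln
scale, where a log-linear depletion with dose becomes linear; on the raw
count scale the exponential curvature drags the per-biomarker optimum away
from the generative RBE, which is visible if `estimateRbe()` is run on an
unengineered panel.

## Stage by stage

**Feature engineering.** `geneNetSignal()` summarises seven genes as the
difference between the geometric mean C_T of the group whose C_T falls
with dose (Lrg1, Phlda3, Rhoc — i.e. the radiation-upregulated
transcripts) and the geometric mean of the group whose C_T rises (Ccr7,
Cd19, Cxcr5, Ly6d). The score is computed directly on the C_T scale (no
$2^{-\Delta C_T}$ conversion): the groups are defined by C_T direction, and
a plain difference of geometric means keeps the score's units
interpretable as cycles. `transformCounts()` replaces raw counts by
`ln_<marker>` columns plus the ln neutrophil/lymphocyte ratio
(`ln_Ly_6G_CD45_ratio`); zero or negative counts are a hard error, never a
silent offset, because a zero count is a measurement failure, not a small
number. `matchBloodCounts()` reproduces a design constraint of the
motivating study: counts were measured on *different animals* than the
omics, so donors are matched to recipients uniformly at random within the
same (exposure group × sampling time) stratum, without replacement until a
stratum's pool is exhausted and only then reusing donors. Matching never
crosses strata, and is seeded.

**Screening.** `screenFeatures()` keeps predictors with
$|r| \ge 0.3$ against $D_{PE}$ (inclusive, with a $10^{-9}$ guard so
exactly-at-threshold values are kept under floating point), then prunes
multicollinearity: a survivor correlated at $|r| \ge 0.7$ with at least
two other survivors qualifies for removal, and the worst offender (most
strong partners; ties toward the weaker dose correlation, then
alphabetical) is removed iteratively until none qualifies. "At least two"
operationalises "several"; a pairwise rule would be stricter and can be
had with `severalMin = 1`. Sex and Time are exempt from both filters and
are carried as predictors of interest. Screening is idempotent: re-running
it on its own output changes nothing.

**Shadow-feature selection.** `borutaSelect()` implements all-relevant
selection: each iteration permutes every live feature's column into a
fresh "shadow", fits a random forest on reals + shadows (ranger, impurity
importance, 500 trees, single-threaded for reproducibility), scores a
"hit" for features whose importance exceeds the 50th percentile of that
iteration's shadow importances, and applies a two-sided binomial test of
the cumulative hit count against chance at $\alpha = 0.05$, Bonferroni
corrected over the features still in the model: significant in the upper
tail confirms, in the lower tail rejects (and removes). Features undecided
after `maxIter` (default 100) iterations are *tentative* and are treated
as not retained — the conservative reading of a binary keep/discard
summary. `minHitsToConfirm()` exposes the exact confirmation threshold.

A caution established while validating this stage (and worth knowing
before trusting any 50th-percentile shadow criterion): for *continuous
i.i.d. noise* predictors the hit indicator is not a fair coin. A noise
feature's chance correlation with the target is fixed for the whole run,
while the shadows are re-randomized each iteration, so a feature whose
fixed chance correlation happens to sit above the typical shadow level
beats the shadow *median* nearly every iteration and will eventually be
confirmed, no matter how the forest size or importance type is chosen. The
package's tests document this: a planted perfect predictor is always
confirmed, but panels of pure continuous noise yield several false
confirmations per run. The classic escape is the shadow *maximum*
(`thresholdPercentile = 100`), which only features beating the best of all
shadows can pass; combined with `importance = "permutation"` it suppresses
the effect. Both knobs are exposed, but the defaults stay at the 50th
percentile with impurity importance — this pipeline's stated protocol
settings. In the intended workflow the
danger is limited: candidates reach this stage only after the $|r| \ge
0.3$ screen, so they are not i.i.d. noise, and genuinely uninformative
binary covariates such as Sex sit reliably below the shadow median.

**Stacking.** `fitStack()` builds a level0 ensemble — linear regression,
elastic net, random forest, gradient-boosted trees and support-vector
regression for regression tasks; logistic regression, random forest,
gradient-boosted trees, k-nearest neighbours and naive Bayes for
classification — fitted with repeated stratified k-fold cross-validation
(defaults: 5 folds × 10 repeats). Each sample's held-out predictions,
averaged over repeats, form the out-of-fold matrix on which the level1
meta-model is trained: a random forest for regression and gradient-boosted
trees for classification. Only out-of-fold predictions reach the
meta-model (raw features are not passed through), repeats are averaged
rather than stacked as rows, SVM/kNN inputs are standardised with
training-fold statistics only, and a learner that errors on any fold is
excluded with a warning rather than imputed. Hyperparameters are library
defaults with fixed seeds; there is deliberately no tuning grid or nested
selection. Level1 classification consumes level0 *probabilities*, which
preserves calibration information that hard labels would discard.

**Evaluation.** `regressionMetrics()` reports RMSE, MAE and
$R^2 = 1 - SS_{res}/SS_{tot}$. `rocAuc()` uses the rank (Mann–Whitney)
formulation with midranks, so ties count one half and the AUC is invariant
under monotone transforms of the scores. `bootstrapAucCi()` resamples
(label, score) pairs with replacement — stratified by class so no
replicate is degenerate — 10,000 times by default and reports the
percentile 95% interval; percentile rather than BCa because the interval
summarises the plain replicate histogram. Classification thresholds
default to 0.5 on the level1 probability. `subgroupErrorTable()` breaks
test errors down by exposure group, the diagnostic that reveals *where* a
classifier fails (typically: photon-only 3 Gy animals mistaken for
neutron-exposed, because sham-vs-exposed is easy and composition is hard).

**Orchestration.** `runPipeline()` wires the stages in training-only
order: stratified half split (`splitTrainTest()`, by exposure group ×
time so no stratum is lost; sizes $\lceil n/2\rceil/\lfloor n/2\rfloor$,
45/44 at $n=89$) → RBE fit on the training half only → targets for all
samples with that fixed RBE → screen on training rows → shadow selection
per endpoint → stack fit → prediction and evaluation on the held-out
half. The endpoints are the photon-equivalent dose and neutron dose
(regression), the binary neutron-fraction ≥ 10% and neutron dose ≥ 0.5 Gy
labels (classification; the fraction comparison carries a $10^{-9}$
epsilon so a group at exactly 10% classifies as positive under binary
floating point), and ln CD19 counts as a biological-injury endpoint
predicted from genes and metabolites only. Modes: `full`, `no-cd19`
(ablation of the strongest count predictor) and `cd19-outcome`. If shadow
selection confirms nothing for an endpoint, the screened set is used with
a warning — an empty model is less informative than a model on screened
predictors. Stratification of the split is an addition over a plain
random half (with 12 strata a plain split can lose whole strata from one
half) and can be bypassed by calling the stage functions directly.

## The synthetic cohort generator

`generateCohort()` emulates the design the analysis assumes: 6 exposure
groups — sham, and 3 Gy total at neutron fractions 0/10/20/30/80%
(neutron doses 0, 0.3, 0.6, 0.9, 2.4 Gy) — at 1 and 7 days, both sexes,
89 animals with near-equal allocation (14 per exposed group, remainder of
19 to sham; per-group animal counts are a calibration choice, not a
reported fact). Each biomarker follows

$$S = \text{baseline} + \text{slope} \times (D_P + \rho\, D_N)
      + \beta_t t + \beta_s \,\mathrm{sex} + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma),$$

on its measurement scale for genes (C_T: upregulated genes get negative
slopes) and metabolites, and on the ln scale for blood counts, which are
exponentiated so counts are strictly positive. Per-biomarker true RBEs
$\rho$ spread over 0.8–2.0 around 1.3, so a weighted estimate near 1.3 is
recoverable; metabolite effect sizes range from strong to null so the
screen has realistic work; count noise is calibrated so within-group CVs
of ln counts bracket a 0.16 target (the CD19 baseline and noise are chosen
jointly so that the within-group spread of ln CD19 — the irreducible error
of any predictor of a randomly matched donor's counts — is comparable to
its reported reconstruction error, which pins the ln-count location near
3–6 rather than the raw-count location).

What the generator does *not* emulate: measurement-level artefacts
(amplification curves, spectral deconvolution, batch effects, missingness,
detection limits), inter-biomarker residual correlation beyond the shared
dose response, nonlinear or saturating dose responses, and any
pharmacokinetics. Passing tests on this cohort therefore demonstrate that
the *pipeline machinery* is correct and that effects of the assumed form
are recovered at realistic noise — not that real animal data meet the
assumptions.

## Numerical choices

- RBE grid: $[0.05, 10]$ at step 0.01, refined once at step 0.001 around
  the coarse optimum; a 1-D bounded objective needs nothing smarter. Grid
  ties break toward the smaller RBE for determinism. A grid point where
  $D_{PE}$ is constant across samples (possible when all exposed samples
  share one total dose) has an undefined correlation and is excluded from
  the argmax. Constant biomarker columns are dropped with a warning; an
  all-constant dose vector is an error ("no dose contrast").
- All stochastic stages (generation, matching, splitting, shadow
  permutations, fold assignment, forest and boosting fits, bootstrap) are
  driven by explicit seeds; forests and boosters run single-threaded so
  repeated runs are bit-identical.
- Every analysis default equals the protocol value: screen thresholds 0.3
  and 0.7, shadow percentile 50, $\alpha = 0.05$ Bonferroni, 5 × 10
  cross-validation, 10,000 bootstrap replicates, threshold 0.5.
- Test problem sizes are deliberately compact — cohorts of 30–89 animals,
  2–10 repeats, 200–1,000 bootstrap replicates, 10-seed batteries for the
  statistical properties — chosen so the full suite exercises every stage
  in a few minutes while the assertions remain sharp.

## Known limitations

- The 50th-percentile shadow criterion is anti-conservative for
  chance-correlated continuous noise (analysis above); interpret
  confirmations of marginal features with care, or rerun with
  `thresholdPercentile = 100`.
- RBE_opt carries no uncertainty interval; the objective is a sum over
  correlated biomarkers and its curvature is not a standard error.
- With a single non-zero total dose in the design, dose-magnitude
  reconstruction is dominated by the sham-vs-exposed contrast and
  composition (neutron share) is the genuinely hard part; the subgroup
  error table makes this visible.
- The blood-count matching deliberately reproduces a donor-sharing design;
  counts attached to a sample describe its stratum, not the individual
  animal, which bounds any predictor of matched counts by the
  within-stratum spread.
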