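---
title: "Classifying treatment arms from self-reported mood dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying treatment arms from self-reported mood dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodtrial)
```

## The problem

Weekly self-reported depression ratings (QIDS-SR16, an integer score from
0 to 27) collected over a year-long two-arm trial form short, unevenly
sampled, bounded integer time series: participants are prompted weekly
but respond at arbitrary times within the week, skip weeks, and drop out
permanently as the trial progresses. The question this package addresses
is whether — and after how many weeks of data — participants can be
assigned to their treatment arm from the *shape and dynamics* of their
score series alone, without using any information about the intervention.

Two per-subject quantities carry most of the signal in this setting:

* the **coefficient of variation** $\sigma/\mu$, the within-subject SD
  divided by the within-subject mean, a standardized dispersion measure
  insensitive to the ordering of the reports; and
* the **DFA scaling exponent** $\alpha$ from detrended fluctuation
  analysis, a measure of temporal self-affinity that is insensitive to
  the marginal distribution: $\alpha \approx 0.5$ for uncorrelated
  (white) fluctuation, $\approx 1$ for $1/f$ (pink) structure, and
  $\approx 1.5$ for a random walk.

A treatment that lowers mean symptom burden while destabilizing the
series raises $\sigma/\mu$ and lowers $\alpha$, so the two features span
a plane in which the arms separate along orthogonal axes — one
distributional, one temporal.

## Feature definitions and estimators

**Moments.** The subject mean and SD (with the $n-1$ denominator) give
$\sigma/\mu$; skewness and kurtosis use bias-uncorrected central sample
moments, $m_3/m_2^{3/2}$ and $m_4/m_2^2 - 3$ (excess form; a normal
sample is near 0). A constant series has $\sigma = 0$, hence
$\sigma/\mu = 0$ and undefined shape moments; a zero mean with positive
SD leaves $\sigma/\mu$ undefined. Undefined values are flagged missing,
never returned as infinities.

**Spectral band powers.** Because sampling is uneven, spectral density is
estimated by the classical Lomb least-squares periodogram: at each
frequency $f$ the power of the best-fitting sinusoid, computed with the
usual phase rotation $\tau$ that orthogonalizes the cosine and sine
bases, normalized by twice the sample variance. Under even sampling this
reduces exactly to the classical periodogram, which the test suite
verifies to $10^{-6}$ relative tolerance. Powers are summed below and
above a threshold of 0.2 cycles/week (the boundary itself counts as low
frequency), and their ratio forms a third feature. The frequency grid is
0.01 to 0.5 cycles/week in steps of 0.01 — 0.5 is the Nyquist frequency
of the weekly prompting schedule. The band features depend on the
variance normalization; raw (unnormalized) band powers would additionally
mix in amplitude information already carried by the SD.

**DFA.** The mean-centered series is integrated to a profile; for each
box size $n$ the profile is covered by non-overlapping boxes anchored at
the series start *and*, when $n$ does not divide the length, a second set
anchored at the series end, so the truncated tail is not discarded — for
the 10–50-point series typical of one subject this roughly halves the
variance of the estimate. A least-squares line is removed per box, and
$F(n)$ is the RMS residual; $\hat\alpha$ is the slope of $\log F(n)$ on
$\log n$. `dfa_alpha()` defaults to approximately ten log-spaced box
sizes from 4 to $N/4$, the standard configuration for long signals, and
the calibration on $10^4$-point simulated white, pink, and random-walk
series uses exactly that configuration. For the short per-subject series
in `build_feature_table()` the ceiling is widened to $N/2$: with
$N \approx 35$ the $N/4$ rule leaves only boxes of size 4–8 and discards
all large-scale information, and simulation shows the $N/2$ ceiling
halves the estimator SD without affecting long-series calibration. A fit
requires at least three distinct box sizes with positive $F(n)$;
otherwise the feature is flagged missing (this makes $\hat\alpha$
unavailable below 12 retained reports).

**Uneven sampling and DFA.** DFA assumes an evenly indexed series. The
default policy (`dfa_mode = "index"`) treats the retained reports, in
time order, as a contiguous sequence; the alternative (`"snap"`) first
averages reports within their nominal week and skips empty weeks, which
coincides with the index policy whenever there is at most one report per
week. The switch exists so the sensitivity of downstream results to this
choice can be tested directly.

## Group-level comparisons

Classical analyses are kept deliberately simple: pooled OLS trend lines
per arm; expanding-window means (the mean of all reports up to week $n$,
plotted against $n$); equal-variance two-sample t-tests on per-subject
window means for 4-week windows, reported as the signed active-minus-
placebo difference with a symmetric 95% CI (subjects without a report in
the window are excluded, so window sample sizes vary); and a permutation
test in which subjects' arm labels are shuffled uniformly, the pooled
mean difference recomputed, and the two-sided p-value taken as
$(1 + \#\{|T^\ast| \ge |T|\})/(B + 1)$. No multiple-testing correction is
applied across windows; the windows are descriptive.

## Feature evaluation, selection and classification

Single features are assessed by Gaussian-kernel density estimates per arm
(Silverman's rule-of-thumb bandwidth, grid spanning the data range plus
three bandwidths) and by ROC curves built from a threshold sweep over the
unique score values, with the active arm as the positive class and
higher scores predicting active. Tied scores are processed jointly, so
the trapezoidal AUC equals the Mann–Whitney pair-counting statistic with
ties worth one half — the test suite checks this identity exhaustively on
random instances.

Feature selection runs in two families. The penalized family fits
lasso, elasticnet (mixing 0.5) and ridge logistic paths and selects the
nonzero coefficients at the penalty minimizing 10-fold cross-validated
binomial deviance; ridge, which zeroes nothing, contributes a ranking by
coefficient magnitude. The sequential family is greedy forward selection
with cross-validated misclassification as the criterion, stopping as
soon as no candidate strictly reduces the error; it can be run with any
of the six classifier kinds, and `select_features()` summarizes each
family by the union of its members' selections, with the intersection of
the two family sets as the consensus. Summarizing at the family level
reflects how agreement across several imperfect selectors, rather than
any single run, justifies trusting a feature set: with a modest
cross-validated error criterion on ~100–140 subjects, two features that
carry overlapping signal (for example $\hat\alpha$ and the low-frequency
band power, both functions of the spectrum) can substitute for one
another in any single greedy run.

Six classifiers are provided: logistic regression, LDA, QDA, linear and
Gaussian-kernel SVMs, and k-nearest neighbors. Hyperparameters that the
analysis does not tune are fixed at documented defaults and exposed in
`params`: $k = 5$ (odd, so binary votes cannot tie), SVM cost 1, RBF
kernel width $\gamma = 1/(2 h^2)$ with $h$ the median pairwise distance
of the standardized training features. Evaluation is stratified 10-fold
cross-validation; fold assignment is a pure function of the seed, every
subject appears in exactly one test fold, and fold sizes differ by at
most one. Feature standardization is fitted on the training folds only
and applied to the held-out fold, so no test-fold statistics leak into
the fit. A fold whose model cannot be fitted (for example QDA with a
class smaller than the feature count) is marked invalid and excluded
from the mean; singular discriminant fits are retried once with a tiny
regularizing jitter and a logged warning.

## Trial-duration analysis

For each candidate duration $w$ (13–52 weeks) the cohort is truncated at
week $w$, subjects with at least 10 responses so far are selected, and
all features are recomputed from scratch on the truncated series —
nothing is cached, because both the spectral features and $\hat\alpha$
depend on series length. The logistic model on
$\{\sigma/\mu, \hat\alpha\}$ is then cross-validated and compared with
the no-information rate (the majority-class fraction of the selected
subset). "Above benchmark" is operationalized as accuracy exceeding the
benchmark by more than twice the SE, where the SE is by default the SD
of the fold accuracies over $\sqrt{k}$ (a binomial SE over subjects is
available as a config switch). Weeks with fewer than 20 eligible
complete-case subjects are marked not computable.

## The synthetic cohort generator

No public individual-level data exist for this kind of trial, so the
package ships a generator whose defaults emulate a 202-participant,
52-week, two-arm cohort, and every downstream stage is exercised against
it. Per subject:

1. a latent mean is drawn from a truncated normal around the arm target
   (defaults 9 active / 11.2 placebo, between-subject SD 5, truncated to
   [1, 26]) — the wide between-subject spread matches the weak windowed
   group differences seen in practice, where differences of ~2 score
   points at ~80 subjects per arm hover around $p \approx .09$;
2. the within-subject SD is the subject's own mean times the arm's
   coefficient of variation ($\sigma/\mu$ = 4/9 active, 3/11.2 placebo)
   times a lognormal factor (log-SD 0.25) — dispersion scales with
   severity, and the distributional arm contrast lives in $\sigma/\mu$
   rather than in the SD alone;
3. a scaling exponent is drawn around the arm target (0.7 active, 1.0
   placebo, SD 0.1) and a latent series of that self-affinity is produced
   by spectral synthesis: Fourier amplitudes $\propto f^{-\beta/2}$ with
   $\beta = 2\alpha - 1$ and uniform random phases;
4. an individual linear trend (SD 0.05 score/week around the arm trend,
   which defaults to zero) adds the slow idiosyncratic drift real
   participants show as they improve or worsen at their own rates;
5. the weekly value is rounded to the nearest integer and clipped to
   [0, 27]; each week is reported with probability 0.7 until an absorbing
   dropout event (weekly hazard 0.013, giving roughly 60% observed
   compliance at week 12); the week-$w$ report time is $w - 0.5$ plus
   truncated Gaussian jitter with SD 0.29 weeks, matching a report
   submitted at essentially any time during its week; and
6. a mania score (ASRM, 0–25) is filled with low-information Poisson
   noise carrying no arm signal, mirroring its lack of predictive value.

The trend heterogeneity and the within-week report-time jitter matter
beyond cosmetics: a zero-trend, exactly-power-law, regularly-sampled
world makes the normalized spectral band powers nearly sufficient
statistics for $\alpha$, which real mood data — with idiosyncratic drift
and messy timing — are not. Without these terms the generator would
overstate how informative the band powers are relative to DFA.

What the generator does *not* emulate: episodic relapses or level
shifts, arm-dependent demographics (age, sex, bipolar type are sampled
independently of arm), adaptive randomization, within-week multiple
reports, and non-random (informative) dropout. Results on synthetic
cohorts therefore demonstrate that the estimators and the pipeline
recover planted structure under realistic sampling — not that any
particular real trial would show the same effect sizes.

## Numerical choices and degenerate inputs

* At the Nyquist frequency of integer sampling the sine basis of the
  Lomb fit has numerically vanishing norm; a basis vector with squared
  norm below $n \times 10^{-10}$ is treated as degenerate and contributes
  zero power, which keeps the periodogram exactly shift-invariant.
* Report-time jitter is truncated at ±0.45 weeks so times stay strictly
  increasing; integer scores are rounded before clipping to the scale
  bounds.
* kNN uses an odd default $k$, so binary votes cannot tie; residual
  distance ties inside `class::knn` are resolved under a stored seed so
  predictions are reproducible.
* Permutation p-values use the add-one form, so the smallest attainable
  p with $B$ permutations is $1/(B+1)$ and the test is exact-level at
  $\alpha$ whenever $\alpha(B+1)$ is an integer.
* The pipeline derives fixed per-stage seeds from the single global seed
  (recorded in the run manifest), so any stage can be re-run in
  isolation and a full re-run is byte-identical.

## Problem sizes used by the test suite

The suite calibrates DFA on twenty $10^4$-point series per noise class;
checks estimator-oracle identities on hundreds of small random
instances; runs the full parameter-recovery analysis on one 202-subject,
52-week synthetic cohort; measures the permutation test's type-I error
on 200 replicate 24-subject null cohorts at $B = 199$; and traces the
null duration curve on a full-size contrast-free cohort. These sizes
were chosen to give stable Monte-Carlo estimates at interactive
runtimes.

## Known limitations

* $\hat\alpha$ from 10–30 points has substantial variance even with the
  widened box range; group contrasts are detectable, individual values
  should not be over-interpreted.
* Index-time DFA ignores the irregular spacing entirely; if reporting
  gaps are long and informative, neither provided policy is fully
  satisfactory.
* The duration sweep tests each week marginally without multiplicity
  control; its per-week "significance" is descriptive, as documented.
* The selection stage's outcome on any single cohort is stochastic when
  features carry overlapping signal; family-level agreement mitigates
  but does not eliminate this.

## A minimal run

```{r example, eval = FALSE}
cfg <- synthetic_config(n_per_arm = 101, weeks = 52, seed = 1)
cohort <- generate_cohort(cfg)
features <- build_feature_table(cohort, min_reports = 10)

fm <- feature_matrix(features)
sel <- select_features(fm$x, fm$y, seed = 1)
sel$consensus

fm2 <- feature_matrix(features, columns = c("cv", "dfa_alpha"))
cv_accuracy("logistic", fm2$x, fm2$y, seed = 1)$mean_accuracy

curve <- accuracy_vs_duration(cohort, seed = 1)
head(curve)
```
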