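# moodtrial

Classify participants of a two-arm randomized trial into treatment arms
from the distributional and temporal structure of their weekly
self-reported mood scores.

## The problem

In year-long bipolar-depression trials, participants self-report a
QIDS-SR16 depression score (integer, 0–27) roughly weekly, at arbitrary
times within the week, with skipped weeks and permanent dropout. Mean
group differences in such data are small relative to the wide
between-subject spread of symptom severity, so classical windowed
t-tests are weakly powered. The dynamics of each participant's series
carry complementary information:

* **σ/μ** — the within-subject coefficient of variation, a standardized
  dispersion measure independent of temporal ordering;
* **DFA α** — the detrended fluctuation analysis scaling exponent, a
  self-affinity measure independent of the marginal distribution
  (α ≈ 0.5 white noise, 1.0 pink noise, 1.5 random walk), estimated from
  the slope of log F(n) versus log n, where F(n) is the RMS residual of
  the integrated, per-box linearly detrended profile.

A treatment that lowers symptom burden while destabilizing mood raises
σ/μ and lowers α, so a linear classifier on the (σ/μ, α) plane can
separate the arms. The package implements the full analysis: a synthetic
cohort generator with controllable arm contrasts; per-subject features
(moments, Lomb least-squares band powers for uneven sampling, DFA α);
classical group statistics (windowed pooled t-tests, trend regression,
expanding-window means, a permutation null for the overall difference);
single-feature evaluation (Gaussian KDE, ROC/AUC); two feature-selection
families and six cross-validated classifiers; and classification
accuracy as a function of trial duration against the no-information
benchmark.

## Worked example

```r
library(moodtrial)

cfg    <- synthetic_config(n_per_arm = 101, weeks = 52, seed = 1)
cohort <- generate_cohort(cfg)
cohort
#> <mood_cohort> 202 subjects (101 active / 101 placebo), 5271 reports

features <- build_feature_table(cohort, min_reports = 10)
aggregate(cbind(cv, dfa_alpha) ~ arm, features,
          function(x) round(mean(x, na.rm = TRUE), 3))
#>       arm    cv dfa_alpha
#> 1  active 0.473     0.733
#> 2 placebo 0.298     0.994

# classical comparison: weak, because between-subject spread is wide
wt <- window_ttest(cohort, 10, 14)
sprintf("weeks 10-14: diff %.2f, p = %.3f", wt$mean_difference, wt$p_value)
#> "weeks 10-14: diff -0.43, p = 0.622"

# both selection families agree that cv and dfa_alpha carry signal
fm  <- feature_matrix(features)
sel <- select_features(fm$x, fm$y, seed = 1)
sel$consensus
#> [1] "cv"        "dfa_alpha" "power_low" "type_I"    "age"       "sex_male"

# the two-feature dynamics classifier, by contrast, is strong
fm2 <- feature_matrix(features, columns = c("cv", "dfa_alpha"))
r   <- cv_accuracy("logistic", fm2$x, fm2$y, seed = 1)
sprintf("accuracy %.3f (se %.3f), benchmark %.3f",
        r$mean_accuracy, r$se_accuracy, no_information_rate(fm2$y))
#> "accuracy 0.821 (se 0.044), benchmark 0.528"
```

The generated active arm sits at a higher coefficient of variation and a
lower scaling exponent, as configured. In this realization the windowed
mean comparison at weeks 10–14 is far from significance while the
cross-validated dynamics classifier is 29 points above the
no-information benchmark — the gap between the two analyses is the point
of the method: arm membership is visible in the shape and roughness of
the series even when mean contrasts drown in between-subject
heterogeneity.

`accuracy_vs_duration(cohort, seed = 1)` traces the same classifier over
truncated trials (13–52 weeks, recomputing all features per truncation)
against the benchmark, and `run_pipeline(run_config(synthetic = cfg,
seed = 1), "out/")` writes every stage output (cohort CSVs, feature
table, window tests, shuffle test, selection report, six-classifier
comparison, duration curve) plus a manifest with per-stage seeds and
file digests. A thin command-line front end with `simulate`, `features`,
`stats`, `select`, `classify`, `duration` and `all` subcommands is at
`inst/scripts/moodtrial-cli.R`.

## Documentation

The methods vignette (`vignettes/mood-arm-classification.Rmd`) describes
the estimators, the generator's design and what it does and does not
emulate, numerical edge-case policies, and known limitations.
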