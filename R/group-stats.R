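#' Two-sample t-test on per-subject window means
#'
#' For a window of weeks, every subject with at least one report inside
#' \[week_start, week_end\] contributes the mean of their reports in that
#' window; the two arms' per-subject means are compared with an
#' equal-variance pooled two-tailed t-test. The difference is reported
#' signed as active minus placebo with a symmetric 95% CI around it.
#'
#' @param cohort A `mood_cohort`.
#' @param week_start,week_end Window bounds in weeks (inclusive).
#' @return A one-row data.frame (class `window_test`): week_start,
#'   week_end, n_active, n_placebo, mean_difference, p_value, ci_low,
#'   ci_high, computable. When either arm has fewer than 2 subjects in the
#'   window the test is marked not computable (`computable = FALSE`, NA
#'   statistics) instead of erroring.
#' @export
window_ttest <- function(cohort, week_start, week_end) {
  stopifnot(inherits(cohort, "mood_cohort"), week_end >= week_start)
  r <- cohort$reports
  inw <- r$time_weeks >= week_start & r$time_weeks <= week_end
  means <- tapply(r$qids[inw], r$subject_id[inw], mean)
  arm <- cohort$subjects$arm[match(names(means), cohort$subjects$subject_id)]
  a <- as.numeric(means[arm == "active"])
  p <- as.numeric(means[arm == "placebo"])
  out <- data.frame(week_start = week_start, week_end = week_end,
                    n_active = length(a), n_placebo = length(p),
                    mean_difference = NA_real_, p_value = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    computable = FALSE)
  if (length(a) >= 2 && length(p) >= 2 &&
      (stats::sd(a) > 0 || stats::sd(p) > 0)) {
    tt <- stats::t.test(a, p, var.equal = TRUE, conf.level = 0.95)
    out$mean_difference <- unname(tt$estimate[1] - tt$estimate[2])
    out$p_value <- tt$p.value
    out$ci_low <- tt$conf.int[1]
    out$ci_high <- tt$conf.int[2]
    out$computable <- TRUE
  } else if (length(a) >= 2 && length(p) >= 2) {
    # both arms constant and equal-variance: define difference directly
    out$mean_difference <- mean(a) - mean(p)
    out$p_value <- if (mean(a) == mean(p)) 1 else 0
    out$ci_low <- out$ci_high <- out$mean_difference
    out$computable <- TRUE
  }
  class(out) <- c("window_test", "data.frame")
  out
}

#' Permutation null for the overall arm difference in mean scores
#'
#' The observed statistic is the difference (active minus placebo) between
#' the pooled means of all reported QIDS values. Subjects' arm labels are
#' then permuted uniformly `n_permutations` times, keeping each subject's
#' reports together, and the statistic recomputed, giving a null
#' distribution for "any two groups regardless of treatment". The
#' two-sided p-value is `(1 + #{|null| >= |observed|}) / (n_permutations + 1)`.
#'
#' @param cohort A `mood_cohort` with at least one subject with reports in
#'   each arm.
#' @param n_permutations Number of label permutations (>= 100).
#' @param seed Integer RNG seed.
#' @return List (class `shuffle_null`): `observed`, `null` (numeric vector),
#'   `p_value`, `n_permutations`, `seed`.
#' @export
shuffle_null <- function(cohort, n_permutations = 10000L, seed) {
  stopifnot(inherits(cohort, "mood_cohort"))
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  if (missing(seed)) stop("seed is required")
  r <- cohort$reports
  ids <- cohort$subjects$subject_id
  sums <- as.numeric(tapply(r$qids, factor(r$subject_id, levels = ids), sum))
  ns <- as.numeric(tapply(r$qids, factor(r$subject_id, levels = ids), length))
  sums[is.na(sums)] <- 0; ns[is.na(ns)] <- 0
  act <- cohort$subjects$arm == "active"
  if (sum(ns[act]) == 0 || sum(ns[!act]) == 0)
    stop("each arm needs at least one reported observation")
  gdiff <- function(is_active) {
    sum(sums[is_active]) / sum(ns[is_active]) -
      sum(sums[!is_active]) / sum(ns[!is_active])
  }
  observed <- gdiff(act)
  n_act <- sum(act)
  set.seed(as.integer(seed))
  null <- vapply(seq_len(n_permutations), function(i) {
    perm <- logical(length(ids))
    perm[sample(length(ids), n_act)] <- TRUE
    if (sum(ns[perm]) == 0 || sum(ns[!perm]) == 0) return(NA_real_)
    gdiff(perm)
  }, numeric(1))
  null <- null[!is.na(null)]
  p <- (1 + sum(abs(null) >= abs(observed))) / (length(null) + 1)
  structure(list(observed = observed, null = null, p_value = p,
                 n_permutations = n_permutations, seed = as.integer(seed)),
            class = "shuffle_null")
}

#' Per-arm linear trend of pooled scores over time
#'
#' Ordinary least-squares line fitted to all (time, qids) points pooled
#' within each arm.
#'
#' @param cohort A `mood_cohort`.
#' @return Data.frame (class `trend_fit`) with one row per arm: `arm`,
#'   `slope` (score units/week), `intercept` (score units). An arm with
#'   fewer than 2 distinct report times gets NA coefficients.
#' @export
trend_fit <- function(cohort) {
  stopifnot(inherits(cohort, "mood_cohort"))
  r <- cohort$reports
  arm_of <- cohort$subjects$arm[match(r$subject_id, cohort$subjects$subject_id)]
  rows <- lapply(c("active", "placebo"), function(a) {
    t <- r$time_weeks[arm_of == a]; q <- r$qids[arm_of == a]
    if (length(unique(t)) < 2)
      return(data.frame(arm = a, slope = NA_real_, intercept = NA_real_))
    co <- stats::coef(stats::lm(q ~ t))
    data.frame(arm = a, slope = unname(co[2]), intercept = unname(co[1]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("trend_fit", "data.frame")
  out
}

#' Expanding-window mean score per arm
#'
#' For each week n the curve value is the mean of every report in the arm
#' with time at most n; weeks without new reports simply keep accumulating
#' nothing.
#'
#' @param cohort A `mood_cohort`.
#' @param weeks Upper week of the sweep (default: ceiling of the last
#'   report time, or 52 for an empty cohort).
#' @return Long data.frame: `week`, `arm`, `mean_qids`, `n_reports`
#'   (reports contributing up to that week; NA mean when none yet).
#' @export
expanding_mean <- function(cohort, weeks = NULL) {
  stopifnot(inherits(cohort, "mood_cohort"))
  r <- cohort$reports
  if (is.null(weeks))
    weeks <- if (nrow(r)) as.integer(ceiling(max(r$time_weeks))) else 52L
  arm_of <- cohort$subjects$arm[match(r$subject_id, cohort$subjects$subject_id)]
  out <- lapply(c("active", "placebo"), function(a) {
    t <- r$time_weeks[arm_of == a]; q <- r$qids[arm_of == a]
    m <- vapply(seq_len(weeks), function(n) {
      sel <- t <= n
      c(mean = if (any(sel)) mean(q[sel]) else NA_real_,
        n = sum(sel))
    }, numeric(2))
    data.frame(week = seq_len(weeks), arm = a,
               mean_qids = m["mean", ], n_reports = as.integer(m["n", ]))
  })
  do.call(rbind, out)
}
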