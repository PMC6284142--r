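#' Truncate a cohort at a week limit
#'
#' Removes every report with time beyond `week_limit`; subjects are kept
#' even if their report list becomes empty.
#'
#' @param cohort A `mood_cohort`.
#' @param week_limit Week cutoff (>= 0); reports with `time_weeks >
#'   week_limit` are dropped.
#' @return A `mood_cohort`.
#' @export
truncate_cohort <- function(cohort, week_limit) {
  stopifnot(inherits(cohort, "mood_cohort"), week_limit >= 0)
  mood_cohort(cohort$subjects,
              cohort$reports[cohort$reports$time_weeks <= week_limit, ,
                             drop = FALSE])
}

#' No-information rate of a label vector
#'
#' The accuracy of always predicting the majority class: the maximum over
#' classes of the class fraction.
#'
#' @param labels Non-empty vector or factor of class labels.
#' @return A single rate in (0, 1\].
#' @examples
#' no_information_rate(rep(c("active", "placebo"), c(70, 68))) # 70/138
#' @export
no_information_rate <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) stop("labels must be non-empty")
  max(table(labels)) / length(labels)
}

#' Classification accuracy as a function of trial duration
#'
#' For each candidate duration w, the cohort is truncated at week w,
#' subjects with at least `min_reports` responses up to then are selected,
#' the features are recomputed from scratch on the truncated series (DFA
#' and spectral features depend on series length, so nothing is cached),
#' and the classifier's stratified 10-fold CV accuracy is compared with the
#' no-information benchmark of the selected subset. A week with fewer than
#' `min_subjects` eligible subjects (after dropping rows missing a used
#' feature) is marked not computable (NA accuracy).
#'
#' @param cohort A `mood_cohort`.
#' @param weeks Integer vector of durations to evaluate (default 13:52).
#' @param min_reports Eligibility threshold on responses (default 10).
#' @param features Feature columns for the classifier (default the
#'   two-feature set `c("cv", "dfa_alpha")`).
#' @param classifier Classifier kind (default `"logistic"`).
#' @param k CV folds (default 10).
#' @param seed Integer seed; the same seed is used at every duration, so
#'   the final week reproduces [cv_accuracy()] on the full cohort.
#' @param min_subjects Minimum eligible subjects per week (default 20).
#' @param se_mode `"fold_sd"` (default; SD of fold accuracies / sqrt(k)) or
#'   `"binomial"` (sqrt(acc (1-acc) / n)).
#' @param dfa_mode Passed to [build_feature_table()].
#' @return Data.frame (class `duration_curve`): `week`, `n_subjects`,
#'   `accuracy`, `se`, `no_information_rate`.
#' @export
accuracy_vs_duration <- function(cohort, weeks = 13:52, min_reports = 10L,
                                 features = c("cv", "dfa_alpha"),
                                 classifier = "logistic", k = 10L, seed,
                                 min_subjects = 20L,
                                 se_mode = c("fold_sd", "binomial"),
                                 dfa_mode = "index") {
  stopifnot(inherits(cohort, "mood_cohort"))
  if (missing(seed)) stop("seed is required")
  se_mode <- match.arg(se_mode)
  rows <- lapply(weeks, function(w) {
    trunc <- truncate_cohort(cohort, w)
    ft <- build_feature_table(trunc, min_reports = min_reports,
                              dfa_mode = dfa_mode)
    na_row <- data.frame(week = w, n_subjects = 0L, accuracy = NA_real_,
                         se = NA_real_, no_information_rate = NA_real_)
    if (nrow(ft) == 0) return(na_row)
    fm <- feature_matrix(ft, columns = features)
    n <- nrow(fm$x)
    na_row$n_subjects <- n
    if (n < min_subjects || nlevels(droplevels(fm$y)) < 2 || n < k)
      return(na_row)
    cvres <- cv_accuracy(classifier, fm$x, fm$y, k = k, seed = seed)
    se <- if (se_mode == "fold_sd") cvres$se_accuracy
          else sqrt(cvres$mean_accuracy * (1 - cvres$mean_accuracy) / n)
    data.frame(week = w, n_subjects = n, accuracy = cvres$mean_accuracy,
               se = se, no_information_rate = no_information_rate(fm$y))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("duration_curve", "data.frame")
  out
}
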