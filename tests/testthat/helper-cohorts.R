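# Hand-built cohort fixtures, constructed in code at test time.

subj_row <- function(id, arm, age = 40L, sex = "female", type = "I") {
  data.frame(subject_id = id, arm = arm, age = age, sex = sex,
             bipolar_type = type, stringsAsFactors = FALSE)
}

# One subject per row of `spec`, with the given qids vectors at integer
# weeks (asrm zero-filled).
hand_cohort <- function(qids_by_subject, arms) {
  ids <- names(qids_by_subject)
  subjects <- do.call(rbind, Map(subj_row, ids, arms))
  reports <- do.call(rbind, lapply(ids, function(id) {
    q <- qids_by_subject[[id]]
    if (!length(q)) return(NULL)
    data.frame(subject_id = id, time_weeks = seq_along(q), qids = q,
               asrm = 0L, stringsAsFactors = FALSE)
  }))
  mood_cohort(subjects, reports)
}

# Fully compliant two-arm cohort generated by the package with
# heterogeneity switched off unless overridden.
homogeneous_config <- function(...) {
  args <- list(...)
  defaults <- list(n_per_arm = 10L, weeks = 26L, report_prob = 1,
                   dropout_hazard = 0, between_subject_sd = 0,
                   sd_dispersion = 0, alpha_sd = 0, trend_sd = 0,
                   time_jitter_sd = 0, seed = 1L)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# Arms generated identically: no distributional or temporal contrast.
null_config <- function(...) {
  homogeneous_config(
    alpha_target = c(active = 1.0, placebo = 1.0),
    mean_target = c(active = 10, placebo = 10),
    sd_target = c(active = 3, placebo = 3),
    between_subject_sd = 4, sd_dispersion = 0.25, alpha_sd = 0.1,
    trend_sd = 0.05, time_jitter_sd = 0.29, report_prob = 0.7,
    dropout_hazard = 0.013, ...)
}
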