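#' Read a cohort from long-format CSV files
#'
#' Expects a reports table (columns subject_id, time_weeks, qids, asrm;
#' one row per self-report) and a subjects table (subject_id, arm, age,
#' sex, bipolar_type). Rows violating the score bounds (QIDS 0--27, ASRM
#' 0--25), referencing unknown subjects, or repeating a time within a
#' subject are rejected with line-numbered errors (line numbers count the
#' header as line 1).
#'
#' @param reports_csv Path to the reports CSV.
#' @param subjects_csv Path to the subjects CSV.
#' @return A [mood_cohort()].
#' @export
read_cohort <- function(reports_csv, subjects_csv) {
  reports <- utils::read.csv(reports_csv, stringsAsFactors = FALSE)
  subjects <- utils::read.csv(subjects_csv, stringsAsFactors = FALSE)
  req_r <- c("subject_id", "time_weeks", "qids", "asrm")
  req_s <- c("subject_id", "arm", "age", "sex", "bipolar_type")
  if (!all(req_r %in% names(reports)))
    stop(reports_csv, ": missing column(s) ",
         paste(setdiff(req_r, names(reports)), collapse = ", "))
  if (!all(req_s %in% names(subjects)))
    stop(subjects_csv, ": missing column(s) ",
         paste(setdiff(req_s, names(subjects)), collapse = ", "))
  line <- seq_len(nrow(reports)) + 1L # header is line 1
  errs <- character()
  bad <- !is.finite(reports$qids) | reports$qids < 0 | reports$qids > 27 |
    reports$qids != round(reports$qids)
  if (any(bad))
    errs <- c(errs, sprintf("line %d: qids=%s outside integer range [0, 27]",
                            line[bad], reports$qids[bad]))
  bad <- !is.finite(reports$asrm) | reports$asrm < 0 | reports$asrm > 25 |
    reports$asrm != round(reports$asrm)
  if (any(bad))
    errs <- c(errs, sprintf("line %d: asrm=%s outside integer range [0, 25]",
                            line[bad], reports$asrm[bad]))
  bad <- !(reports$subject_id %in% subjects$subject_id)
  if (any(bad))
    errs <- c(errs, sprintf("line %d: unknown subject_id '%s'",
                            line[bad], reports$subject_id[bad]))
  dup <- duplicated(reports[, c("subject_id", "time_weeks")])
  if (any(dup))
    errs <- c(errs, sprintf("line %d: duplicate report time for subject '%s'",
                            line[dup], reports$subject_id[dup]))
  if (length(errs))
    stop(reports_csv, ": invalid rows\n  ",
         paste(utils::head(errs, 10), collapse = "\n  "), call. = FALSE)
  mood_cohort(subjects, reports)
}

#' Write a cohort to long-format CSV files
#'
#' @param cohort A `mood_cohort`.
#' @param reports_csv,subjects_csv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, reports_csv, subjects_csv) {
  stopifnot(inherits(cohort, "mood_cohort"))
  utils::write.csv(cohort$reports, reports_csv, row.names = FALSE)
  utils::write.csv(cohort$subjects, subjects_csv, row.names = FALSE)
  invisible(c(reports = reports_csv, subjects = subjects_csv))
}

#' Assemble a pipeline run configuration
#'
#' Exactly one of `synthetic` (a [synthetic_config()]) or the pair
#' `reports_csv`/`subjects_csv` must be given. The global `seed` fans out
#' to fixed per-stage seeds (recorded in the manifest), so any stage can
#' be re-run in isolation.
#'
#' @param synthetic Optional [synthetic_config()].
#' @param reports_csv,subjects_csv Optional input CSV paths.
#' @param min_reports Compliance filter for the feature table (default 10).
#' @param freq_threshold Lomb band boundary in cycles/week (default 0.2).
#' @param folds CV folds (default 10).
#' @param n_permutations Shuffle-test permutations (default 10000).
#' @param classifier Classifier for the duration sweep (default logistic).
#' @param duration_weeks Weeks for the duration sweep (default 13:52).
#' @param windows List of `c(start, end)` week windows for the t-tests.
#' @param seed Global integer seed (required).
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = NULL, reports_csv = NULL,
                       subjects_csv = NULL, min_reports = 10L,
                       freq_threshold = 0.2, folds = 10L,
                       n_permutations = 10000L, classifier = "logistic",
                       duration_weeks = 13:52,
                       windows = list(c(1, 12), c(10, 14), c(20, 24),
                                      c(30, 34), c(40, 44), c(48, 52)),
                       seed) {
  if (missing(seed)) stop("seed is required")
  has_syn <- !is.null(synthetic)
  has_files <- !is.null(reports_csv) && !is.null(subjects_csv)
  if (has_syn == has_files)
    stop("exactly one of 'synthetic' or input CSV paths must be given")
  if (has_syn) stopifnot(inherits(synthetic, "synthetic_config"))
  structure(list(synthetic = synthetic, reports_csv = reports_csv,
                 subjects_csv = subjects_csv,
                 min_reports = as.integer(min_reports),
                 freq_threshold = freq_threshold, folds = as.integer(folds),
                 n_permutations = as.integer(n_permutations),
                 classifier = classifier, duration_weeks = duration_weeks,
                 windows = windows, seed = as.integer(seed)),
            class = "run_config")
}

## Fixed per-stage seed offsets from the global seed.
stage_seeds <- function(seed) {
  c(generate = seed, shuffle = seed + 11L, select = seed + 23L,
    classify = seed + 37L, duration = seed + 53L) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) the cohort, builds the feature table, runs the
#' classical group comparisons, the single-feature evaluation, both
#' feature-selection families, the six-classifier CV comparison, and the
#' duration sweep; writes every stage output as CSV/JSON under `out_dir`
#' together with a manifest recording the config, per-stage seeds, and
#' MD5 digests of each output file. Deterministic given the config.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(config$seed)
  outfile <- function(f) file.path(out_dir, f)
  files <- character()

  ## stage 1: cohort
  cohort <- if (!is.null(config$synthetic)) generate_cohort(config$synthetic)
            else read_cohort(config$reports_csv, config$subjects_csv)
  write_cohort(cohort, outfile("reports.csv"), outfile("subjects.csv"))
  files <- c(files, "reports.csv", "subjects.csv")

  ## stage 2: features
  features <- build_feature_table(cohort, min_reports = config$min_reports,
                                  freq_threshold = config$freq_threshold)
  utils::write.csv(features, outfile("features.csv"), row.names = FALSE,
                   na = "")
  files <- c(files, "features.csv")

  ## stage 3: classical group statistics
  wt <- do.call(rbind, lapply(config$windows, function(w)
    window_ttest(cohort, w[1], w[2])))
  utils::write.csv(wt, outfile("window_tests.csv"), row.names = FALSE)
  tr <- trend_fit(cohort)
  utils::write.csv(tr, outfile("trend.csv"), row.names = FALSE)
  em <- expanding_mean(cohort)
  utils::write.csv(em, outfile("expanding_mean.csv"), row.names = FALSE)
  sh <- shuffle_null(cohort, n_permutations = config$n_permutations,
                     seed = seeds[["shuffle"]])
  jsonlite::write_json(list(observed = sh$observed, p_value = sh$p_value,
                            n_permutations = sh$n_permutations,
                            seed = sh$seed),
                       outfile("shuffle_test.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, "window_tests.csv", "trend.csv", "expanding_mean.csv",
             "shuffle_test.json")

  ## stage 4: single-feature evaluation + selection
  fm_all <- feature_matrix(features)
  feat_eval <- do.call(rbind, lapply(colnames(fm_all$x), function(f) {
    v <- fm_all$x[, f]
    auc <- tryCatch(roc_curve(v, fm_all$y)$auc, error = function(e) NA_real_)
    acc <- tryCatch(cv_accuracy(config$classifier,
                                fm_all$x[, f, drop = FALSE], fm_all$y,
                                k = config$folds,
                                seed = seeds[["classify"]])$mean_accuracy,
                    error = function(e) NA_real_)
    data.frame(feature = f,
               mean_active = mean(v[fm_all$y == "active"]),
               mean_placebo = mean(v[fm_all$y == "placebo"]),
               auc = auc, cv_accuracy = acc)
  }))
  utils::write.csv(feat_eval, outfile("feature_evaluation.csv"),
                   row.names = FALSE)
  sels <- c(lapply(c("lasso", "elasticnet", "ridge"), function(pen)
    regularized_selection(fm_all$x, fm_all$y, penalty = pen,
                          seed = seeds[["select"]], nfolds = config$folds)),
    list(sequential_selection(fm_all$x, fm_all$y,
                              classifier = config$classifier,
                              seed = seeds[["select"]], k = config$folds)))
  sel_df <- do.call(rbind, lapply(sels, function(s)
    data.frame(method = s$method,
               selected = paste(s$selected_features, collapse = ";"))))
  utils::write.csv(sel_df, outfile("selection.csv"), row.names = FALSE)
  files <- c(files, "feature_evaluation.csv", "selection.csv")

  ## stage 5: classifier comparison on the two-feature and full sets
  fm2 <- feature_matrix(features, columns = c("cv", "dfa_alpha"))
  cmp <- do.call(rbind, lapply(CLASSIFIER_KINDS, function(kind) {
    r2 <- cv_accuracy(kind, fm2$x, fm2$y, k = config$folds,
                      seed = seeds[["classify"]])
    ra <- cv_accuracy(kind, fm_all$x, fm_all$y, k = config$folds,
                      seed = seeds[["classify"]])
    data.frame(classifier = kind,
               acc_two_features = r2$mean_accuracy,
               se_two_features = r2$se_accuracy,
               acc_all_features = ra$mean_accuracy,
               se_all_features = ra$se_accuracy)
  }))
  cmp$no_information_rate <- no_information_rate(fm2$y)
  utils::write.csv(cmp, outfile("model_comparison.csv"), row.names = FALSE)
  files <- c(files, "model_comparison.csv")

  ## stage 6: duration sweep
  dur <- accuracy_vs_duration(cohort, weeks = config$duration_weeks,
                              min_reports = config$min_reports,
                              classifier = config$classifier,
                              k = config$folds, seed = seeds[["duration"]])
  utils::write.csv(dur, outfile("duration_curve.csv"), row.names = FALSE)
  files <- c(files, "duration_curve.csv")

  manifest <- list(
    package = "moodtrial",
    package_version = as.character(utils::packageVersion("moodtrial")),
    r_version = as.character(getRversion()),
    global_seed = config$seed,
    stage_seeds = as.list(seeds),
    config = list(min_reports = config$min_reports,
                  freq_threshold = config$freq_threshold,
                  folds = config$folds,
                  n_permutations = config$n_permutations,
                  classifier = config$classifier,
                  synthetic = if (!is.null(config$synthetic))
                    unclass(config$synthetic) else NULL,
                  inputs = list(reports_csv = config$reports_csv,
                                subjects_csv = config$subjects_csv)),
    outputs = lapply(stats::setNames(files, files), function(f)
      list(path = f, md5 = unname(tools::md5sum(outfile(f)))))
  )
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(cohort = cohort, features = features, window_tests = wt,
                 trend = tr, expanding_mean = em, shuffle = sh,
                 feature_evaluation = feat_eval, selection = sels,
                 model_comparison = cmp, duration = dur,
                 manifest = manifest))
}
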