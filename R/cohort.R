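#' Configuration for the synthetic two-arm mood cohort generator
#'
#' Defines the generative conditions for a simulated two-arm trial in which
#' participants self-report a QIDS-SR16 depression score (integer, 0--27)
#' roughly once a week, with irregular report times, intermittent missed
#' reports and permanent dropout. Each arm has its own latent mean, SD and
#' DFA scaling exponent, so distributional (sigma/mu) and temporal (alpha)
#' arm contrasts can be switched on or off.
#'
#' The defaults emulate a 202-participant, 52-week trial in which the active
#' arm has a lower mean score, a larger SD (hence a higher coefficient of
#' variation) and a rougher, less persistent series (lower DFA alpha) than
#' the placebo arm, and overall compliance is about 60% at 12 weeks.
#'
#' @param n_per_arm Number of subjects per arm (>= 1).
#' @param weeks Trial length in weeks.
#' @param alpha_target Named numeric, DFA scaling exponent of the latent
#'   process per arm (`active`, `placebo`); each in (0, 2).
#' @param mean_target Named numeric, latent QIDS mean per arm, in score
#'   units within \[0, 27\].
#' @param sd_target Named numeric, latent QIDS SD per arm (> 0).
#' @param trend Named numeric, linear latent trend per arm in score units
#'   per week (default 0: no arm-level trend).
#' @param trend_sd SD (score units/week) of the per-subject linear trend
#'   around the arm trend (default 0.05, i.e. individual drifts of a few
#'   score points over a year, as participants improve or worsen at their
#'   own rates; 0 for trend-free series).
#' @param between_subject_sd SD (score units) of the per-subject latent
#'   mean around the arm target, truncated so subject means stay in
#'   \[1, 26\]. Default 5, reflecting the wide spread of baseline
#'   depression severity between participants; set 0 for homogeneous arms.
#' @param sd_dispersion Log-scale SD of the multiplicative per-subject
#'   spread of the within-subject SD around the arm target (default 0.25;
#'   0 for homogeneous).
#' @param alpha_sd SD of the per-subject scaling exponent around the arm
#'   target, truncated to (0.1, 1.9) (default 0.1; 0 for homogeneous).
#' @param report_prob Per-week probability of submitting a report, in (0, 1].
#' @param dropout_hazard Per-week probability of permanently stopping to
#'   report, in \[0, 1); dropout is absorbing.
#' @param time_jitter_sd SD (weeks) of the report-time offset within a
#'   week, truncated at +/- 0.45 weeks so report times stay strictly
#'   increasing. The default 0.29 matches a report submitted uniformly at
#'   any time during the week.
#' @param seed Integer RNG seed; the cohort is a pure function of the config.
#' @return An object of class `synthetic_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(n_per_arm = 5, weeks = 20, seed = 1)
#' coh <- generate_cohort(cfg)
#' nrow(coh$subjects)
#' @export
synthetic_config <- function(n_per_arm = 101L,
                             weeks = 52L,
                             alpha_target = c(active = 0.7, placebo = 1.0),
                             mean_target = c(active = 9, placebo = 11.2),
                             sd_target = c(active = 4, placebo = 3),
                             trend = c(active = 0, placebo = 0),
                             trend_sd = 0.05,
                             between_subject_sd = 5,
                             sd_dispersion = 0.25,
                             alpha_sd = 0.1,
                             report_prob = 0.7,
                             dropout_hazard = 0.013,
                             time_jitter_sd = 0.29,
                             seed = 1L) {
  arm_par <- function(x, nm) {
    if (length(x) == 1L && is.null(names(x))) x <- c(active = x, placebo = x)
    if (!all(c("active", "placebo") %in% names(x)))
      stop(sprintf("'%s' must be named with elements 'active' and 'placebo'", nm))
    x[c("active", "placebo")]
  }
  alpha_target <- arm_par(alpha_target, "alpha_target")
  mean_target <- arm_par(mean_target, "mean_target")
  sd_target <- arm_par(sd_target, "sd_target")
  trend <- arm_par(trend, "trend")
  if (n_per_arm < 1) stop("n_per_arm must be >= 1")
  if (weeks < 1) stop("weeks must be >= 1")
  if (!(report_prob > 0 && report_prob <= 1)) stop("report_prob must be in (0, 1]")
  if (!(dropout_hazard >= 0 && dropout_hazard < 1)) stop("dropout_hazard must be in [0, 1)")
  if (any(alpha_target <= 0 | alpha_target >= 2)) stop("alpha_target must be in (0, 2)")
  if (any(mean_target < 0 | mean_target > 27)) stop("mean_target must be in [0, 27]")
  if (any(sd_target <= 0)) stop("sd_target must be > 0")
  if (time_jitter_sd < 0) stop("time_jitter_sd must be >= 0")
  if (between_subject_sd < 0 || sd_dispersion < 0 || alpha_sd < 0 ||
      trend_sd < 0)
    stop("heterogeneity SDs must be >= 0")
  structure(list(
    n_per_arm = as.integer(n_per_arm), weeks = as.integer(weeks),
    alpha_target = alpha_target, mean_target = mean_target,
    sd_target = sd_target, trend = trend, trend_sd = trend_sd,
    between_subject_sd = between_subject_sd,
    sd_dispersion = sd_dispersion, alpha_sd = alpha_sd,
    report_prob = report_prob, dropout_hazard = dropout_hazard,
    time_jitter_sd = time_jitter_sd, seed = as.integer(seed)
  ), class = "synthetic_config")
}

## Colored noise from the current RNG stream: spectral synthesis with
## amplitude ~ f^(-beta/2), beta = 2*alpha - 1, random phases, inverse FFT.
.colored_noise <- function(n, alpha_target) {
  beta <- 2 * alpha_target - 1
  nf <- n %/% 2L
  f <- (1:nf) / n
  amp <- f^(-beta / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  coefs <- complex(modulus = amp, argument = ph)
  if (n %% 2L == 0L) # Nyquist coefficient must be real for a real series
    coefs[nf] <- complex(real = amp[nf] * cos(ph[nf]), imaginary = 0)
  spec <- complex(real = rep(0, n))
  spec[1L + (1:nf)] <- coefs
  spec[n + 1L - (1:nf)] <- Conj(coefs) # for even n the Nyquist bin maps to itself
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Generate colored noise with a prescribed DFA scaling exponent
#'
#' Spectral synthesis: Fourier amplitudes proportional to f^(-beta/2) with
#' beta = 2 * alpha_target - 1 and i.i.d. uniform random phases, inverse
#' transformed to the time domain. alpha_target = 0.5 gives white noise,
#' 1.0 pink (1/f) noise, and 1.5 a random walk. The returned series has
#' zero mean and unit sample SD.
#'
#' @param n Series length (>= 16).
#' @param alpha_target Target DFA scaling exponent, in (0, 2).
#' @param seed Integer RNG seed; the series is a pure function of
#'   `(n, alpha_target, seed)`.
#' @return Numeric vector of length `n`.
#' @seealso [dfa_alpha()] for estimating the exponent back.
#' @examples
#' x <- generate_colored_noise(1024, alpha_target = 1.0, seed = 7)
#' dfa_alpha(x)$alpha # close to 1
#' @export
generate_colored_noise <- function(n, alpha_target, seed) {
  if (n < 16) stop("n must be >= 16")
  if (!(alpha_target > 0 && alpha_target < 2)) stop("alpha_target must be in (0, 2)")
  set.seed(as.integer(seed))
  .colored_noise(as.integer(n), alpha_target)
}

#' Generate one synthetic subject
#'
#' The subject's latent mean and scaling exponent are first drawn around
#' the arm targets (truncated Gaussians with the configured heterogeneity
#' SDs). The subject's within-series SD scales with their own mean: the
#' arm fixes the coefficient of variation `sd_target / mean_target`, and
#' `sd_i = cv_arm * mean_i * lognormal(0, sd_dispersion)` — the
#' distributional arm contrast lives in sigma/mu, with dispersion growing
#' with severity. The latent weekly trajectory is `mean_i + sd_i * colored
#' noise at alpha_i + trend * (week - 1)`; the reported QIDS value is the
#' latent value rounded to the nearest integer and clipped to \[0, 27\]. Each week is
#' reported with probability `report_prob` until a permanent dropout event
#' (geometric with `dropout_hazard`); the week-w report time is
#' `w - 0.5 + jitter` with truncated Gaussian jitter, so a report falls
#' strictly inside its own week and times stay strictly increasing. ASRM is
#' filled with low-information noise in \[0, 25\] carrying no arm signal.
#'
#' @param config A [synthetic_config()].
#' @param arm `"active"` or `"placebo"`.
#' @param subject_id Identifier string.
#' @param seed Integer RNG seed for this subject.
#' @return A list with `subject` (one-row data.frame: subject_id, arm, age,
#'   sex, bipolar_type) and `observations` (data.frame: time_weeks, qids,
#'   asrm, strictly time-ordered; possibly zero rows).
#' @export
generate_subject <- function(config, arm = c("active", "placebo"), subject_id, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  arm <- match.arg(arm)
  set.seed(as.integer(seed))
  w <- config$weeks
  mean_i <- min(26, max(1, config$mean_target[[arm]] +
                          stats::rnorm(1, 0, config$between_subject_sd)))
  ## dispersion scales with the subject's own severity: the arm controls
  ## the coefficient of variation sigma/mu, not the SD directly
  cv_arm <- config$sd_target[[arm]] / config$mean_target[[arm]]
  sd_i <- cv_arm * mean_i * exp(stats::rnorm(1, 0, config$sd_dispersion))
  alpha_i <- min(1.9, max(0.1, config$alpha_target[[arm]] +
                            stats::rnorm(1, 0, config$alpha_sd)))
  trend_i <- config$trend[[arm]] + stats::rnorm(1, 0, config$trend_sd)
  noise <- .colored_noise(max(w, 16L), alpha_i)[seq_len(w)]
  latent <- mean_i + sd_i * noise + trend_i * (seq_len(w) - 1)
  qids <- pmin(27L, pmax(0L, as.integer(round(latent))))

  ## compliance: absorbing dropout, then intermittent missingness
  last_week <- if (config$dropout_hazard > 0)
    1L + stats::rgeom(1L, config$dropout_hazard) else w
  reported <- seq_len(w) <= last_week &
    stats::runif(w) <= config$report_prob

  jit <- stats::rnorm(w, 0, config$time_jitter_sd)
  jit <- pmin(0.45, pmax(-0.45, jit)) # keep report times strictly increasing
  times <- seq_len(w) - 0.5 + jit # a report lands inside its own week
  asrm <- pmin(25L, pmax(0L, as.integer(stats::rpois(w, 2))))

  obs <- data.frame(
    time_weeks = times[reported],
    qids = qids[reported],
    asrm = asrm[reported]
  )
  subject <- data.frame(
    subject_id = subject_id, arm = arm,
    age = as.integer(round(stats::runif(1, 18, 70))),
    sex = sample(c("male", "female"), 1L),
    bipolar_type = sample(c("I", "II"), 1L, prob = c(149, 53)),
    stringsAsFactors = FALSE
  )
  list(subject = subject, observations = obs)
}

#' Generate a full two-arm synthetic cohort
#'
#' Produces `n_per_arm` subjects per arm with per-subject seeds derived
#' deterministically from `config$seed`, so two calls with the same config
#' give identical cohorts.
#'
#' @param config A [synthetic_config()].
#' @return A [mood_cohort()] object.
#' @examples
#' coh <- generate_cohort(synthetic_config(n_per_arm = 3, weeks = 12, seed = 9))
#' table(coh$subjects$arm)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  arms <- rep(c("active", "placebo"), each = config$n_per_arm)
  ids <- sprintf("S%03d", seq_along(arms))
  subs <- vector("list", length(arms))
  reps <- vector("list", length(arms))
  for (i in seq_along(arms)) {
    sseed <- (config$seed + 104729 * i) %% 2147483647L
    s <- generate_subject(config, arms[i], ids[i], seed = sseed)
    subs[[i]] <- s$subject
    if (nrow(s$observations) > 0)
      reps[[i]] <- cbind(subject_id = ids[i], s$observations)
  }
  mood_cohort(
    subjects = do.call(rbind, subs),
    reports = do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  )
}

#' Construct a mood cohort container
#'
#' A cohort is a pair of data frames: `subjects` (one row per participant:
#' subject_id, arm, age, sex, bipolar_type) and `reports` (long format, one
#' row per self-report: subject_id, time_weeks, qids, asrm). Score bounds
#' (QIDS 0--27, ASRM 0--25) and strict within-subject time ordering are
#' enforced at construction.
#'
#' @param subjects Subject-level data.frame.
#' @param reports Long-format report data.frame (may have zero rows).
#' @return An object of class `mood_cohort`.
#' @export
mood_cohort <- function(subjects, reports) {
  req_s <- c("subject_id", "arm", "age", "sex", "bipolar_type")
  req_r <- c("subject_id", "time_weeks", "qids", "asrm")
  if (is.null(reports) || nrow(reports) == 0)
    reports <- data.frame(subject_id = character(), time_weeks = numeric(),
                          qids = integer(), asrm = integer())
  if (!all(req_s %in% names(subjects)))
    stop("subjects must have columns: ", paste(req_s, collapse = ", "))
  if (!all(req_r %in% names(reports)))
    stop("reports must have columns: ", paste(req_r, collapse = ", "))
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id in subjects table")
  if (!all(subjects$arm %in% c("active", "placebo")))
    stop("arm must be 'active' or 'placebo'")
  bad <- which(!(reports$qids >= 0 & reports$qids <= 27))
  if (length(bad)) stop("qids out of [0, 27] at report row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!(reports$asrm >= 0 & reports$asrm <= 25))
  if (length(bad)) stop("asrm out of [0, 25] at report row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  if (!all(reports$subject_id %in% subjects$subject_id))
    stop("reports reference unknown subject_id")
  reports <- reports[order(match(reports$subject_id, subjects$subject_id),
                           reports$time_weeks), , drop = FALSE]
  rownames(reports) <- NULL
  for (id in unique(reports$subject_id)) {
    tt <- reports$time_weeks[reports$subject_id == id]
    if (any(diff(tt) <= 0))
      stop("non-increasing or duplicate report times for subject ", id)
  }
  structure(list(subjects = subjects[, req_s], reports = reports[, req_r]),
            class = "mood_cohort")
}

#' @export
print.mood_cohort <- function(x, ...) {
  cat(sprintf("<mood_cohort> %d subjects (%d active / %d placebo), %d reports\n",
              nrow(x$subjects),
              sum(x$subjects$arm == "active"),
              sum(x$subjects$arm == "placebo"),
              nrow(x$reports)))
  invisible(x)
}

#' Per-subject QIDS series from a cohort
#'
#' @param cohort A `mood_cohort`.
#' @param subject_id Subject identifier.
#' @return A data.frame with `time_weeks` and `qids`, time-ordered.
#' @export
qids_series <- function(cohort, subject_id) {
  r <- cohort$reports[cohort$reports$subject_id == subject_id, , drop = FALSE]
  r[order(r$time_weeks), c("time_weeks", "qids")]
}
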