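#' Distributional summary statistics of a score series
#'
#' Sample mean, SD (n-1 denominator), coefficient of variation (sd/mean),
#' skewness and excess kurtosis. Skewness and kurtosis use bias-uncorrected
#' central sample moments: skew = m3 / m2^(3/2), kurtosis = m4 / m2^2 - 3,
#' so a normal sample has kurtosis near 0. Moments that cannot be computed
#' are returned as `NA`: sd needs >= 2 points, skewness >= 3, kurtosis >= 4;
#' a constant series has sd = 0, cv = 0 and undefined shape moments; a zero
#' mean with positive sd leaves cv undefined (`NA`), never infinite.
#'
#' @param x Numeric series.
#' @return Named list: `mean`, `sd`, `cv`, `skewness`, `kurtosis`.
#' @examples
#' summary_stats(c(1, 2, 3)) # mean 2, sd 1, cv 0.5, skewness 0
#' @export
summary_stats <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  m <- if (n >= 1) mean(x) else NA_real_
  s <- if (n >= 2) stats::sd(x) else NA_real_
  cv <- if (is.na(s)) NA_real_
        else if (s == 0) 0
        else if (m == 0) NA_real_ # undefined, flagged missing
        else s / m
  m2 <- mean((x - m)^2)
  skew <- if (n >= 3 && !is.na(s) && s > 0) mean((x - m)^3) / m2^1.5 else NA_real_
  kurt <- if (n >= 4 && !is.na(s) && s > 0) mean((x - m)^4) / m2^2 - 3 else NA_real_
  list(mean = m, sd = s, cv = cv, skewness = skew, kurtosis = kurt)
}

#' Classical Lomb normalized periodogram for unevenly sampled series
#'
#' Least-squares spectral power of a (possibly unevenly sampled) series at
#' the requested frequencies, in the classical Lomb normalization: at each
#' frequency the best-fitting sinusoid's power is divided by twice the
#' sample variance (n-1 denominator). Values are mean-centered internally,
#' so the estimate is invariant to adding a constant to all values and to a
#' global time shift. Under even sampling at Fourier frequencies it reduces
#' to the classical periodogram |DFT|^2 / (n * var).
#'
#' @param times Strictly increasing sample times (weeks).
#' @param values Scores at `times`.
#' @param frequencies Frequency grid in cycles/week; default 0.01 to 0.5
#'   (the Nyquist frequency of weekly sampling) in steps of 0.01.
#' @return Object of class `periodogram`: list with `frequencies` and
#'   non-negative `powers`.
#' @examples
#' t <- 1:52
#' p <- lomb_periodogram(t, cos(2 * pi * 0.1 * t))
#' p$frequencies[which.max(p$powers)] # 0.1
#' @export
lomb_periodogram <- function(times, values,
                             frequencies = seq(0.01, 0.5, by = 0.01)) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (length(times) < 4) stop("lomb_periodogram needs at least 4 observations")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing (no duplicates)")
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  y <- values - mean(values)
  v <- sum(y^2) / (length(y) - 1)
  if (v == 0) {
    powers <- rep(0, length(frequencies))
  } else {
    t0 <- times - times[1]
    powers <- vapply(frequencies, function(f) {
      w <- 2 * pi * f
      tau <- atan2(sum(sin(2 * w * t0)), sum(cos(2 * w * t0))) / (2 * w)
      ct <- cos(w * (t0 - tau)); st <- sin(w * (t0 - tau))
      cc <- sum(ct^2); ss <- sum(st^2)
      # a basis vector with numerically vanishing norm (e.g. the sine at
      # the Nyquist frequency of integer sampling) carries no power
      eps <- length(y) * 1e-10
      pc <- if (cc > eps) sum(y * ct)^2 / cc else 0
      ps <- if (ss > eps) sum(y * st)^2 / ss else 0
      (pc + ps) / (2 * v)
    }, numeric(1))
  }
  structure(list(frequencies = frequencies, powers = powers),
            class = "periodogram")
}

#' Low/high frequency band powers from a periodogram
#'
#' Splits spectral power at a frequency threshold: the low band includes
#' the threshold itself (f <= threshold), the high band is f > threshold.
#'
#' @param p A [lomb_periodogram()] result.
#' @param threshold Band boundary in cycles/week (default 0.2).
#' @return Named list: `power_low`, `power_high`, `power_ratio`
#'   (high/low; `NA` when the low band has zero power).
#' @export
band_powers <- function(p, threshold = 0.2) {
  stopifnot(inherits(p, "periodogram"))
  low <- sum(p$powers[p$frequencies <= threshold])
  high <- sum(p$powers[p$frequencies > threshold])
  ratio <- if (low > 0) high / low else NA_real_
  list(power_low = low, power_high = high, power_ratio = ratio)
}

#' Detrended fluctuation analysis scaling exponent
#'
#' Standard first-order DFA: the mean-centered series is integrated into a
#' profile; for each box size n the profile is partitioned into
#' non-overlapping boxes starting from both the beginning and the end of
#' the series (so the truncated remainder is not wasted), a least-squares
#' line is removed per box, and F(n) is the RMS residual over all covered
#' points. The scaling exponent alpha is the slope of log F(n) against
#' log n. White noise gives alpha near
#' 0.5, pink (1/f) noise near 1.0 and a random walk near 1.5.
#'
#' Box sizes are about `n_box_sizes` log-spaced integers between `box_min`
#' and `box_max` (default 4 to N/4). The fit needs at least 3 distinct box
#' sizes with positive F(n); otherwise (series shorter than 10 points, or
#' a degenerate series such as a constant whose detrended residuals all
#' vanish) `alpha` is returned as `NA` rather than an error, so callers
#' can flag the feature missing.
#'
#' @param x Numeric series, treated as evenly indexed in report order.
#' @param box_min Smallest box size (default 4).
#' @param box_max Largest box size (default `floor(length(x)/4)`).
#' @param n_box_sizes Target number of log-spaced box sizes (default 10).
#' @return Object of class `dfa_result`: list with `box_sizes`,
#'   `fluctuations`, `alpha` and `fit_r2`.
#' @examples
#' set.seed(1)
#' dfa_alpha(cumsum(rnorm(2048)))$alpha # near 1.5
#' @export
dfa_alpha <- function(x, box_min = 4L, box_max = NULL, n_box_sizes = 10L) {
  x <- as.numeric(x)
  N <- length(x)
  empty <- structure(list(box_sizes = integer(), fluctuations = numeric(),
                          alpha = NA_real_, fit_r2 = NA_real_),
                     class = "dfa_result")
  if (N < 10) return(empty)
  if (is.null(box_max)) box_max <- N %/% 4L
  if (box_max < box_min) return(empty)
  sizes <- unique(as.integer(round(exp(
    seq(log(box_min), log(box_max), length.out = n_box_sizes)))))
  sizes <- sizes[sizes >= box_min & sizes <= box_max]
  if (length(sizes) < 3) return(empty)
  Y <- cumsum(x - mean(x))
  box_resid <- function(Yv, s) {
    mat <- matrix(Yv, nrow = s)
    tc <- seq_len(s) - (s + 1) / 2
    slope <- colSums(mat * tc) / sum(tc^2)
    mat - outer(tc, slope) - rep(colMeans(mat), each = s)
  }
  flucts <- vapply(sizes, function(s) {
    m <- N %/% s
    r <- box_resid(Y[seq_len(s * m)], s)
    if (s * m < N) # cover the tail with boxes anchored at the series end
      r <- c(r, box_resid(Y[(N - s * m + 1):N], s))
    sqrt(mean(r^2))
  }, numeric(1))
  keep <- flucts > 0
  if (sum(keep) < 3)
    return(structure(list(box_sizes = sizes, fluctuations = flucts,
                          alpha = NA_real_, fit_r2 = NA_real_),
                     class = "dfa_result"))
  lx <- log(sizes[keep]); ly <- log(flucts[keep])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  structure(list(box_sizes = sizes, fluctuations = flucts,
                 alpha = unname(fit$coefficients[2]), fit_r2 = r2),
            class = "dfa_result")
}

## Series fed to DFA for one subject. "index": retained reports in time
## order as a contiguous sequence. "snap": reports snapped to their nominal
## integer week, duplicates within a week averaged, empty weeks skipped.
.dfa_series <- function(times, qids, mode = c("index", "snap")) {
  mode <- match.arg(mode)
  if (mode == "index") return(qids)
  wk <- ceiling(times - 1e-9) # nominal week of each report
  as.numeric(tapply(qids, wk, mean)) # tapply sorts the unique weeks
}

#' Build the per-subject feature table for a cohort
#'
#' Computes, for every subject with at least `min_reports` reports, the
#' distributional features (mean, SD, coefficient of variation, skewness,
#' excess kurtosis), the Lomb band powers at the given frequency threshold,
#' the DFA scaling exponent, and carries the demographic covariates.
#' Subjects below the report threshold are excluded and counted in the
#' `n_excluded` attribute. Features that cannot be computed for a subject
#' (too few points, degenerate series) are `NA`; downstream models drop
#' such subjects only when they use the affected feature.
#'
#' @param cohort A `mood_cohort`.
#' @param min_reports Minimum number of reports for inclusion (default 10,
#'   the stricter of the two compliance subsets used in practice; 5 gives
#'   the lenient subset).
#' @param freq_threshold Band boundary for [band_powers()] (cycles/week).
#' @param frequencies Lomb frequency grid.
#' @param dfa_mode How uneven sampling is handled before DFA: `"index"`
#'   (default) treats retained reports as a contiguous sequence; `"snap"`
#'   averages reports within their nominal integer week first.
#' @return A data.frame (class `feature_table`) with one row per retained
#'   subject and columns subject_id, arm, age, sex, bipolar_type,
#'   n_reports, mean_qids, sd_qids, cv, skewness, kurtosis, power_low,
#'   power_high, power_ratio, dfa_alpha. Attribute `n_excluded` counts
#'   subjects filtered out. An empty cohort after filtering yields a
#'   zero-row table, not an error.
#' @export
build_feature_table <- function(cohort, min_reports = 10L,
                                freq_threshold = 0.2,
                                frequencies = seq(0.01, 0.5, by = 0.01),
                                dfa_mode = c("index", "snap")) {
  stopifnot(inherits(cohort, "mood_cohort"), min_reports >= 1)
  dfa_mode <- match.arg(dfa_mode)
  counts <- table(factor(cohort$reports$subject_id,
                         levels = cohort$subjects$subject_id))
  keep <- cohort$subjects$subject_id[counts >= min_reports]
  rows <- lapply(keep, function(id) {
    ser <- qids_series(cohort, id)
    st <- summary_stats(ser$qids)
    bp <- if (nrow(ser) >= 4) {
      band_powers(lomb_periodogram(ser$time_weeks, ser$qids, frequencies),
                  freq_threshold)
    } else list(power_low = NA_real_, power_high = NA_real_, power_ratio = NA_real_)
    v <- .dfa_series(ser$time_weeks, ser$qids, dfa_mode)
    # short subject series: extend the box ceiling to N/2 so the handful
    # of large-scale boxes is not discarded (halves the estimator SD below
    # ~50 points; indistinguishable from N/4 on long series)
    a <- dfa_alpha(v, box_max = max(4L, length(v) %/% 2L))$alpha
    sub <- cohort$subjects[cohort$subjects$subject_id == id, ]
    data.frame(subject_id = id, arm = sub$arm, age = sub$age, sex = sub$sex,
               bipolar_type = sub$bipolar_type, n_reports = nrow(ser),
               mean_qids = st$mean, sd_qids = st$sd, cv = st$cv,
               skewness = st$skewness, kurtosis = st$kurtosis,
               power_low = bp$power_low, power_high = bp$power_high,
               power_ratio = bp$power_ratio, dfa_alpha = a,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), arm = character(), age = integer(),
               sex = character(), bipolar_type = character(),
               n_reports = integer(), mean_qids = numeric(),
               sd_qids = numeric(), cv = numeric(), skewness = numeric(),
               kurtosis = numeric(), power_low = numeric(),
               power_high = numeric(), power_ratio = numeric(),
               dfa_alpha = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- nrow(cohort$subjects) - length(keep)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Numeric model matrix from a feature table
#'
#' Encodes the feature columns used for selection and classification as a
#' numeric matrix: sex as `sex_male` (1 = male), bipolar type as `type_I`
#' (1 = type I). `n_reports` is bookkeeping, not a candidate feature.
#'
#' @param features A [build_feature_table()] result.
#' @param columns Candidate feature names; default all candidates.
#' @param complete Drop rows with any `NA` among `columns` (default TRUE).
#' @return List with `x` (matrix), `y` (factor placebo/active) and
#'   `subject_id`; attribute `n_dropped` counts rows removed for
#'   missingness.
#' @export
feature_matrix <- function(features,
                           columns = c("mean_qids", "sd_qids", "cv",
                                       "skewness", "kurtosis", "power_low",
                                       "power_high", "power_ratio",
                                       "dfa_alpha", "age", "sex_male",
                                       "type_I"),
                           complete = TRUE) {
  df <- as.data.frame(features)
  df$sex_male <- as.numeric(df$sex == "male")
  df$type_I <- as.numeric(df$bipolar_type == "I")
  missing_cols <- setdiff(columns, names(df))
  if (length(missing_cols))
    stop("unknown feature column(s): ", paste(missing_cols, collapse = ", "))
  x <- as.matrix(df[, columns, drop = FALSE])
  ok <- if (complete) stats::complete.cases(x) else rep(TRUE, nrow(x))
  y <- factor(df$arm, levels = c("placebo", "active"))
  out <- list(x = x[ok, , drop = FALSE], y = y[ok],
              subject_id = df$subject_id[ok])
  attr(out, "n_dropped") <- sum(!ok)
  out
}
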