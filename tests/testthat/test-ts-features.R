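test_that("summary statistics match hand-computed moments", {
  s <- summary_stats(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$cv, 0.5)
  expect_equal(s$skewness, 0)

  # x = (3, 7, 7, 19): deviations (-6, -2, -2, 10);
  # sd = sqrt(144/3); m2 = 36, m3 = 192, m4 = 2832
  s2 <- summary_stats(c(3, 7, 7, 19))
  expect_equal(s2$mean, 9)
  expect_equal(s2$sd, sqrt(48))
  expect_equal(s2$cv, sqrt(48) / 9)
  expect_equal(s2$skewness, 192 / 36^1.5)
  expect_equal(s2$kurtosis, 2832 / 36^2 - 3)
})

test_that("degenerate series flag rather than blow up", {
  s <- summary_stats(c(5, 5, 5, 5))
  expect_equal(s$sd, 0)
  expect_equal(s$cv, 0)
  expect_true(is.na(s$skewness))
  expect_true(is.na(s$kurtosis))

  # zero mean with positive sd: cv undefined, flagged missing
  s2 <- summary_stats(c(-1, 0, 1))
  expect_true(is.na(s2$cv))

  expect_true(is.na(summary_stats(c(4))$sd))
})

test_that("cv is invariant under positive rescaling of the series", {
  set.seed(11)
  for (i in 1:20) {
    x <- rpois(15, 8) + 1
    k <- runif(1, 0.1, 50)
    expect_equal(summary_stats(k * x)$cv, summary_stats(x)$cv,
                 tolerance = 1e-12)
  }
})

test_that("Lomb periodogram reduces to the classical periodogram under even sampling", {
  set.seed(3)
  n <- 64
  t <- 1:n
  y <- cos(2 * pi * 0.1 * t) + rnorm(n, 0, 0.5)
  fk <- (1:(n / 2 - 1)) / n # Fourier frequencies below Nyquist
  p <- lomb_periodogram(t, y, fk)$powers
  yc <- y - mean(y)
  classical <- abs(fft(yc))[2:(n / 2)]^2 / (n * sum(yc^2) / (n - 1))
  expect_equal(p, classical, tolerance = 1e-6)
})

test_that("Lomb power equals the least-squares sinusoid fit at every frequency", {
  set.seed(9)
  t <- sort(sample(seq(1, 52, by = 0.5), 30))
  y <- 10 + 3 * cos(2 * pi * 0.1 * t + 0.7) + rnorm(30)
  freqs <- seq(0.02, 0.48, by = 0.02)
  p <- lomb_periodogram(t, y, freqs)$powers
  oracle <- vapply(freqs, function(f) ls_sinusoid_power(t, y, f), numeric(1))
  expect_equal(p, oracle, tolerance = 1e-8)
})

test_that("Lomb peak localization survives uneven sampling and invariances hold", {
  t_full <- 1:52
  y_full <- cos(2 * pi * 0.1 * t_full)
  p_full <- lomb_periodogram(t_full, y_full)
  expect_equal(p_full$frequencies[which.max(p_full$powers)], 0.1)

  set.seed(5) # delete 30% of weeks
  keep <- sort(sample(52, 36))
  p_gap <- lomb_periodogram(t_full[keep], y_full[keep])
  expect_lt(abs(p_gap$frequencies[which.max(p_gap$powers)] - 0.1), 0.021)

  # value-offset and time-shift invariance
  p_off <- lomb_periodogram(t_full[keep] + 13.7, y_full[keep] + 42)
  expect_equal(p_gap$powers, p_off$powers, tolerance = 1e-9)

  # constant series has zero power everywhere
  p0 <- lomb_periodogram(1:10, rep(7, 10))
  expect_true(all(p0$powers == 0))

  expect_error(lomb_periodogram(c(1, 2, 2, 3), c(1, 2, 3, 4)), "increasing")
  expect_error(lomb_periodogram(1:3, 1:3), "at least 4")
})

test_that("band powers split at an inclusive threshold", {
  p <- structure(list(frequencies = c(0.1, 0.2, 0.3),
                      powers = c(2, 3, 5)), class = "periodogram")
  bp <- band_powers(p, threshold = 0.2)
  expect_equal(bp$power_low, 5) # 0.2 itself counted low
  expect_equal(bp$power_high, 5)
  expect_equal(bp$power_ratio, 1)

  all_low <- band_powers(structure(list(frequencies = 0.1, powers = 4),
                                   class = "periodogram"))
  expect_equal(all_low$power_high, 0)
  expect_equal(all_low$power_ratio, 0)

  none_low <- band_powers(structure(list(frequencies = 0.4, powers = 4),
                                    class = "periodogram"))
  expect_true(is.na(none_low$power_ratio))
})

test_that("dfa_alpha matches an independent loop-based implementation exactly", {
  set.seed(17)
  for (n in c(64, 200)) {
    x <- cumsum(rnorm(n))
    got <- dfa_alpha(x)
    expect_equal(got$alpha, naive_dfa(x), tolerance = 1e-10)
    expect_true(all(diff(got$box_sizes) > 0))
    expect_true(all(got$fluctuations >= 0))
    expect_gt(got$fit_r2, 0.9)
  }
})

test_that("dfa_alpha recovers canonical exponents for canonical processes", {
  white <- vapply(1:5, function(s) {
    set.seed(s); dfa_alpha(rnorm(4096))$alpha }, numeric(1))
  expect_equal(mean(white), 0.5, tolerance = 0.1)
  walk <- vapply(1:5, function(s) {
    set.seed(s); dfa_alpha(cumsum(rnorm(4096)))$alpha }, numeric(1))
  expect_equal(mean(walk), 1.5, tolerance = 0.1)
  pink <- vapply(1:5, function(s)
    dfa_alpha(generate_colored_noise(4096, 1.0, seed = s))$alpha, numeric(1))
  expect_equal(mean(pink), 1.0, tolerance = 0.1)
})

test_that("dfa_alpha flags degenerate and too-short inputs as missing", {
  expect_true(is.na(dfa_alpha(rnorm(8))$alpha))            # below 10 points
  expect_true(is.na(dfa_alpha(rep(3, 40))$alpha))          # constant
  set.seed(1)
  expect_false(is.na(dfa_alpha(rnorm(40))$alpha))
})

test_that("feature table filters by report count like a direct count oracle", {
  coh <- generate_cohort(synthetic_config(n_per_arm = 30L, weeks = 26L,
                                          seed = 8L))
  for (mr in c(5L, 10L)) {
    ft <- build_feature_table(coh, min_reports = mr)
    oracle_keep <- names(which(table(coh$reports$subject_id) >= mr))
    expect_setequal(ft$subject_id, oracle_keep)
    expect_equal(attr(ft, "n_excluded"),
                 nrow(coh$subjects) - length(oracle_keep))
  }

  # boundary: a 9-report subject is excluded at min_reports = 10
  coh2 <- hand_cohort(list(A = rpois(9, 8), B = rpois(12, 8)),
                      arms = c("active", "placebo"))
  ft2 <- build_feature_table(coh2, min_reports = 10)
  expect_equal(ft2$subject_id, "B")

  # full compliance keeps everyone
  coh3 <- generate_cohort(homogeneous_config(n_per_arm = 5L, weeks = 52L))
  expect_equal(nrow(build_feature_table(coh3, 10)), 10L)

  # empty result is a zero-row table, not an error
  ft4 <- build_feature_table(coh2, min_reports = 100)
  expect_equal(nrow(ft4), 0L)
})
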