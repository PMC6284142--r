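# Independent oracles, written as naive direct implementations so they
# share no code path with the package internals.

# Brute-force DFA: explicit loops, lm() per box, boxes from the start and
# (when the tail is not covered) from the end of the profile.
naive_dfa <- function(x, box_min = 4, box_max = floor(length(x) / 4),
                      n_sizes = 10, forward_only = FALSE) {
  N <- length(x)
  sizes <- unique(round(exp(seq(log(box_min), log(box_max),
                                length.out = n_sizes))))
  Y <- cumsum(x - mean(x))
  F <- numeric(length(sizes))
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    m <- floor(N / s)
    starts <- ((1:m) - 1) * s + 1
    res <- c()
    for (st in starts) {
      seg <- Y[st:(st + s - 1)]
      tt <- 1:s
      res <- c(res, stats::residuals(stats::lm(seg ~ tt)))
    }
    if (!forward_only && m * s < N) {
      starts2 <- N - ((1:m) * s) + 1
      for (st in starts2) {
        seg <- Y[st:(st + s - 1)]
        tt <- 1:s
        res <- c(res, stats::residuals(stats::lm(seg ~ tt)))
      }
    }
    F[si] <- sqrt(mean(res^2))
  }
  keep <- F > 0
  unname(stats::coef(stats::lm(log(F[keep]) ~ log(sizes[keep])))[2])
}

# Mann-Whitney pair-counting AUC: exhaustive enumeration of all
# (positive, negative) pairs, ties counting one half.
pair_count_auc <- function(scores, labels, positive = "active") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Least-squares sinusoid fit at one frequency: explained sum of squares of
# the joint (cos, sin) regression on the mean-centered values, over twice
# the sample variance.
ls_sinusoid_power <- function(times, values, f) {
  y <- values - mean(values)
  w <- 2 * pi * f
  t0 <- times - times[1]
  fit <- stats::lm(y ~ 0 + cos(w * t0) + sin(w * t0))
  (sum(y^2) - sum(stats::residuals(fit)^2)) /
    (2 * sum(y^2) / (length(y) - 1))
}

# Two-sample pooled-variance t-test from first principles.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), na + nb - 2))
}
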