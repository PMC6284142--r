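two_clusters <- function(n = 20, gap = 6, seed = 3) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n), ncol = 2),
             matrix(rnorm(2 * n, mean = gap), ncol = 2))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = factor(rep(c("placebo", "active"), each = n),
                         levels = c("placebo", "active")))
}

test_that("each classifier separates two distant clusters at training time", {
  d <- two_clusters()
  for (kind in c("logistic", "lda", "qda", "svm_linear", "svm_rbf", "knn")) {
    m <- fit_classifier(kind, d$x, d$y, seed = 1)
    expect_equal(mean(predict(m, d$x) == d$y), 1,
                 info = kind)
  }
})

test_that("1-nearest-neighbour memorizes distinct training points", {
  set.seed(6)
  x <- matrix(rnorm(60), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(sample(c("placebo", "active"), 30, replace = TRUE),
              levels = c("placebo", "active"))
  m <- fit_classifier("knn", x, y, params = list(k = 1), seed = 1)
  expect_equal(mean(predict(m, x) == y), 1)
})

test_that("LDA boundary direction matches the closed-form pooled-covariance solution", {
  set.seed(15)
  n <- 400
  sigma <- matrix(c(2, 0.8, 0.8, 1), 2)
  L <- chol(sigma)
  x <- rbind(matrix(rnorm(2 * n), ncol = 2) %*% L,
             sweep(matrix(rnorm(2 * n), ncol = 2) %*% L, 2, c(2, 1), "+"))
  colnames(x) <- c("f1", "f2")
  y <- factor(rep(c("placebo", "active"), each = n),
              levels = c("placebo", "active"))
  m <- fit_classifier("lda", x, y, seed = 1)
  got <- m$model$scaling[, 1]
  # oracle in the standardized coordinates the model was fitted in
  xs <- scale(x)
  mu_d <- colMeans(xs[y == "active", ]) - colMeans(xs[y == "placebo", ])
  S <- (cov(xs[y == "active", ]) * (n - 1) +
        cov(xs[y == "placebo", ]) * (n - 1)) / (2 * n - 2)
  want <- solve(S, mu_d)
  cosine <- sum(got * want) / sqrt(sum(got^2) * sum(want^2))
  expect_gt(abs(cosine), 0.999)
})

test_that("stratified folds partition every subject once with near-equal sizes", {
  y <- factor(rep(c("placebo", "active"), c(53, 48)))
  for (seed in 1:5) {
    f <- moodtrial:::make_folds(y, 10, seed)
    expect_equal(sort(unique(f)), 1:10)
    expect_equal(length(f), 101L)              # every subject in one fold
    expect_lte(diff(range(table(f))), 1)       # sizes differ by at most 1
    for (j in 1:10)                            # both classes in every training set
      expect_equal(nlevels(droplevels(y[f != j])), 2)
    expect_identical(f, moodtrial:::make_folds(y, 10, seed))
  }
})

test_that("cross-validated accuracy is reproducible and calibrated", {
  d <- two_clusters(n = 30, gap = 4, seed = 9)
  r1 <- cv_accuracy("logistic", d$x, d$y, seed = 7)
  r2 <- cv_accuracy("logistic", d$x, d$y, seed = 7)
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
  expect_gt(r1$mean_accuracy, 0.9) # well-separated task
  expect_true(all(r1$fold_accuracies >= 0 & r1$fold_accuracies <= 1))

  # destroying the labels leaves accuracy at the no-information rate
  set.seed(1)
  ysh <- sample(d$y)
  rs <- cv_accuracy("logistic", d$x, ysh, seed = 7)
  nir <- no_information_rate(ysh)
  expect_lt(abs(rs$mean_accuracy - nir), 2 * rs$se_accuracy + 0.1)
})

test_that("lasso recovers a single informative feature among noise", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 120
    y <- factor(rep(c("placebo", "active"), each = n / 2),
                levels = c("placebo", "active"))
    x <- matrix(rnorm(n * 9), ncol = 9,
                dimnames = list(NULL, paste0("f", 1:9)))
    x[, 1] <- x[, 1] + 1.5 * (as.integer(y) - 1.5) # only f1 informative
    sel <- regularized_selection(x, y, penalty = "lasso", seed = s)
    if ("f1" %in% sel$selected_features) hits <- hits + 1L
  }
  expect_gte(hits, 18L) # at least 90% of runs
})

test_that("pure-noise features yield an empty lasso selection in most seeds", {
  empty <- 0L
  for (s in 1:20) {
    set.seed(s + 100)
    y <- factor(rep(c("placebo", "active"), each = 50),
                levels = c("placebo", "active"))
    x <- matrix(rnorm(100 * 8), ncol = 8,
                dimnames = list(NULL, paste0("f", 1:8)))
    sel <- regularized_selection(x, y, penalty = "lasso", seed = s)
    if (length(sel$selected_features) == 0) empty <- empty + 1L
  }
  expect_gte(empty, 10L) # at least half the seeds
})

test_that("ridge reports a full magnitude ranking instead of a sparse set", {
  set.seed(5)
  y <- factor(rep(c("placebo", "active"), each = 40),
              levels = c("placebo", "active"))
  x <- matrix(rnorm(80 * 5), ncol = 5, dimnames = list(NULL, paste0("f", 1:5)))
  x[, 3] <- x[, 3] + 2 * (as.integer(y) - 1.5)
  sel <- regularized_selection(x, y, penalty = "ridge", seed = 2)
  expect_setequal(sel$selected_features, paste0("f", 1:5))
  expect_equal(sel$selected_features[1], "f3") # informative one ranks first
})

test_that("sequential selection takes a single perfect feature and stops", {
  set.seed(3)
  y <- factor(rep(c("placebo", "active"), each = 30),
              levels = c("placebo", "active"))
  x <- cbind(perfect = 10 * (as.integer(y) - 1.5) + rnorm(60, 0, 0.01),
             noise1 = rnorm(60), noise2 = rnorm(60))
  sel <- sequential_selection(x, y, seed = 4)
  expect_identical(sel$selected_features, "perfect")
})

test_that("a redundant duplicate of the informative feature is selected only once", {
  set.seed(7)
  y <- factor(rep(c("placebo", "active"), each = 40),
              levels = c("placebo", "active"))
  base <- 3 * (as.integer(y) - 1.5) + rnorm(80, 0, 0.5)
  x <- cbind(copy_a = base, copy_b = base, noise = rnorm(80))
  sel <- sequential_selection(x, y, seed = 4)
  expect_equal(sum(c("copy_a", "copy_b") %in% sel$selected_features), 1L)
})

test_that("a logistic decision boundary over two features is a straight line", {
  d <- two_clusters(n = 25, gap = 3, seed = 21)
  m <- fit_classifier("logistic", d$x, d$y, seed = 1)
  db <- decision_boundary(m, grid_resolution = 40)
  expect_equal(nrow(db$grid), 1600L)
  # predictions agree with the sign of the fitted linear predictor
  co <- coef(m$model)
  gs <- scale(as.matrix(db$grid), m$center, m$scale)
  eta <- co[1] + gs %*% co[-1]
  expect_equal(unname(db$predicted_class == "active"), c(eta > 0))
  # lattice spans the observed feature ranges
  expect_equal(range(db$grid[[1]]), unname(m$feature_range[, 1]))
})

test_that("constant features are dropped with a warning during selection", {
  set.seed(2)
  y <- factor(rep(c("placebo", "active"), each = 20),
              levels = c("placebo", "active"))
  x <- cbind(flat = rep(1, 40), ok = rnorm(40) + as.integer(y),
             ok2 = rnorm(40))
  expect_warning(sel <- regularized_selection(x, y, penalty = "lasso", seed = 1),
                 "constant")
  expect_false("flat" %in% sel$selected_features)
})
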