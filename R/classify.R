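`%||%` <- function(a, b) if (is.null(a)) b else a

CLASSIFIER_KINDS <- c("logistic", "lda", "qda", "svm_linear", "svm_rbf", "knn")

## Stratified fold assignment: within each class, shuffle and deal folds
## round-robin with a carried-over counter so overall fold sizes differ by
## at most one. Pure function of (y, k, seed).
make_folds <- function(y, k, seed) {
  y <- as.factor(y)
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  nxt <- 0L
  for (cl in levels(y)) {
    i <- which(y == cl)
    i <- if (length(i) > 1) sample(i) else i
    fold[i] <- ((nxt + seq_along(i) - 1L) %% k) + 1L
    nxt <- nxt + length(i)
  }
  fold
}

fit_da_with_fallback <- function(fun, xs, y, seed) {
  tryCatch(fun(xs, grouping = y), error = function(e) {
    warning("discriminant fit singular (", conditionMessage(e),
            "); refitting with tiny regularizing jitter", call. = FALSE)
    set.seed(as.integer(seed))
    fun(xs + matrix(stats::rnorm(length(xs), 0, 1e-3), nrow(xs)),
        grouping = y)
  })
}

#' Fit one of the six binary arm classifiers
#'
#' Supported model families: logistic regression, linear and quadratic
#' discriminant analysis, linear and Gaussian-kernel support vector
#' machines, and k-nearest neighbors. Features are standardized internally
#' on the training data (the stored center/scale is applied again at
#' prediction, so cross-validation never leaks test-fold statistics).
#' Undocumented-in-the-field defaults are fixed and exposed via `params`:
#' knn `k = 5` (odd, so binary votes cannot tie), SVM `cost = 1`, RBF
#' kernel width by the median pairwise-distance heuristic.
#'
#' @param kind One of `"logistic"`, `"lda"`, `"qda"`, `"svm_linear"`,
#'   `"svm_rbf"`, `"knn"`.
#' @param x Numeric feature matrix or data.frame (no missing values).
#' @param y Binary factor of arm labels; the second level (conventionally
#'   `"active"`) is the positive class.
#' @param params Named list of hyperparameters (`k`, `cost`, `gamma`).
#' @param seed Integer seed (used by the discriminant-singularity fallback
#'   and any tie-breaking), making the fit deterministic.
#' @return Object of class `mood_classifier` with a [predict()] method
#'   returning class labels for new feature rows.
#' @export
fit_classifier <- function(kind, x, y, params = list(), seed = 1L) {
  kind <- match.arg(kind, CLASSIFIER_KINDS)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("y must have exactly 2 classes")
  if (any(table(y) < 2)) stop("each class needs at least 2 subjects")
  if (anyNA(x)) stop("missing feature values; drop or impute before fitting")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  dimnames(xs) <- dimnames(x)
  model <- switch(kind,
    logistic = {
      df <- data.frame(.y = y, xs, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    lda = fit_da_with_fallback(MASS::lda, xs, y, seed),
    qda = fit_da_with_fallback(MASS::qda, xs, y, seed),
    svm_linear = e1071::svm(xs, y, kernel = "linear",
                            cost = params$cost %||% 1, scale = FALSE),
    svm_rbf = {
      gamma <- params$gamma
      if (is.null(gamma)) {
        h <- stats::median(stats::dist(xs))
        gamma <- if (h > 0) 1 / (2 * h^2) else 1
      }
      e1071::svm(xs, y, kernel = "radial", cost = params$cost %||% 1,
                 gamma = gamma, scale = FALSE)
    },
    knn = list(train = xs, cl = y, k = params$k %||% 5L)
  )
  structure(list(kind = kind, model = model, center = ctr, scale = scl,
                 features = colnames(x), levels = levels(y),
                 feature_range = apply(x, 2, range), params = params,
                 seed = as.integer(seed)),
            class = "mood_classifier")
}

#' @export
predict.mood_classifier <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  storage.mode(x) <- "double"
  xs <- scale(x, object$center, object$scale)
  colnames(xs) <- object$features
  out <- switch(object$kind,
    logistic = {
      p <- suppressWarnings(stats::predict(object$model,
                          newdata = data.frame(xs, check.names = FALSE),
                          type = "response"))
      factor(object$levels[1L + (p > 0.5)], levels = object$levels)
    },
    lda = stats::predict(object$model, xs)$class,
    qda = stats::predict(object$model, xs)$class,
    svm_linear = stats::predict(object$model, xs),
    svm_rbf = stats::predict(object$model, xs),
    knn = {
      set.seed(object$seed) # distance ties in knn are broken reproducibly
      class::knn(object$model$train, xs, object$model$cl, k = object$model$k)
    }
  )
  factor(as.character(out), levels = object$levels)
}

#' Stratified k-fold cross-validated accuracy of a classifier
#'
#' Partitions subjects into `k` stratified folds (a pure function of
#' `seed`), fits the classifier on each training set and records the
#' accuracy on the held-out fold. Standardization happens inside
#' [fit_classifier()] on training folds only.
#'
#' @param kind Classifier kind, see [fit_classifier()].
#' @param x Numeric feature matrix (no missing values).
#' @param y Binary factor of labels.
#' @param k Number of folds (default 10); requires `n >= k`.
#' @param seed Integer seed controlling fold assignment.
#' @param params Hyperparameters forwarded to [fit_classifier()].
#' @return Object of class `cv_result`: `classifier`, `fold_accuracies`
#'   (NA where a fold had a single-class training set), `mean_accuracy`,
#'   `se_accuracy` (SD of valid fold accuracies / sqrt(#valid)), `folds`,
#'   `seed`, `n`.
#' @export
cv_accuracy <- function(kind, x, y, k = 10L, seed, params = list()) {
  if (missing(seed)) stop("seed is required")
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nrow(x) < k) stop("need at least k subjects")
  fold <- make_folds(y, k, seed)
  acc <- vapply(seq_len(k), function(j) {
    tr <- fold != j
    if (nlevels(droplevels(y[tr])) < 2 || !any(!tr)) return(NA_real_)
    tryCatch({
      m <- fit_classifier(kind, x[tr, , drop = FALSE], y[tr],
                          params = params, seed = seed)
      mean(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }, error = function(e) NA_real_) # unfittable fold reported as invalid
  }, numeric(1))
  ok <- !is.na(acc)
  structure(list(classifier = kind, fold_accuracies = acc,
                 mean_accuracy = mean(acc[ok]),
                 se_accuracy = stats::sd(acc[ok]) / sqrt(sum(ok)),
                 folds = fold, seed = as.integer(seed), n = nrow(x)),
            class = "cv_result")
}

#' Penalized-regression feature selection by cross-validated deviance
#'
#' Fits a penalized logistic model (lasso, elasticnet with mixing 0.5, or
#' ridge) over a penalty path with internally standardized features, picks
#' the penalty minimizing 10-fold cross-validated binomial deviance, and
#' reports the features with nonzero coefficients there, ordered by
#' absolute coefficient size. Ridge zeroes nothing, so it reports the full
#' ranking by coefficient magnitude instead. Constant features are dropped
#' with a warning before fitting.
#'
#' @param x Numeric feature matrix (no missing values).
#' @param y Binary factor of labels.
#' @param penalty `"lasso"`, `"elasticnet"` or `"ridge"`.
#' @param seed Integer seed for the fold assignment.
#' @param nfolds Folds for the deviance criterion (default 10).
#' @param mixing Elasticnet mixing parameter (default 0.5).
#' @return Object of class `selection_result`: `method`,
#'   `selected_features` (ordered), `cv_criterion_path` (data.frame of
#'   lambda and mean CV deviance), `lambda_min`, `coefficients`.
#' @export
regularized_selection <- function(x, y,
                                  penalty = c("lasso", "elasticnet", "ridge"),
                                  seed, nfolds = 10L, mixing = 0.5) {
  penalty <- match.arg(penalty)
  if (missing(seed)) stop("seed is required")
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  alpha <- switch(penalty, lasso = 1, elasticnet = mixing, ridge = 0)
  foldid <- make_folds(y, nfolds, seed)
  cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                             foldid = foldid, type.measure = "deviance",
                             standardize = TRUE)
  co <- stats::coef(cvfit, s = "lambda.min")
  co <- stats::setNames(as.numeric(co)[-1], rownames(co)[-1])
  sel <- if (penalty == "ridge") names(sort(abs(co), decreasing = TRUE))
         else {
           nz <- co[co != 0]
           names(sort(abs(nz), decreasing = TRUE))
         }
  structure(list(method = penalty, selected_features = sel,
                 cv_criterion_path = data.frame(lambda = cvfit$lambda,
                                                deviance = cvfit$cvm),
                 lambda_min = cvfit$lambda.min, coefficients = co),
            class = "selection_result")
}

#' Greedy forward feature selection by cross-validated misclassification
#'
#' Starting from the empty model (whose error is one minus the majority
#' class fraction), repeatedly adds the candidate feature that most
#' reduces the cross-validated misclassification rate of the given
#' classifier, and stops as soon as no candidate strictly reduces it. The
#' fold assignment is fixed by `seed` across all comparisons.
#'
#' @param x Numeric feature matrix (no missing values).
#' @param y Binary factor of labels.
#' @param classifier Classifier kind used for the error metric
#'   (default `"logistic"`).
#' @param seed Integer seed.
#' @param k CV folds (default 10).
#' @param params Hyperparameters for the classifier.
#' @return Object of class `selection_result`: `method = "sequential"`,
#'   `selected_features` (in inclusion order), `cv_criterion_path`
#'   (data.frame: step, feature, cv_error).
#' @export
sequential_selection <- function(x, y, classifier = "logistic", seed,
                                 k = 10L, params = list()) {
  if (missing(seed)) stop("seed is required")
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  remaining <- colnames(x)
  selected <- character()
  best_err <- 1 - no_information_rate(y)
  path <- data.frame(step = 0L, feature = "(none)", cv_error = best_err,
                     stringsAsFactors = FALSE)
  while (length(remaining)) {
    errs <- vapply(remaining, function(f) {
      cols <- c(selected, f)
      1 - cv_accuracy(classifier, x[, cols, drop = FALSE], y, k = k,
                      seed = seed, params = params)$mean_accuracy
    }, numeric(1))
    if (min(errs) >= best_err) break
    f <- remaining[which.min(errs)]
    best_err <- min(errs)
    selected <- c(selected, f)
    remaining <- setdiff(remaining, f)
    path <- rbind(path, data.frame(step = length(selected), feature = f,
                                   cv_error = best_err,
                                   stringsAsFactors = FALSE))
  }
  structure(list(method = "sequential", selected_features = selected,
                 cv_criterion_path = path),
            class = "selection_result")
}

#' Classification decision boundary over a two-feature lattice
#'
#' Evaluates a fitted two-feature classifier on a rectangular grid
#' spanning the observed training ranges of the two features, so the
#' decision regions can be plotted (e.g. coefficient of variation against
#' the DFA exponent).
#'
#' @param model A [fit_classifier()] result trained on exactly 2 features.
#' @param grid_resolution Lattice points per axis (default 100).
#' @return Object of class `decision_boundary`: `feature_pair`, `grid`
#'   (data.frame of the two feature columns) and `predicted_class`.
#' @export
decision_boundary <- function(model, grid_resolution = 100L) {
  stopifnot(inherits(model, "mood_classifier"))
  if (length(model$features) != 2)
    stop("decision_boundary needs a model fitted on exactly 2 features")
  r <- model$feature_range
  g1 <- seq(r[1, 1], r[2, 1], length.out = grid_resolution)
  g2 <- seq(r[1, 2], r[2, 2], length.out = grid_resolution)
  grid <- expand.grid(g1, g2, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- model$features
  structure(list(feature_pair = model$features, grid = grid,
                 predicted_class = predict(model, grid)),
            class = "decision_boundary")
}

#' Multi-method feature selection with family-level agreement
#'
#' Runs both selection families — the penalized-deviance family (lasso and
#' elasticnet, plus the ridge magnitude ranking) and the sequential
#' misclassification family (one greedy run per classifier kind) — and
#' summarizes them at the family level: a family's selected set is the
#' union of its members' selections, and the consensus is the intersection
#' of the two family sets. This mirrors the practice of trusting the
#' features on which independent selection methods agree.
#'
#' @param x Numeric feature matrix (no missing values).
#' @param y Binary factor of labels.
#' @param seed Integer seed shared by all member runs.
#' @param sequential_classifiers Classifier kinds for the sequential
#'   family (default all six).
#' @param k CV folds (default 10).
#' @return List (class `selection_summary`): `by_method` (named list of
#'   `selection_result`s), `regularized` and `sequential` (family union
#'   character vectors), `consensus` (their intersection), `ridge_ranking`.
#' @export
select_features <- function(x, y, seed,
                            sequential_classifiers = CLASSIFIER_KINDS,
                            k = 10L) {
  if (missing(seed)) stop("seed is required")
  by_method <- list()
  for (pen in c("lasso", "elasticnet", "ridge"))
    by_method[[pen]] <- regularized_selection(x, y, penalty = pen,
                                              seed = seed, nfolds = k)
  for (cl in sequential_classifiers)
    by_method[[paste0("sequential_", cl)]] <-
      sequential_selection(x, y, classifier = cl, seed = seed, k = k)
  reg <- unique(c(by_method$lasso$selected_features,
                  by_method$elasticnet$selected_features))
  seq_u <- unique(unlist(lapply(sequential_classifiers, function(cl)
    by_method[[paste0("sequential_", cl)]]$selected_features)))
  structure(list(by_method = by_method, regularized = reg,
                 sequential = seq_u,
                 consensus = intersect(reg, seq_u),
                 ridge_ranking = by_method$ridge$selected_features),
            class = "selection_summary")
}
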