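#' Gaussian kernel density estimate of a feature
#'
#' Standard Gaussian-kernel density estimate evaluated on an automatic grid
#' spanning the data range plus three bandwidths on either side. The
#' default bandwidth is Silverman's rule of thumb (`stats::bw.nrd0`).
#'
#' @param values Numeric sample (>= 2 values, non-constant).
#' @param bandwidth Either `"silverman"` or a positive number.
#' @param n_grid Number of grid points (default 512).
#' @return Object of class `density_estimate`: `grid`, `density`,
#'   `bandwidth`. The density integrates to 1 over the grid to within 0.01.
#' @examples
#' d <- kde(rnorm(500))
#' sum(d$density) * diff(d$grid[1:2]) # ~1
#' @export
kde <- function(values, bandwidth = "silverman", n_grid = 512L) {
  values <- as.numeric(values[!is.na(values)])
  if (length(values) < 2) stop("kde needs at least 2 values")
  if (stats::sd(values) == 0)
    stop("kde undefined for zero-variance input (no bandwidth)")
  bw <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(values)
        else {
          if (!is.numeric(bandwidth) || bandwidth <= 0)
            stop("bandwidth must be 'silverman' or a positive number")
          bandwidth
        }
  d <- stats::density(values, bw = bw, kernel = "gaussian", n = n_grid,
                      from = min(values) - 3 * bw, to = max(values) + 3 * bw)
  structure(list(grid = d$x, density = d$y, bandwidth = bw),
            class = "density_estimate")
}

#' Per-arm kernel density estimates of one feature
#'
#' Evaluates [kde()] for the active and placebo arms of a feature table on
#' a shared grid, so the two distributions can be overlaid.
#'
#' @param features A [build_feature_table()] result.
#' @param feature Feature column name (e.g. `"cv"`, `"dfa_alpha"`).
#' @param ... Passed to [kde()].
#' @return Data.frame with `grid`, `density_active`, `density_placebo`;
#'   attribute `bandwidths`.
#' @export
arm_feature_density <- function(features, feature, ...) {
  v <- features[[feature]]
  if (is.null(v)) stop("unknown feature: ", feature)
  va <- v[features$arm == "active" & !is.na(v)]
  vp <- v[features$arm == "placebo" & !is.na(v)]
  da <- kde(va, ...); dp <- kde(vp, ...)
  lo <- min(da$grid, dp$grid); hi <- max(da$grid, dp$grid)
  grid <- seq(lo, hi, length.out = 512)
  dens <- function(sample, bw)
    vapply(grid, function(g) mean(stats::dnorm(g, sample, bw)), numeric(1))
  out <- data.frame(grid = grid,
                    density_active = dens(va, da$bandwidth),
                    density_placebo = dens(vp, dp$bandwidth))
  attr(out, "bandwidths") <- c(active = da$bandwidth, placebo = dp$bandwidth)
  out
}

#' ROC curve and AUC for a score against binary arm labels
#'
#' Sweeps the classification threshold over the unique score values
#' (predicting the positive class when score >= threshold, so higher
#' scores mean "more positive"), and integrates the curve by the
#' trapezoidal rule. Tied scores are processed jointly, which makes the
#' AUC equal to the Mann-Whitney pair-counting statistic with ties
#' contributing one half.
#'
#' @param scores Numeric scores.
#' @param labels Class labels; both classes must be present.
#' @param positive Label treated as positive (default `"active"`).
#' @return Object of class `roc_result`: `thresholds` (decreasing, starting
#'   at Inf), `tpr`, `fpr` (both non-decreasing), `auc`.
#' @examples
#' roc_curve(c(1, 2, 3, 4), c("placebo", "placebo", "active", "active"))$auc
#' @export
roc_curve <- function(scores, labels, positive = "active") {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.character(labels[ok])
  if (!positive %in% labels || all(labels == positive))
    stop("both classes must be present")
  y <- labels == positive
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  blocks <- cumsum(rle(ss)$lengths) # last index of each tied block
  tp <- cumsum(ys)[blocks]; fp <- cumsum(!ys)[blocks]
  tpr <- c(0, tp / sum(y)); fpr <- c(0, fp / sum(!y))
  k <- length(tpr)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-k]) / 2)
  structure(list(thresholds = c(Inf, rle(ss)$values), tpr = tpr, fpr = fpr,
                 auc = auc),
            class = "roc_result")
}
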