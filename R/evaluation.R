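#' Random cross-validation folds
#'
#' Observations are assigned to `k` folds at random, with fold sizes
#' differing by at most one.
#'
#' @param n Number of observations.
#' @param k Number of folds (at most `n`).
#' @param seed Optional integer seed.
#' @return A `fold_assignment`: integer vector of fold labels in `1..k` with
#'   attributes `scheme` and `seed`.
#' @examples
#' table(random_folds(100, 10, seed = 1))
#' @export
random_folds <- function(n, k, seed = NULL) {
  if (k > n) abort(sprintf("Cannot make k = %d folds from n = %d observations.", k, n))
  if (k < 1) abort("`k` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)
  f <- sample(rep_len(seq_len(k), n))
  structure(f, scheme = "random", seed = seed, class = "fold_assignment")
}

#' Blocked (spatial) cross-validation folds
#'
#' Folds are k-means clusters of the observation coordinates, so each fold is
#' a spatially contiguous block. Blocking reduces the spatial autocorrelation
#' between training and held-out data and thereby the optimism of
#' cross-validated performance estimates.
#'
#' @param data Data frame with coordinate columns `x`, `y`.
#' @param k Number of folds.
#' @param seed Optional integer seed.
#' @param restarts k-means restarts kept at the best inertia (default 10).
#' @return A `fold_assignment` (see [random_folds()]).
#' @examples
#' d <- sample_locations(15, 100, seed = 1)
#' table(blocked_folds(d, 10, seed = 1))
#' @export
blocked_folds <- function(data, k, seed = NULL, restarts = 10) {
  xy <- as_coords(data)
  n <- nrow(xy)
  if (k > n) abort(sprintf("Cannot make k = %d folds from n = %d observations.", k, n))
  if (!is.null(seed)) set.seed(seed)
  if (k == 1) {
    return(structure(rep(1L, n), scheme = "blocked", seed = seed, class = "fold_assignment"))
  }
  km <- NULL
  for (attempt in seq_len(10)) {
    km <- tryCatch(kmeans(xy, centers = k, nstart = restarts), error = function(e) NULL,
                   warning = function(w) NULL)
    if (!is.null(km) && all(km$size > 0)) break
    km <- NULL
  }
  if (is.null(km)) abort("k-means failed to produce non-empty folds after 10 restarts.")
  structure(as.integer(km$cluster), scheme = "blocked", seed = seed,
            class = "fold_assignment")
}

#' Mean-centered R-squared
#'
#' Both observed and predicted vectors are centered by their own means before
#' computing `1 - sum((a - a_hat)^2) / sum(a^2)`; baseline differences
#' between fields are thus ignored and only relative variation counts. Poor
#' models can yield negative values.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return A scalar, at most 1.
#' @examples
#' r_squared_centered(c(1, 2, 3), c(1, 1, 4))
#' @export
r_squared_centered <- function(observed, predicted) {
  if (length(observed) != length(predicted)) abort("Vector lengths differ.")
  if (length(observed) < 2) abort("Need at least 2 observations.")
  a <- observed - mean(observed)
  if (sum(a^2) == 0) abort("Observed vector is constant; centered R-squared is undefined.")
  ah <- predicted - mean(predicted)
  1 - sum((a - ah)^2) / sum(a^2)
}

#' Cross-validated R-squared
#'
#' Refits a model on each training portion and averages the mean-centered
#' R-squared over held-out folds. A fold whose model fit fails contributes 0,
#' the convention used when aggregating study results; an error is raised
#' only if every fold fails.
#'
#' @param data A field dataset.
#' @param folds A [random_folds()] / [blocked_folds()] assignment (or integer
#'   vector of fold labels).
#' @param fit_fun Function taking the training data frame and returning a
#'   fitted object.
#' @param predict_fun Function `(fit, newdata) -> numeric`; defaults to
#'   [predict()].
#' @param outcome Outcome column name.
#' @return Mean held-out centered R-squared across folds.
#' @examples
#' d <- simulate_observational(p = 2, n = 60, beta = c(1, -1), seed = 2)
#' cv_r_squared(d, random_folds(60, 5, seed = 1), fit_ols)
#' @export
cv_r_squared <- function(data, folds, fit_fun, predict_fun = predict,
                         outcome = "A") {
  f <- as.integer(folds)
  if (length(f) != nrow(data)) abort("Fold labels must match the number of rows.")
  ks <- sort(unique(f))
  if (length(ks) < 2) abort("Need at least 2 folds.")
  r2 <- vapply(ks, function(k) {
    train <- data[f != k, , drop = FALSE]
    test <- data[f == k, , drop = FALSE]
    tryCatch({
      fit <- fit_fun(train)
      r_squared_centered(test[[outcome]], predict_fun(fit, test))
    }, error = function(e) 0)
  }, numeric(1))
  mean(r2)
}

# Inverse-distance weight matrix (zero diagonal), not row-standardized.
inv_dist_weights <- function(xy) {
  D <- coord_dist(xy)
  if (any(D[upper.tri(D)] == 0)) abort("Duplicate coordinates give infinite Moran weights.")
  W <- 1 / D
  diag(W) <- 0
  W
}

#' Moran's I spatial autocorrelation statistic
#'
#' Computes Moran's I with inverse-Euclidean-distance weights (zero diagonal,
#' not row-standardized): `I = n / s_w * sum_ij w_ij z_i z_j / sum_i z_i^2`
#' with `s_w` the sum of all weights. The marginal form uses deviations of
#' the values from their mean; the conditional form uses residuals
#' `values - predictions` directly (predictions from the coefficients only,
#' with all spatial model terms omitted). The null expectation is
#' `-1/(n - 1)`.
#'
#' @param values Numeric vector of observations.
#' @param data Data frame with coordinate columns `x`, `y`.
#' @param kind `"marginal"` or `"conditional"`.
#' @param predictions Model predictions (required for `"conditional"`).
#' @return Moran's I, a product-moment-type correlation in \[-1, 1\].
#' @examples
#' d <- expand.grid(x = 1:5, y = 1:5)
#' morans_i(d$x, d, "marginal")  # strong gradient: positive
#' @export
morans_i <- function(values, data, kind = c("marginal", "conditional"),
                     predictions = NULL) {
  kind <- match.arg(kind)
  xy <- as_coords(data)
  n <- length(values)
  if (n < 3) abort("Moran's I needs at least 3 observations.")
  if (nrow(xy) != n) abort("`values` length must match the number of locations.")
  z <- if (kind == "marginal") {
    values - mean(values)
  } else {
    if (is.null(predictions)) abort("`predictions` required for conditional Moran's I.")
    values - predictions
  }
  if (sum(z^2) == 0) abort("Constant input; Moran's I is undefined.")
  W <- inv_dist_weights(xy)
  sw <- sum(W)
  (n / sw) * drop(crossprod(z, W %*% z)) / sum(z^2)
}

#' Expectation-adjusted Moran's I
#'
#' Adds the null expectation `1/(n - 1)` to Moran's I so that the statistic
#' has mean zero under exchangeability regardless of sample size, making
#' values comparable between full training sets and small held-out folds.
#'
#' @inheritParams morans_i
#' @return Adjusted Moran's I.
#' @export
adjusted_morans_i <- function(values, data, kind = c("marginal", "conditional"),
                              predictions = NULL) {
  n <- length(values)
  morans_i(values, data, kind, predictions) + 1 / (n - 1)
}

#' Mean squared error of coefficient estimates
#'
#' @param beta_hat,beta_true Numeric vectors of equal length.
#' @return Mean of squared component-wise errors.
#' @export
beta_mse <- function(beta_hat, beta_true) {
  if (length(beta_hat) != length(beta_true)) abort("Coefficient vectors differ in length.")
  mean((beta_hat - beta_true)^2)
}

#' Feature-selection metrics against a known truth
#'
#' Counts true/false positives against the nonzero true coefficients and the
#' per-regressor spatial flags. With no selected features, sensitivity is 0
#' while TDP and the spatial proportion are undefined (`NA`), and undefined
#' values propagate as missing into study tables.
#'
#' @param selected Integer indices (or logical vector) of selected regressors.
#' @param truth A truth list from [sim_truth()] (or a `fieldsim` dataset).
#' @return A one-row tibble with `sensitivity` (TP / (TP + FN)), `tdp`
#'   (TP / (TP + FP)) and `spatial_prop` (share of selected features that are
#'   spatially structured; 0.5 expected for unbiased selection).
#' @examples
#' d <- simulate_observational(p = 10, n = 40, seed = 5)
#' selection_metrics(c(1, 2, 6), d)
#' @export
selection_metrics <- function(selected, truth) {
  if (inherits(truth, "fieldsim")) truth <- sim_truth(truth)
  p <- length(truth$beta)
  if (is.logical(selected)) selected <- which(selected)
  selected <- as.integer(selected)
  if (length(selected) > 0 && (min(selected) < 1 || max(selected) > p)) {
    abort(sprintf("Selected indices must lie in 1..%d.", p))
  }
  support <- which(truth$beta != 0)
  tp <- length(intersect(selected, support))
  fp <- length(setdiff(selected, support))
  fn <- length(setdiff(support, selected))
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  if (length(selected) == 0) {
    sens <- if (length(support) == 0) NA_real_ else 0
    return(tibble::tibble(sensitivity = sens, tdp = NA_real_, spatial_prop = NA_real_))
  }
  tibble::tibble(
    sensitivity = sens,
    tdp = tp / (tp + fp),
    spatial_prop = mean(truth$spatial_flags[selected])
  )
}
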