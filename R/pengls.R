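# Core elastic-net solve on (possibly whitened) data with an unpenalized
# intercept direction `w1` (the whitened column of ones). The intercept is
# projected out analytically, the remaining columns are scaled to unit
# root-mean-square before penalization, and coefficients are returned on the
# original scale. `lambda` may be a descending path; returns one column of
# coefficients per penalty value. Objective per penalty value lambda:
#   1/(2n) ||y - b0 w1 - X b||^2 + lambda * (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)
en_core <- function(y, X, w1, lambda, alpha = 0.5, thresh = 1e-9) {
  n <- length(y)
  p <- ncol(X)
  if (any(lambda < 0)) abort("`lambda` must be non-negative.")
  lambda <- sort(unique(lambda), decreasing = TRUE)
  w1n2 <- sum(w1^2)
  proj <- function(v) v - w1 * (sum(w1 * v) / w1n2)
  yp <- proj(y)
  Xp <- X - tcrossprod(w1 / w1n2, crossprod(X, w1))
  sds <- sqrt(colSums(Xp^2) / n)
  sds[sds == 0] <- 1
  Xs <- sweep(Xp, 2, sds, "/")
  lmax <- max(abs(crossprod(Xs, yp))) / (n * alpha)
  L <- length(lambda)
  beta <- matrix(0, p, L)
  active <- lambda < lmax
  if (any(active)) {
    lam_fit <- lambda[active]
    # prepend a short warm-up path from the all-zero penalty for stability
    lead <- exp(seq(log(lmax), log(max(lam_fit[1], lmax * 0.99)), length.out = 3))
    path <- sort(unique(c(lead, lam_fit)), decreasing = TRUE)
    path_pos <- path[path > 0]
    fit <- glmnet::glmnet(Xs, yp, alpha = alpha, lambda = path_pos,
                          intercept = FALSE, standardize = FALSE,
                          thresh = thresh)
    cf <- as.matrix(coef(fit, s = pmax(lam_fit, min(path_pos)), exact = FALSE))[-1, , drop = FALSE]
    if (any(lam_fit == 0)) {
      # glmnet paths cannot end at exactly zero on a log scale; refit the
      # unpenalized case as least squares on the projected data
      ls <- qr.coef(qr(Xs), yp)
      ls[is.na(ls)] <- 0
      cf[, lam_fit == 0] <- ls
    }
    beta[, active] <- cf / sds
  }
  beta0 <- drop(crossprod(w1, y - X %*% beta)) / w1n2
  list(beta0 = beta0, beta = beta, lambda = lambda)
}

#' Elastic net on whitened data
#'
#' Minimizes `1/(2n) * ||Aw - beta0 - Bw %*% beta||^2 +
#' lambda * (alpha * ||beta||_1 + (1 - alpha)/2 * ||beta||_2^2)` with an
#' unpenalized intercept; at `alpha = 0.5` the L1 and squared-L2 penalty
#' weights are `0.5 * lambda` and `0.25 * lambda`. Regressors are scaled to
#' unit variance before penalization and coefficients reported on the
#' original scale. The quadratic part carries the conventional `1/(2n)`
#' factor, so `lambda` here is on the per-observation scale.
#'
#' @param outcome Numeric (whitened) outcome vector.
#' @param x Numeric (whitened) regressor matrix.
#' @param lambda Penalty value (>= 0), or a descending path.
#' @param alpha Elastic-net mixing parameter in \[0, 1\] (default 0.5).
#' @return A list with `beta0` and `beta` (a vector for scalar `lambda`, a
#'   p x L matrix for a path) and the `lambda` values used.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X[, 1] + rnorm(20)
#' elastic_net(y, X, lambda = 0.1)
#' @export
elastic_net <- function(outcome, x, lambda, alpha = 0.5) {
  x <- as.matrix(x)
  res <- en_core(outcome, x, rep(1, length(outcome)), lambda, alpha)
  if (length(lambda) == 1) {
    list(beta0 = res$beta0[1], beta = drop(res$beta), lambda = res$lambda)
  } else res
}

new_pengls_fit <- function(beta0, beta, lambda, alpha, cov_params, n_iter,
                           converged, regressors, fitted, residuals, n,
                           method, trace = numeric(), eigen_beta = NULL) {
  names(beta) <- regressors
  structure(
    list(beta0 = beta0, beta = beta, lambda = lambda, alpha = alpha,
         cov_params = cov_params, n_iter = n_iter, converged = converged,
         selected = which(beta != 0), regressors = regressors,
         fitted = fitted, residuals = residuals, n = n, method = method,
         trace = trace, eigen_beta = eigen_beta),
    class = "pengls_fit"
  )
}

#' GLS elastic net for spatially correlated data
#'
#' Alternates between (i) an elastic net fitted on outcome and design
#' premultiplied by the inverse square-root factor of the current residual
#' covariance (with an unpenalized whitened intercept), and (ii) restricted
#' maximum-likelihood re-estimation of a Gaussian-decay covariance from the
#' residuals `A - beta0 - B %*% beta` under an intercept-only mean model.
#' The covariance starts at the identity matrix, so the first pass is a plain
#' elastic net; the loop stops when the mean squared change in predictions
#' between iterations drops below 0.00025. Whitening removes the selection
#' advantage that spatially structured regressors enjoy under spatially
#' structured outcomes ("red-shift").
#'
#' @inheritParams fit_ols
#' @param lambda Penalty value; typically tuned with [tune_lambda()].
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param max_iter Maximum outer alternations (default 30). Non-convergence
#'   is reported via the `converged` flag, not an error.
#' @param tol Convergence tolerance on the mean squared change in
#'   predictions (default 0.00025).
#' @return A `pengls_fit` with the sparse coefficient vector, selected set,
#'   covariance parameters and convergence trace.
#' @examples
#' d <- simulate_observational(p = 20, n = 50, outcome_spec = "gaussCor",
#'                             regressor_spec = "gaussCor", beta_sd = 0.5,
#'                             seed = 7)
#' fit <- fit_pengls(d, lambda = 0.2)
#' fit$selected
#' @export
fit_pengls <- function(data, lambda, alpha = 0.5, outcome = "A",
                       regressors = NULL, max_iter = 30, tol = 0.00025) {
  mp <- model_parts(data, outcome, regressors)
  xy <- as_coords(data)
  n <- length(mp$A)
  p <- ncol(mp$B)
  D <- coord_dist(xy)

  cf <- diag(n)  # chol of the identity: plain EN on the first pass
  cp <- structure(list(sigma2 = NA_real_, r = NA_real_, tau = 1),
                  class = "gauss_cov_params")
  cp_start <- NULL
  fitted_prev <- rep(mean(mp$A), n)
  trace <- numeric()
  converged <- FALSE
  beta0 <- mean(mp$A); beta <- numeric(p)

  for (it in seq_len(max_iter)) {
    w1 <- backsolve(cf, rep(1, n), transpose = TRUE)
    Bw <- backsolve(cf, mp$B, transpose = TRUE)
    Aw <- backsolve(cf, mp$A, transpose = TRUE)
    en <- en_core(Aw, Bw, w1, lambda, alpha)
    beta0 <- en$beta0[1]
    beta <- drop(en$beta)
    fitted <- drop(beta0 + mp$B %*% beta)
    delta <- mean((fitted - fitted_prev)^2)
    trace <- c(trace, delta)
    fitted_prev <- fitted
    if (delta < tol) { converged <- TRUE; break }
    resid <- mp$A - fitted
    cp_new <- tryCatch(
      fit_cov_params(resid, matrix(1, n, 1), xy, method = "REML", start = cp_start),
      error = function(e) e
    )
    if (inherits(cp_new, "error")) {
      warn(paste0("Covariance re-estimation failed (", conditionMessage(cp_new),
                  "); stopping at the current iterate."))
      break
    }
    cp <- cp_new
    cp_start <- cp_new
    cf <- chol(gauss_correlation(D, cp$r, cp$tau))
  }
  if (!converged && length(trace) == max_iter) {
    warn(sprintf("GLS elastic net did not converge in %d iterations (last change %.3g).",
                 max_iter, trace[length(trace)]))
  }
  new_pengls_fit(beta0, beta, lambda, alpha, cp, length(trace), converged,
                 mp$regressors, fitted_prev, mp$A - fitted_prev, n, "pengls",
                 trace = trace)
}

#' @export
print.pengls_fit <- function(x, ...) {
  cat(sprintf("<pengls_fit> %s, n = %d, p = %d, lambda = %.4g, alpha = %.2g\n",
              x$method, x$n, length(x$beta), x$lambda, x$alpha))
  cat(sprintf("selected %d feature(s)%s\n", length(x$selected),
              if (x$converged) "" else " (not converged)"))
  if (!is.na(x$cov_params$r)) {
    cat(sprintf("spatial covariance: sigma2 = %.3g, range = %.3g, nugget = %.3g (%d iterations)\n",
                x$cov_params$sigma2, x$cov_params$r, x$cov_params$tau, x$n_iter))
  }
  invisible(x)
}

#' Predict from an elastic-net fit
#'
#' Uses the intercept and regressor coefficients only; spatial terms
#' (the whitening covariance or spatial eigenvectors) are omitted, as they do
#' not transfer to new locations.
#'
#' @param object A `pengls_fit`.
#' @param newdata Data frame containing the fit's regressor columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pengls_fit <- function(object, newdata, ...) {
  missing <- setdiff(object$regressors, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("`newdata` lacks regressor columns: ", paste(missing, collapse = ", ")))
  }
  B <- as.matrix(newdata[object$regressors])
  drop(object$beta0 + B %*% object$beta)
}

#' Moran spatial eigenvectors
#'
#' Eigenvectors of the doubly-centered proximity matrix `M C M` with
#' `M = I - 11'/n` and `C = exp(-d/dbar)` (zero diagonal), where `dbar` is
#' the average nearest-neighbor distance. Columns with eigenvalue above
#' `threshold` times the leading eigenvalue are returned; they are
#' orthonormal, orthogonal to the constant vector, and ordered by decreasing
#' Moran's I of the pattern they encode.
#'
#' @param data Data frame with coordinate columns `x`, `y`.
#' @param threshold Relative eigenvalue cutoff (default 0.25).
#' @return An n x q matrix of eigenvector columns (possibly q = 0).
#' @examples
#' ncol(moran_eigenvectors(expand.grid(x = 1:5, y = 1:5)))
#' @export
moran_eigenvectors <- function(data, threshold = 0.25) {
  xy <- as_coords(data)
  n <- nrow(xy)
  if (n < 3) abort("Need at least 3 locations to extract spatial eigenvectors.")
  D <- coord_dist(xy)
  diag(D) <- Inf
  dbar <- mean(apply(D, 1, min))
  C <- exp(-D / dbar)
  diag(C) <- 0
  Cc <- sweep(C, 1, rowMeans(C))
  Cc <- sweep(Cc, 2, colMeans(Cc))
  eg <- eigen(Cc, symmetric = TRUE)
  keep <- eg$values > threshold * max(eg$values)
  if (!any(keep)) {
    inform("No eigenvalue exceeds the threshold; returning an empty eigenvector matrix.")
    return(matrix(0, n, 0))
  }
  E <- eg$vectors[, keep, drop = FALSE]
  colnames(E) <- paste0("eig_", seq_len(ncol(E)))
  E
}

#' Elastic net augmented with Moran spatial eigenvectors
#'
#' Fits a plain elastic net on the regressors plus the spatial eigenvectors
#' of [moran_eigenvectors()], a spatial-filtering comparator: the
#' eigenvectors soak up smooth spatial patterns so the penalty competes less
#' on spatial structure. Eigenvector coefficients are excluded from the
#' selected set and from predictions.
#'
#' @inheritParams fit_pengls
#' @param threshold Relative eigenvalue cutoff for the eigenvectors.
#' @return A `pengls_fit` (with `eigen_beta` holding the eigenvector
#'   coefficients).
#' @export
fit_en_eigen <- function(data, lambda, alpha = 0.5, outcome = "A",
                         regressors = NULL, threshold = 0.25) {
  mp <- model_parts(data, outcome, regressors)
  E <- moran_eigenvectors(data, threshold)
  X <- cbind(mp$B, E)
  en <- en_core(mp$A, X, rep(1, nrow(X)), lambda, alpha)
  p <- ncol(mp$B)
  beta <- drop(en$beta)[seq_len(p)]
  eig_beta <- if (ncol(E) > 0) drop(en$beta)[-seq_len(p)] else numeric(0)
  fitted <- drop(en$beta0[1] + mp$B %*% beta)
  cp <- structure(list(sigma2 = NA_real_, r = NA_real_, tau = 1),
                  class = "gauss_cov_params")
  new_pengls_fit(en$beta0[1], beta, sort(lambda, decreasing = TRUE)[1], alpha,
                 cp, 1L, TRUE, mp$regressors, fitted, mp$A - fitted,
                 length(mp$A), "en_eigen",
                 eigen_beta = setNames(eig_beta, colnames(E)))
}

#' Plain elastic net on a field dataset
#'
#' Convenience wrapper fitting the ordinary elastic net (no spatial
#' correction) with the package's standardization conventions; equivalent to
#' the first iterate of [fit_pengls()].
#'
#' @inheritParams fit_pengls
#' @return A `pengls_fit`.
#' @export
fit_en <- function(data, lambda, alpha = 0.5, outcome = "A", regressors = NULL) {
  mp <- model_parts(data, outcome, regressors)
  en <- en_core(mp$A, mp$B, rep(1, length(mp$A)), lambda, alpha)
  beta <- drop(en$beta)
  fitted <- drop(en$beta0[1] + mp$B %*% beta)
  cp <- structure(list(sigma2 = NA_real_, r = NA_real_, tau = 1),
                  class = "gauss_cov_params")
  new_pengls_fit(en$beta0[1], beta, sort(lambda, decreasing = TRUE)[1], alpha,
                 cp, 1L, TRUE, mp$regressors, fitted, mp$A - fitted,
                 length(mp$A), "en")
}
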