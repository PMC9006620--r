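#' Parameters of the Gaussian-decay spatial covariance model
#'
#' The covariance between observations at distance d is
#' `sigma2 * (tau * 1(d == 0) + (1 - tau) * exp(-(d/r)^2))`, i.e. the
#' correlation drops from 1 at the point itself to `1 - tau` just off it
#' (the nugget discontinuity) and then decays as a bell curve with range `r`.
#'
#' @param sigma2 Marginal variance (> 0).
#' @param r Range parameter (> 0), in coordinate distance units.
#' @param tau Nugget, in \[0, 1\]: the spatially uncorrelated variance
#'   fraction. `tau = 1` gives independent observations.
#' @return An object of class `gauss_cov_params`.
#' @examples
#' gauss_cov_params(sigma2 = 1, r = 7.5, tau = 0.25)
#' @export
gauss_cov_params <- function(sigma2, r, tau) {
  if (!is.numeric(sigma2) || length(sigma2) != 1 || !is.finite(sigma2) || sigma2 <= 0) {
    abort("`sigma2` must be a single positive number.")
  }
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r <= 0) {
    abort("`r` must be a single positive number.")
  }
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau < 0 || tau > 1) {
    abort("`tau` must lie in [0, 1].")
  }
  structure(list(sigma2 = sigma2, r = r, tau = tau), class = "gauss_cov_params")
}

#' @export
print.gauss_cov_params <- function(x, ...) {
  cat(sprintf("<gauss_cov_params> sigma2 = %.4g, range r = %.4g, nugget tau = %.4g\n",
              x$sigma2, x$r, x$tau))
  invisible(x)
}

# Extract an n x 2 coordinate matrix from a data frame (columns x, y) or a
# two-column matrix; errors on duplicated locations when requested.
as_coords <- function(data, require_distinct = TRUE) {
  if (is.matrix(data) && ncol(data) == 2) {
    xy <- data
  } else if (is.data.frame(data)) {
    if (!all(c("x", "y") %in% names(data))) {
      abort("`data` must contain coordinate columns `x` and `y`.")
    }
    xy <- cbind(data$x, data$y)
  } else {
    abort("Coordinates must be a data frame with columns x, y or an n x 2 matrix.")
  }
  storage.mode(xy) <- "double"
  if (require_distinct && anyDuplicated(xy) > 0) {
    abort("Duplicate coordinates found; all locations must be distinct.")
  }
  xy
}

# Dense Euclidean distance matrix between rows of an n x 2 coordinate matrix.
coord_dist <- function(xy) {
  unname(as.matrix(dist(xy)))
}

# Gaussian-decay correlation matrix: tau on the nugget, unit diagonal.
gauss_correlation <- function(D, r, tau) {
  C <- (1 - tau) * exp(-(D / r)^2)
  diag(C) <- 1
  C
}

#' Build the Gaussian-decay spatial covariance matrix
#'
#' Constructs `Sigma = sigma2 * (tau * I + (1 - tau) * exp(-(d_ij/r)^2))`
#' over the pairwise Euclidean distances `d_ij` of the supplied locations.
#' The result is symmetric, has `sigma2` on the diagonal, and is positive
#' semidefinite for any set of distinct points.
#'
#' @param params A [gauss_cov_params()] object.
#' @param data A data frame with coordinate columns `x` and `y` (or an n x 2
#'   matrix of coordinates). Locations must be distinct.
#' @return An n x n covariance matrix.
#' @examples
#' d <- expand.grid(x = 1:3, y = 1:3)
#' build_sigma(gauss_cov_params(1, 7.5, 0.25), d)
#' @export
build_sigma <- function(params, data) {
  stopifnot(inherits(params, "gauss_cov_params"))
  xy <- as_coords(data)
  D <- coord_dist(xy)
  params$sigma2 * gauss_correlation(D, params$r, params$tau)
}

#' Whitening factor of a covariance matrix
#'
#' Returns the symmetric inverse square root `W = Sigma^{-1/2}` such that
#' `W %*% Sigma %*% t(W)` is the identity (to 1e-8 in max norm). Premultiplying
#' outcome and design matrix by `W` turns a correlated-error regression into
#' one with uncorrelated homoscedastic errors.
#'
#' @param sigma A symmetric positive-definite matrix.
#' @param tol Relative eigenvalue tolerance below which the matrix is treated
#'   as singular.
#' @return The whitening matrix `W`.
#' @examples
#' whitening_factor(diag(4, 2))  # 0.5 * identity
#' @export
whitening_factor <- function(sigma, tol = 1e-10) {
  if (!is.matrix(sigma) || nrow(sigma) != ncol(sigma)) {
    abort("`sigma` must be a square matrix.")
  }
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(abs(sigma))) {
    abort("`sigma` must be symmetric.")
  }
  eg <- eigen(sigma, symmetric = TRUE)
  if (min(eg$values) <= tol * max(eg$values)) {
    abort("Covariance matrix is numerically singular; cannot whiten.")
  }
  eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
}

# Internal profiled negative log-likelihood over (r, tau) with sigma2 and the
# mean coefficients profiled out analytically. A and X are the outcome and
# mean-model design matrix (intercept included by the caller); D the distance
# matrix. Returns +large on a failed Cholesky so optimizers can step back.
profiled_nll <- function(r, tau, A, X, D, reml = TRUE) {
  C <- gauss_correlation(D, r, tau)
  cf <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(cf)) return(1e10)
  M <- backsolve(cf, cbind(A, X), transpose = TRUE)
  Aw <- M[, 1]
  Xw <- M[, -1, drop = FALSE]
  qrX <- qr(Xw)
  if (qrX$rank < ncol(Xw)) return(1e10)
  rss <- sum(qr.resid(qrX, Aw)^2)
  if (rss <= 0) return(1e10)
  n <- length(A)
  q <- ncol(X)
  logdetC <- 2 * sum(log(diag(cf)))
  if (reml) {
    df <- n - q
    s2 <- rss / df
    0.5 * (df * log(2 * pi) + df * log(s2) + logdetC +
             2 * sum(log(abs(diag(qr.R(qrX))))) + df)
  } else {
    s2 <- rss / n
    0.5 * (n * log(2 * pi) + n * log(s2) + logdetC + n)
  }
}

#' Gaussian negative log-likelihood of a spatial covariance model
#'
#' Evaluates the exact (or restricted) multivariate-normal negative
#' log-likelihood at fixed covariance parameters, with the mean-model
#' coefficients set to their generalized-least-squares values under that
#' covariance. Used as the objective underlying [fit_cov_params()].
#'
#' @param params A [gauss_cov_params()] object (all three parameters fixed).
#' @param outcome Numeric outcome vector.
#' @param design_matrix Mean-model design matrix (include an intercept column
#'   if one is wanted); `NULL` for a zero-mean model.
#' @param data Data frame with coordinate columns `x`, `y` (or n x 2 matrix).
#' @param method `"REML"` or `"ML"`.
#' @return A finite scalar negative log-likelihood.
#' @export
neg_log_likelihood <- function(params, outcome, design_matrix = NULL, data,
                               method = c("REML", "ML")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "gauss_cov_params"))
  xy <- as_coords(data)
  n <- length(outcome)
  if (nrow(xy) != n) abort("`outcome` length must match the number of locations.")
  D <- coord_dist(xy)
  C <- gauss_correlation(D, params$r, params$tau)
  cf <- tryCatch(chol(C), error = function(e) abort("Covariance matrix is not positive definite."))
  s2 <- params$sigma2
  if (is.null(design_matrix)) {
    if (method == "REML") abort("REML requires a mean-model design matrix.")
    e <- backsolve(cf, outcome, transpose = TRUE)
    quad <- sum(e^2) / s2
    return(0.5 * (n * log(2 * pi) + n * log(s2) + 2 * sum(log(diag(cf))) + quad))
  }
  X <- as.matrix(design_matrix)
  q <- ncol(X)
  M <- backsolve(cf, cbind(outcome, X), transpose = TRUE)
  Aw <- M[, 1]
  Xw <- M[, -1, drop = FALSE]
  qrX <- qr(Xw)
  rss <- sum(qr.resid(qrX, Aw)^2)
  logdetC <- 2 * sum(log(diag(cf)))
  if (method == "ML") {
    0.5 * (n * log(2 * pi) + n * log(s2) + logdetC + rss / s2)
  } else {
    # -2 l_REML = (n-q) log 2pi + log|Sigma| + log|X' Sigma^-1 X| + e' Sigma^-1 e
    # with Sigma = s2 * C; the s2 powers of the two determinants combine to n-q.
    logdetXwX <- 2 * sum(log(abs(diag(qr.R(qrX)))))
    0.5 * ((n - q) * log(2 * pi) + (n - q) * log(s2) + logdetC +
             logdetXwX + rss / s2)
  }
}

#' Estimate Gaussian-decay covariance parameters by (RE)ML
#'
#' Maximizes the profiled Gaussian log-likelihood over the range `r` and
#' nugget `tau` (on the (log r, logit tau) scale), with the variance `sigma2`
#' and mean coefficients profiled out analytically. The optimization
#' multistarts from a 3 x 3 grid of (r, tau) values because the surface is
#' flat and multimodal; range and nugget estimates from a single field are
#' strongly correlated and highly variable, so wide spread in the estimates
#' is expected.
#'
#' @param outcome Numeric outcome vector (the variable whose residual spatial
#'   structure is being estimated).
#' @param design_matrix Mean-model design matrix; defaults to an
#'   intercept-only column.
#' @param data Data frame with coordinate columns `x`, `y` (or n x 2 matrix).
#' @param method `"REML"` (default) or `"ML"`.
#' @param r_bounds Search bounds for the range; defaults to
#'   \[0.1, 2 * max pairwise distance\].
#' @param tau_bounds Search bounds for the nugget; defaults to
#'   \[1e-4, 1 - 1e-4\].
#' @param start Optional `gauss_cov_params` warm start added to the grid.
#' @return A `gauss_cov_params` object with attributes `loglik` (achieved
#'   log-likelihood), `converged`, and `method`.
#' @examples
#' d <- expand.grid(x = 1:8, y = 1:8)
#' set.seed(1)
#' a <- draw_variable(scenario_spec("gaussCor"), d)
#' fit_cov_params(a, data = d)
#' @export
fit_cov_params <- function(outcome, design_matrix = NULL, data,
                           method = c("REML", "ML"),
                           r_bounds = NULL, tau_bounds = c(1e-4, 1 - 1e-4),
                           start = NULL) {
  method <- match.arg(method)
  xy <- as_coords(data)
  n <- length(outcome)
  if (nrow(xy) != n) abort("`outcome` length must match the number of locations.")
  if (is.null(design_matrix)) design_matrix <- matrix(1, n, 1)
  X <- as.matrix(design_matrix)
  if (n <= ncol(X)) {
    abort(sprintf("Need more observations (%d) than mean parameters (%d) to estimate covariance.",
                  n, ncol(X)))
  }
  D <- coord_dist(xy)
  if (is.null(r_bounds)) r_bounds <- c(0.1, 2 * max(D))
  reml <- method == "REML"

  to_theta <- function(r, tau) c(log(r), qlogis((tau - tau_bounds[1]) / diff(tau_bounds)))
  from_theta <- function(theta) {
    r <- min(max(exp(theta[1]), r_bounds[1]), r_bounds[2])
    tau <- tau_bounds[1] + diff(tau_bounds) * plogis(theta[2])
    c(r, tau)
  }
  obj <- function(theta) {
    p <- from_theta(theta)
    profiled_nll(p[1], p[2], outcome, X, D, reml = reml)
  }

  starts <- expand.grid(r = c(2, 7.5, 15), tau = c(0.1, 0.5, 0.9))
  if (!is.null(start)) starts <- rbind(starts, c(start$r, start$tau))
  starts$r <- pmin(pmax(starts$r, r_bounds[1]), r_bounds[2])
  theta0 <- mapply(to_theta, starts$r, starts$tau)
  vals <- apply(theta0, 2, obj)
  ord <- order(vals)[seq_len(min(3, ncol(theta0)))]

  best <- NULL
  for (i in ord) {
    o <- tryCatch(
      optim(theta0[, i], obj, method = "Nelder-Mead",
            control = list(maxit = 200, reltol = 1e-7)),
      error = function(e) NULL
    )
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e10) {
    abort("Covariance parameter estimation failed: no start converged to a finite likelihood.")
  }
  p <- from_theta(best$par)
  r_hat <- p[1]; tau_hat <- p[2]

  # Recover the profiled sigma2 at the optimum.
  C <- gauss_correlation(D, r_hat, tau_hat)
  cf <- chol(C)
  M <- backsolve(cf, cbind(outcome, X), transpose = TRUE)
  rss <- sum(qr.resid(qr(M[, -1, drop = FALSE]), M[, 1])^2)
  s2 <- rss / if (reml) n - ncol(X) else n

  out <- gauss_cov_params(sigma2 = s2, r = r_hat, tau = tau_hat)
  attr(out, "loglik") <- -best$value
  attr(out, "converged") <- best$convergence == 0
  attr(out, "method") <- method
  out
}
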