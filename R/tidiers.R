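#' Tidy a GLS/OLS fit
#'
#' @param x A `gls_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic` and the two-sided `p.value` on `n - p - 1`
#'   degrees of freedom.
#' @method tidy gls_fit
#' @export
tidy.gls_fit <- function(x, ...) {
  df <- x$n - length(x$regressors) - 1
  stat <- x$coefficients / x$se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(stat),
    p.value = unname(2 * pt(-abs(stat), df))
  )
}

#' Glance at a GLS/OLS fit
#'
#' @param x A `gls_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the residual variance and spatial covariance
#'   parameters, log-likelihood, iteration count and convergence flags.
#' @method glance gls_fit
#' @export
glance.gls_fit <- function(x, ...) {
  tibble::tibble(
    sigma2 = x$cov_params$sigma2,
    range = x$cov_params$r,
    nugget = x$cov_params$tau,
    logLik = x$loglik,
    n_iter = x$n_iter,
    converged = x$converged,
    cov_failed = x$cov_failed,
    nobs = x$n
  )
}

#' Tidy an elastic-net fit
#'
#' @param x A `pengls_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` and `selected` (nonzero
#'   coefficient), intercept first.
#' @method tidy pengls_fit
#' @export
tidy.pengls_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$beta)),
    estimate = c(x$beta0, unname(x$beta)),
    selected = c(NA, unname(x$beta != 0))
  )
}

#' Glance at an elastic-net fit
#'
#' @param x A `pengls_fit`.
#' @param ... Unused.
#' @return A one-row tibble with penalty, mixing parameter, selection count,
#'   covariance parameters and convergence information.
#' @method glance pengls_fit
#' @export
glance.pengls_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    alpha = x$alpha,
    n_selected = length(x$selected),
    sigma2 = x$cov_params$sigma2,
    range = x$cov_params$r,
    nugget = x$cov_params$tau,
    n_iter = x$n_iter,
    converged = x$converged,
    nobs = x$n
  )
}
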