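#' Describe a spatial structure scenario
#'
#' A scenario specifies how a simulated field variable acquires spatial
#' structure: either through its mean surface (`"linear"` gradient or an
#' `"edge"` effect) or through spatially correlated noise (`"gaussCor"`,
#' Gaussian-decay correlation), or not at all (`"none"`).
#'
#' For `"linear"`, the mean at location (x, y) is `x * gamma[1] + y * gamma[2]`.
#' For `"edge"`, it is `beta_edge * d_edge(x, y)` where `d_edge` is the
#' distance to the closest field edge, taken to lie one unit outside the
#' border rows, so border cells have `d_edge = 1`. For `"gaussCor"`, the mean
#' is zero and the noise covariance is
#' `sigma2 * (tau * I + (1 - tau) * exp(-(d/r)^2))`.
#'
#' When `gamma` or `beta_edge` are left `NULL` they are drawn afresh for each
#' simulated variable: gradient components uniform on \[-0.5, 0.5\], edge
#' coefficient normal with mean 0 and variance 50.
#'
#' @param structure One of `"none"`, `"linear"`, `"edge"`, `"gaussCor"`.
#' @param sigma2 Residual variance (> 0). Default 1.
#' @param r Range of the Gaussian correlation decay, in grid distance units
#'   (`"gaussCor"` only). Default 7.5.
#' @param tau Nugget: fraction of variance that is spatially uncorrelated,
#'   in \[0, 1\] (`"gaussCor"` only). Default 0.25.
#' @param gamma Optional fixed 2-vector gradient (`"linear"` only).
#' @param beta_edge Optional fixed edge coefficient (`"edge"` only).
#'
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec("gaussCor", r = 7.5, tau = 0.25)
#' scenario_spec("linear", gamma = c(0.3, -0.1))
#' @export
scenario_spec <- function(structure = c("none", "linear", "edge", "gaussCor"),
                          sigma2 = 1, r = 7.5, tau = 0.25,
                          gamma = NULL, beta_edge = NULL) {
  structure <- match.arg(structure)
  if (!is.numeric(sigma2) || length(sigma2) != 1 || sigma2 <= 0) {
    abort("`sigma2` must be a single positive number.")
  }
  if (structure == "gaussCor") {
    if (!is.numeric(r) || length(r) != 1 || r <= 0) {
      abort("`r` (range) must be a single positive number.")
    }
    if (!is.numeric(tau) || length(tau) != 1 || tau < 0 || tau > 1) {
      abort("`tau` (nugget) must lie in [0, 1].")
    }
  }
  if (!is.null(gamma)) {
    if (structure != "linear") abort("`gamma` is only meaningful for structure 'linear'.")
    if (!is.numeric(gamma) || length(gamma) != 2) abort("`gamma` must be a numeric 2-vector.")
  }
  if (!is.null(beta_edge)) {
    if (structure != "edge") abort("`beta_edge` is only meaningful for structure 'edge'.")
    if (!is.numeric(beta_edge) || length(beta_edge) != 1) abort("`beta_edge` must be a single number.")
  }
  structure(
    list(structure = structure, sigma2 = sigma2,
         r = if (structure == "gaussCor") r else NULL,
         tau = if (structure == "gaussCor") tau else NULL,
         gamma = gamma, beta_edge = beta_edge),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$structure, "\n")
  cat("  sigma2 =", x$sigma2, "\n")
  if (x$structure == "gaussCor") cat("  range r =", x$r, ", nugget tau =", x$tau, "\n")
  if (!is.null(x$gamma)) cat("  gamma = (", x$gamma[1], ",", x$gamma[2], ")\n")
  if (!is.null(x$beta_edge)) cat("  beta_edge =", x$beta_edge, "\n")
  invisible(x)
}

#' Coerce to a scenario specification
#'
#' Passes [scenario_spec()] objects through and converts a bare structure name
#' (`"none"`, `"linear"`, `"edge"`, `"gaussCor"`) to a spec with default
#' parameters.
#'
#' @param x A `scenario_spec` or a single structure name.
#' @param arg Argument name used in error messages.
#' @return A `scenario_spec`.
#' @examples
#' as_scenario_spec("edge")
#' @export
as_scenario_spec <- function(x, arg = "scenario") {
  if (inherits(x, "scenario_spec")) return(x)
  if (is.character(x) && length(x) == 1) return(scenario_spec(x))
  abort(paste0("`", arg, "` must be a scenario_spec or a structure name."))
}
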