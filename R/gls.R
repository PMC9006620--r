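# Resolve outcome / regressor columns from a tabular dataset.
model_parts <- function(data, outcome = "A", regressors = NULL) {
  if (!outcome %in% names(data)) {
    abort(sprintf("Outcome column `%s` not found in `data`.", outcome))
  }
  regs <- regressors %||% setdiff(names(data), c("x", "y", outcome))
  missing <- setdiff(regs, names(data))
  if (length(missing) > 0) {
    abort(paste0("Regressor columns not found: ", paste(missing, collapse = ", ")))
  }
  B <- as.matrix(data[regs])
  storage.mode(B) <- "double"
  list(A = as.numeric(data[[outcome]]), B = B, regressors = regs)
}

new_gls_fit <- function(coefficients, se, cov_params, n_iter, converged, loglik,
                        sigma2, n, regressors, fitted, residuals, method,
                        cov_failed = FALSE, trace = numeric()) {
  structure(
    list(coefficients = coefficients, se = se, cov_params = cov_params,
         n_iter = n_iter, converged = converged, loglik = loglik,
         sigma2 = sigma2, n = n, regressors = regressors, fitted = fitted,
         residuals = residuals, method = method, cov_failed = cov_failed,
         trace = trace),
    class = "gls_fit"
  )
}

#' Ordinary least squares on a field dataset
#'
#' Baseline estimator that ignores spatial correlation. Coefficients, their
#' classical standard errors and the residual variance are returned in the
#' same container as [fit_gls()], with the nugget fixed at 1 (independent
#' errors).
#'
#' @param data A data frame with the outcome column and regressor columns
#'   (coordinate columns `x`, `y` are ignored as regressors).
#' @param outcome Name of the outcome column (default `"A"`).
#' @param regressors Optional character vector of regressor columns; defaults
#'   to every column except `x`, `y` and the outcome.
#' @return A `gls_fit` object; see [tidy.gls_fit()] and [glance.gls_fit()].
#' @examples
#' d <- simulate_observational(p = 2, n = 50, seed = 1)
#' tidy(fit_ols(d))
#' @export
fit_ols <- function(data, outcome = "A", regressors = NULL) {
  mp <- model_parts(data, outcome, regressors)
  X <- cbind(`(Intercept)` = 1, mp$B)
  n <- nrow(X); q <- ncol(X)
  if (n <= q) abort(sprintf("Need n > p + 1 (%d observations for %d coefficients).", n, q))
  qrX <- qr(X)
  if (qrX$rank < q) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, q)]]
    abort(paste0("Design matrix is rank deficient; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qrX, mp$A)
  fitted <- drop(X %*% beta)
  res <- mp$A - fitted
  s2 <- sum(res^2) / (n - q)
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(s2 * diag(XtXinv))
  names(se) <- names(beta)
  cp <- structure(list(sigma2 = s2, r = NA_real_, tau = 1), class = "gauss_cov_params")
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sum(res^2) / n) + n)
  new_gls_fit(beta, se, cp, n_iter = 0L, converged = TRUE, loglik = loglik,
              sigma2 = s2, n = n, regressors = mp$regressors, fitted = fitted,
              residuals = res, method = "OLS")
}

#' Generalized least squares with Gaussian-decay spatial covariance
#'
#' Iterates between estimating the Gaussian-decay covariance of the
#' residuals by (restricted) maximum likelihood ([fit_cov_params()]) and
#' refitting the regression on outcome and design premultiplied by the
#' inverse square-root factor of that covariance, until the mean squared
#' change in fitted values falls below `tol`. Standard errors come from
#' `sigma2 * (X' C^-1 X)^-1` at the fitted correlation `C`.
#'
#' If covariance estimation fails the fit falls back to OLS and is flagged
#' via `cov_failed`; downstream study code treats such runs as failures.
#'
#' @inheritParams fit_ols
#' @param method `"REML"` (default) or `"ML"` for the covariance step.
#' @param tol Convergence tolerance on the mean squared change in fitted
#'   values (default 1e-6).
#' @param max_iter Maximum alternation count (default 25).
#' @param cov_params Optional fixed [gauss_cov_params()]: skip covariance
#'   estimation and fit a single weighted least squares under this
#'   covariance. With `tau = 1` (identity correlation) the coefficients equal
#'   [fit_ols()] exactly.
#' @return A `gls_fit` object.
#' @examples
#' d <- simulate_observational(p = 1, n = 60, outcome_spec = "gaussCor",
#'                             beta = 0.5, seed = 3)
#' fit <- fit_gls(d)
#' tidy(fit)
#' @export
fit_gls <- function(data, outcome = "A", regressors = NULL,
                    method = c("REML", "ML"), tol = 1e-6, max_iter = 25,
                    cov_params = NULL) {
  method <- match.arg(method)
  mp <- model_parts(data, outcome, regressors)
  xy <- as_coords(data)
  X <- cbind(`(Intercept)` = 1, mp$B)
  n <- nrow(X); q <- ncol(X)
  if (n <= q) abort(sprintf("Need n > p + 1 (%d observations for %d coefficients).", n, q))

  if (!is.null(cov_params)) {
    stopifnot(inherits(cov_params, "gauss_cov_params"))
    C <- gauss_correlation(coord_dist(xy), if (is.na(cov_params$r)) 1 else cov_params$r,
                           cov_params$tau)
    cf <- chol(C)
    M <- backsolve(cf, cbind(mp$A, X), transpose = TRUE)
    qrXw <- qr(M[, -1, drop = FALSE])
    beta <- qr.coef(qrXw, M[, 1])
    names(beta) <- colnames(X)
    fitted <- drop(X %*% beta)
    resw <- qr.resid(qrXw, M[, 1])
    s2 <- sum(resw^2) / (n - q)
    se <- sqrt(s2 * diag(chol2inv(qr.R(qrXw))))
    names(se) <- names(beta)
    ll <- -neg_log_likelihood(gauss_cov_params(s2, if (is.na(cov_params$r)) 1 else cov_params$r,
                                               cov_params$tau),
                              mp$A, X, xy, method = method)
    return(new_gls_fit(beta, se, cov_params, n_iter = 1L, converged = TRUE,
                       loglik = ll, sigma2 = s2, n = n,
                       regressors = mp$regressors, fitted = fitted,
                       residuals = mp$A - fitted, method = method))
  }

  # iteration 0: identity covariance = OLS
  ols <- fit_ols(data, outcome, regressors)
  fitted_prev <- ols$fitted
  cp <- NULL
  trace <- numeric()
  converged <- FALSE
  beta <- ols$coefficients; se <- ols$se; s2 <- ols$sigma2; loglik <- ols$loglik

  for (it in seq_len(max_iter)) {
    cp_new <- tryCatch(
      fit_cov_params(mp$A, X, xy, method = method, start = cp),
      error = function(e) e
    )
    if (inherits(cp_new, "error")) {
      warn(paste0("Covariance estimation failed (", conditionMessage(cp_new),
                  "); falling back to OLS."))
      ols$cov_failed <- TRUE
      ols$converged <- FALSE
      return(ols)
    }
    cp <- cp_new
    C <- gauss_correlation(coord_dist(xy), cp$r, cp$tau)
    cf <- chol(C)
    M <- backsolve(cf, cbind(mp$A, X), transpose = TRUE)
    qrXw <- qr(M[, -1, drop = FALSE])
    beta <- qr.coef(qrXw, M[, 1])
    names(beta) <- colnames(X)
    fitted <- drop(X %*% beta)
    delta <- mean((fitted - fitted_prev)^2)
    trace <- c(trace, delta)
    fitted_prev <- fitted
    s2 <- cp$sigma2
    XtCiXinv <- chol2inv(qr.R(qrXw))
    se <- sqrt(s2 * diag(XtCiXinv))
    names(se) <- names(beta)
    loglik <- attr(cp, "loglik")
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("GLS did not converge in %d iterations (last change %.3g); returning best iterate.",
                 max_iter, trace[length(trace)]))
  }
  res <- mp$A - fitted_prev
  new_gls_fit(beta, se, cp, n_iter = length(trace), converged = converged,
              loglik = loglik, sigma2 = s2, n = n, regressors = mp$regressors,
              fitted = fitted_prev, residuals = res, method = method,
              trace = trace)
}

#' Wald test for a single regression coefficient
#'
#' Two-sided p-value of `t = beta_hat_j / se_j` on `n - p - 1` degrees of
#' freedom (covariance-parameter estimation is not counted, which is mildly
#' anti-conservative in principle).
#'
#' @param fit A `gls_fit` object.
#' @param j Regressor index (1-based, excluding the intercept) or regressor
#'   name.
#' @return A p-value in \[0, 1\].
#' @examples
#' d <- simulate_observational(p = 1, n = 50, beta = 0, seed = 4)
#' wald_test(fit_ols(d), 1)
#' @export
wald_test <- function(fit, j) {
  stopifnot(inherits(fit, "gls_fit"))
  p <- length(fit$regressors)
  if (is.character(j)) j <- match(j, fit$regressors)
  if (is.na(j) || j < 1 || j > p) {
    abort(sprintf("Coefficient index out of range (1..%d).", p))
  }
  tstat <- fit$coefficients[j + 1] / fit$se[j + 1]
  df <- fit$n - p - 1
  unname(2 * pt(-abs(tstat), df))
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("<gls_fit> %s, n = %d, p = %d%s\n", x$method, x$n,
              length(x$regressors),
              if (x$cov_failed) " [covariance estimation failed; OLS fallback]" else ""))
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  if (!is.na(x$cov_params$r)) {
    cat(sprintf("spatial covariance: sigma2 = %.3g, range = %.3g, nugget = %.3g (%d iterations%s)\n",
                x$cov_params$sigma2, x$cov_params$r, x$cov_params$tau, x$n_iter,
                if (x$converged) "" else ", not converged"))
  }
  invisible(x)
}

#' Predict from a GLS or OLS fit
#'
#' Predictions use the estimated coefficients only: the spatial error term is
#' deliberately omitted (no kriging), because the model's purpose is to
#' extrapolate the regressor--outcome relation to new fields, not to
#' interpolate the training field.
#'
#' @param object A `gls_fit`.
#' @param newdata Data frame containing the fit's regressor columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.gls_fit <- function(object, newdata, ...) {
  missing <- setdiff(object$regressors, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("`newdata` lacks regressor columns: ", paste(missing, collapse = ", ")))
  }
  B <- as.matrix(newdata[object$regressors])
  drop(cbind(1, B) %*% object$coefficients)
}

#' Add row and column dummy variables
#'
#' Augments a field dataset with indicator columns for each grid row and
#' column present in the sample, excluding a reference level (the smallest
#' present row / column), as used to correct checkerboard experiments for
#' row/column effects. Levels absent from the sample are skipped with a
#' message.
#'
#' @param data A field dataset with coordinate columns `x`, `y`.
#' @param grid_size Grid side `G`; taken from `data` attributes when omitted.
#' @return `data` with added columns `row_<k>` / `col_<k>`.
#' @examples
#' d <- simulate_checkerboard(9, seed = 1)
#' ncol(add_row_col_dummies(d)) - ncol(d)  # up to 17 + 17
#' @export
add_row_col_dummies <- function(data, grid_size = NULL) {
  G <- grid_size_of(data, grid_size)
  out <- data
  for (fam in c("row", "col")) {
    v <- if (fam == "row") data$y else data$x
    lev <- sort(unique(v))
    if (length(lev) < length(seq_len(G))) {
      inform(sprintf("%s levels absent from the sample are dropped: %s", fam,
                     paste(setdiff(seq_len(G), lev), collapse = ", ")))
    }
    for (l in lev[-1]) {
      out[[paste0(fam, "_", l)]] <- as.numeric(v == l)
    }
  }
  out
}
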