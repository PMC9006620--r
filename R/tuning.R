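# Descending log-spaced penalty path from the smallest all-zero penalty.
lambda_path <- function(A, B, alpha = 0.5, nlambda = 100, min_ratio = 0.01) {
  n <- length(A)
  yc <- A - mean(A)
  Bc <- scale(B, center = TRUE, scale = FALSE)
  sds <- sqrt(colSums(Bc^2) / n)
  sds[sds == 0] <- 1
  lmax <- max(abs(crossprod(sweep(Bc, 2, sds, "/"), yc))) / (n * alpha)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

one_se_rule <- function(lambda, r2_by_fold) {
  mean_r2 <- rowMeans(r2_by_fold)
  se_r2 <- apply(r2_by_fold, 1, sd) / sqrt(ncol(r2_by_fold))
  best <- which.max(mean_r2)
  thr <- mean_r2[best] - se_r2[best]
  chosen <- which(mean_r2 >= thr)[1]  # path is descending: first = largest lambda
  list(lambda = lambda[chosen], lambda_best = lambda[best],
       cv = tibble::tibble(lambda = lambda, mean_r2 = mean_r2, se_r2 = se_r2))
}

#' Tune the elastic-net penalty by cross-validated R-squared
#'
#' Computes the held-out mean-centered R-squared along a descending penalty
#' path (100 values, log-spaced down to 1% of the smallest all-zero penalty)
#' and applies the one-standard-error rule: the largest penalty whose mean CV
#' R-squared is within one standard error of the best is returned.
#'
#' For `method = "pengls"` a full alternating fit per fold and penalty value
#' is avoided: each fold's spatial covariance is estimated once by running
#' the alternating scheme at a reference penalty (the plain elastic net's
#' one-SE choice over the same folds), and the penalty path is then evaluated
#' with that whitening held fixed. The final model should be refit with
#' [fit_pengls()] at the returned penalty.
#'
#' @param data A field dataset with columns `x`, `y`, the outcome and
#'   regressors.
#' @param folds A fold assignment from [random_folds()] or [blocked_folds()]
#'   (at least 2 folds).
#' @param method `"en"`, `"pengls"` or `"en_eigen"`.
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param nlambda,lambda_min_ratio Path resolution and lower endpoint.
#' @param outcome,regressors Column selection as in [fit_ols()].
#' @return A `lambda_tuning` list: `lambda` (the one-SE choice),
#'   `lambda_best`, and the per-penalty CV table `cv`.
#' @examples
#' d <- simulate_observational(p = 20, n = 50, beta_sd = 1, seed = 9)
#' tl <- tune_lambda(d, random_folds(50, 5, seed = 1), method = "en")
#' tl$lambda
#' @export
tune_lambda <- function(data, folds, method = c("en", "pengls", "en_eigen"),
                        alpha = 0.5, nlambda = 100, lambda_min_ratio = 0.01,
                        outcome = "A", regressors = NULL) {
  method <- match.arg(method)
  mp <- model_parts(data, outcome, regressors)
  f <- as.integer(folds)
  ks <- sort(unique(f))
  if (length(ks) < 2) abort("Need at least 2 folds to tune lambda.")
  path <- lambda_path(mp$A, mp$B, alpha, nlambda, lambda_min_ratio)

  fold_r2 <- function(predict_path) {
    vapply(ks, function(k) {
      tr <- f != k
      te <- !tr
      preds <- tryCatch(predict_path(tr, te), error = function(e) NULL)
      if (is.null(preds)) return(rep(0, length(path)))
      apply(preds, 2, function(ph) r_squared_centered(mp$A[te], ph))
    }, numeric(length(path)))
  }

  en_path_fold <- function(tr, te, X_extra = NULL, eigen_train = FALSE) {
    B_tr <- mp$B[tr, , drop = FALSE]
    X_tr <- if (eigen_train) {
      cbind(B_tr, moran_eigenvectors(data[tr, , drop = FALSE]))
    } else B_tr
    en <- en_core(mp$A[tr], X_tr, rep(1, sum(tr)), path, alpha)
    bet <- en$beta[seq_len(ncol(mp$B)), , drop = FALSE]
    sweep(mp$B[te, , drop = FALSE] %*% bet, 2, en$beta0, "+")
  }

  if (method %in% c("en", "en_eigen")) {
    r2 <- fold_r2(function(tr, te) en_path_fold(tr, te, eigen_train = method == "en_eigen"))
    res <- one_se_rule(path, r2)
  } else {
    ref <- one_se_rule(path, fold_r2(function(tr, te) en_path_fold(tr, te)))$lambda
    r2 <- fold_r2(function(tr, te) {
      train <- data[tr, , drop = FALSE]
      pf <- fit_pengls(train, lambda = ref, alpha = alpha, outcome = outcome,
                       regressors = mp$regressors)
      cfm <- if (is.na(pf$cov_params$r)) {
        diag(sum(tr))
      } else {
        chol(gauss_correlation(coord_dist(as_coords(train)), pf$cov_params$r,
                               pf$cov_params$tau))
      }
      w1 <- backsolve(cfm, rep(1, sum(tr)), transpose = TRUE)
      Bw <- backsolve(cfm, mp$B[tr, , drop = FALSE], transpose = TRUE)
      Aw <- backsolve(cfm, mp$A[tr], transpose = TRUE)
      en <- en_core(Aw, Bw, w1, path, alpha)
      sweep(mp$B[te, , drop = FALSE] %*% en$beta, 2, en$beta0, "+")
    })
    res <- one_se_rule(path, r2)
  }
  structure(res, class = "lambda_tuning")
}

#' @export
print.lambda_tuning <- function(x, ...) {
  cat(sprintf("<lambda_tuning> one-SE lambda = %.4g (best-R2 lambda = %.4g)\n",
              x$lambda, x$lambda_best))
  invisible(x)
}
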