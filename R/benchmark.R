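# Deterministic per-replicate seed below 2^31, independent of execution order.
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) %% 2147483647 * 48271 + index * 2654435) %% 2147483629 + 1)
}

new_study_result <- function(rows, failures, config) {
  out <- dplyr::bind_rows(rows)
  attr(out, "failures") <- dplyr::bind_rows(failures)
  attr(out, "config") <- config
  class(out) <- c("study_result", class(out))
  out
}

#' Study failures
#'
#' @param result A `study_result` from one of the `run_*()` functions.
#' @return A tibble of logged per-replicate failures (possibly empty).
#' @export
study_failures <- function(result) {
  attr(result, "failures") %||% tibble::tibble()
}

#' Univariate observational Monte-Carlo study
#'
#' For every combination of outcome and regressor spatial structure,
#' simulates univariate observational datasets and records, per method, the
#' Wald-test rejection at the 5% level (type I error under the null setting
#' `beta = 0`; power under the alternative `beta ~ N(0, 0.25)`) and the
#' squared error of the coefficient estimate under the alternative.
#'
#' @param reps Monte-Carlo replicates per cell (the full study used 1000;
#'   default 100).
#' @param methods Subset of `c("ols", "gls")`.
#' @param outcome_structures,regressor_structures Structure names to cross.
#' @param settings Subset of `c("null", "alternative")`.
#' @param n,G Sample size and grid side (defaults 100 and 15).
#' @param level Significance level (default 0.05).
#' @param master_seed Integer master seed; replicate seeds are derived from it.
#' @return A `study_result` tibble with one row per
#'   (replicate, method, scenario pair, setting, metric).
#' @export
run_univariate_observational <- function(reps = 100, methods = c("ols", "gls"),
                                         outcome_structures = c("none", "linear", "edge", "gaussCor"),
                                         regressor_structures = c("none", "linear", "edge", "gaussCor"),
                                         settings = c("null", "alternative"),
                                         n = 100, G = 15, level = 0.05,
                                         master_seed = 1) {
  if (length(methods) == 0) abort("At least one method must be requested.")
  methods <- match.arg(methods, c("ols", "gls"), several.ok = TRUE)
  grid <- expand.grid(outcome = outcome_structures, regressor = regressor_structures,
                      setting = settings, rep = seq_len(reps),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid) * length(methods))
  fails <- list()
  ri <- 0L
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    set.seed(derive_seed(master_seed, i))
    beta <- if (g$setting == "null") 0 else rnorm(1, 0, sqrt(0.25))
    d <- simulate_observational(p = 1, n = n, G = G,
                                outcome_spec = g$outcome,
                                regressor_spec = g$regressor,
                                spatial_fraction = 1, beta = beta)
    for (m in methods) {
      ri <- ri + 1L
      fit <- tryCatch(
        suppressWarnings(if (m == "ols") fit_ols(d) else fit_gls(d)),
        error = function(e) NULL
      )
      failed <- is.null(fit) || isTRUE(fit$cov_failed)
      if (failed) {
        fails[[length(fails) + 1]] <- tibble::tibble(
          study = "univariate_observational", replicate = g$rep, method = m,
          scenario_outcome = g$outcome, scenario_regressor = g$regressor,
          setting = g$setting)
      }
      pv <- if (failed) NA_real_ else wald_test(fit, 1)
      rows[[ri]] <- tibble::tibble(
        replicate = g$rep, method = m,
        scenario_outcome = g$outcome, scenario_regressor = g$regressor,
        setting = g$setting,
        metric = c("reject", "beta_se2"),
        value = c(as.numeric(pv < level),
                  if (failed || g$setting == "null") NA_real_
                  else (fit$coefficients[2] - beta)^2))
    }
  }
  new_study_result(rows, fails,
                   list(study = "univariate_observational", reps = reps,
                        methods = methods, n = n, G = G, level = level,
                        master_seed = master_seed))
}

#' Univariate checkerboard Monte-Carlo study
#'
#' Type I error of the treatment test in a checkerboard experiment on an
#' 18 x 18 field, per outcome structure, subplot size and row/column
#' correction.
#'
#' @inheritParams run_univariate_observational
#' @param subplot_sizes Subset of `c(9, 6, 3)`.
#' @param corrections Logical values: fit with and/or without row/column
#'   dummy correction.
#' @param beta True treatment effect (0 for the null study).
#' @return A `study_result` tibble.
#' @export
run_univariate_checkerboard <- function(reps = 100, methods = c("ols", "gls"),
                                        outcome_structures = c("none", "linear", "edge", "gaussCor"),
                                        subplot_sizes = c(9, 6, 3),
                                        corrections = c(FALSE, TRUE),
                                        beta = 0, n = 100, level = 0.05,
                                        master_seed = 1) {
  if (!all(subplot_sizes %in% c(9, 6, 3))) abort("`subplot_sizes` must be among 9, 6, 3.")
  methods <- match.arg(methods, c("ols", "gls"), several.ok = TRUE)
  grid <- expand.grid(outcome = outcome_structures, size = subplot_sizes,
                      rep = seq_len(reps), stringsAsFactors = FALSE)
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    set.seed(derive_seed(master_seed, i))
    d <- simulate_checkerboard(g$size, outcome_spec = g$outcome, beta = beta, n = n)
    for (corr in corrections) {
      dd <- if (corr) suppressMessages(add_row_col_dummies(d)) else d
      for (m in methods) {
        fit <- tryCatch(
          suppressWarnings(if (m == "ols") fit_ols(dd) else fit_gls(dd)),
          error = function(e) NULL
        )
        failed <- is.null(fit) || isTRUE(fit$cov_failed)
        if (failed) {
          fails[[length(fails) + 1]] <- tibble::tibble(
            study = "univariate_checkerboard", replicate = g$rep, method = m,
            scenario_outcome = g$outcome, subplot_size = g$size, corrected = corr)
        }
        pv <- if (failed) NA_real_ else wald_test(fit, "B_1")
        rows[[length(rows) + 1]] <- tibble::tibble(
          replicate = g$rep, method = m, scenario_outcome = g$outcome,
          subplot_size = g$size, corrected = corr, metric = "reject",
          value = as.numeric(pv < level))
      }
    }
  }
  new_study_result(rows, fails,
                   list(study = "univariate_checkerboard", reps = reps,
                        methods = methods, n = n, level = level,
                        master_seed = master_seed))
}

# Shared evaluation of one fitted low-dimensional model on one replicate.
lowdim_metrics_for <- function(data, folds_by_scheme, fitter, truth, seed) {
  n <- nrow(data)
  full_fit <- fitter(data)
  if (is.null(full_fit)) return(NULL)
  # train minus one fold, matching the held-out size used in CV
  hold <- as.integer(folds_by_scheme[["random"]]) == 1L
  sub_fit <- fitter(data[!hold, , drop = FALSE])
  if (is.null(sub_fit)) return(NULL)
  test_sp <- simulate_test_set(truth, "spatial", n = 10, seed = seed)
  test_no <- simulate_test_set(truth, "none", n = 10, seed = seed + 1L)

  out <- list()
  for (scheme in names(folds_by_scheme)) {
    f <- folds_by_scheme[[scheme]]
    out[[paste0("cv_r2_", scheme)]] <- cv_r_squared(data, f, fitter)
    im <- vapply(sort(unique(as.integer(f))), function(k) {
      te <- data[as.integer(f) == k, , drop = FALSE]
      tr_fit <- tryCatch(fitter(data[as.integer(f) != k, , drop = FALSE]),
                         error = function(e) NULL)
      if (is.null(tr_fit)) return(NA_real_)
      tryCatch(adjusted_morans_i(te$A, te, "conditional", predict(tr_fit, te)),
               error = function(e) NA_real_)
    }, numeric(1))
    out[[paste0("moran_cv_", scheme)]] <- mean(im, na.rm = TRUE)
  }
  out$test_r2_spatial <- r_squared_centered(test_sp$A, predict(sub_fit, test_sp))
  out$test_r2_none <- r_squared_centered(test_no$A, predict(sub_fit, test_no))
  out$moran_train <- adjusted_morans_i(data$A, data, "conditional", predict(full_fit, data))
  out$moran_test <- adjusted_morans_i(test_sp$A, test_sp, "conditional",
                                      predict(sub_fit, test_sp))
  out$beta_mse <- beta_mse(full_fit$coefficients[-1], truth$beta)
  out
}

#' Low-dimensional Monte-Carlo study
#'
#' For OLS and GLS on p-regressor datasets (no feature selection), records
#' the three R-squared measures (random-CV, blocked-CV, spatial and
#' structure-free test sets), expectation-adjusted conditional Moran's I of
#' the residuals (training, held-out folds, test set) and the MSE of the
#' coefficient estimates.
#'
#' @inheritParams run_univariate_observational
#' @param p Number of regressors (default 50).
#' @param beta_sd Standard deviation of the nonzero true coefficients.
#' @param k Number of CV folds (default 10).
#' @return A `study_result` tibble.
#' @export
run_lowdim <- function(reps = 50, methods = c("ols", "gls"), p = 50, n = 100,
                       G = 15, beta_sd = 1,
                       outcome_structures = "none", regressor_structures = "none",
                       k = 10, master_seed = 1) {
  methods <- match.arg(methods, c("ols", "gls"), several.ok = TRUE)
  grid <- expand.grid(outcome = outcome_structures, regressor = regressor_structures,
                      rep = seq_len(reps), stringsAsFactors = FALSE)
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    seed_i <- derive_seed(master_seed, i)
    d <- simulate_observational(p = p, n = n, G = G, outcome_spec = g$outcome,
                                regressor_spec = g$regressor, beta_sd = beta_sd,
                                seed = seed_i)
    folds <- list(random = random_folds(n, k, seed = seed_i + 1L),
                  blocked = blocked_folds(d, k, seed = seed_i + 2L))
    for (m in methods) {
      fitter <- function(dd) {
        tryCatch(suppressWarnings({
          fit <- if (m == "ols") fit_ols(dd) else fit_gls(dd)
          if (isTRUE(fit$cov_failed)) NULL else fit
        }), error = function(e) NULL)
      }
      mets <- lowdim_metrics_for(d, folds, fitter, sim_truth(d), seed_i + 3L)
      if (is.null(mets)) {
        fails[[length(fails) + 1]] <- tibble::tibble(
          study = "lowdim", replicate = g$rep, method = m,
          scenario_outcome = g$outcome, scenario_regressor = g$regressor)
        mets <- list(cv_r2_random = 0, cv_r2_blocked = 0, test_r2_spatial = 0,
                     test_r2_none = 0)  # failed fits contribute R^2 = 0
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        replicate = g$rep, method = m, scenario_outcome = g$outcome,
        scenario_regressor = g$regressor,
        metric = names(mets), value = unlist(mets, use.names = FALSE))
    }
  }
  new_study_result(rows, fails,
                   list(study = "lowdim", reps = reps, methods = methods,
                        p = p, n = n, G = G, beta_sd = beta_sd, k = k,
                        master_seed = master_seed))
}

#' High-dimensional Monte-Carlo study
#'
#' For elastic-net variants (plain EN, GLS elastic net, EN with Moran
#' eigenvectors) with the penalty tuned per CV paradigm by the
#' one-standard-error rule: test R-squared on a structure-free test set, and
#' feature-selection metrics (sensitivity, true discovery proportion, and the
#' proportion of spatially structured features among the discoveries, whose
#' unbiased value is 0.5).
#'
#' @inheritParams run_lowdim
#' @param methods Subset of `c("en", "pengls", "en_eigen")`.
#' @param p Number of regressors (default 100).
#' @param beta_sd Standard deviation of nonzero true coefficients
#'   (default 0.5).
#' @param schemes CV paradigms used for tuning, subset of
#'   `c("random", "blocked")`.
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @return A `study_result` tibble.
#' @export
run_highdim <- function(reps = 50, methods = c("en", "pengls", "en_eigen"),
                        p = 100, n = 50, G = 15, beta_sd = 0.5,
                        outcome_structures = "gaussCor",
                        regressor_structures = "gaussCor",
                        k = 5, schemes = "random", alpha = 0.5,
                        master_seed = 1) {
  methods <- match.arg(methods, c("en", "pengls", "en_eigen"), several.ok = TRUE)
  grid <- expand.grid(outcome = outcome_structures, regressor = regressor_structures,
                      rep = seq_len(reps), stringsAsFactors = FALSE)
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    seed_i <- derive_seed(master_seed, i)
    d <- simulate_observational(p = p, n = n, G = G, outcome_spec = g$outcome,
                                regressor_spec = g$regressor, beta_sd = beta_sd,
                                seed = seed_i)
    truth <- sim_truth(d)
    test_no <- simulate_test_set(truth, "none", n = 10, seed = seed_i + 1L)
    for (scheme in schemes) {
      f <- if (scheme == "random") random_folds(n, k, seed = seed_i + 2L)
           else blocked_folds(d, k, seed = seed_i + 2L)
      hold <- as.integer(f) == sort(unique(as.integer(f)))[1]
      for (m in methods) {
        res <- tryCatch(suppressWarnings(suppressMessages({
          tl <- tune_lambda(d, f, method = m, alpha = alpha)
          fit_full <- switch(m,
            en = fit_en(d, tl$lambda, alpha),
            pengls = fit_pengls(d, tl$lambda, alpha),
            en_eigen = fit_en_eigen(d, tl$lambda, alpha))
          fit_sub <- switch(m,
            en = fit_en(d[!hold, , drop = FALSE], tl$lambda, alpha),
            pengls = fit_pengls(d[!hold, , drop = FALSE], tl$lambda, alpha),
            en_eigen = fit_en_eigen(d[!hold, , drop = FALSE], tl$lambda, alpha))
          sel <- selection_metrics(fit_full$selected, truth)
          list(test_r2_none = r_squared_centered(test_no$A, predict(fit_sub, test_no)),
               sensitivity = sel$sensitivity, tdp = sel$tdp,
               spatial_prop = sel$spatial_prop, lambda = tl$lambda)
        })), error = function(e) NULL)
        if (is.null(res)) {
          fails[[length(fails) + 1]] <- tibble::tibble(
            study = "highdim", replicate = g$rep, method = m, scheme = scheme,
            scenario_outcome = g$outcome, scenario_regressor = g$regressor)
          res <- list(test_r2_none = 0, sensitivity = NA_real_, tdp = NA_real_,
                      spatial_prop = NA_real_, lambda = NA_real_)
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          replicate = g$rep, method = m, scheme = scheme,
          scenario_outcome = g$outcome, scenario_regressor = g$regressor,
          metric = names(res), value = unlist(res, use.names = FALSE))
      }
    }
  }
  new_study_result(rows, fails,
                   list(study = "highdim", reps = reps, methods = methods,
                        p = p, n = n, G = G, beta_sd = beta_sd, k = k,
                        schemes = schemes, alpha = alpha,
                        master_seed = master_seed))
}

#' Aggregate a study result
#'
#' Per-cell means with Monte-Carlo standard errors and counts; undefined
#' per-replicate metrics (`NA`) are dropped from the aggregation while failed
#' fits have already contributed R-squared 0 upstream.
#'
#' @param result A `study_result`.
#' @return A tibble with one row per cell and metric: `mean`, `mc_se`
#'   (`NA` for a single replicate), `n_reps`, `n_missing`.
#' @export
summarize_study <- function(result) {
  if (!inherits(result, "study_result") || nrow(result) == 0) {
    abort("`result` must be a non-empty study_result.")
  }
  keys <- setdiff(names(result), c("replicate", "value"))
  dplyr::group_by(tibble::as_tibble(result), dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      mc_se = ifelse(sum(!is.na(.data$value)) > 1,
                     sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
                     NA_real_),
      n_reps = sum(!is.na(.data$value)),
      n_missing = sum(is.na(.data$value)),
      .groups = "drop"
    )
}
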