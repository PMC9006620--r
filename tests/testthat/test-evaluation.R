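test_that("random_folds produce balanced reproducible assignments", {
  f <- random_folds(100, 10, seed = 1)
  expect_length(f, 100)
  expect_equal(sort(unique(as.integer(f))), 1:10)
  expect_true(all(table(f) == 10))
  # sizes differ by at most one when k does not divide n
  f2 <- random_folds(10, 3, seed = 2)
  expect_lte(diff(range(table(f2))), 1)
  # leave-one-out
  expect_true(all(table(random_folds(6, 6, seed = 3)) == 1))
  expect_identical(as.integer(random_folds(50, 5, seed = 4)),
                   as.integer(random_folds(50, 5, seed = 4)))
  expect_error(random_folds(5, 6), "Cannot make")
  expect_error(random_folds(5, 0), "at least 1")
})

test_that("blocked_folds recover spatial clusters and reduce within-fold spread", {
  # two well-separated clouds: k = 2 must split them exactly
  d <- tibble::tibble(x = c(1:5, 101:105), y = rep(1:5, 2))
  f <- blocked_folds(d, 2, seed = 5)
  expect_length(unique(f[1:5]), 1)
  expect_length(unique(f[6:10]), 1)
  expect_false(f[1] == f[6])
  expect_equal(unique(as.integer(blocked_folds(d, 1, seed = 6))), 1L)

  # blocked folds are spatially tighter than random folds
  mean_within <- function(d, f) {
    mean(vapply(unique(as.integer(f)), function(k) {
      xy <- cbind(d$x, d$y)[as.integer(f) == k, , drop = FALSE]
      if (nrow(xy) < 2) return(0)
      mean(dist(xy))
    }, numeric(1)))
  }
  set.seed(7)
  wins <- replicate(50, {
    dd <- sample_locations(15, 60)
    s <- sample.int(1e6, 1)
    mean_within(dd, blocked_folds(dd, 5, seed = s)) <
      mean_within(dd, random_folds(60, 5, seed = s + 1))
  })
  expect_true(all(wins))
})

test_that("r_squared_centered matches hand-computed values", {
  expect_equal(r_squared_centered(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared_centered(c(1, 2, 3), c(5, 5, 5)), 0)  # constant prediction
  expect_equal(r_squared_centered(c(1, 2, 3), c(1, 1, 4)), 0)  # worked example
  # shifting predictions by a constant changes nothing (mean-centering)
  set.seed(8)
  a <- rnorm(10); ah <- rnorm(10)
  expect_equal(r_squared_centered(a, ah), r_squared_centered(a, ah + 100))
  expect_lt(r_squared_centered(c(1, 2, 3), c(3, -2, 1)), 0)  # worse than the mean
  expect_error(r_squared_centered(1:3, 1:4), "lengths differ")
  expect_error(r_squared_centered(1, 1), "at least 2")
  expect_error(r_squared_centered(c(2, 2), c(1, 3)), "constant")
})

test_that("cv_r_squared is exact in noiseless cases and 0 for constant models", {
  d <- tibble::tibble(x = 1:20, y = rep(1:4, 5), A = 0, B_1 = rnorm(20))
  d$A <- 2 + 3 * d$B_1
  f <- random_folds(20, 4, seed = 9)
  expect_equal(cv_r_squared(d, f, fit_ols), 1, tolerance = 1e-10)
  # a model predicting a constant has centered R2 exactly 0 on every fold
  const_fit <- function(train) structure(list(mu = mean(train$A)), class = "constfit")
  expect_equal(cv_r_squared(d, f, const_fit,
                            predict_fun = function(fit, nd) rep(fit$mu, nrow(nd))),
               0)
  # failed folds contribute 0
  half_fail <- function(train) if (min(train$x) <= 2) stop("boom") else const_fit(train)
  cv <- cv_r_squared(d, f, half_fail,
                     predict_fun = function(fit, nd) rep(fit$mu, nrow(nd)))
  expect_equal(cv, 0)
  expect_error(cv_r_squared(d, rep(1L, 20), fit_ols), "at least 2")
  expect_error(cv_r_squared(d, f[1:5], fit_ols), "match the number of rows")
})

test_that("morans_i equals the brute-force double loop", {
  set.seed(10)
  for (i in 1:5) {
    n <- sample(5:20, 1)
    d <- sample_locations(10, n)
    v <- rnorm(n)
    xy <- cbind(d$x, d$y)
    expect_equal(morans_i(v, d, "marginal"),
                 moran_brute(v - mean(v), xy), tolerance = 1e-10)
    pr <- rnorm(n)
    expect_equal(morans_i(v, d, "conditional", predictions = pr),
                 moran_brute(v - pr, xy), tolerance = 1e-10)
  }
})

test_that("morans_i detects gradients and alternation with the right sign", {
  d <- expand.grid(x = 1:5, y = 1:5)
  expect_gt(morans_i(d$x, d, "marginal"), 0.1)           # smooth gradient
  chess <- (-1)^(d$x + d$y)
  expect_lt(morans_i(chess, d, "marginal"), -0.1)        # alternating pattern
  expect_error(morans_i(rep(1, 25), d), "Constant")
  expect_error(morans_i(1:2, d[1:2, ]), "at least 3")
  expect_error(morans_i(1:24, d), "must match")
  expect_error(morans_i(d$x, d, "conditional"), "predictions")
  dd <- tibble::tibble(x = c(1, 1, 2), y = c(1, 1, 2))
  expect_error(morans_i(1:3, dd), "Duplicate")
})

test_that("the mean of Moran's I over all permutations is -1/(n-1)", {
  # classical exact identity under exchangeability, here enumerated fully
  d <- tibble::tibble(x = c(1, 2, 4, 3, 5), y = c(1, 3, 2, 5, 4))
  v <- c(0.3, -1.2, 2.1, 0.4, -0.9)
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 5), ]
  vals <- apply(perms, 1, function(pp) morans_i(v[pp], d, "marginal"))
  expect_equal(mean(vals), -1 / 4, tolerance = 1e-10)
  # hence the adjusted statistic has exact permutation mean zero
  adj <- apply(perms, 1, function(pp) adjusted_morans_i(v[pp], d, "marginal"))
  expect_equal(mean(adj), 0, tolerance = 1e-10)
})

test_that("adjusted_morans_i is centered under independence (Monte Carlo)", {
  set.seed(11)
  sims <- replicate(400, {
    d <- sample_locations(12, 30)
    adjusted_morans_i(rnorm(30), d, "marginal")
  })
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims)), 4 * se + 1e-3)
  # and the offset is exactly 1/(n-1)
  d <- sample_locations(10, 20, seed = 12)
  v <- rnorm(20)
  expect_equal(adjusted_morans_i(v, d, "marginal"),
               morans_i(v, d, "marginal") + 1 / 19, tolerance = 1e-12)
})

test_that("beta_mse is the mean of squared errors", {
  expect_equal(beta_mse(c(1, 2, 3), c(0, 0, 0)), 14 / 3)
  expect_equal(beta_mse(c(1, 1), c(1, 1)), 0)
  expect_error(beta_mse(1:3, 1:2), "differ in length")
})

test_that("selection_metrics counts TP/FP against the truth", {
  truth <- list(beta = c(1, 0, -2, 0, 0, 3), spatial_flags = rep(c(TRUE, FALSE), each = 3))
  m <- selection_metrics(c(1, 2, 6), truth)
  expect_tbl(m)
  expect_equal(m$sensitivity, 2 / 3)   # hits 1 and 6 of {1, 3, 6}
  expect_equal(m$tdp, 2 / 3)           # 2 TP of 3 selected
  expect_equal(m$spatial_prop, 2 / 3)  # selections 1, 2 spatial; 6 not
  # logical selection vector
  expect_equal(selection_metrics(c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE), truth), m)
  # empty selection: sensitivity 0, the rest undefined
  m0 <- selection_metrics(integer(0), truth)
  expect_equal(m0$sensitivity, 0)
  expect_true(is.na(m0$tdp) && is.na(m0$spatial_prop))
  # no true support: sensitivity undefined
  m1 <- selection_metrics(integer(0), list(beta = c(0, 0), spatial_flags = c(TRUE, FALSE)))
  expect_true(is.na(m1$sensitivity))
  expect_error(selection_metrics(c(1, 9), truth), "1..6")
})

test_that("OLS residuals look clean in training but spatially structured out of sample", {
  set.seed(13)
  res <- t(replicate(150, {
    # many regressors relative to n: the in-sample fit soaks up the structure
    d <- simulate_observational(p = 50, n = 100, outcome_spec = "gaussCor",
                                regressor_spec = "none", beta_sd = 1)
    f <- fit_ols(d)
    ts <- simulate_test_set(sim_truth(d), "spatial", n = 12)
    c(train = adjusted_morans_i(d$A, d, "conditional", predict(f, d)),
      test = adjusted_morans_i(ts$A, ts, "conditional", predict(f, ts)))
  }))
  m_tr <- mean(res[, "train"]); m_te <- mean(res[, "test"])
  se_te <- sd(res[, "test"]) / sqrt(nrow(res))
  expect_lt(abs(m_tr), 0.1)           # in-sample fit absorbs the structure
  expect_gt(m_te, m_tr + 2 * se_te)   # held-out residuals reveal it
  expect_gt(m_te, 0)
})
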