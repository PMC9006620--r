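test_that("sample_locations draws distinct grid points and respects bounds", {
  d <- sample_locations(15, 100, seed = 1)
  expect_equal(nrow(d), 100)
  expect_true(all(d$x %in% 1:15) && all(d$y %in% 1:15))
  expect_equal(anyDuplicated(cbind(d$x, d$y)), 0L)
  expect_equal(attr(d, "grid_size"), 15)

  # exhaustive sample covers the full grid exactly once
  full <- sample_locations(4, 16, seed = 2)
  expect_setequal(paste(full$x, full$y),
                  paste(rep(1:4, 4), rep(1:4, each = 4)))

  expect_error(sample_locations(4, 17), "Cannot sample")
  expect_error(sample_locations(4, 0), "at least 1")

  expect_identical(sample_locations(15, 50, seed = 7),
                   sample_locations(15, 50, seed = 7))
  expect_false(identical(sample_locations(15, 50, seed = 7),
                         sample_locations(15, 50, seed = 8)))
})

test_that("mean_surface matches closed forms for each structure", {
  d <- tibble::tibble(x = c(3, 8, 1, 15), y = c(9, 8, 1, 15))
  expect_equal(mean_surface(scenario_spec("none"), d, grid_size = 15),
               rep(0, 4))
  expect_equal(mean_surface(scenario_spec("linear", gamma = c(1, 0)), d),
               c(3, 8, 1, 15))
  expect_equal(mean_surface(scenario_spec("linear", gamma = c(0.2, -0.4)), d),
               0.2 * d$x - 0.4 * d$y)
  # edge distance is 1 on the border, G/2 rounded up in the middle of a 15-grid
  expect_equal(mean_surface(scenario_spec("edge", beta_edge = 2), d, grid_size = 15),
               2 * pmin(d$x, d$y, 16 - d$x, 16 - d$y))
  expect_equal(mean_surface(scenario_spec("edge", beta_edge = 2), d, grid_size = 15)[3],
               2)  # corner cell (1,1)
  expect_error(mean_surface(scenario_spec("gaussCor"), d), "no mean structure")
})

test_that("unspecified linear/edge parameters are drawn from the documented laws", {
  set.seed(42)
  gam <- replicate(400, {
    d <- tibble::tibble(x = c(1, 2), y = c(1, 1))
    m <- mean_surface(scenario_spec("linear"), d, grid_size = 5)
    m[2] - m[1]  # = gamma[1]
  })
  expect_true(all(abs(gam) <= 0.5))
  expect_lt(abs(mean(gam)), 0.05)               # uniform on [-0.5, 0.5]: mean 0
  expect_lt(abs(var(gam) - 1 / 12), 0.02)       # variance 1/12

  set.seed(43)
  be <- replicate(400, {
    d <- tibble::tibble(x = 1, y = 1)
    mean_surface(scenario_spec("edge"), d, grid_size = 5)  # beta_edge * 1
  })
  expect_lt(abs(mean(be)), 1)
  expect_lt(abs(var(be) - 50) / 50, 0.25)       # variance 50
})

test_that("covariance_matrix matches the scenario definitions", {
  d <- tibble::tibble(x = c(1, 1, 5), y = c(1, 2, 5))
  expect_equal(covariance_matrix(scenario_spec("none"), d), diag(3))
  expect_equal(covariance_matrix(scenario_spec("linear", sigma2 = 2), d),
               diag(2, 3))
  S <- covariance_matrix(scenario_spec("gaussCor"), d)
  expect_equal(diag(S), rep(1, 3))
  expect_equal(S[1, 2], 0.75 * exp(-(1 / 7.5)^2))
  expect_equal(S, t(S))
  # tau = 1 kills all off-diagonal correlation
  expect_equal(covariance_matrix(scenario_spec("gaussCor", tau = 1), d), diag(3))
})

test_that("draw_variable has the documented mean and covariance (Monte Carlo)", {
  d <- tibble::tibble(x = c(1, 2, 6), y = c(1, 1, 6))
  spec <- scenario_spec("gaussCor", sigma2 = 1, r = 7.5, tau = 0.25)
  set.seed(11)
  draws <- t(replicate(4000, draw_variable(spec, d)))
  S_hat <- cov(draws)
  S <- covariance_matrix(spec, d)
  expect_lt(max(abs(S_hat - S)), 0.08)
  expect_lt(max(abs(colMeans(draws))), 0.06)

  set.seed(12)
  lin <- t(replicate(2000, draw_variable(scenario_spec("linear", gamma = c(1, 0), sigma2 = 4),
                                         d, grid_size = 6)))
  expect_lt(max(abs(colMeans(lin) - c(1, 2, 6))), 0.2)
  expect_lt(max(abs(apply(lin, 2, var) - 4)), 0.5)
  expect_lt(max(abs(cor(lin)[upper.tri(diag(3))])), 0.08)  # independent noise
})

test_that("simulate_observational obeys counts, flags and reproducibility", {
  d <- simulate_observational(p = 50, n = 80, G = 15, seed = 1)
  expect_s3_class(d, "fieldsim")
  expect_equal(nrow(d), 80)
  expect_named(d, c("x", "y", "A", paste0("B_", 1:50)))
  tr <- sim_truth(d)
  expect_equal(sum(tr$spatial_flags), 25)          # spatial_fraction 0.5
  expect_equal(sum(tr$beta != 0), 10)              # active_fraction 0.2
  expect_equal(sum(tr$beta[tr$spatial_flags] != 0), 5)   # 5 per group
  expect_equal(sum(tr$beta[!tr$spatial_flags] != 0), 5)

  expect_equal(as.data.frame(simulate_observational(p = 3, n = 20, seed = 5)),
               as.data.frame(simulate_observational(p = 3, n = 20, seed = 5)))

  expect_error(simulate_observational(p = 2, spatial_fraction = 1.5), "0, 1")
  expect_error(simulate_observational(p = 2, active_fraction = -0.1), "0, 1")

  # beta override wins over random support
  d0 <- simulate_observational(p = 4, n = 20, beta = 0, seed = 2)
  expect_equal(sim_truth(d0)$beta, rep(0, 4))
})

test_that("spatial outcome structure raises in-sample variance; gaussCor does not", {
  set.seed(21)
  v <- function(structure) {
    mean(replicate(200, {
      d <- sample_locations(15, 40)
      # a fresh scenario_spec each replicate redraws gamma / beta_edge
      var(draw_variable(scenario_spec(structure), d, grid_size = 15))
    }))
  }
  v_none <- v("none"); v_lin <- v("linear"); v_edge <- v("edge"); v_gc <- v("gaussCor")
  expect_gt(v_lin, 1.5 * v_none)   # gradients add between-location variance
  expect_gt(v_edge, 1.5 * v_none)  # edge effects likewise
  expect_lt(v_gc, 1.2 * v_none)    # correlated noise does not inflate variance
})

test_that("checkerboard design matches the parity rule and arm counts", {
  expect_true(checkerboard_treatment(1, 1, 9))          # (1+1) even
  expect_false(checkerboard_treatment(10, 1, 9))        # (2+1) odd
  full <- expand.grid(x = 1:18, y = 1:18)
  dc <- sqrt((full$x - 9.5)^2 + (full$y - 9.5)^2)  # distance from field center
  for (s in c(9, 3)) {
    tr <- checkerboard_treatment(full$x, full$y, s)
    expect_equal(sum(tr), 162)  # balanced arms on the full grid
    # balanced sizes place both arms symmetrically: no spatial confounding
    expect_equal(cor(as.numeric(tr), dc), 0)
  }
  # subplot size 6: 5 treated vs 4 control subplots, and the treated arm sits
  # systematically closer to the field border / farther from the center
  tr6 <- checkerboard_treatment(full$x, full$y, 6)
  expect_equal(sum(tr6), 5 * 36)
  expect_gt(abs(cor(as.numeric(tr6), dc)), 0.1)

  d <- simulate_checkerboard(6, outcome_spec = "edge", beta = 1.5, n = 90, seed = 3)
  expect_equal(sim_truth(d)$subplot_size, 6)
  expect_equal(sim_truth(d)$beta, 1.5)
  expect_equal(d$B_1, as.numeric(checkerboard_treatment(d$x, d$y, 6)))
  expect_error(simulate_checkerboard(5), "must divide")
})

test_that("test sets share the truth but not the training field's surface", {
  d <- simulate_observational(p = 6, n = 40, outcome_spec = "linear",
                              regressor_spec = "edge", seed = 9)
  tr <- sim_truth(d)
  ts <- simulate_test_set(tr, "spatial", n = 10, seed = 10)
  expect_equal(sim_truth(ts)$beta, tr$beta)
  expect_equal(nrow(ts), 10)
  expect_true(all(ts$x %in% 1:5) && all(ts$y %in% 1:5))
  expect_equal(anyDuplicated(cbind(ts$x, ts$y)), 0L)
  # gradient redrawn, not copied from training
  expect_false(isTRUE(all.equal(sim_truth(ts)$outcome_scenario$gamma,
                                tr$outcome_scenario$gamma)))
  ts0 <- simulate_test_set(d, "none", n = 12, seed = 11)
  expect_equal(sim_truth(ts0)$outcome_scenario$structure, "none")
  expect_equal(sim_truth(ts0)$regressor_scenario$structure, "none")
  expect_error(simulate_test_set(tr, "spatial", n = 26), "exceeds")
  dc <- simulate_checkerboard(9, seed = 1)
  expect_error(simulate_test_set(dc), "observational")
})

test_that("scenario_spec validates its arguments", {
  expect_error(scenario_spec("banana"))
  expect_error(scenario_spec("none", sigma2 = -1))
  expect_error(scenario_spec("gaussCor", tau = 2))
  sp <- scenario_spec("linear", gamma = c(1, 2))
  expect_equal(as_scenario_spec("edge")$structure, "edge")
  expect_identical(as_scenario_spec(sp), sp)
})
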