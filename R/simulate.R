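#' Sample observation locations from a square grid
#'
#' Locations are drawn without replacement and with equal probability from an
#' equispaced `G` x `G` grid with interpoint distance 1, indexed by integer
#' coordinates in `1..G`.
#'
#' @param G Grid side length (cells per side).
#' @param n Number of locations to sample; at most `G^2`.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with integer columns `x` and `y`, one row per location,
#'   all rows distinct, with attribute `grid_size = G`.
#' @examples
#' sample_locations(15, 100, seed = 1)
#' @export
sample_locations <- function(G, n, seed = NULL) {
  if (n > G^2) {
    abort(sprintf("Cannot sample n = %d distinct locations from a %d x %d grid (%d cells).",
                  n, G, G, G^2))
  }
  if (n < 1) abort("`n` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(x = seq_len(G), y = seq_len(G))
  idx <- sample.int(nrow(grid), n)
  out <- tibble::as_tibble(grid[idx, , drop = FALSE])
  attr(out, "grid_size") <- G
  out
}

grid_size_of <- function(data, grid_size = NULL) {
  G <- grid_size %||% attr(data, "grid_size")
  if (is.null(G)) {
    G <- max(data$x, data$y)
    warn(sprintf("No grid size supplied; using max coordinate (%d).", G))
  }
  G
}

# Distance to the closest field edge, with the edge taken to lie one unit
# outside the border rows so that border cells have distance 1.
edge_distance <- function(x, y, G) {
  pmin(x, y, G + 1 - x, G + 1 - y)
}

# Complete a scenario spec by drawing any absent mean-surface parameters
# (gamma uniform on [-0.5, 0.5]^2, beta_edge ~ N(0, var 50)) from the
# current RNG state.
materialize_scenario <- function(spec) {
  spec <- as_scenario_spec(spec)
  if (spec$structure == "linear" && is.null(spec$gamma)) {
    spec$gamma <- runif(2, -0.5, 0.5)
  }
  if (spec$structure == "edge" && is.null(spec$beta_edge)) {
    spec$beta_edge <- rnorm(1, 0, sqrt(50))
  }
  spec
}

#' Mean surface of a spatial scenario
#'
#' Evaluates the scenario's expected value at each location: zero for
#' `"none"`, the planar gradient `x * gamma[1] + y * gamma[2]` for
#' `"linear"`, and `beta_edge * d_edge(x, y)` for `"edge"`, where the edge
#' distance `min(x, y, G + 1 - x, G + 1 - y)` equals 1 on the border rows.
#' `"gaussCor"` has no mean structure (its spatial structure lives in the
#' covariance) and is rejected here.
#'
#' @param spec A [scenario_spec()]; absent `gamma`/`beta_edge` are drawn from
#'   the current RNG state.
#' @param data Data frame with coordinate columns `x`, `y`.
#' @param grid_size Grid side length `G`; taken from `data`'s attribute when
#'   omitted.
#' @return A numeric vector of means, one per row of `data`.
#' @examples
#' d <- sample_locations(15, 20, seed = 1)
#' mean_surface(scenario_spec("linear", gamma = c(1, 0)), d)
#' @export
mean_surface <- function(spec, data, grid_size = NULL) {
  spec <- as_scenario_spec(spec)
  if (spec$structure == "gaussCor") {
    abort("Scenario 'gaussCor' has no mean structure; its spatial structure is in the covariance.")
  }
  spec <- materialize_scenario(spec)
  switch(spec$structure,
    none = rep(0, nrow(data)),
    linear = data$x * spec$gamma[1] + data$y * spec$gamma[2],
    edge = {
      G <- grid_size_of(data, grid_size)
      spec$beta_edge * edge_distance(data$x, data$y, G)
    }
  )
}

#' Noise covariance matrix of a spatial scenario
#'
#' `"none"`, `"linear"` and `"edge"` scenarios have independent noise,
#' `sigma2 * I`; `"gaussCor"` uses the Gaussian-decay model of
#' [build_sigma()].
#'
#' @inheritParams mean_surface
#' @return An n x n covariance matrix.
#' @export
covariance_matrix <- function(spec, data) {
  spec <- as_scenario_spec(spec)
  n <- nrow(data)
  as_coords(data)  # validates distinctness
  if (spec$structure == "gaussCor") {
    build_sigma(gauss_cov_params(spec$sigma2, spec$r, spec$tau), data)
  } else {
    diag(spec$sigma2, n)
  }
}

# Factor L with L %*% t(L) = Sigma via eigendecomposition with an eigenvalue
# floor of 1e-10 * sigma2 (gaussCor matrices on dense grids are near-singular).
mvn_factor <- function(sigma, floor_rel = 1e-10) {
  eg <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(eg$values, floor_rel * max(eg$values))
  eg$vectors %*% diag(sqrt(lam), length(lam))
}

#' Draw one spatially structured variable
#'
#' Draws a multivariate-normal vector with mean [mean_surface()] (zero for
#' `"gaussCor"`) and covariance [covariance_matrix()] at the supplied
#' locations, using the current RNG state.
#'
#' @inheritParams mean_surface
#' @param factor Optional pre-computed covariance factor (as returned by the
#'   internal eigendecomposition); avoids refactorizing when drawing many
#'   variables on one design.
#' @return A numeric vector of length `nrow(data)`.
#' @examples
#' d <- sample_locations(15, 50, seed = 2)
#' a <- draw_variable(scenario_spec("gaussCor"), d)
#' @export
draw_variable <- function(spec, data, grid_size = NULL, factor = NULL) {
  spec <- as_scenario_spec(spec)
  n <- nrow(data)
  mu <- if (spec$structure == "gaussCor") rep(0, n) else mean_surface(spec, data, grid_size)
  if (spec$structure == "gaussCor") {
    L <- factor %||% mvn_factor(covariance_matrix(spec, data))
    drop(mu + L %*% rnorm(n))
  } else {
    mu + rnorm(n, sd = sqrt(spec$sigma2))
  }
}

new_fieldsim <- function(df, truth, grid_size, seed = NULL) {
  out <- tibble::as_tibble(df)
  attr(out, "grid_size") <- grid_size
  attr(out, "truth") <- truth
  attr(out, "seed") <- seed
  class(out) <- c("fieldsim", class(out))
  out
}

#' Ground truth of a simulated dataset
#'
#' @param data A dataset produced by one of the `simulate_*()` functions.
#' @return A list with elements `beta` (true coefficients), `spatial_flags`
#'   (logical, per regressor), `outcome_scenario`, `regressor_scenario`,
#'   `design` and, for checkerboard designs, `subplot_size`.
#' @export
sim_truth <- function(data) {
  tr <- attr(data, "truth")
  if (is.null(tr)) abort("`data` carries no simulation truth.")
  tr
}

regressor_names <- function(data) {
  setdiff(names(data), c("x", "y", "A"))
}

#' Simulate an observational field-trial dataset
#'
#' Generates `n` locations on a `G` x `G` grid, `p` regressors of which a
#' fraction carries spatial structure (each spatial regressor draws its own
#' independent gradient/edge coefficient/correlated noise), and an outcome
#' `A = f_a(x, y) + B %*% beta + noise`, where `f_a` and the noise covariance
#' follow `outcome_spec`. Within the spatial and non-spatial regressor groups
#' separately, a fraction `active_fraction` of the true coefficients is drawn
#' from `N(0, beta_sd^2)`; the rest are exactly zero, so spatially structured
#' features make up 50% of the truly predictive ones when
#' `spatial_fraction = 0.5`.
#'
#' @param p Number of regressors.
#' @param n Sample size (default 100).
#' @param G Grid side (default 15).
#' @param outcome_spec,regressor_spec [scenario_spec()]s (or structure names)
#'   for the outcome and for the spatially structured regressors.
#' @param beta_sd Standard deviation of the nonzero true coefficients.
#' @param spatial_fraction Fraction of regressors given spatial structure
#'   (default 0.5).
#' @param active_fraction Fraction of regressors, within each group, with
#'   nonzero true coefficient (default 0.2).
#' @param beta Optional vector of true coefficients overriding the random
#'   draw (recycled to length `p`); used for the univariate null (`beta = 0`)
#'   and alternative settings.
#' @param seed Optional integer seed.
#' @return A `fieldsim` tibble with columns `x`, `y`, `A`, `B_1..B_p` and the
#'   truth retrievable via [sim_truth()].
#' @examples
#' d <- simulate_observational(p = 5, n = 40, outcome_spec = "linear",
#'                             regressor_spec = "gaussCor", seed = 1)
#' sim_truth(d)$beta
#' @export
simulate_observational <- function(p, n = 100, G = 15,
                                   outcome_spec = "none", regressor_spec = "none",
                                   beta_sd = 1, spatial_fraction = 0.5,
                                   active_fraction = 0.2, beta = NULL,
                                   seed = NULL) {
  if (spatial_fraction < 0 || spatial_fraction > 1) abort("`spatial_fraction` must lie in [0, 1].")
  if (active_fraction < 0 || active_fraction > 1) abort("`active_fraction` must lie in [0, 1].")
  if (!is.null(seed)) set.seed(seed)
  outcome_spec <- as_scenario_spec(outcome_spec, "outcome_spec")
  regressor_spec <- as_scenario_spec(regressor_spec, "regressor_spec")

  design <- sample_locations(G, n)
  n_spatial <- round(spatial_fraction * p)
  spatial_flags <- seq_len(p) <= n_spatial

  if (is.null(beta)) {
    beta <- numeric(p)
    for (grp in list(which(spatial_flags), which(!spatial_flags))) {
      k <- round(active_fraction * length(grp))
      if (k > 0) beta[sample(grp, k)] <- rnorm(k, 0, beta_sd)
    }
  } else {
    beta <- rep_len(beta, p)
  }

  reg_factor <- if (regressor_spec$structure == "gaussCor" && n_spatial > 0) {
    mvn_factor(covariance_matrix(regressor_spec, design))
  } else NULL
  B <- matrix(0, n, p)
  for (j in seq_len(p)) {
    spec_j <- if (spatial_flags[j]) regressor_spec else scenario_spec("none", sigma2 = regressor_spec$sigma2)
    # each spatial regressor gets its own freshly drawn gamma / beta_edge
    if (spatial_flags[j]) spec_j[c("gamma", "beta_edge")] <- list(NULL, NULL)
    B[, j] <- draw_variable(spec_j, design, grid_size = G, factor = reg_factor)
  }
  colnames(B) <- paste0("B_", seq_len(p))

  outcome_done <- materialize_scenario(outcome_spec)
  A <- drop(B %*% beta) + draw_variable(outcome_done, design, grid_size = G)

  truth <- list(beta = beta, spatial_flags = spatial_flags,
                outcome_scenario = outcome_done, regressor_scenario = regressor_spec,
                grid_size = G, design = "observational")
  new_fieldsim(dplyr::bind_cols(design, tibble::tibble(A = A), tibble::as_tibble(B)),
               truth, G, seed)
}

#' Simulate a checkerboard experimental design
#'
#' An 18 x 18 field is partitioned into square subplots of side
#' `subplot_size`; treatment is assigned to subplots in a checkerboard
#' pattern (parity of the subplot-index sum), each cell inherits its
#' subplot's treatment, and `n` cells are sampled without replacement. The
#' outcome is `f_a(x, y) + beta * treatment + noise` under `outcome_spec`.
#' Subplot side 6 yields an uneven number of subplots per arm (5 vs 4), the
#' configuration in which edge effects are spatially confounded with
#' treatment.
#'
#' @param subplot_size Subplot side length; must divide 18.
#' @param outcome_spec [scenario_spec()] for the outcome.
#' @param beta True treatment effect (scalar).
#' @param n Sample size (default 100).
#' @param seed Optional integer seed.
#' @return A `fieldsim` tibble with columns `x`, `y`, `A` and the binary
#'   treatment column `B_1`.
#' @examples
#' d <- simulate_checkerboard(9, outcome_spec = "edge", beta = 0, seed = 1)
#' table(d$B_1)
#' @export
simulate_checkerboard <- function(subplot_size, outcome_spec = "none",
                                  beta = 0, n = 100, seed = NULL) {
  G <- 18L
  if (G %% subplot_size != 0) {
    abort(sprintf("`subplot_size` (%d) must divide %d.", subplot_size, G))
  }
  if (!is.null(seed)) set.seed(seed)
  outcome_spec <- as_scenario_spec(outcome_spec, "outcome_spec")
  design <- sample_locations(G, n)
  treat <- checkerboard_treatment(design$x, design$y, subplot_size)
  B <- matrix(as.numeric(treat), ncol = 1, dimnames = list(NULL, "B_1"))
  outcome_done <- materialize_scenario(outcome_spec)
  A <- beta * B[, 1] + draw_variable(outcome_done, design, grid_size = G)
  truth <- list(beta = beta, spatial_flags = FALSE,
                outcome_scenario = outcome_done,
                regressor_scenario = scenario_spec("none"),
                grid_size = G, design = "checkerboard",
                subplot_size = subplot_size)
  new_fieldsim(dplyr::bind_cols(design, tibble::tibble(A = A), tibble::as_tibble(B)),
               truth, G, seed)
}

#' Checkerboard treatment indicator
#'
#' @param x,y Integer cell coordinates.
#' @param subplot_size Subplot side length.
#' @return Logical: `TRUE` for treated cells (even subplot-index sum).
#' @export
checkerboard_treatment <- function(x, y, subplot_size) {
  (ceiling(x / subplot_size) + ceiling(y / subplot_size)) %% 2 == 0
}

#' Simulate a matched test set for a trained scenario
#'
#' Generates a small test dataset with the same true coefficients as a
#' training dataset. In `"spatial"` mode the outcome and regressors keep the
#' training structure types but redraw their gradient / edge coefficients,
#' and locations come from a 5 x 5 grid (similar spacing to the training
#' field); in `"none"` mode all spatial structure is removed, reflecting
#' performance across unrelated fields.
#'
#' @param truth A truth list from [sim_truth()] (or a `fieldsim` dataset).
#' @param mode `"spatial"` or `"none"`.
#' @param n Test size (default 10; at most 25 in spatial mode).
#' @param seed Optional integer seed.
#' @return A `fieldsim` tibble matching the training columns.
#' @export
simulate_test_set <- function(truth, mode = c("spatial", "none"), n = 10,
                              seed = NULL) {
  mode <- match.arg(mode)
  if (inherits(truth, "fieldsim")) truth <- sim_truth(truth)
  if (!identical(truth$design, "observational")) {
    abort("Test sets are only defined for observational training designs.")
  }
  G_test <- 5L
  if (mode == "spatial" && n > G_test^2) {
    abort(sprintf("Spatial test sets live on a %d x %d grid; n = %d exceeds %d cells.",
                  G_test, G_test, n, G_test^2))
  }
  if (!is.null(seed)) set.seed(seed)
  strip_params <- function(spec) { spec[c("gamma", "beta_edge")] <- list(NULL, NULL); spec }
  to_none <- function(spec) scenario_spec("none", sigma2 = spec$sigma2)
  out_spec <- if (mode == "spatial") strip_params(truth$outcome_scenario) else to_none(truth$outcome_scenario)
  reg_spec <- if (mode == "spatial") strip_params(truth$regressor_scenario) else to_none(truth$regressor_scenario)

  design <- sample_locations(G_test, n)
  p <- length(truth$beta)
  reg_factor <- if (reg_spec$structure == "gaussCor") {
    mvn_factor(covariance_matrix(reg_spec, design))
  } else NULL
  B <- matrix(0, n, p)
  for (j in seq_len(p)) {
    spec_j <- if (truth$spatial_flags[j]) reg_spec else to_none(truth$regressor_scenario)
    B[, j] <- draw_variable(spec_j, design, grid_size = G_test, factor = reg_factor)
  }
  colnames(B) <- paste0("B_", seq_len(p))
  out_done <- materialize_scenario(out_spec)
  A <- drop(B %*% truth$beta) + draw_variable(out_done, design, grid_size = G_test)
  truth_test <- truth
  truth_test$outcome_scenario <- out_done
  truth_test$regressor_scenario <- reg_spec
  truth_test$grid_size <- G_test
  new_fieldsim(dplyr::bind_cols(design, tibble::tibble(A = A), tibble::as_tibble(B)),
               truth_test, G_test, seed)
}
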