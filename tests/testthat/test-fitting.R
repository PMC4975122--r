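test_that("constrained repulsion recovers noiseless generating parameters", {
  dat <- noiseless_dataset("repulsion", gd_params(2.4, 20))
  fit <- fit_constrained_repulsion(dat, default_design)
  expect_lt(abs(fit$params$amplitude - 2.4), 1e-3)
  expect_lt(abs(fit$params$sigma - 20), 1e-3)
  expect_lt(fit$sse, 1e-6)
  expect_true(fit$converged)
})

test_that("constrained fit predicts exactly zero at every adapting age", {
  dat <- generate_dataset(simulation_config(truth_model = "repulsion",
                                            seed = 41))
  fit <- fit_constrained_repulsion(dat, default_design)
  for (cc in CONDITIONS) {
    expect_equal(predict_condition(default_design, cc, fit$params,
                                   adapt_age(default_design, cc)), 0)
  }
})

test_that("all-zero aftereffects give A = 0 with an unidentifiability flag", {
  dat <- noiseless_dataset("none")
  fit <- fit_constrained_repulsion(dat, default_design)
  expect_equal(fit$params$amplitude, 0)
  expect_false(fit$identifiable)
  expect_equal(fit$sse, 0)
  fitn <- fit_normalization(dat, default_design)
  expect_equal(fitn$params$gain, 0)
})

test_that("normalization gain has the closed-form weighted-average solution", {
  dat <- manual_dataset(
    pre_by_condition = list(young = c(20, 40, 60, 80),
                            middle = c(25, 45, 65, 85),
                            old = c(30, 50, 70, 88)),
    aftereffect_by_condition = list(young = rep(2.2, 4), middle = rep(0, 4),
                                    old = rep(-0.8, 4)))
  fit <- fit_normalization(dat, default_design)
  expect_equal(fit$params$gain, 0.1, tolerance = 1e-12)
  expect_equal(fit$sse, 0, tolerance = 1e-20)
  # independent 1-D grid oracle
  k_grid <- seq(-1, 1, by = 1e-4)
  y <- dat$points$aftereffect
  d <- 57 - vapply(dat$points$condition,
                   function(cc) adapt_age(default_design, cc), numeric(1))
  sse_grid <- vapply(k_grid, function(k) sum((y - k * d)^2), numeric(1))
  expect_equal(k_grid[which.min(sse_grid)], fit$params$gain, tolerance = 1e-4)
})

test_that("noiseless normalization data give the exact gain", {
  dat <- noiseless_dataset("normalization", norm_params(0.1, 57))
  fit <- fit_normalization(dat, default_design)
  expect_equal(fit$params$gain, 0.1, tolerance = 1e-12)
})

test_that("unconstrained GD recovers noiseless parameters per condition", {
  truth <- gd_params(2, 15, mu = 57)
  pre <- seq(18, 89, length.out = 24)
  dat <- manual_dataset(
    pre_by_condition = list(middle = pre, young = pre, old = pre),
    aftereffect_by_condition = list(middle = gd_aftereffect(pre, truth),
                                    young = rep(0, 24), old = rep(0, 24)))
  fit <- fit_unconstrained_gd(dat, "middle")
  expect_lt(abs(fit$params$amplitude - 2), 1e-3)
  expect_lt(abs(fit$params$sigma - 15), 1e-2)
  expect_lt(abs(fit$params$mu - 57), 1e-2)
})

test_that("a linear ramp drives the unconstrained GD to broad remote tuning", {
  # broad tuning plus a remote zero-crossing approximates a line over the
  # measured range, so an offset ramp is absorbed almost perfectly
  pre <- seq(18, 89, length.out = 24)
  ramp <- 2 + 0.02 * (pre - 53.5)
  dat <- manual_dataset(pre_by_condition = list(young = pre),
                        aftereffect_by_condition = list(young = ramp))
  fit <- fit_unconstrained_gd(dat, "young")
  expect_false(fit$params$mu >= 18 && fit$params$mu <= 89)
  expect_gt(fit$params$sigma, 25)
  ols <- fit_linear_regression(pre, ramp)
  rms_gd_vs_line <- rms_error(fit$fitted, ols$fitted)
  expect_lt(rms_gd_vs_line, 0.05 * rms_error(ramp, rep(0, length(ramp))))
})

test_that("model nesting orders the pooled SSE values", {
  dat <- generate_dataset(simulation_config(truth_model = "repulsion",
                                            seed = 55))
  fit_rep <- fit_constrained_repulsion(dat, default_design)
  fit_norm <- fit_normalization(dat, default_design)
  sse_zero <- sum(dat$points$aftereffect^2)
  expect_lte(fit_rep$sse, sse_zero)      # A = 0 is in the parameter space
  expect_lte(fit_norm$sse, sse_zero)     # k = 0 is in the parameter space
  sse_unc <- sum(vapply(CONDITIONS, function(cc)
    fit_unconstrained_gd(dat, cc)$sse, numeric(1)))
  expect_lte(sse_unc, fit_rep$sse + 1e-6)  # per-condition GD nests constrained
})

test_that("unconstrained SSE never exceeds the constrained SSE per condition", {
  dat <- generate_dataset(simulation_config(truth_model = "normalization",
                                            seed = 56))
  fit_rep <- fit_constrained_repulsion(dat, default_design)
  for (cc in CONDITIONS) {
    idx <- dat$points$condition == cc
    sse_constrained_cc <- sum((dat$points$aftereffect[idx] -
                                 fit_rep$fitted[idx])^2)
    fit_unc <- fit_unconstrained_gd(dat, cc)
    expect_lte(fit_unc$sse, sse_constrained_cc + 1e-6)
  }
})

test_that("multi-start optimizer matches dense grid search", {
  for (i in 1:5) {
    dat <- generate_dataset(simulation_config(
      truth_model = c("repulsion", "normalization", "none")[(i %% 3) + 1],
      n_faces_per_condition = 10, seed = 600 + i))
    fit <- fit_constrained_repulsion(dat, default_design)
    grid_sse <- grid_search_repulsion_sse(dat, default_design)
    expect_lt(abs(fit$sse - grid_sse) / grid_sse, 1e-3)
  }
})

test_that("parameter recovery sharpens with more faces per condition", {
  rmse_at_n <- function(n_faces, n_rep = 100, seed0 = 7000) {
    est <- vapply(seq_len(n_rep), function(i) {
      dat <- generate_dataset(simulation_config(
        truth_model = "repulsion", truth_params = gd_params(2.4, 20),
        n_faces_per_condition = n_faces, seed = seed0 + i))
      fit_constrained_repulsion(dat, default_design)$params$amplitude
    }, numeric(1))
    sqrt(mean((est - 2.4)^2))
  }
  rmse <- vapply(c(12, 24, 48), rmse_at_n, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("fit preconditions are enforced", {
  expect_error(fit_constrained_repulsion(
    manual_dataset(list(young = c(20, 40)), list(young = c(1, 1))),
    default_design), class = "ageadapt_insufficient_data")
  expect_error(fit_unconstrained_gd(
    manual_dataset(list(young = c(20, 40, 60)), list(young = c(1, 1, 1))),
    "young"), class = "ageadapt_insufficient_data")
})

test_that("straight-line regression has the textbook closed form", {
  fit <- fit_linear_regression(c(18, 89), c(0, 7.1))
  expect_equal(fit$slope, 0.1, tolerance = 1e-12)
  expect_equal(fit$intercept, -1.8, tolerance = 1e-12)
  x <- seq(18, 89, by = 1)
  const <- fit_linear_regression(x, rep(2.4, length(x)))
  expect_equal(const$slope, 0)
  expect_equal(const$intercept, 2.4)
  zero <- fit_linear_regression(x, rep(0, length(x)))
  expect_equal(zero$slope, 0)
  expect_equal(zero$intercept, 0)
  expect_error(fit_linear_regression(rep(5, 4), 1:4),
               class = "ageadapt_degenerate_regression")
})
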