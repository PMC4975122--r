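#' @keywords internal
#' @noRd
fit_result <- function(model_label, params, sse, n_points, fitted,
                       converged = TRUE, n_restarts_used = 0L,
                       identifiable = TRUE, condition = NULL) {
  structure(list(model_label = model_label, params = params, sse = sse,
                 n_points = n_points, fitted = fitted, converged = converged,
                 n_restarts_used = n_restarts_used,
                 identifiable = identifiable, condition = condition),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit: %s%s\n", x$model_label,
              if (is.null(x$condition)) "" else
                sprintf(" (condition %s)", x$condition)))
  if (inherits(x$params, "norm_params")) {
    cat(sprintf("  k = %.4g (norm age %.4g y)\n",
                x$params$gain, x$params$norm_age))
  } else if (inherits(x$params, "gd_params")) {
    cat(sprintf("  A = %.4g y, sigma = %.4g y%s\n",
                x$params$amplitude, x$params$sigma,
                if (is.na(x$params$mu)) "" else
                  sprintf(", mu = %.4g y", x$params$mu)))
  } else if (is.list(x$params)) {
    for (nm in names(x$params)) {
      p <- x$params[[nm]]
      cat(sprintf("  %s: A = %.4g y, sigma = %.4g y, mu = %.4g y\n",
                  nm, p$amplitude, p$sigma, p$mu))
    }
  }
  cat(sprintf("  SSE = %.5g over %d points; RMS = %.4g y%s\n",
              x$sse, x$n_points, sqrt(x$sse / x$n_points),
              if (x$identifiable) "" else "  [unidentifiable]"))
  invisible(x)
}

check_fit_data <- function(data, min_per_condition = 3L, min_conditions = 2L) {
  stopifnot(inherits(data, "rating_dataset"))
  pts <- data$points
  if (nrow(pts) == 0L) abort("dataset contains no points", "empty_input")
  counts <- tabulate(factor(pts$condition, levels = CONDITIONS))
  if (sum(counts >= min_per_condition) < min_conditions) {
    abort(sprintf(
      "need at least %d conditions with >= %d points each (have %s)",
      min_conditions, min_per_condition,
      paste(sprintf("%s=%d", CONDITIONS, counts), collapse = ", ")),
      "insufficient_data")
  }
  pts
}

# GD basis with unit peak: sqrt(e) * u * exp(-u^2/2); multiplying by A gives
# the full curve, so A enters the least-squares problem linearly.
gd_basis <- function(age, mu, sigma) {
  u <- (age - mu) / sigma
  sqrt(exp(1)) * u * exp(-u^2 / 2)
}

best_amplitude <- function(basis, y, lower, upper) {
  denom <- sum(basis^2)
  if (denom == 0) return(0)
  clamp(sum(basis * y) / denom, lower, upper)
}

#' Fit the constrained repulsion model
#'
#' Fits the two-parameter repulsion model: a Gaussian-derivative aftereffect
#' curve whose zero-crossing is forced to each condition's adapting age and
#' whose amplitude and bandwidth are shared across all conditions. The summed
#' squared residual is minimised jointly over the pooled data by bounded
#' quasi-Newton optimisation (`optim` L-BFGS-B) restarted from a grid of
#' bandwidths, with the amplitude initialised at its conditional
#' least-squares value (the model is linear in the amplitude at fixed
#' bandwidth). Ties between restarts are broken deterministically: smallest
#' bandwidth, then smallest absolute amplitude.
#'
#' @param data A `rating_dataset` with at least two conditions of three or
#'   more points each.
#' @param design A [study_design()] supplying the adapting ages.
#' @param sigma_grid Bandwidth restarts in years.
#' @param amplitude_bounds,sigma_bounds Box constraints in years.
#' @param reltol Relative SSE convergence tolerance.
#' @return A `fit_result` with `gd_params` (zero-crossing `NA`: pinned per
#'   condition) and fitted values aligned with `data$points`. If all
#'   aftereffects are exactly zero the amplitude is 0, the bandwidth is
#'   reported at its first initialisation, and `identifiable` is `FALSE`.
#' @export
fit_constrained_repulsion <- function(data, design,
                                      sigma_grid = c(2, 5, 10, 20, 40, 80),
                                      amplitude_bounds = c(-20, 20),
                                      sigma_bounds = c(1, 100),
                                      reltol = 1e-8) {
  pts <- check_fit_data(data)
  stopifnot(inherits(design, "study_design"))
  mu <- vapply(pts$condition, function(cc) adapt_age(design, cc), numeric(1))
  x <- pts$pre_age
  y <- pts$aftereffect
  if (all(y == 0)) {
    return(fit_result("constrained_repulsion",
                      gd_params(0, sigma_grid[1]),
                      sse = 0, n_points = nrow(pts),
                      fitted = rep(0, nrow(pts)),
                      identifiable = FALSE))
  }
  sse_fn <- function(par) {
    b <- gd_basis(x, mu, par[2])
    sum((y - par[1] * b)^2)
  }
  # L-BFGS-B factr is relative to machine epsilon
  factr <- max(reltol / .Machine$double.eps, 10)
  runs <- lapply(sigma_grid, function(s0) {
    a0 <- best_amplitude(gd_basis(x, mu, s0), y,
                         amplitude_bounds[1], amplitude_bounds[2])
    tryCatch(
      stats::optim(c(a0, s0), sse_fn, method = "L-BFGS-B",
                   lower = c(amplitude_bounds[1], sigma_bounds[1]),
                   upper = c(amplitude_bounds[2], sigma_bounds[2]),
                   control = list(factr = factr)),
      error = function(e) list(par = c(a0, s0), value = sse_fn(c(a0, s0)),
                               convergence = 99L))
  })
  if (all(vapply(runs, function(r) r$convergence != 0, logical(1)))) {
    abort(paste0("constrained repulsion fit failed to converge from every ",
                 "restart (codes: ",
                 paste(vapply(runs, function(r) r$convergence, numeric(1)),
                       collapse = ", "), ")"),
          "fit_failure")
  }
  best <- pick_best_run(runs)
  params <- gd_params(best$par[1], best$par[2])
  fitted <- params$amplitude * gd_basis(x, mu, params$sigma)
  fit_result("constrained_repulsion", params, sse = best$value,
             n_points = nrow(pts), fitted = fitted,
             converged = best$convergence == 0,
             n_restarts_used = length(sigma_grid))
}

# Deterministic best-of-restarts: lowest SSE, ties (to relative 1e-9) broken
# by smallest sigma then smallest |A|; sigma is par[2] and A par[1] except for
# the 3-parameter fits where A, sigma, mu are par[1:3].
pick_best_run <- function(runs) {
  vals <- vapply(runs, function(r) r$value, numeric(1))
  tol <- (min(vals) + 1) * 1e-9
  cand <- runs[vals <= min(vals) + tol]
  sig <- vapply(cand, function(r) r$par[2], numeric(1))
  amp <- abs(vapply(cand, function(r) r$par[1], numeric(1)))
  cand[[order(sig, amp)[1]]]
}

#' Fit the renormalization model
#'
#' Fits the one-parameter norm-based model, whose prediction for each
#' condition is the constant `k * (norm_age - adapt_age)`. The model is linear
#' in the gain, so the pooled least-squares solution is closed-form:
#' `k = sum(y * d) / sum(d^2)` with `d` the per-point norm-to-adaptor
#' distance. Points in the condition adapting at the norm have `d = 0` and
#' contribute residuals against a zero prediction.
#'
#' @inheritParams fit_constrained_repulsion
#' @return A `fit_result` with `norm_params`. If every adaptor sits at the
#'   norm the gain is unidentifiable and is reported as 0 with
#'   `identifiable = FALSE`.
#' @export
fit_normalization <- function(data, design) {
  pts <- check_fit_data(data, min_per_condition = 1L, min_conditions = 1L)
  stopifnot(inherits(design, "study_design"))
  d <- design$norm_age -
    vapply(pts$condition, function(cc) adapt_age(design, cc), numeric(1))
  y <- pts$aftereffect
  if (all(d == 0)) {
    return(fit_result("normalization", norm_params(0, design$norm_age),
                      sse = sum(y^2), n_points = nrow(pts),
                      fitted = rep(0, nrow(pts)), identifiable = FALSE))
  }
  k <- sum(y * d) / sum(d^2)
  fitted <- k * d
  fit_result("normalization", norm_params(k, design$norm_age),
             sse = sum((y - fitted)^2), n_points = nrow(pts), fitted = fitted)
}

#' Fit an unconstrained Gaussian derivative to one condition
#'
#' Replicates the per-condition curve-fitting procedure in which the
#' Gaussian-derivative amplitude, bandwidth and zero-crossing are all free.
#' The zero-crossing bounds extend far beyond the test-age range because the
#' interest of this fit is precisely that, unconstrained, it can wander to
#' implausible null ages (negative "ages", or ages far above the adaptor)
#' while approximating a near-linear or near-constant aftereffect over the
#' measured range.
#'
#' Optimisation is multi-start over a (bandwidth, zero-crossing) grid with
#' closed-form initial amplitudes; the most promising starts are refined with
#' bounded quasi-Newton steps and the best SSE wins (ties: smallest bandwidth,
#' then smallest absolute amplitude).
#'
#' @param data A `rating_dataset`.
#' @param condition Condition label to fit.
#' @param sigma_grid,mu_grid Restart grids in years.
#' @param amplitude_bounds,sigma_bounds,mu_bounds Box constraints in years.
#' @param n_refine Number of grid starts refined by the optimiser.
#' @param reltol Relative SSE convergence tolerance.
#' @return A `fit_result` with a fully specified `gd_params`.
#' @export
fit_unconstrained_gd <- function(data, condition,
                                 sigma_grid = c(2, 5, 10, 20, 40, 80),
                                 mu_grid = seq(-50, 150, by = 10),
                                 amplitude_bounds = c(-20, 20),
                                 sigma_bounds = c(1, 100),
                                 mu_bounds = c(-50, 150),
                                 n_refine = 12L,
                                 reltol = 1e-8) {
  stopifnot(inherits(data, "rating_dataset"))
  condition <- match_condition(condition)
  pts <- data$points[data$points$condition == condition, ]
  if (nrow(pts) < 4L) {
    abort(sprintf("condition '%s' has %d points; at least 4 are needed",
                  condition, nrow(pts)), "insufficient_data")
  }
  x <- pts$pre_age
  y <- pts$aftereffect
  if (all(y == 0)) {
    return(fit_result("unconstrained_gd",
                      gd_params(0, sigma_grid[1], mu = mean(x)),
                      sse = 0, n_points = nrow(pts),
                      fitted = rep(0, nrow(pts)),
                      identifiable = FALSE, condition = condition))
  }
  starts <- expand.grid(sigma = sigma_grid, mu = mu_grid)
  start_fits <- mapply(function(s, m) {
    b <- gd_basis(x, m, s)
    a <- best_amplitude(b, y, amplitude_bounds[1], amplitude_bounds[2])
    c(a = a, sse = sum((y - a * b)^2))
  }, starts$sigma, starts$mu)
  ord <- order(start_fits["sse", ])[seq_len(min(n_refine, nrow(starts)))]
  sse_fn <- function(par) sum((y - par[1] * gd_basis(x, par[3], par[2]))^2)
  factr <- max(reltol / .Machine$double.eps, 10)
  runs <- lapply(ord, function(i) {
    p0 <- c(start_fits["a", i], starts$sigma[i], starts$mu[i])
    tryCatch(
      stats::optim(p0, sse_fn, method = "L-BFGS-B",
                   lower = c(amplitude_bounds[1], sigma_bounds[1], mu_bounds[1]),
                   upper = c(amplitude_bounds[2], sigma_bounds[2], mu_bounds[2]),
                   control = list(factr = factr)),
      error = function(e) list(par = p0, value = sse_fn(p0), convergence = 99L))
  })
  if (all(vapply(runs, function(r) r$convergence != 0, logical(1)))) {
    abort("unconstrained GD fit failed to converge from every restart",
          "fit_failure")
  }
  best <- pick_best_run(runs)
  params <- gd_params(best$par[1], best$par[2], mu = best$par[3])
  fit_result("unconstrained_gd", params, sse = best$value,
             n_points = nrow(pts),
             fitted = gd_aftereffect(x, params),
             converged = best$convergence == 0,
             n_restarts_used = length(ord), condition = condition)
}

#' Ordinary least-squares line fit
#'
#' Straight-line regression used throughout the intercept analyses. The
#' intercept is the conventional OLS value at age 0 (extrapolated below the
#' test range).
#'
#' @param x,y Numeric vectors of equal length; `x` must contain at least two
#'   distinct values.
#' @return A list with `slope`, `intercept`, `residuals` and `fitted`.
#' @examples
#' fit_linear_regression(c(18, 89), c(0, 7.1))  # slope 0.1, intercept -1.8
#' @export
fit_linear_regression <- function(x, y) {
  if (length(x) != length(y)) abort("x and y lengths differ", "data")
  if (length(x) < 2L) abort("need at least 2 points", "insufficient_data")
  if (length(unique(x)) < 2L) {
    abort("x is constant: regression line undefined", "degenerate_regression")
  }
  fit <- stats::lm(y ~ x)
  co <- unname(stats::coef(fit))
  list(slope = co[2], intercept = co[1],
       residuals = unname(stats::residuals(fit)),
       fitted = unname(stats::fitted(fit)))
}
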