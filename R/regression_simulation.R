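#' Intercepts of lines fit to repulsion aftereffect curves
#'
#' The discriminating regression analysis: for each bandwidth in
#' `sigma_grid`, a Gaussian-derivative aftereffect curve with its
#' zero-crossing at the condition's adapting age and peak `amplitude` is
#' evaluated at every integer test age, an ordinary least-squares line is fit
#' to it, and the intercept (at age 0) is recorded. The renormalization
#' reference intercept — the intercept shift produced by a uniform shift of
#' the same peak size — is `+amplitude` for the young condition, `0` for the
#' middle, and `-amplitude` for the old: opposite in sign for young versus old
#' adaptors. Repulsion, by contrast, drives the intercept negative at every
#' adapting age, so the sign pattern of measured intercept shifts separates
#' the two accounts.
#'
#' @param design A [study_design()].
#' @param condition Condition label; sets the curve's zero-crossing.
#' @param amplitude Peak aftereffect in years (default 2.4).
#' @param sigma_grid Bandwidths in years at which to evaluate the intercept.
#' @param ages Ages at which the curve is sampled before the line fit;
#'   defaults to the integer ages spanning the design's test range.
#' @return An object of class `intercept_curve`: a list with `condition`,
#'   `sigma_grid`, `intercepts`, `slopes`, `renorm_reference_intercept`, and
#'   `table` (a data frame with columns `condition`, `sigma`, `intercept`).
#' @examples
#' ic <- intercept_curve(study_design(), "old")
#' ic$renorm_reference_intercept  # -2.4
#' @export
intercept_curve <- function(design, condition, amplitude = 2.4,
                            sigma_grid = c(2, 5, 10, 20, 30, 40, 48, 50, 80),
                            ages = NULL) {
  stopifnot(inherits(design, "study_design"))
  condition <- match_condition(condition)
  if (any(sigma_grid <= 0)) abort("all sigma values must be positive",
                                  "invalid_params")
  if (is.null(ages)) {
    ages <- seq(ceiling(design$test_age_min), floor(design$test_age_max))
  }
  a <- adapt_age(design, condition)
  fits <- lapply(sigma_grid, function(s) {
    curve <- gd_aftereffect(ages, gd_params(amplitude, s, mu = a))
    fit_linear_regression(ages, curve)
  })
  ref <- if (a < design$norm_age) amplitude
         else if (a > design$norm_age) -amplitude
         else 0
  structure(list(condition = condition,
                 sigma_grid = sigma_grid,
                 intercepts = vapply(fits, `[[`, numeric(1), "intercept"),
                 slopes = vapply(fits, `[[`, numeric(1), "slope"),
                 renorm_reference_intercept = ref,
                 table = data.frame(condition = condition,
                                    sigma = sigma_grid,
                                    intercept = vapply(fits, `[[`, numeric(1),
                                                       "intercept"),
                                    stringsAsFactors = FALSE)),
            class = "intercept_curve")
}

#' @export
print.intercept_curve <- function(x, ...) {
  cat(sprintf(
    "Intercepts of OLS lines fit to GD aftereffect curves (%s condition)\n",
    x$condition))
  cat(sprintf("Uniform-renormalization reference intercept: %+.4g y\n",
              x$renorm_reference_intercept))
  print.data.frame(data.frame(sigma = x$sigma_grid,
                              intercept = signif(x$intercepts, 4)),
                   row.names = FALSE)
  invisible(x)
}

#' Intercept curves for all three conditions
#'
#' Convenience wrapper running [intercept_curve()] for the young, middle and
#' old conditions and stacking the results.
#'
#' @inheritParams intercept_curve
#' @return A data frame with columns `condition`, `sigma`, `intercept`,
#'   `renorm_reference`.
#' @export
intercept_curves_all <- function(design, amplitude = 2.4,
                                 sigma_grid = c(2, 5, 10, 20, 30, 40, 48, 50,
                                                80),
                                 ages = NULL) {
  do.call(rbind, lapply(CONDITIONS, function(cc) {
    ic <- intercept_curve(design, cc, amplitude, sigma_grid, ages)
    cbind(ic$table, renorm_reference = ic$renorm_reference_intercept)
  }))
}

#' Change in regression slope and intercept with adaptation
#'
#' Fits ordinary least-squares lines to the pre-adaptation and
#' post-adaptation perceived ages against a common axis (by default the
#' pre-adapt perceived age) and reports the post-minus-pre changes. A uniform
#' renormalization changes the intercept but not the slope; local repulsion
#' steepens the slope and pushes the intercept negative.
#'
#' @param pre_ages,post_ages Perceived ages in years, matched per face.
#' @param axis Regressor, matched per face; defaults to `pre_ages`.
#' @return A list with `slope_change`, `intercept_change`, `pre_fit` and
#'   `post_fit` (each a [fit_linear_regression()] result).
#' @examples
#' pre <- seq(18, 89, by = 3)
#' slope_intercept_change(pre, pre + 2.4)  # slope 0, intercept +2.4
#' @export
slope_intercept_change <- function(pre_ages, post_ages, axis = pre_ages) {
  if (length(pre_ages) != length(post_ages) ||
      length(pre_ages) != length(axis)) {
    abort("pre_ages, post_ages and axis must have matching lengths", "data")
  }
  if (length(pre_ages) < 3L) abort("need at least 3 faces",
                                   "insufficient_data")
  pre_fit <- fit_linear_regression(axis, pre_ages)
  post_fit <- fit_linear_regression(axis, post_ages)
  list(slope_change = post_fit$slope - pre_fit$slope,
       intercept_change = post_fit$intercept - pre_fit$intercept,
       pre_fit = pre_fit, post_fit = post_fit)
}

#' Plot intercept curves
#'
#' Base-graphics rendering of the intercept-versus-bandwidth curves for the
#' three adapting conditions, with the uniform-renormalization reference
#' intercepts drawn as horizontal dashed lines.
#'
#' @param x Output of [intercept_curves_all()] (or a single
#'   `intercept_curve`'s `table` with a `renorm_reference` column).
#' @param ... Passed to [graphics::matplot()].
#' @return The input, invisibly.
#' @export
plot_intercept_curves <- function(x, ...) {
  conds <- intersect(CONDITIONS, unique(x$condition))
  sig <- sort(unique(x$sigma))
  mat <- sapply(conds, function(cc) {
    sub <- x[x$condition == cc, ]
    sub$intercept[match(sig, sub$sigma)]
  })
  graphics::matplot(sig, mat, type = "b", pch = 1:3, lty = 1,
                    xlab = "GD bandwidth sigma (years)",
                    ylab = "Intercept of fitted line (years)", ...)
  refs <- vapply(conds, function(cc)
    x$renorm_reference[x$condition == cc][1], numeric(1))
  graphics::abline(h = refs, lty = 2, col = seq_along(conds))
  graphics::legend("bottomright", legend = conds, pch = 1:3,
                   col = seq_along(conds), bty = "n")
  invisible(x)
}
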