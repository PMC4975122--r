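#' Adaptation conditions recognised throughout the package
#'
#' The three adapting conditions of the age-adaptation design, in canonical
#' order: adapt to young, middle-aged, or old faces.
#'
#' @export
CONDITIONS <- c("young", "middle", "old")

#' Define the study design
#'
#' The design of an age-adaptation experiment: the three adapting ages, the
#' norm (prototype) age, and the span of test ages over which perceived-age
#' ratings are collected. Defaults follow the original design: adapting faces
#' of roughly 35 (young), 57 (middle) and 65 (old) years, test faces spanning
#' perceived ages 18 to 89, and a norm at the middle adapting age, which
#' observers judge as age-neutral.
#'
#' @param adapt_age_young,adapt_age_middle,adapt_age_old Adapting ages in
#'   years, one per condition.
#' @param norm_age Age of the perceptual norm in years. Defaults to the middle
#'   adapting age.
#' @param test_age_min,test_age_max Bounds of the test-age range in years.
#' @return An object of class `study_design`.
#' @examples
#' design <- study_design()
#' adapt_age(design, "old")
#' @export
study_design <- function(adapt_age_young = 35,
                         adapt_age_middle = 57,
                         adapt_age_old = 65,
                         norm_age = adapt_age_middle,
                         test_age_min = 18,
                         test_age_max = 89) {
  for (v in c(adapt_age_young, adapt_age_middle, adapt_age_old, norm_age,
              test_age_min, test_age_max)) {
    if (!is_number(v)) abort("invalid design: all ages must be finite numbers",
                             "config")
  }
  if (test_age_min >= test_age_max) {
    abort("invalid design: test_age_min must be below test_age_max", "config")
  }
  adapts <- c(young = adapt_age_young, middle = adapt_age_middle,
              old = adapt_age_old)
  if (any(adapts < test_age_min | adapts > test_age_max)) {
    abort("invalid design: adapt ages must lie within the test-age range",
          "config")
  }
  structure(list(adapt_age_young = adapt_age_young,
                 adapt_age_middle = adapt_age_middle,
                 adapt_age_old = adapt_age_old,
                 norm_age = norm_age,
                 test_age_min = test_age_min,
                 test_age_max = test_age_max),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Age-adaptation study design\n")
  cat(sprintf("  adapt ages : young %.1f | middle %.1f | old %.1f\n",
              x$adapt_age_young, x$adapt_age_middle, x$adapt_age_old))
  cat(sprintf("  norm age   : %.1f\n", x$norm_age))
  cat(sprintf("  test range : [%.0f, %.0f] years\n",
              x$test_age_min, x$test_age_max))
  invisible(x)
}

#' Adapting age for a condition
#'
#' @param design A [study_design()].
#' @param condition One of `"young"`, `"middle"`, `"old"`.
#' @return The adapting age in years.
#' @export
adapt_age <- function(design, condition) {
  stopifnot(inherits(design, "study_design"))
  switch(match_condition(condition),
         young = design$adapt_age_young,
         middle = design$adapt_age_middle,
         old = design$adapt_age_old)
}

match_condition <- function(condition) {
  if (!(is.character(condition) && length(condition) == 1L &&
        condition %in% CONDITIONS)) {
    abort(sprintf("unknown condition label '%s' (expected one of %s)",
                  paste(condition, collapse = ","),
                  paste(CONDITIONS, collapse = ", ")),
          "config")
  }
  condition
}

#' Gaussian-derivative repulsion parameters
#'
#' Parameters of the Gaussian-derivative (GD) aftereffect curve used to model
#' local repulsion: a signed peak amplitude `amplitude` (years), a bandwidth
#' `sigma` (years), and a zero-crossing `mu` (years). The curve is
#' parameterised so that its extrema are exactly `+amplitude` and
#' `-amplitude`, located at `mu + sigma` and `mu - sigma`. In the constrained
#' repulsion model `mu` is pinned to each condition's adapting age and may be
#' left `NA` here.
#'
#' @param amplitude Signed peak aftereffect in years.
#' @param sigma Bandwidth in years; must be positive.
#' @param mu Zero-crossing (null) age in years, or `NA` when the zero-crossing
#'   is supplied per condition.
#' @return An object of class `gd_params`.
#' @export
gd_params <- function(amplitude, sigma, mu = NA_real_) {
  if (!is_number(amplitude)) abort("amplitude must be a finite number",
                                   "invalid_params")
  if (!is_number(sigma) || sigma <= 0) {
    abort("sigma must be a positive finite number", "invalid_params")
  }
  if (!(length(mu) == 1L && (is.na(mu) || is_number(mu)))) {
    abort("mu must be a single number or NA", "invalid_params")
  }
  structure(list(amplitude = amplitude, sigma = sigma, mu = as.numeric(mu)),
            class = "gd_params")
}

#' @export
print.gd_params <- function(x, ...) {
  cat(sprintf("GD repulsion parameters: A = %.4g y, sigma = %.4g y, mu = %s\n",
              x$amplitude, x$sigma,
              if (is.na(x$mu)) "adapt age (pinned)" else sprintf("%.4g y", x$mu)))
  invisible(x)
}

#' Renormalization parameters
#'
#' Parameters of the norm-based (renormalization) aftereffect model: a
#' dimensionless gain `gain` and the norm age. The predicted aftereffect is
#' `gain * (norm_age - adapt_age)` at every test age: a constant bias whose
#' size grows with the adaptor's distance from the norm and which vanishes
#' when adapting to the norm itself.
#'
#' @param gain Dimensionless gain.
#' @param norm_age Norm age in years.
#' @return An object of class `norm_params`.
#' @export
norm_params <- function(gain, norm_age) {
  if (!is_number(gain)) abort("gain must be a finite number", "invalid_params")
  if (!is_number(norm_age)) abort("norm_age must be a finite number",
                                  "invalid_params")
  structure(list(gain = gain, norm_age = norm_age), class = "norm_params")
}

#' @export
print.norm_params <- function(x, ...) {
  cat(sprintf("Renormalization parameters: k = %.4g, norm age = %.4g y\n",
              x$gain, x$norm_age))
  invisible(x)
}

#' Gaussian-derivative aftereffect curve
#'
#' Predicted aftereffect (in years, positive = perceived as older) of a local
#' repulsion mechanism at one or more test ages. The curve is the first
#' derivative of a Gaussian, scaled so that its peak magnitude equals
#' `params$amplitude`:
#' \deqn{f(t) = A \sqrt{e}\, u\, e^{-u^2/2}, \quad u = (t - \mu)/\sigma.}
#' It is odd-symmetric about the zero-crossing `mu`, reaches its extrema
#' `\pm A` at `mu \pm sigma`, and decays to zero far from `mu`: test ages
#' above the null are pushed older and ages below it younger when `A > 0`.
#'
#' @param test_age Test age(s) in years; vectorised.
#' @param params A [gd_params()] with a non-`NA` zero-crossing.
#' @return Predicted aftereffects in years, one per test age.
#' @examples
#' p <- gd_params(amplitude = 2.4, sigma = 20, mu = 57)
#' gd_aftereffect(c(37, 57, 77), p)  # -2.4, 0, +2.4
#' @export
gd_aftereffect <- function(test_age, params) {
  stopifnot(inherits(params, "gd_params"))
  if (is.na(params$mu)) {
    abort("gd_aftereffect needs a concrete zero-crossing mu", "invalid_params")
  }
  u <- (test_age - params$mu) / params$sigma
  params$amplitude * sqrt(exp(1)) * u * exp(-u^2 / 2)
}

#' Renormalization aftereffect
#'
#' Predicted aftereffect of the norm-based model: a constant
#' `gain * (norm_age - adapt_age)` at every test age. Adapting to the norm
#' produces no aftereffect; adapting to a younger age makes all faces look
#' older (positive), and to an older age younger (negative), when `gain > 0`.
#'
#' @param test_age Test age(s) in years; used only for output length.
#' @param adapt_age Adapting age in years.
#' @param params A [norm_params()].
#' @return Predicted aftereffects in years, one per test age (all equal).
#' @examples
#' p <- norm_params(gain = 0.1, norm_age = 57)
#' normalization_aftereffect(c(20, 50, 80), adapt_age = 35, p)  # all +2.2
#' @export
normalization_aftereffect <- function(test_age, adapt_age, params) {
  stopifnot(inherits(params, "norm_params"))
  if (!is_number(adapt_age)) abort("adapt_age must be a finite number",
                                   "invalid_params")
  rep(params$gain * (params$norm_age - adapt_age), length(test_age))
}

#' Predict aftereffects for one adapting condition
#'
#' Dispatches to the model implied by the parameter class. For
#' [gd_params()] the zero-crossing is pinned to the condition's adapting age
#' (the constrained repulsion model); for [norm_params()] the constant
#' renormalization shift for that adapting age is returned.
#'
#' @param design A [study_design()].
#' @param condition One of `"young"`, `"middle"`, `"old"`.
#' @param model A [gd_params()] or [norm_params()].
#' @param test_ages Non-empty numeric vector of test ages in years.
#' @return Predicted aftereffects in years, one per test age, in input order.
#' @export
predict_condition <- function(design, condition, model, test_ages) {
  stopifnot(inherits(design, "study_design"))
  condition <- match_condition(condition)
  if (length(test_ages) == 0L) abort("test_ages must be non-empty", "data")
  a <- adapt_age(design, condition)
  if (inherits(model, "gd_params")) {
    pinned <- gd_params(model$amplitude, model$sigma, mu = a)
    gd_aftereffect(test_ages, pinned)
  } else if (inherits(model, "norm_params")) {
    normalization_aftereffect(test_ages, a, model)
  } else {
    abort("model must be gd_params or norm_params", "config")
  }
}
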