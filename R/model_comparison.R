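#' Root-mean-square error
#'
#' @param observed,predicted Numeric vectors of equal, non-zero length, in
#'   years. A zero `predicted` vector gives the no-model baseline: the RMS of
#'   the raw aftereffects.
#' @return RMS error in years.
#' @examples
#' rms_error(c(3, 4), c(0, 0))  # sqrt(12.5)
#' @export
rms_error <- function(observed, predicted) {
  if (length(observed) == 0L) abort("empty input", "empty_input")
  if (length(observed) != length(predicted)) {
    abort("observed and predicted lengths differ", "data")
  }
  sqrt(mean((observed - predicted)^2))
}

#' Wilcoxon signed-rank test on paired model errors
#'
#' Two-sided paired test on the per-point differences between two models'
#' absolute errors. Zero differences are dropped and tied absolute differences
#' receive midranks. For `n <= exact_cutoff` usable pairs the null
#' distribution of the positive-rank sum is enumerated exactly over all `2^n`
#' sign assignments; for larger `n` a normal approximation with tie correction
#' and a 0.5 continuity correction is used. The reported `z` is always the
#' (corrected) normal deviate, signed so that positive `z` means
#' `errors_model_a` tends to exceed `errors_model_b`.
#'
#' @param errors_model_a,errors_model_b Numeric vectors of equal length:
#'   paired per-point errors of the two models.
#' @param exact_cutoff Largest `n` for which the exact enumeration is used.
#' @return A list with `z`, `p`, `n_pairs` (pairs remaining after dropping
#'   zero differences) and `statistic` (the positive-rank sum W+).
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))  # p = 0.0625
#' @export
wilcoxon_signed_rank <- function(errors_model_a, errors_model_b,
                                 exact_cutoff = 12L) {
  if (length(errors_model_a) != length(errors_model_b)) {
    abort("error vectors must have equal length", "data")
  }
  d <- errors_model_a - errors_model_b
  d <- d[d != 0]
  if (length(d) == 0L) {
    abort("all paired differences are zero: test degenerate", "degenerate_test")
  }
  n <- length(d)
  if (n < 5L) {
    abort(sprintf("only %d non-zero pairs; at least 5 are needed", n),
          "insufficient_data")
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    abort("zero variance in signed ranks: test degenerate", "degenerate_test")
  }
  z <- if (w == mu) 0 else (w - mu - 0.5 * sign(w - mu)) / sqrt(sigma2)
  if (n <= exact_cutoff) {
    idx <- 0:(2^n - 1)
    signs <- vapply(seq_len(n),
                    function(j) bitwAnd(idx, bitwShiftL(1L, j - 1L)) > 0L,
                    logical(2^n))
    w_all <- as.numeric(signs %*% r)
    eps <- 1e-9
    p <- 2 * min(mean(w_all >= w - eps), mean(w_all <= w + eps))
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(z = z, p = min(1, p), n_pairs = n, statistic = w)
}

#' Compare renormalization and repulsion fits
#'
#' Scores two fitted models against the data they were fit to, per adapting
#' condition and pooled ("combined"): RMS error of each model and of the
#' no-model (zero-prediction) baseline, plus a Wilcoxon signed-rank test on
#' the paired per-point absolute residuals of the two models. A winner is
#' declared only when the test is significant at `alpha`; otherwise the scope
#' is a tie. When the test cannot run in a scope (identical errors, too few
#' pairs) the z and p are `NA` and the scope is a tie.
#'
#' @param data The `rating_dataset` both models were fit to.
#' @param fit_norm A `fit_result` from [fit_normalization()].
#' @param fit_rep A `fit_result` from [fit_constrained_repulsion()].
#' @param alpha Two-sided significance level for declaring a winner.
#' @param exact_cutoff Passed to [wilcoxon_signed_rank()].
#' @return A `model_comparison_report`: a data frame with one row per scope
#'   (`young`, `middle`, `old`, `combined`) and columns `n`,
#'   `rms_normalization`, `rms_repulsion`, `rms_no_model`, `wilcoxon_z`,
#'   `wilcoxon_p`, `n_pairs`, `better_model`.
#' @export
compare_models <- function(data, fit_norm, fit_rep, alpha = 0.05,
                           exact_cutoff = 12L) {
  stopifnot(inherits(data, "rating_dataset"),
            inherits(fit_norm, "fit_result"),
            inherits(fit_rep, "fit_result"))
  pts <- data$points
  if (fit_norm$n_points != nrow(pts) || fit_rep$n_points != nrow(pts)) {
    abort("fits were not produced on this dataset (point counts differ)",
          "data")
  }
  if (fit_norm$model_label != "normalization" ||
      fit_rep$model_label != "constrained_repulsion") {
    abort("expected a normalization fit and a constrained repulsion fit",
          "config")
  }
  y <- pts$aftereffect
  res_norm <- y - fit_norm$fitted
  res_rep <- y - fit_rep$fitted
  scopes <- c(CONDITIONS, "combined")
  rows <- lapply(scopes, function(sc) {
    idx <- if (sc == "combined") seq_along(y) else which(pts$condition == sc)
    if (length(idx) == 0L) {
      return(data.frame(scope = sc, n = 0L, rms_normalization = NA_real_,
                        rms_repulsion = NA_real_, rms_no_model = NA_real_,
                        wilcoxon_z = NA_real_, wilcoxon_p = NA_real_,
                        n_pairs = 0L, better_model = "tie",
                        stringsAsFactors = FALSE))
    }
    rms_n <- rms_error(y[idx], fit_norm$fitted[idx])
    rms_r <- rms_error(y[idx], fit_rep$fitted[idx])
    rms_0 <- rms_error(y[idx], rep(0, length(idx)))
    test <- tryCatch(
      wilcoxon_signed_rank(abs(res_norm[idx]), abs(res_rep[idx]),
                           exact_cutoff = exact_cutoff),
      ageadapt_error = function(e) list(z = NA_real_, p = NA_real_,
                                        n_pairs = 0L))
    better <- "tie"
    if (!is.na(test$p) && test$p < alpha && rms_n != rms_r) {
      better <- if (rms_n < rms_r) "normalization" else "repulsion"
    }
    data.frame(scope = sc, n = length(idx), rms_normalization = rms_n,
               rms_repulsion = rms_r, rms_no_model = rms_0,
               wilcoxon_z = test$z, wilcoxon_p = test$p,
               n_pairs = test$n_pairs, better_model = better,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  attr(report, "alpha") <- alpha
  class(report) <- c("model_comparison_report", "data.frame")
  report
}

#' @export
print.model_comparison_report <- function(x, digits = 3, ...) {
  cat("Model comparison: renormalization vs constrained repulsion\n")
  cat(sprintf("(winner declared at two-sided alpha = %g)\n\n",
              attr(x, "alpha")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
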