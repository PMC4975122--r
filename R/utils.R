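# Internal helpers: classed errors and seed-scoped evaluation.

abort <- function(message, class) {
  stop(errorCondition(message,
                      class = c(paste0("ageadapt_", class), "ageadapt_error")))
}

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
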