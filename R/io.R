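#' Read a per-face ratings CSV
#'
#' Reads the fixture format written by [write_fixture()]: a comma-separated
#' file with header `condition,face_id,pre_age,post_age[,aftereffect]`. The
#' aftereffect column, when present, is cross-checked against
#' `post_age - pre_age` and any disagreement is reported with its row number;
#' when absent it is computed. Row order is preserved.
#'
#' @param path Path to the CSV file.
#' @param tolerance Maximum allowed aftereffect discrepancy in years.
#' @return A `rating_dataset` whose `config` records the source path.
#' @export
read_ratings_csv <- function(path, tolerance = 1e-6) {
  if (!file.exists(path)) {
    abort(sprintf("ratings file not found: %s", path), "file_not_found")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  needed <- c("condition", "face_id", "pre_age", "post_age")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")), "data")
  }
  num_cols <- intersect(c("pre_age", "post_age", "aftereffect"), names(raw))
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      # +1 for the header row
      abort(sprintf("%s line %d: non-numeric %s value '%s'",
                    path, bad[1] + 1L, col, raw[[col]][bad[1]]), "data")
    }
    raw[[col]] <- vals
  }
  tryCatch(
    rating_dataset(raw, config = list(source = path), tolerance = tolerance),
    ageadapt_data = function(e) {
      abort(sprintf("%s: %s", path, conditionMessage(e)), "data")
    })
}

#' Assemble and validate a pipeline configuration
#'
#' Configuration for [run_pipeline()]. Exactly one input source must be
#' given: a simulation config (data are generated) or a ratings CSV path.
#' Unknown fields are rejected so that typos in configuration files fail
#' loudly before any stage runs.
#'
#' @param design A [study_design()]; defaults to the simulation's design when
#'   simulating.
#' @param simulation A [simulation_config()], or `NULL` when reading a CSV.
#' @param input_csv Path to a ratings CSV, or `NULL` when simulating.
#' @param alpha Significance level for [compare_models()].
#' @param exact_cutoff Exact-enumeration cutoff for the signed-rank test.
#' @param sigma_grid Bandwidth restarts for [fit_constrained_repulsion()].
#' @param fit_unconstrained Also run the per-condition unconstrained GD fits.
#' @param out_dir Directory for artifacts (report JSON, ratings and
#'   fitted-curve CSVs), or `NULL` to write nothing.
#' @param seed Integer seed applied to the simulation stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(design = NULL, simulation = NULL, input_csv = NULL,
                       alpha = 0.05, exact_cutoff = 12L,
                       sigma_grid = c(2, 5, 10, 20, 40, 80),
                       fit_unconstrained = FALSE, out_dir = NULL, seed = 1) {
  if (is.null(simulation) && is.null(input_csv)) {
    abort("either a simulation config or an input CSV is required", "config")
  }
  if (!is.null(simulation) && !is.null(input_csv)) {
    abort("give either a simulation config or an input CSV, not both",
          "config")
  }
  if (!is.null(simulation)) {
    stopifnot(inherits(simulation, "simulation_config"))
    simulation$seed <- as.integer(seed)
    if (is.null(design)) design <- simulation$design
  }
  if (is.null(design)) design <- study_design()
  stopifnot(inherits(design, "study_design"))
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1)", "config")
  }
  structure(list(design = design, simulation = simulation,
                 input_csv = input_csv, alpha = alpha,
                 exact_cutoff = as.integer(exact_cutoff),
                 sigma_grid = sigma_grid,
                 fit_unconstrained = isTRUE(fit_unconstrained),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' Parses a JSON configuration file into a [run_config()]. The schema mirrors
#' the `run_config` arguments, with `design` and `simulation` given as nested
#' objects of their constructor arguments (`simulation$truth_params` as
#' `{gain, norm_age}` or `{amplitude, sigma}`). Unknown keys anywhere are
#' rejected.
#'
#' @param path Path to a JSON file.
#' @param seed Optional seed overriding the file's.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), "file_not_found")
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(cfg, c("design", "simulation", "input_csv", "alpha",
                    "exact_cutoff", "sigma_grid", "fit_unconstrained",
                    "out_dir", "seed"), "config")
  design <- NULL
  if (!is.null(cfg$design)) {
    check_keys(cfg$design, names(formals(study_design)), "config$design")
    design <- do.call(study_design, cfg$design)
  }
  simulation <- NULL
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    check_keys(sim, names(formals(simulation_config)), "config$simulation")
    if (!is.null(sim$truth_params)) {
      tp <- sim$truth_params
      if (setequal(names(tp), c("gain", "norm_age"))) {
        sim$truth_params <- norm_params(tp$gain, tp$norm_age)
      } else if (setequal(names(tp), c("amplitude", "sigma")) ||
                 setequal(names(tp), c("amplitude", "sigma", "mu"))) {
        sim$truth_params <- do.call(gd_params, tp)
      } else {
        abort("truth_params must be {gain, norm_age} or {amplitude, sigma}",
              "config")
      }
    }
    if (!is.null(design)) sim$design <- design
    simulation <- do.call(simulation_config, sim)
  }
  args <- cfg[setdiff(names(cfg), c("design", "simulation"))]
  args$design <- design
  args$simulation <- simulation
  if (!is.null(seed)) args$seed <- seed
  do.call(run_config, args)
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("unknown key(s) in %s: %s", where,
                  paste(unknown, collapse = ", ")), "config")
  }
}

#' Run the full model-comparison pipeline
#'
#' Executes the end-to-end analysis: obtain data (simulate or read), fit the
#' renormalization and constrained repulsion models (and optionally the
#' unconstrained per-condition GD curves), and compare them by RMS error and
#' the signed-rank test. With `out_dir` set, writes `ratings.csv`,
#' `report.json`, and `fitted_curves.csv` (both models' predictions on the
#' integer test-age grid); runs are byte-identical given the same config and
#' seed. Stage boundaries are reported via [message()].
#'
#' @param config A [run_config()].
#' @return A list with `data`, `fit_normalization`, `fit_repulsion`,
#'   `fit_unconstrained` (or `NULL`), and `report` (a
#'   `model_comparison_report`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  design <- config$design
  if (!is.null(config$simulation)) {
    message("stage [simulate]: generating synthetic ratings (seed ",
            config$seed, ")")
    data <- generate_dataset(config$simulation)
  } else {
    message("stage [read]: loading ratings from ", config$input_csv)
    data <- read_ratings_csv(config$input_csv)
  }
  message("stage [fit]: normalization and constrained repulsion")
  fit_norm <- fit_normalization(data, design)
  fit_rep <- fit_constrained_repulsion(data, design,
                                       sigma_grid = config$sigma_grid)
  fit_unc <- NULL
  if (config$fit_unconstrained) {
    message("stage [fit]: unconstrained per-condition GD")
    fit_unc <- lapply(stats::setNames(CONDITIONS, CONDITIONS), function(cc)
      fit_unconstrained_gd(data, cc))
  }
  message("stage [compare]: RMS error and signed-rank test")
  report <- compare_models(data, fit_norm, fit_rep, alpha = config$alpha,
                           exact_cutoff = config$exact_cutoff)
  if (!is.null(config$out_dir)) {
    message("stage [write]: artifacts in ", config$out_dir)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fixture(data, file.path(config$out_dir, "ratings.csv"))
    write_report_json(report, fit_norm, fit_rep, fit_unc,
                      file.path(config$out_dir, "report.json"))
    utils::write.csv(fitted_curves_table(design, fit_norm, fit_rep),
                     file.path(config$out_dir, "fitted_curves.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(data = data, fit_normalization = fit_norm, fit_repulsion = fit_rep,
       fit_unconstrained = fit_unc, report = report)
}

fitted_curves_table <- function(design, fit_norm, fit_rep) {
  ages <- seq(ceiling(design$test_age_min), floor(design$test_age_max))
  do.call(rbind, lapply(CONDITIONS, function(cc) {
    data.frame(condition = cc, age = ages,
               normalization = predict_condition(design, cc, fit_norm$params,
                                                 ages),
               repulsion = predict_condition(design, cc, fit_rep$params, ages))
  }))
}

params_to_list <- function(p) {
  if (inherits(p, "norm_params")) list(gain = p$gain, norm_age = p$norm_age)
  else list(amplitude = p$amplitude, sigma = p$sigma, mu = p$mu)
}

write_report_json <- function(report, fit_norm, fit_rep, fit_unc, path) {
  out <- list(
    comparison = as.data.frame(report),
    alpha = attr(report, "alpha"),
    fits = list(
      normalization = c(params_to_list(fit_norm$params),
                        list(sse = fit_norm$sse,
                             identifiable = fit_norm$identifiable)),
      constrained_repulsion = c(params_to_list(fit_rep$params),
                                list(sse = fit_rep$sse,
                                     identifiable = fit_rep$identifiable))))
  if (!is.null(fit_unc)) {
    out$fits$unconstrained_gd <- lapply(fit_unc, function(f)
      c(params_to_list(f$params), list(sse = f$sse)))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
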