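#' Configure a synthetic rating study
#'
#' Describes a simulated pre/post perceived-age rating experiment with the
#' statistical structure the downstream analysis assumes: per-face preadapt
#' perceived ages spread over the test range in each of the three adapting
#' conditions, aftereffects generated under a chosen truth model, and
#' independent Gaussian rating noise on the pre and post judgments, optionally
#' averaged over observers.
#'
#' Defaults (24 faces per condition, post-rating noise SD of 3 years per
#' observer, 20 observers averaged) emulate a multi-observer rating study:
#' individual age judgments scatter by a few years and per-face aftereffects
#' are means over observers, giving a per-face standard error of about 0.7
#' years — small enough that aftereffects of around 2 years are measurable.
#'
#' @param design A [study_design()].
#' @param truth_model `"normalization"`, `"repulsion"`, or `"none"`.
#' @param truth_params Parameters of the truth model: a [norm_params()] for
#'   normalization, a [gd_params()] (zero-crossing pinned per condition) for
#'   repulsion, ignored for `"none"`. Defaults: gain 0.1 at the design norm,
#'   or a GD with peak 2.4 years and bandwidth 20 years.
#' @param n_faces_per_condition Number of test faces per condition (>= 2).
#' @param n_observers Number of observers whose ratings are averaged per face.
#' @param rating_noise_sd SD in years of the noise on each post-adapt rating.
#' @param pre_rating_noise_sd SD in years of the noise on each pre-adapt
#'   rating.
#' @param seed Integer seed; fixes the dataset exactly.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(design = study_design(),
                              truth_model = c("normalization", "repulsion",
                                              "none"),
                              truth_params = NULL,
                              n_faces_per_condition = 24,
                              n_observers = 20,
                              rating_noise_sd = 3,
                              pre_rating_noise_sd = 0,
                              seed = 1) {
  stopifnot(inherits(design, "study_design"))
  if (!(is.character(truth_model) && truth_model[1] %in%
        c("normalization", "repulsion", "none"))) {
    abort(sprintf("unknown truth_model '%s'", truth_model[1]), "config")
  }
  truth_model <- truth_model[1]
  if (is.null(truth_params)) {
    truth_params <- switch(truth_model,
                           normalization = norm_params(0.1, design$norm_age),
                           repulsion = gd_params(2.4, 20),
                           none = NULL)
  }
  if (truth_model == "normalization" && !inherits(truth_params, "norm_params"))
    abort("normalization truth needs norm_params", "config")
  if (truth_model == "repulsion" && !inherits(truth_params, "gd_params"))
    abort("repulsion truth needs gd_params", "config")
  if (!is_number(n_faces_per_condition) || n_faces_per_condition < 2)
    abort("n_faces_per_condition must be >= 2", "config")
  if (!is_number(n_observers) || n_observers < 1)
    abort("n_observers must be >= 1", "config")
  if (!is_number(rating_noise_sd) || rating_noise_sd < 0)
    abort("rating_noise_sd must be >= 0", "config")
  if (!is_number(pre_rating_noise_sd) || pre_rating_noise_sd < 0)
    abort("pre_rating_noise_sd must be >= 0", "config")
  if (!is_number(seed)) abort("seed must be a finite number", "config")
  structure(list(design = design,
                 truth_model = truth_model,
                 truth_params = truth_params,
                 n_faces_per_condition = as.integer(n_faces_per_condition),
                 n_observers = as.integer(n_observers),
                 rating_noise_sd = rating_noise_sd,
                 pre_rating_noise_sd = pre_rating_noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

truth_prediction <- function(config, condition, ages) {
  design <- config$design
  switch(config$truth_model,
         none = rep(0, length(ages)),
         normalization = normalization_aftereffect(
           ages, adapt_age(design, condition), config$truth_params),
         repulsion = {
           p <- config$truth_params
           gd_aftereffect(ages, gd_params(p$amplitude, p$sigma,
                                          mu = adapt_age(design, condition)))
         })
}

#' Generate a synthetic rating dataset
#'
#' Draws, for each adapting condition, `n_faces_per_condition` latent face
#' ages spaced evenly over the test range with a small uniform jitter (at most
#' 30% of the grid spacing, so coverage stays even). Each observer's preadapt
#' rating is the latent age plus `N(0, pre_rating_noise_sd)` noise, and each
#' postadapt rating is the latent age plus the truth model's aftereffect at
#' that latent age plus `N(0, rating_noise_sd)` noise. Per-face `pre_age` and
#' `post_age` are the means over observers, and the aftereffect is their
#' difference, so the aftereffect noise SD is
#' `sqrt(pre_sd^2 + post_sd^2) / sqrt(n_observers)`.
#'
#' The generator is deterministic given the config seed and restores the
#' caller's RNG state.
#'
#' @param config A [simulation_config()].
#' @return An object of class `rating_dataset`: a list with `points` (a
#'   data frame with columns `condition`, `face_id`, `pre_age`, `post_age`,
#'   `aftereffect`) and `config` (the generating configuration).
#' @examples
#' dat <- generate_dataset(simulation_config(seed = 42))
#' head(dat$points)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  design <- config$design
  n <- config$n_faces_per_condition
  n_obs <- config$n_observers
  with_seed(config$seed, {
    rows <- lapply(CONDITIONS, function(cond) {
      grid <- seq(design$test_age_min, design$test_age_max, length.out = n)
      spacing <- diff(grid[1:2])
      latent <- clamp(grid + stats::runif(n, -0.3, 0.3) * spacing,
                      design$test_age_min, design$test_age_max)
      shift <- truth_prediction(config, cond, latent)
      pre_noise <- matrix(stats::rnorm(n * n_obs, 0, config$pre_rating_noise_sd),
                          nrow = n)
      post_noise <- matrix(stats::rnorm(n * n_obs, 0, config$rating_noise_sd),
                           nrow = n)
      pre <- latent + rowMeans(pre_noise)
      post <- latent + shift + rowMeans(post_noise)
      data.frame(condition = cond,
                 face_id = sprintf("%s_%02d", cond, seq_len(n)),
                 pre_age = pre,
                 post_age = post,
                 aftereffect = post - pre,
                 stringsAsFactors = FALSE)
    })
    rating_dataset(do.call(rbind, rows), config = config)
  })
}

#' Construct a rating dataset
#'
#' Low-level constructor validating the per-face aftereffect records used by
#' all fitting and comparison functions.
#'
#' @param points Data frame with columns `condition`, `face_id`, `pre_age`,
#'   `post_age` and optionally `aftereffect` (recomputed and cross-checked
#'   when present).
#' @param config Provenance: a [simulation_config()] or an arbitrary note
#'   (e.g. the source file path).
#' @param tolerance Maximum allowed discrepancy in years between a stored
#'   aftereffect and `post_age - pre_age`.
#' @return An object of class `rating_dataset`.
#' @export
rating_dataset <- function(points, config = NULL, tolerance = 1e-6) {
  needed <- c("condition", "face_id", "pre_age", "post_age")
  missing_cols <- setdiff(needed, names(points))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          "data")
  }
  bad <- which(!(points$condition %in% CONDITIONS))
  if (length(bad) > 0) {
    abort(sprintf("unknown condition label '%s' in row %d",
                  points$condition[bad[1]], bad[1]), "data")
  }
  for (col in c("pre_age", "post_age")) {
    if (!is.numeric(points[[col]]) || anyNA(points[[col]])) {
      bad <- if (is.numeric(points[[col]])) which(is.na(points[[col]]))[1] else 1L
      abort(sprintf("non-numeric %s in row %d", col, bad), "data")
    }
  }
  recomputed <- points$post_age - points$pre_age
  if ("aftereffect" %in% names(points)) {
    off <- which(abs(points$aftereffect - recomputed) > tolerance)
    if (length(off) > 0) {
      abort(sprintf(
        "aftereffect disagrees with post_age - pre_age in row %d (%.4g vs %.4g)",
        off[1], points$aftereffect[off[1]], recomputed[off[1]]), "data")
    }
  }
  points$aftereffect <- recomputed
  dup <- points[duplicated(points[c("condition", "face_id")]), ]
  if (nrow(dup) > 0) {
    abort(sprintf("duplicated face_id '%s' within condition '%s'",
                  dup$face_id[1], dup$condition[1]), "data")
  }
  rownames(points) <- NULL
  structure(list(points = points, config = config), class = "rating_dataset")
}

#' @export
print.rating_dataset <- function(x, ...) {
  cat(sprintf("Rating dataset: %d faces (%s)\n", nrow(x$points),
              paste(sprintf("%s: %d", CONDITIONS,
                            tabulate(factor(x$points$condition,
                                            levels = CONDITIONS))),
                    collapse = ", ")))
  if (inherits(x$config, "simulation_config")) {
    cat(sprintf("  synthetic, truth model '%s', seed %d\n",
                x$config$truth_model, x$config$seed))
  }
  invisible(x)
}

#' @export
as.data.frame.rating_dataset <- function(x, ...) x$points

#' Write a rating dataset to CSV
#'
#' Writes the per-face records as a comma-separated UTF-8 file with a header
#' row (`condition,face_id,pre_age,post_age,aftereffect`), the fixture format
#' read back by [read_ratings_csv()]. The round trip is lossless to full
#' double precision.
#'
#' @param dataset A `rating_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(dataset, path) {
  stopifnot(inherits(dataset, "rating_dataset"))
  pts <- dataset$points
  for (col in c("pre_age", "post_age", "aftereffect")) {
    pts[[col]] <- format(pts[[col]], digits = 17, trim = TRUE,
                         scientific = FALSE)
  }
  utils::write.csv(pts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
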