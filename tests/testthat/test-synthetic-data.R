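test_that("generator is deterministic given the seed", {
  cfg <- simulation_config(seed = 11)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$points, b$points)
  c_ <- generate_dataset(simulation_config(seed = 12))
  expect_identical(a$points[c("condition", "face_id")],
                   c_$points[c("condition", "face_id")])
  expect_false(isTRUE(all.equal(a$points$aftereffect, c_$points$aftereffect)))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_dataset(simulation_config(seed = 5)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("noiseless normalization data carry the exact constant shifts", {
  dat <- noiseless_dataset("normalization", norm_params(0.1, 57))
  pts <- dat$points
  expect_equal(pts$aftereffect[pts$condition == "young"], rep(2.2, 24))
  expect_equal(pts$aftereffect[pts$condition == "middle"], rep(0, 24))
  expect_equal(pts$aftereffect[pts$condition == "old"], rep(-0.8, 24))
})

test_that("no-effect truth with zero noise gives exactly zero aftereffects", {
  dat <- noiseless_dataset("none")
  expect_equal(dat$points$aftereffect, rep(0, 72))
  expect_equal(dat$points$post_age, dat$points$pre_age)
})

test_that("pre ages span the test range evenly in every condition", {
  dat <- generate_dataset(simulation_config(seed = 3))
  for (cc in CONDITIONS) {
    pre <- sort(dat$points$pre_age[dat$points$condition == cc])
    expect_gte(min(pre), 18)
    expect_lte(max(pre), 89)
    expect_lt(max(diff(pre)), 2 * (89 - 18) / 23)  # no big gaps
  }
})

test_that("aftereffect noise follows sqrt(pre^2 + post^2) / sqrt(n_obs)", {
  cfg <- simulation_config(truth_model = "normalization",
                           truth_params = norm_params(0.1, 57),
                           n_faces_per_condition = 600, n_observers = 4,
                           rating_noise_sd = 3, pre_rating_noise_sd = 2,
                           seed = 21)
  dat <- generate_dataset(cfg)
  pts <- dat$points
  shift <- c(young = 2.2, middle = 0, old = -0.8)
  resid <- pts$aftereffect - shift[pts$condition]
  expected_sd <- sqrt(3^2 + 2^2) / sqrt(4)
  expect_equal(stats::sd(resid), expected_sd, tolerance = 0.05)
  expect_lt(abs(mean(resid)), 3 * expected_sd / sqrt(length(resid)) + 0.02)
})

test_that("per-face means hug the GD curve under repulsion truth", {
  # Gaussian standard-error bound: with post noise 3 over 20 observers the
  # per-face error exceeds 3 * 3/sqrt(20) for well under 1% of faces
  cfg <- simulation_config(truth_model = "repulsion",
                           truth_params = gd_params(2.4, 20),
                           n_faces_per_condition = 200, n_observers = 20,
                           rating_noise_sd = 3, seed = 8)
  dat <- generate_dataset(cfg)
  pts <- dat$points
  d <- default_design
  pred_aligned <- numeric(nrow(pts))
  for (cc in CONDITIONS) {
    sel <- pts$condition == cc
    pred_aligned[sel] <- predict_condition(d, cc, cfg$truth_params,
                                           pts$pre_age[sel])
  }
  frac_ok <- mean(abs(pts$aftereffect - pred_aligned) <= 3 * 3 / sqrt(20))
  expect_gte(frac_ok, 0.99)
})

test_that("hallmark sign patterns appear in the synthetic data", {
  rep_dat <- generate_dataset(simulation_config(truth_model = "repulsion",
                                                seed = 31))
  pts <- rep_dat$points
  for (cc in CONDITIONS) {
    a <- adapt_age(default_design, cc)
    sub <- pts[pts$condition == cc, ]
    above <- mean(sub$aftereffect[sub$pre_age > a + 2])
    below <- mean(sub$aftereffect[sub$pre_age < a - 2])
    expect_gt(above, 0)
    expect_lt(below, 0)
  }
  norm_dat <- generate_dataset(simulation_config(truth_model = "normalization",
                                                 seed = 32))
  pn <- norm_dat$points
  m <- tapply(pn$aftereffect, pn$condition, mean)
  expect_gt(m[["young"]], 0)
  expect_lt(m[["old"]], 0)
  expect_lt(abs(m[["middle"]]), 3 * 3 / sqrt(20) / sqrt(24) * 3 + 0.3)
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulation_config(truth_model = "drift"),
               class = "ageadapt_config")
  expect_error(simulation_config(n_faces_per_condition = 1),
               class = "ageadapt_config")
  expect_error(simulation_config(rating_noise_sd = -1),
               class = "ageadapt_config")
  expect_error(simulation_config(truth_model = "repulsion",
                                 truth_params = norm_params(0.1, 57)),
               class = "ageadapt_config")
})

test_that("fixture CSVs round-trip losslessly", {
  dat <- generate_dataset(simulation_config(seed = 17))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture(dat, path)
  back <- read_ratings_csv(path)
  expect_equal(back$points$pre_age, dat$points$pre_age, tolerance = 0)
  expect_equal(back$points$post_age, dat$points$post_age, tolerance = 0)
  expect_equal(back$points$aftereffect, dat$points$aftereffect,
               tolerance = 1e-12)
  expect_identical(back$points$face_id, dat$points$face_id)
  expect_identical(nrow(back$points), 72L)
})

test_that("an empty dataset writes a header-only file and reads back empty", {
  empty <- rating_dataset(data.frame(condition = character(0),
                                     face_id = character(0),
                                     pre_age = numeric(0),
                                     post_age = numeric(0)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture(empty, path)
  expect_identical(length(readLines(path)), 1L)
  back <- read_ratings_csv(path)
  expect_identical(nrow(back$points), 0L)
  expect_error(fit_normalization(back, default_design),
               class = "ageadapt_empty_input")
})
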