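# Shared fixtures: all datasets are generated in code, never stored.

default_design <- study_design()

# Noiseless dataset from a given truth model: fits must recover it exactly.
noiseless_dataset <- function(truth_model, truth_params = NULL, n_faces = 24,
                              seed = 1) {
  generate_dataset(simulation_config(
    design = default_design, truth_model = truth_model,
    truth_params = truth_params, n_faces_per_condition = n_faces,
    n_observers = 1, rating_noise_sd = 0, pre_rating_noise_sd = 0,
    seed = seed))
}

# Hand-built dataset with explicit aftereffects at explicit pre ages.
manual_dataset <- function(pre_by_condition, aftereffect_by_condition) {
  rows <- lapply(names(pre_by_condition), function(cond) {
    pre <- pre_by_condition[[cond]]
    af <- aftereffect_by_condition[[cond]]
    data.frame(condition = cond,
               face_id = sprintf("%s_%02d", cond, seq_along(pre)),
               pre_age = pre, post_age = pre + af,
               stringsAsFactors = FALSE)
  })
  rating_dataset(do.call(rbind, rows))
}

# Dense brute-force SSE for the constrained repulsion model: evaluates the
# pooled SSE over a full (A, sigma) grid using the exact quadratic identity
# SSE(A) = sum(y^2) - 2A sum(by) + A^2 sum(b^2), which equals the elementwise
# grid evaluation. Independent of the optimizer path.
grid_search_repulsion_sse <- function(data, design,
                                      a_grid = seq(-20, 20, by = 0.01),
                                      sigma_grid = seq(1, 100, by = 0.1)) {
  pts <- data$points
  mu <- vapply(pts$condition, function(cc) adapt_age(design, cc), numeric(1))
  x <- pts$pre_age
  y <- pts$aftereffect
  yy <- sum(y^2)
  best <- Inf
  for (s in sigma_grid) {
    u <- (x - mu) / s
    b <- sqrt(exp(1)) * u * exp(-u^2 / 2)
    sse <- yy - 2 * a_grid * sum(b * y) + a_grid^2 * sum(b^2)
    best <- min(best, min(sse))
  }
  best
}
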