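# Shared fixtures: small synthetic study systems built in code.

# A compact simulated system: grid, env stack, effort, observations and the
# filtered modelling frame (predictors joined, not yet standardized).
make_system <- function(seed = 1, n_x = 10, n_y = 10, years = 2006,
                        truth = truth_scenario(),
                        effort_params = list(coverage = 0.8, dist = "gamma",
                                             mean = 4, shape = 2)) {
  grid <- generate_grid(n_x, n_y)
  sch <- make_schedule(years)
  env <- generate_environment(grid, sch, seed = seed)
  eff <- simulate_effort(grid, sch, effort_params, seed = seed)
  ds <- simulate_observations(env, eff, truth, seed = seed)
  frame <- build_model_frame(ds$records,
                             ds$cells[, c("cell_id", "season", "year",
                                          "effort_km")],
                             grid, env)
  list(grid = grid, schedule = sch, env = env, effort = eff, dataset = ds,
       frame = frame)
}

# Quick standardized frame for model-level tests.
make_frame <- function(seed = 1, ...) {
  sys <- make_system(seed = seed, ...)
  standardize_predictors(sys$frame)
}

# Brute-force minimum distance, the oracle for distance layers.
brute_min_dist <- function(centers, pts) {
  vapply(seq_len(nrow(centers)), function(i)
    min(sqrt((pts[, 1] - centers[i, 1])^2 + (pts[, 2] - centers[i, 2])^2)),
    numeric(1))
}

# Rook-adjacency weights on a small grid, built by hand for Moran oracles.
rook_weights <- function(grid) {
  ctr <- cell_centers(grid)
  d <- as.matrix(stats::dist(ctr))
  w <- (abs(d - grid$cell_size) < 1e-9) * 1
  diag(w) <- 0
  w
}
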