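test_that("environmental stacks are seed-deterministic", {
  g <- generate_grid(6, 6)
  sch <- make_schedule(2006:2007)
  a <- generate_environment(g, sch, seed = 11)
  b <- generate_environment(g, sch, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_environment(g, sch, seed = 12)
  expect_false(identical(a$BAT, c$BAT))
})

test_that("field layers respect configured ranges and static layers repeat", {
  g <- generate_grid(8, 8)
  sch <- default_schedule()
  env <- generate_environment(g, sch, seed = 2)
  expect_true(all(env$BAT >= 0.12 & env$BAT <= 102.12))
  expect_true(all(env$SST >= 25.43 & env$SST <= 29.95))
  expect_true(all(env$CHL >= 0.22 & env$CHL <= 1.39))
  # static layers identical across strata
  for (v in c("BAT", "GRAD", "COAST", "REEF", "BATH100")) {
    m <- matrix(env[[v]], nrow = g$n_cells)
    expect_true(all(m == m[, 1]), info = v)
  }
  # dynamic layers vary across strata
  m <- matrix(env$SST, nrow = g$n_cells)
  expect_false(all(m == m[, 1]))
  # distances are non-negative
  for (v in c("COAST", "REEF", "BATH100", "FRONT"))
    expect_true(all(env[[v]] >= 0), info = v)
  # seasonal SST structure: summer warmer than winter on average
  expect_gt(mean(env$SST[env$season == "summer"]),
            mean(env$SST[env$season == "winter"]))
})

test_that("distance layers match the exhaustive pairwise oracle", {
  g <- generate_grid(15, 20, 1, c(3, -1))
  set.seed(42)
  pts <- cbind(runif(17, 3, 18), runif(17, -1, 19))
  expect_equal(distance_to_features(g, pts),
               brute_min_dist(cell_centers(g), pts), tolerance = 1e-12)
})

test_that("rejects bad environment configs and empty schedules", {
  g <- generate_grid(3, 3)
  expect_error(generate_environment(g, make_schedule(2006)[0, ]), "schedule")
  cfg <- default_env_config()
  cfg$BAT$range <- c(5, 5)
  expect_error(generate_environment(g, make_schedule(2006), cfg), "BAT")
})

test_that("effort coverage hits its target and is reproducible", {
  g <- generate_grid(20, 20)
  sch <- make_schedule(2006, "summer")
  eff <- simulate_effort(g, sch, list(coverage = 0.69, dist = "gamma",
                                      mean = 4, shape = 2), seed = 5)
  expect_true(all(eff$effort_km >= 0))
  frac <- mean(eff$effort_km >= 1)
  expect_lt(abs(frac - 0.69), 0.1)
  # some surveyed cells fall under the 1 km threshold (filter is exercised)
  expect_gt(sum(eff$effort_km > 0 & eff$effort_km < 1), 0)
  expect_identical(eff, simulate_effort(g, sch, list(coverage = 0.69,
                                                     dist = "gamma", mean = 4,
                                                     shape = 2), seed = 5))
})

test_that("constant-effort spec gives every cell the same effort", {
  g <- generate_grid(5, 5)
  eff <- simulate_effort(g, make_schedule(2006, "summer"),
                         list(coverage = 1, dist = "constant", mean = 2),
                         seed = 1)
  expect_true(all(eff$effort_km == 2))
})

test_that("mean effort obeys the law of large numbers at n = 10^4", {
  g <- generate_grid(100, 100)
  eff <- simulate_effort(g, make_schedule(2006, "summer"),
                         list(coverage = 0.69, dist = "gamma", mean = 4,
                              shape = 2), seed = 9)
  surveyed <- eff$effort_km > 0
  expect_lt(abs(mean(eff$effort_km[surveyed]) - 4), 3 * 4 / sqrt(sum(surveyed)))
  expect_lt(abs(mean(eff$effort_km >= 1) - 0.69), 0.02)
})

test_that("coverage outside (0, 1] is rejected", {
  g <- generate_grid(3, 3)
  expect_error(simulate_effort(g, make_schedule(2006),
                               list(coverage = 0, dist = "constant",
                                    mean = 2)), "coverage")
  expect_error(simulate_effort(g, make_schedule(2006),
                               list(coverage = 1.2, dist = "constant",
                                    mean = 2)), "coverage")
})

test_that("null truth gives presence rate 1/2 at n = 10^4", {
  g <- generate_grid(100, 100)
  sch <- make_schedule(2006, "summer")
  env <- generate_environment(g, sch, seed = 3)
  eff <- simulate_effort(g, sch, list(coverage = 1, dist = "constant",
                                      mean = 2), seed = 3)
  tr <- truth_scenario(beta_occ = c(`(Intercept)` = 0),
                       beta_sgt = c(`(Intercept)` = -1))
  ds <- simulate_observations(env, eff, tr, seed = 3)
  rate <- mean(ds$cells$presence_latent)
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("expected sighting counts are linear in effort", {
  g <- generate_grid(100, 100)
  sch <- make_schedule(2006, "summer")
  env <- generate_environment(g, sch, seed = 4)
  tr <- truth_scenario(beta_occ = c(`(Intercept)` = 10),  # always suitable
                       beta_sgt = c(`(Intercept)` = 0), theta = 1)
  eff1 <- simulate_effort(g, sch, list(coverage = 1, dist = "constant",
                                       mean = 1), seed = 4)
  eff2 <- simulate_effort(g, sch, list(coverage = 1, dist = "constant",
                                       mean = 2), seed = 4)
  m1 <- mean(simulate_observations(env, eff1, tr, seed = 5)$cells$n_sightings)
  m2 <- mean(simulate_observations(env, eff2, tr, seed = 6)$cells$n_sightings)
  # mu doubles from 1 to 2; sd(m2 - 2*m1) ~ 0.037 at n = 10^4, allow 4 sigma
  expect_lt(abs(m2 - 2 * m1), 0.15)
})

test_that("zero-effort cells yield no records and no counts", {
  g <- generate_grid(6, 6)
  sch <- make_schedule(2006, "summer")
  env <- generate_environment(g, sch, seed = 7)
  eff <- simulate_effort(g, sch, list(coverage = 0.4, dist = "gamma",
                                      mean = 3, shape = 2), seed = 7)
  ds <- simulate_observations(env, eff, seed = 7)
  zero <- ds$cells$effort_km <= 0
  expect_true(all(ds$cells$n_sightings[zero] == 0))
  rast <- rasterize_observations(ds$records, g)
  key0 <- paste(ds$cells$cell_id[zero], ds$cells$season[zero],
                ds$cells$year[zero])
  expect_false(any(paste(rast$assigned$cell_id, rast$assigned$season,
                         rast$assigned$year) %in% key0))
})

test_that("simulated counts are overdispersed when theta is small", {
  g <- generate_grid(100, 100)
  sch <- make_schedule(2006, "summer")
  env <- generate_environment(g, sch, seed = 8)
  eff <- simulate_effort(g, sch, list(coverage = 1, dist = "constant",
                                      mean = 2), seed = 8)
  tr <- truth_scenario(beta_occ = c(`(Intercept)` = 10),
                       beta_sgt = c(`(Intercept)` = 0, BAT = 0.5),
                       theta = 0.5)
  n <- simulate_observations(env, eff, tr, seed = 8)$cells$n_sightings
  expect_gt(var(n) / mean(n), 1.5)
})

test_that("group sizes are positive integers with a heavy tail", {
  sys <- make_system(seed = 13)
  gs <- sys$dataset$records$group_size
  expect_true(all(gs >= 1))
  expect_gt(stats::sd(gs), mean(gs))  # heavy-tailed at the default params
})

test_that("observation generation is seed-deterministic end to end", {
  a <- make_system(seed = 21)
  b <- make_system(seed = 21)
  expect_identical(a$dataset$records, b$dataset$records)
  expect_identical(a$dataset$cells, b$dataset$cells)
  expect_identical(a$frame, b$frame)
})

test_that("invalid dispersion is rejected", {
  expect_error(truth_scenario(theta = 0), "theta")
  expect_error(truth_scenario(group_theta = -1), "group_theta")
})
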