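test_that("intercept-only binomial fit recovers logit prevalence", {
  frame <- make_frame(seed = 2)
  fit <- fit_candidate(model_spec("presence"), frame)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit$fit)), qlogis(mean(frame$presence)),
               tolerance = 1e-6)
  expect_equal(fit$explained_deviance, 0)
})

test_that("AIC equals -2 logLik + 2k by independent likelihood evaluation", {
  frame <- make_frame(seed = 4)
  # binomial: recompute the Bernoulli log-likelihood directly
  fb <- fit_candidate(model_spec("presence", c("BAT", "REEF")), frame)
  p <- fitted(fb$fit)
  ll_b <- sum(dbinom(frame$presence, 1, p, log = TRUE))
  expect_equal(fb$log_lik, ll_b, tolerance = 1e-8)
  expect_equal(fb$k, 3L)
  expect_equal(fb$aic, -2 * ll_b + 2 * 3, tolerance = 1e-8)
  # negative binomial: theta counts as an estimated parameter
  fn <- fit_candidate(model_spec("n_sightings", c("BAT", "REEF")), frame)
  mu <- fitted(fn$fit)
  ll_n <- sum(dnbinom(frame$n_sightings, mu = mu, size = fn$theta,
                      log = TRUE))
  expect_equal(fn$log_lik, ll_n, tolerance = 1e-6)
  expect_equal(fn$k, 4L)  # intercept + 2 slopes + theta
  expect_equal(fn$aic, -2 * ll_n + 2 * 4, tolerance = 1e-5)
})

test_that("known coefficients are recovered within 3 SE on one large draw", {
  g <- generate_grid(25, 20)
  sch <- make_schedule(2006:2007, c("summer", "winter"))  # 2000 strata
  env <- generate_environment(g, sch, seed = 51)
  eff <- simulate_effort(g, sch, list(coverage = 1, dist = "constant",
                                      mean = 2), seed = 51)
  truth <- truth_scenario(
    beta_occ = c(`(Intercept)` = 0.4, BAT = 0.8, REEF = -0.7),
    beta_sgt = c(`(Intercept)` = -0.5),  # counts irrelevant here
    theta = 1)
  ds <- simulate_observations(env, eff, truth, seed = 51)
  frame <- build_model_frame(ds$records, ds$cells[, 1:4], g, env)
  frame$presence_latent <- ds$cells$presence_latent[
    match(paste(frame$cell_id, frame$season, frame$year),
          paste(ds$cells$cell_id, ds$cells$season, ds$cells$year))]
  frame <- standardize_predictors(frame)
  fit <- glm(presence_latent ~ BAT + REEF, frame, family = binomial())
  est <- coef(fit); se <- sqrt(diag(vcov(fit)))
  truth_vec <- c(0.4, 0.8, -0.7)
  expect_true(all(abs(est - truth_vec) <= 3 * se))
})

test_that("GAM equals GLM in the linear limit and beats it when curved", {
  set.seed(61)
  n <- 800
  tab <- data.frame(BAT = rnorm(n), effort_km = 2)
  # linear truth: spline fit reproduces the straight line
  tab$presence <- rbinom(n, 1, plogis(0.2 + 0.9 * tab$BAT))
  f_glm <- fit_candidate(model_spec("presence", "BAT", "glm"), tab)
  f_gam <- fit_candidate(model_spec("presence", "BAT", "gam"), tab)
  sweep <- data.frame(BAT = seq(-2, 2, length.out = 50), effort_km = 2)
  p_glm <- predict_candidate(f_glm, sweep)
  p_gam <- predict_candidate(f_gam, sweep)
  expect_lt(max(abs(p_glm - p_gam)), 0.06)
  # quadratic truth: the spline explains more deviance
  tab$presence <- rbinom(n, 1, plogis(1 - 1.2 * tab$BAT^2))
  q_glm <- fit_candidate(model_spec("presence", "BAT", "glm"), tab)
  q_gam <- fit_candidate(model_spec("presence", "BAT", "gam"), tab)
  expect_gt(q_gam$explained_deviance, q_glm$explained_deviance)
  # each smooth term spends at most 3 design-matrix columns
  expect_true(all(ensdm:::term_df(q_gam) <= 3))
  expect_true(all(ensdm:::term_df(
    fit_candidate(model_spec("presence", c("BAT", "effort_km"), "gam"),
                  tab)) <= 3))
})

test_that("overdispersion check separates Poisson from NB counts", {
  set.seed(71)
  n <- 5000
  tab <- data.frame(effort_km = runif(n, 1, 4))
  tab$n_sightings <- rpois(n, lambda = tab$effort_km * 0.8)
  r1 <- check_overdispersion(tab)
  expect_lt(abs(r1$ratio - 1), 0.15)
  expect_false(r1$recommend_negbin)
  tab$n_sightings <- rnbinom(n, mu = tab$effort_km * 0.8, size = 0.5)
  r2 <- check_overdispersion(tab)
  expect_gt(r2$ratio, 1.5)
  expect_true(r2$recommend_negbin)
  tab$n_sightings <- 0L
  r3 <- check_overdispersion(tab)
  expect_equal(r3$ratio, 0)
  expect_true(r3$degenerate)
})

test_that("predictions invert the link and honour the offset", {
  frame <- make_frame(seed = 6)
  fit <- fit_candidate(model_spec("presence", c("BAT", "REEF")), frame)
  # hand-evaluated dot product through the link inverse
  nd <- data.frame(BAT = c(0, 1.2), REEF = c(0, -0.5))
  beta <- coef(fit$fit)
  eta <- beta[1] + beta["BAT"] * nd$BAT + beta["REEF"] * nd$REEF
  expect_equal(predict_candidate(fit, nd), unname(plogis(eta)),
               tolerance = 1e-10)
  # at linear predictor zero the probability is one half
  nd0 <- data.frame(BAT = -beta[1] / beta["BAT"], REEF = 0)
  expect_equal(predict_candidate(fit, nd0), 0.5, tolerance = 1e-10)
  # count predictions scale linearly with the reference effort
  fn <- fit_candidate(model_spec("n_sightings", c("BAT", "REEF")), frame)
  nd2 <- frame[1:5, c("BAT", "REEF")]
  expect_equal(predict_candidate(fn, nd2, reference_effort = 2),
               2 * predict_candidate(fn, nd2, reference_effort = 1),
               tolerance = 1e-10)
  expect_error(predict_candidate(fn, nd2["BAT"]), "REEF")
})

test_that("adding predictors never increases residual deviance", {
  frame <- make_frame(seed = 8)
  d0 <- fit_candidate(model_spec("presence"), frame)$deviance
  d1 <- fit_candidate(model_spec("presence", "BAT"), frame)$deviance
  d2 <- fit_candidate(model_spec("presence", c("BAT", "SST")), frame)$deviance
  d3 <- fit_candidate(model_spec("presence", c("BAT", "SST", "REEF")),
                      frame)$deviance
  expect_true(d0 >= d1 && d1 >= d2 && d2 >= d3)
})

test_that("rescaling effort shifts only the count-model intercept", {
  frame <- make_frame(seed = 10)
  f1 <- fit_candidate(model_spec("n_sightings", c("BAT", "REEF")), frame)
  frame2 <- frame
  frame2$effort_km <- frame$effort_km * 3
  f2 <- fit_candidate(model_spec("n_sightings", c("BAT", "REEF")), frame2)
  b1 <- coef(f1$fit); b2 <- coef(f2$fit)
  expect_equal(b2[["(Intercept)"]], b1[["(Intercept)"]] - log(3),
               tolerance = 1e-4)
  expect_equal(b2[c("BAT", "REEF")], b1[c("BAT", "REEF")], tolerance = 1e-4)
})

test_that("a failed candidate is flagged rather than fatal", {
  tab <- data.frame(presence = c(0, 0, 1, 1), BAT = c(-2, -1, 1, 2),
                    effort_km = 1)  # complete separation
  fit <- fit_candidate(model_spec("presence", "BAT"), tab)
  expect_s3_class(fit, "sdm_fit")   # may or may not converge, never errors
  expect_error(fit_candidate(model_spec("presence", "NOPE"), tab), "NOPE")
  expect_error(model_spec("bogus_response"), "response")
})
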