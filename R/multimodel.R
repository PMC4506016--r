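## The package core: all-subsets fitting, AIC ranking, Akaike weights, the
## 95% confidence set, and weight-averaged prediction, wrapped in one
## fitting function returning a classed object.

#' Enumerate all predictor subsets as model specs
#'
#' Produces the `2^k` candidate specs (including the null model) in a
#' deterministic order: by subset size, then lexicographically.
#'
#' @param response Response column name.
#' @param predictors Character vector of retained predictors (`k <= 15`).
#' @param technique `"glm"` or `"gam"`.
#' @return List of [model_spec()] objects.
#' @export
enumerate_models <- function(response, predictors,
                             technique = c("glm", "gam")) {
  technique <- match.arg(technique)
  k <- length(predictors)
  if (k > 15) stop("refusing to enumerate 2^", k,
                   " models; reduce the predictor set", call. = FALSE)
  predictors <- sort(predictors)
  subsets <- list(character(0))
  for (size in seq_len(k)) {
    cmb <- utils::combn(predictors, size, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  lapply(subsets, function(s) model_spec(response, s, technique))
}

#' Akaike weights from AIC values
#'
#' `w_m = exp(-Delta_m / 2) / sum(exp(-Delta / 2))` with
#' `Delta_m = AIC_m - min(AIC)`; the Delta subtraction makes the
#' computation numerically stable. Non-finite AICs (failed fits) get
#' weight 0.
#'
#' @param aic Numeric vector of AIC values.
#' @return Numeric weights summing to 1 over finite-AIC models.
#' @examples
#' akaike_weights(c(100, 102, 110))
#' @export
akaike_weights <- function(aic) {
  ok <- is.finite(aic)
  if (!any(ok)) stop("no finite AIC values", call. = FALSE)
  w <- numeric(length(aic))
  d <- aic[ok] - min(aic[ok])
  rl <- exp(-d / 2)
  w[ok] <- rl / sum(rl)
  w
}

#' Flag the 95% confidence set of models
#'
#' Orders models by descending Akaike weight and flags the minimal prefix
#' whose cumulative weight exceeds `level`.
#'
#' @param weights Numeric Akaike weights.
#' @param level Cumulative-weight threshold (default 0.95).
#' @return Logical vector, `TRUE` for members of the confidence set.
#' @export
confidence_set <- function(weights, level = 0.95) {
  ord <- order(weights, decreasing = TRUE)
  cum <- cumsum(weights[ord])
  # small tolerance so exact-boundary cumulative sums (e.g. uniform
  # weights) are not tipped over the level by floating-point error
  size <- which(cum > level + 1e-9)[1]
  if (is.na(size)) size <- length(weights)  # weights sum to <= level
  flag <- logical(length(weights))
  flag[ord[seq_len(size)]] <- TRUE
  flag
}

#' All-subsets multimodel averaging for one ecological response
#'
#' The central fitting routine: enumerates every predictor subset, fits each
#' candidate (binomial logit for presence; negative binomial with log-effort
#' offset for counts; linear or fixed-df spline terms), ranks candidates by
#' AIC, computes Akaike weights, and flags the 95% confidence set used for
#' weight-averaged prediction. Non-converged candidates are dropped from the
#' ranking with a log entry.
#'
#' @param formula Model scope, e.g. `presence ~ BAT + SST + REEF`. The right
#'   side lists the candidate predictors (main effects only); all `2^k`
#'   subsets of them are fitted.
#' @param data Filtered cell-season table with standardized predictors and,
#'   for count responses, an `effort_km` column. If the table carries a
#'   `"scaling"` attribute (see [standardize_predictors()]) it is stored for
#'   prediction-time reuse.
#' @param technique `"glm"` or `"gam"`.
#' @param level Confidence-set level (default 0.95).
#' @return An object of class `"sdm_avg"`: list with `specs`, `models`
#'   (converged `sdm_fit`s), `ranking` (data frame: id, n_terms, aic, delta,
#'   weight, cum_weight, in_cs, explained_deviance), `response`, `family`,
#'   `technique`, `predictors`, `scaling`, `dropped` (failed candidate ids),
#'   `data` (the training frame).
#' @seealso [predict.sdm_avg()], [summary.sdm_avg()], [akaike_weights()],
#'   [confidence_set()]
#' @examples
#' \donttest{
#' g <- generate_grid(10, 10)
#' env <- generate_environment(g, make_schedule(2006), seed = 2)
#' eff <- simulate_effort(g, make_schedule(2006), seed = 2)
#' ds <- simulate_observations(env, eff, seed = 2)
#' tab <- build_model_frame(ds$records, ds$cells[, 1:4], g, env)
#' tab <- standardize_predictors(tab)
#' fit <- sdm_avg(presence ~ BAT + REEF + FRONT, tab)
#' summary(fit)
#' }
#' @export
sdm_avg <- function(formula, data, technique = c("glm", "gam"),
                    level = 0.95) {
  technique <- match.arg(technique)
  response <- all.vars(formula[[2]])
  predictors <- attr(stats::terms(formula), "term.labels")
  specs <- enumerate_models(response, predictors, technique)
  fits <- lapply(specs, fit_candidate, table = data)
  ok <- vapply(fits, function(f) f$converged && is.finite(f$aic), logical(1))
  dropped <- vapply(fits[!ok], function(f) spec_id(f$spec), character(1))
  fits <- fits[ok]
  if (length(fits) == 0) stop("no candidate model converged", call. = FALSE)
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  w <- akaike_weights(aic)
  ord <- order(aic)
  fits <- fits[ord]; aic <- aic[ord]; w <- w[ord]
  in_cs <- confidence_set(w, level)
  ranking <- data.frame(
    id = vapply(fits, function(f) spec_id(f$spec), character(1)),
    n_terms = vapply(fits, function(f) length(f$spec$terms), integer(1)),
    aic = aic, delta = aic - min(aic), weight = w,
    cum_weight = cumsum(w), in_cs = in_cs,
    explained_deviance = vapply(fits, `[[`, numeric(1),
                                "explained_deviance"))
  structure(list(formula = formula, specs = specs, models = fits,
                 ranking = ranking, response = response,
                 family = fits[[1]]$spec$family, technique = technique,
                 predictors = predictors, level = level,
                 scaling = attr(data, "scaling"), dropped = dropped,
                 data = data),
            class = "sdm_avg")
}

#' @export
print.sdm_avg <- function(x, ...) {
  r <- x$ranking
  cat(sprintf("<sdm_avg> %s %s | %d candidates (%d in %d%% confidence set)\n",
              toupper(x$technique), x$response, nrow(r), sum(r$in_cs),
              round(100 * x$level)))
  cat(sprintf("  best: %s (AIC %.2f, w %.3f, ED %.2f%%)\n",
              r$id[1], r$aic[1], r$weight[1], r$explained_deviance[1]))
  if (length(x$dropped))
    cat("  dropped (non-converged): ", length(x$dropped), "\n")
  invisible(x)
}

#' Summary of a multimodel set
#'
#' @param object An `sdm_avg`.
#' @param n_show Rows of the ranking to print.
#' @param ... Unused.
#' @return The ranking data frame, invisibly.
#' @export
summary.sdm_avg <- function(object, n_show = 10, ...) {
  r <- object$ranking
  cat(sprintf("%s multimodel set for '%s' (%s family), %d predictors\n",
              toupper(object$technique), object$response, object$family,
              length(object$predictors)))
  cat(sprintf("%d candidates; %d in the %d%% confidence set; best ED %.2f%%\n\n",
              nrow(r), sum(r$in_cs), round(100 * object$level),
              r$explained_deviance[1]))
  print(utils::head(r, n_show), digits = 4, row.names = FALSE)
  invisible(r)
}

#' Model-averaged coefficients (full average)
#'
#' Averages coefficients over the confidence set with renormalized Akaike
#' weights, treating predictors absent from a candidate as zero (the
#' full-average convention). Reported for interpretation; prediction uses
#' response-scale averaging (see [predict.sdm_avg()]). Only defined for GLM
#' sets, where coefficients share a common basis.
#'
#' @param object An `sdm_avg` with `technique = "glm"`.
#' @param ... Unused.
#' @return Named numeric vector of averaged coefficients.
#' @export
coef.sdm_avg <- function(object, ...) {
  if (object$technique == "gam")
    stop("averaged coefficients are only reported for GLM sets", call. = FALSE)
  r <- object$ranking
  idx <- which(r$in_cs)
  w <- r$weight[idx] / sum(r$weight[idx])
  all_terms <- c("(Intercept)", object$predictors)
  out <- stats::setNames(numeric(length(all_terms)), all_terms)
  for (j in seq_along(idx)) {
    cf <- stats::coef(object$models[[idx[j]]]$fit)
    out[names(cf)] <- out[names(cf)] + w[j] * cf
  }
  out
}

#' Weight-averaged predictions over the confidence set
#'
#' Per-row prediction = sum of member response-scale predictions times their
#' confidence-set-renormalized Akaike weights; a convex combination, so
#' averaged probabilities stay in [0, 1] and averaged counts stay
#' non-negative.
#'
#' @param object An `sdm_avg`.
#' @param newdata Data frame of predictors. If the fit stored a scaling and
#'   `newdata` is flagged raw (`standardized = FALSE`), the training scaling
#'   is applied first.
#' @param reference_effort Effort (km) at which count predictions are
#'   expressed.
#' @param standardized Set `FALSE` to have the training scaling applied to
#'   `newdata` before prediction.
#' @param ... Unused.
#' @return Numeric vector of averaged response-scale predictions.
#' @export
predict.sdm_avg <- function(object, newdata = object$data,
                            reference_effort = 1, standardized = TRUE,
                            ...) {
  if (!standardized) {
    if (is.null(object$scaling))
      stop("fit stores no scaling; standardize newdata first", call. = FALSE)
    newdata <- standardize_predictors(newdata, params = object$scaling)
  }
  r <- object$ranking
  idx <- which(r$in_cs)
  if (length(idx) == 0) stop("empty confidence set", call. = FALSE)
  w <- r$weight[idx] / sum(r$weight[idx])
  out <- numeric(nrow(newdata))
  for (j in seq_along(idx))
    out <- out + w[j] * predict_candidate(object$models[[idx[j]]], newdata,
                                          reference_effort)
  out
}

#' Deviance residuals of the lowest-AIC candidate
#'
#' The residuals used for spatial-autocorrelation diagnostics.
#'
#' @param object An `sdm_avg`.
#' @param type Residual type passed to the underlying glm.
#' @param ... Unused.
#' @return Numeric residual vector (training rows).
#' @export
residuals.sdm_avg <- function(object, type = "deviance", ...) {
  stats::residuals(object$models[[1]]$fit, type = type)
}

#' Plot the Akaike-weight profile of a model set
#'
#' Delta-AIC against rank, with the confidence-set boundary marked.
#'
#' @param x An `sdm_avg`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sdm_avg <- function(x, ...) {
  r <- x$ranking
  graphics::plot(seq_len(nrow(r)), r$delta, type = "h", lwd = 2,
                 xlab = "model rank", ylab = expression(Delta * AIC),
                 main = sprintf("%s %s: %d of %d in confidence set",
                                toupper(x$technique), x$response,
                                sum(r$in_cs), nrow(r)), ...)
  graphics::abline(v = sum(r$in_cs) + 0.5, lty = 2, col = "grey40")
  invisible(x)
}

#' Simulate responses from the best candidate model
#'
#' Draws new response vectors from the fitted distribution of the
#' lowest-AIC candidate (binomial or negative binomial with the fitted
#' theta), at the training rows' effort.
#'
#' @param object An `sdm_avg`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated responses.
#' @export
simulate.sdm_avg <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  best <- object$models[[1]]
  mu <- stats::predict(best$fit, type = "response")
  n <- length(mu)
  out <- lapply(seq_len(nsim), function(i) {
    if (object$family == "binomial") stats::rbinom(n, 1, mu)
    else stats::rnbinom(n, mu = mu, size = best$theta)
  })
  out <- as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
  out
}

#' Write the ranking table as CSV
#'
#' @param object An `sdm_avg`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(object, path) {
  utils::write.csv(object$ranking, path, row.names = FALSE)
  invisible(path)
}
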