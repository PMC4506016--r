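## Candidate model fitting. Presence is binomial-logit; the two count
## responses (number of sightings, summed group size) are negative binomial
## with a log-effort offset. "GAM" candidates use fixed-df natural cubic
## spline terms (df = 3 per predictor) inside the same ML machinery, which
## makes the degrees-of-freedom cap exact and the fits fully reproducible.

GAM_DF <- 3L

#' Describe one candidate model
#'
#' @param response `"presence"`, `"n_sightings"` or `"group_size_sum"`.
#' @param terms Character vector of predictor names (may be empty: null
#'   model).
#' @param technique `"glm"` (linear terms) or `"gam"` (natural cubic spline
#'   terms with 3 degrees of freedom each).
#' @return A `"model_spec"` list with `response`, `family`, `terms`,
#'   `technique`, `offset` flag.
#' @export
model_spec <- function(response, terms = character(0),
                       technique = c("glm", "gam")) {
  technique <- match.arg(technique)
  if (!response %in% c("presence", "n_sightings", "group_size_sum"))
    stop("unknown response: ", response, call. = FALSE)
  family <- if (response == "presence") "binomial" else "negbin"
  structure(list(response = response, family = family,
                 terms = as.character(terms), technique = technique,
                 offset = family == "negbin"),
            class = "model_spec")
}

spec_formula <- function(spec) {
  rhs <- if (length(spec$terms) == 0) "1"
  else if (spec$technique == "gam")
    paste(sprintf("splines::ns(%s, df = %d)", spec$terms, GAM_DF),
          collapse = " + ")
  else paste(spec$terms, collapse = " + ")
  if (spec$offset) rhs <- paste(rhs, "+ offset(log(effort_km))")
  stats::as.formula(paste(spec$response, "~", rhs))
}

spec_id <- function(spec) {
  paste0(spec$technique, ":", spec$response, ":",
         if (length(spec$terms)) paste(sort(spec$terms), collapse = "+")
         else "1")
}

#' Fit one candidate model
#'
#' Maximum-likelihood fit of a [model_spec()] on a filtered, standardized
#' cell-season table. Negative-binomial dispersion `theta` is estimated by
#' ML and counted as a parameter in AIC's `k`. Non-convergence or fitting
#' errors are flagged (`converged = FALSE`) rather than fatal, so
#' all-subsets runs can drop such candidates with a log entry.
#'
#' @param spec A [model_spec()].
#' @param table Cell-season table with the response, `effort_km` and all
#'   predictors in `spec$terms` (standardized).
#' @return An `"sdm_fit"`: `spec`, `fit` (the underlying glm), `aic`,
#'   `log_lik`, `k`, `null_deviance`, `deviance`, `explained_deviance`
#'   (percent), `theta` (NB only), `converged`, `n`.
#' @export
fit_candidate <- function(spec, table) {
  stopifnot(inherits(spec, "model_spec"))
  miss <- setdiff(spec$terms, names(table))
  if (length(miss))
    stop("missing predictor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  f <- spec_formula(spec)
  fit <- withCallingHandlers(
    tryCatch(
      if (spec$family == "binomial")
        stats::glm(f, data = table, family = stats::binomial())
      else
        MASS::glm.nb(f, data = table),
      error = function(e) e),
    warning = function(w) invokeRestart("muffleWarning"))
  if (inherits(fit, "error")) {
    return(structure(list(spec = spec, fit = NULL, aic = Inf,
                          log_lik = -Inf, k = NA_integer_,
                          null_deviance = NA_real_, deviance = NA_real_,
                          explained_deviance = NA_real_, theta = NA_real_,
                          converged = FALSE, n = nrow(table),
                          error = conditionMessage(fit)),
                     class = "sdm_fit"))
  }
  conv <- isTRUE(fit$converged)
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  nd <- fit$null.deviance
  # for NB fits the reported null deviance conditions on the fitted theta;
  # explained deviance uses it as-is (same convention as summary.glm)
  ed <- if (is.finite(nd) && nd > 0) 100 * (nd - fit$deviance) / nd else 0
  structure(list(spec = spec, fit = fit, aic = stats::AIC(fit),
                 log_lik = as.numeric(ll), k = k,
                 null_deviance = nd, deviance = fit$deviance,
                 explained_deviance = ed,
                 theta = if (spec$family == "negbin") fit$theta else NA_real_,
                 converged = conv, n = nrow(table)),
            class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("<sdm_fit> %s | AIC %.2f | ED %.2f%% | %s\n", spec_id(x$spec),
              x$aic, x$explained_deviance,
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

#' Check count overdispersion under a null Poisson model
#'
#' Fits the intercept-only Poisson model with log-effort offset and returns
#' the Pearson chi-square divided by residual degrees of freedom. Ratios
#' clearly above 1 indicate overdispersion and motivate the negative
#' binomial family.
#'
#' @param table Cell-season table.
#' @param response A count response column name.
#' @return List: `ratio`, `recommend_negbin` (ratio > 1.5), `degenerate`
#'   (all counts zero).
#' @export
check_overdispersion <- function(table, response = "n_sightings") {
  y <- table[[response]]
  if (all(y == 0))
    return(list(ratio = 0, recommend_negbin = FALSE, degenerate = TRUE))
  f <- stats::as.formula(paste(response, "~ 1 + offset(log(effort_km))"))
  fit <- stats::glm(f, data = table, family = stats::poisson())
  ratio <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  list(ratio = ratio, recommend_negbin = ratio > 1.5, degenerate = FALSE)
}

#' Predict from a fitted candidate on the response scale
#'
#' Count predictions are scaled to a common reference effort so surfaces
#' from different strata are comparable.
#'
#' @param model An `sdm_fit`.
#' @param newdata Data frame carrying every predictor in the model's spec,
#'   standardized with the training scaling.
#' @param reference_effort Effort (km) at which count predictions are
#'   expressed (ignored for binomial models).
#' @return Numeric vector of response-scale predictions.
#' @export
predict_candidate <- function(model, newdata, reference_effort = 1) {
  stopifnot(inherits(model, "sdm_fit"))
  if (!model$converged || is.null(model$fit))
    stop("cannot predict from a non-converged model", call. = FALSE)
  miss <- setdiff(model$spec$terms, names(newdata))
  if (length(miss))
    stop("newdata lacks predictor(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (model$spec$offset) newdata$effort_km <- reference_effort
  as.numeric(stats::predict(model$fit, newdata = newdata, type = "response"))
}

# effective number of design-matrix columns per term, used to assert the
# smoother df cap
term_df <- function(model) {
  asn <- attr(model$fit$qr$qr, "assign")
  tab <- table(asn[asn > 0])
  as.integer(tab)
}
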