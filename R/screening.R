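## Collinearity screening: z-standardization, Spearman rank correlations,
## and pairwise resolution by univariate-model AIC.

#' Z-standardize predictor columns
#'
#' Centers and scales each predictor to mean 0, sample SD 1, storing the
#' transformation so it can be re-applied to test or prediction data with
#' the training parameters (never re-estimated).
#'
#' @param table Data frame containing the predictor columns.
#' @param vars Predictor column names (default: all of [predictor_names()]
#'   present in `table`).
#' @param params Optional scaling from a previous call (attribute
#'   `"scaling"`); when given, its centers/scales are applied as-is.
#' @return The table with standardized columns and attribute `"scaling"`
#'   (data frame `var`, `center`, `scale`).
#' @export
standardize_predictors <- function(table, vars = NULL, params = NULL) {
  if (is.null(vars))
    vars <- if (!is.null(params)) params$var
            else intersect(predictor_names(), names(table))
  if (is.null(params)) {
    ctr <- vapply(vars, function(v) mean(table[[v]]), numeric(1))
    scl <- vapply(vars, function(v) stats::sd(table[[v]]), numeric(1))
    zero <- scl == 0 | is.na(scl)
    if (any(zero))
      stop("zero-variance predictor(s): ",
           paste(vars[zero], collapse = ", "), call. = FALSE)
    params <- data.frame(var = vars, center = ctr, scale = scl,
                         row.names = NULL)
  }
  for (k in seq_len(nrow(params))) {
    v <- params$var[k]
    if (is.null(table[[v]])) stop("missing predictor column: ", v,
                                  call. = FALSE)
    table[[v]] <- (table[[v]] - params$center[k]) / params$scale[k]
  }
  attr(table, "scaling") <- params
  table
}

#' Spearman rank-correlation matrix over predictors
#'
#' Midranks for ties; pairwise over the named columns.
#'
#' @param table Data frame (>= 3 rows).
#' @param vars Predictor columns (default: all known predictors present).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(table, vars = NULL) {
  if (is.null(vars)) vars <- intersect(predictor_names(), names(table))
  if (nrow(table) < 3) stop("need at least 3 rows", call. = FALSE)
  stats::cor(as.matrix(table[, vars, drop = FALSE]), method = "spearman")
}

# Univariate model AIC for one predictor against one response.
univariate_aic <- function(table, var, response, family) {
  f <- switch(family,
    binomial = stats::as.formula(paste(response, "~", var)),
    negbin = stats::as.formula(
      paste(response, "~", var, "+ offset(log(effort_km))")),
    stop("unknown family: ", family, call. = FALSE))
  fit <- tryCatch(
    if (family == "binomial")
      stats::glm(f, data = table, family = stats::binomial())
    else
      suppressWarnings(MASS::glm.nb(f, data = table)),
    error = function(e) NULL)
  if (is.null(fit)) return(Inf)
  stats::AIC(fit)
}

#' Resolve collinear predictor pairs by univariate AIC
#'
#' For every pair with `|rs| >= threshold`, fits one univariate model per
#' member (binomial logit for presence; negative binomial with log-effort
#' offset for counts) and removes the member with the higher AIC. Pairs are
#' processed in descending `|rs|`; pairs involving an already-removed
#' variable are skipped, so chained collinearity resolves deterministically.
#' AIC ties break alphabetically (first name kept).
#'
#' @param cor_matrix Spearman matrix from [spearman_matrix()].
#' @param table Cell-season table with standardized predictors, the response
#'   column and `effort_km`.
#' @param response One of `"presence"`, `"n_sightings"`, `"group_size_sum"`.
#' @param family `"binomial"` or `"negbin"` (must match the response).
#' @param threshold Absolute Spearman threshold, inclusive (default 0.7).
#' @return List: `retained` (character), `removed` (character), and `log`
#'   (data frame: pair, rs, the two AICs, decision).
#' @export
resolve_collinearity <- function(cor_matrix, table, response,
                                 family = if (response == "presence")
                                   "binomial" else "negbin",
                                 threshold = 0.7) {
  vars <- colnames(cor_matrix)
  pairs <- which(upper.tri(cor_matrix) & abs(cor_matrix) >= threshold,
                 arr.ind = TRUE)
  logs <- list(); removed <- character(0)
  if (nrow(pairs) > 0) {
    ord <- order(-abs(cor_matrix[pairs]))
    pairs <- pairs[ord, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      a <- vars[pairs[k, 1]]; b <- vars[pairs[k, 2]]
      if (a %in% removed || b %in% removed) next
      aic_a <- univariate_aic(table, a, response, family)
      aic_b <- univariate_aic(table, b, response, family)
      drop_var <- if (aic_a < aic_b) b
        else if (aic_b < aic_a) a
        else sort(c(a, b))[2]  # tie: keep alphabetically first
      removed <- c(removed, drop_var)
      logs[[length(logs) + 1]] <- data.frame(
        var_a = a, var_b = b, rs = cor_matrix[pairs[k, 1], pairs[k, 2]],
        aic_a = aic_a, aic_b = aic_b, removed = drop_var)
    }
  }
  list(retained = setdiff(vars, removed), removed = removed,
       log = if (length(logs)) do.call(rbind, logs) else
         data.frame(var_a = character(0), var_b = character(0),
                    rs = numeric(0), aic_a = numeric(0), aic_b = numeric(0),
                    removed = character(0)))
}

#' Full screening step for one response
#'
#' Standardizes predictors, computes the Spearman matrix and resolves
#' collinear pairs; returns everything downstream stages need.
#'
#' @inheritParams resolve_collinearity
#' @param table Cell-season table with raw predictors joined.
#' @param vars Candidate predictors.
#' @return List: `table` (standardized), `scaling`, `cor_matrix`,
#'   `retained`, `removed`, `log`.
#' @export
screen_predictors <- function(table, response, vars = NULL,
                              family = if (response == "presence")
                                "binomial" else "negbin",
                              threshold = 0.7) {
  if (is.null(vars)) vars <- intersect(predictor_names(), names(table))
  table <- standardize_predictors(table, vars)
  cm <- spearman_matrix(table, vars)
  res <- resolve_collinearity(cm, table, response, family, threshold)
  list(table = table, scaling = attr(table, "scaling"), cor_matrix = cm,
       retained = res$retained, removed = res$removed, log = res$log)
}
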