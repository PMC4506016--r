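## Temporal cross-validation with the concordance index, and residual
## spatial-autocorrelation diagnostics.

#' Split a cell-season table by survey year
#'
#' @param table Cell-season table with a `year` column.
#' @param train_years,test_years Disjoint integer vectors of years.
#' @return List `train`, `test` of row-subsets.
#' @export
split_by_year <- function(table, train_years, test_years) {
  if (length(test_years) == 0 || length(train_years) == 0)
    stop("train and test year sets must be non-empty", call. = FALSE)
  if (length(intersect(train_years, test_years)))
    stop("train and test years overlap", call. = FALSE)
  list(train = table[table$year %in% train_years, , drop = FALSE],
       test = table[table$year %in% test_years, , drop = FALSE])
}

#' Concordance index (C-index)
#'
#' Over all pairs of rows with unequal observed outcomes, the proportion
#' ranked concordantly by the predictions (ties in prediction count 0.5).
#' Applies to binary and count outcomes alike; for binary outcomes it
#' equals the area under the ROC curve.
#'
#' @param predicted Numeric prediction scores.
#' @param observed Numeric observed outcomes.
#' @return Concordance in [0, 1].
#' @examples
#' c_index(c(0.1, 0.8, 0.6, 0.9), c(0, 0, 1, 1))  # 0.75
#' @export
c_index <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  keep <- is.finite(predicted) & is.finite(observed)
  p <- predicted[keep]; o <- observed[keep]
  if (length(unique(o)) < 2)
    stop("C-index undefined: observed outcomes are constant", call. = FALSE)
  # O(n log n)-ish via rank algebra would obscure the tie handling; the
  # pairwise form is explicit and fast enough at survey scale
  do <- outer(o, o, "-")
  use <- do > 0  # each unordered pair once, oriented by the outcome
  dp <- outer(p, p, "-")[use]
  (sum(dp > 0) + 0.5 * sum(dp == 0)) / sum(use)
}

#' Per-stratum C-index summary
#'
#' Computes the C-index separately within each season-year stratum of a
#' table (strata whose outcomes are constant are skipped) and returns the
#' mean and SD across strata, the summary reported for model evaluation.
#'
#' @param table Cell-season table with `season` and `year`.
#' @param predicted Predictions aligned with `table` rows.
#' @param response Observed-outcome column name.
#' @return List: `mean`, `sd`, `per_stratum` (data frame), `n_strata`.
#' @export
c_index_by_stratum <- function(table, predicted, response) {
  key <- paste(table$season, table$year, sep = "-")
  out <- lapply(unique(key), function(k) {
    i <- key == k
    ci <- tryCatch(c_index(predicted[i], table[[response]][i]),
                   error = function(e) NA_real_)
    data.frame(stratum = k, n = sum(i), c_index = ci)
  })
  per <- do.call(rbind, out)
  ok <- per$c_index[!is.na(per$c_index)]
  list(mean = mean(ok), sd = stats::sd(ok), per_stratum = per,
       n_strata = length(ok))
}

#' Global Moran's I
#'
#' `I = (n / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `W = sum_ij w_ij`. Under row-standardized or binary symmetric
#' weights the null expectation is `-1 / (n - 1)`.
#'
#' @param values Numeric vector (e.g. per-cell residuals), non-constant.
#' @param weights Square spatial weight matrix, zero diagonal.
#' @return Moran's I.
#' @export
morans_i <- function(values, weights) {
  n <- length(values)
  if (n < 2) stop("need at least 2 cells", call. = FALSE)
  if (!is.matrix(weights) || any(dim(weights) != n))
    stop("weights must be an n x n matrix", call. = FALSE)
  z <- values - mean(values)
  s2 <- sum(z^2)
  if (s2 == 0) stop("Moran's I undefined for constant values", call. = FALSE)
  W <- sum(weights)
  if (W == 0) stop("total weight is zero", call. = FALSE)
  (n / W) * as.numeric(t(z) %*% weights %*% z) / s2
}

#' Binary distance-band spatial weights
#'
#' `w_ij = 1` when the inter-point distance lies in `(lower, upper]`
#' (diagonal zero), the default neighbourhood for residual diagnostics
#' (0-2 km captures the eight neighbours of a 1 km cell).
#'
#' @param coords Two-column coordinate matrix (km).
#' @param lower,upper Band edges (km).
#' @return Symmetric 0/1 weight matrix.
#' @export
distance_band_weights <- function(coords, lower = 0, upper = 2) {
  d <- as.matrix(stats::dist(coords))
  w <- (d > lower & d <= upper) * 1
  diag(w) <- 0
  w
}

#' Spatial correlogram with permutation tests
#'
#' Moran's I per distance class with binary band weights, and a two-sided
#' randomization test per class: values are permuted over locations and
#' `p = (1 + #{|I_perm| >= |I_obs|}) / (1 + n_permutations)`.
#'
#' @param values Numeric per-cell values (residuals).
#' @param coords Two-column coordinate matrix.
#' @param class_edges Increasing numeric vector of band edges (km); class
#'   `c` is `(edges[c], edges[c+1]]`.
#' @param n_permutations Number of permutations (>= 99).
#' @param seed Integer seed for the permutations.
#' @return Data frame: `lower`, `upper`, `n_pairs`, `morans_i`, `p_value`
#'   (`NA` rows for empty classes).
#' @export
spatial_correlogram <- function(values, coords, class_edges = c(0, 2, 4, 6, 8),
                                n_permutations = 999, seed = 1) {
  if (is.unsorted(class_edges, strictly = TRUE))
    stop("class_edges must be strictly increasing", call. = FALSE)
  if (n_permutations < 99)
    stop("use at least 99 permutations", call. = FALSE)
  n <- length(values)
  z <- values - mean(values)
  s2 <- sum(z^2)
  if (s2 == 0) stop("correlogram undefined for constant values", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  set.seed(seed)
  perm <- replicate(n_permutations, sample.int(n))
  Z <- matrix(z[perm], nrow = n)
  out <- vector("list", length(class_edges) - 1)
  for (c in seq_len(length(class_edges) - 1)) {
    w <- (d > class_edges[c] & d <= class_edges[c + 1]) * 1
    diag(w) <- 0
    W <- sum(w)
    if (W == 0) {
      out[[c]] <- data.frame(lower = class_edges[c],
                             upper = class_edges[c + 1], n_pairs = 0,
                             morans_i = NA_real_, p_value = NA_real_)
      next
    }
    i_obs <- (n / W) * as.numeric(t(z) %*% w %*% z) / s2
    qf <- colSums((w %*% Z) * Z)          # permuted quadratic forms
    i_perm <- (n / W) * qf / s2           # variance is permutation-invariant
    p <- (1 + sum(abs(i_perm) >= abs(i_obs))) / (1 + n_permutations)
    out[[c]] <- data.frame(lower = class_edges[c],
                           upper = class_edges[c + 1], n_pairs = W / 2,
                           morans_i = i_obs, p_value = p)
  }
  do.call(rbind, out)
}

#' Residual spatial-autocorrelation check for a fitted model set
#'
#' Aggregates the lowest-AIC candidate's deviance residuals per cell
#' (averaging over season-year strata), then computes global Moran's I with
#' distance-band weights and its permutation p-value.
#'
#' @param object An `sdm_avg`.
#' @param grid The `sdm_grid` the table's `cell_id`s refer to.
#' @param band Distance band (km) defining neighbours.
#' @param n_permutations Permutations for the test.
#' @param seed Integer seed.
#' @return List: `morans_i`, `p_value`, `n_cells`.
#' @export
check_residual_autocorrelation <- function(object, grid, band = c(0, 2),
                                           n_permutations = 999, seed = 1) {
  res <- stats::residuals(object$models[[1]]$fit, type = "deviance")
  tab <- object$data
  cell_res <- tapply(res, tab$cell_id, mean)
  ids <- as.integer(names(cell_res))
  ctr <- cell_centers(grid)[match(ids, grid$cells$cell_id), , drop = FALSE]
  w <- distance_band_weights(ctr, band[1], band[2])
  i_obs <- morans_i(as.numeric(cell_res), w)
  n <- length(cell_res)
  z <- as.numeric(cell_res) - mean(cell_res)
  set.seed(seed)
  perm <- replicate(n_permutations, sample.int(n))
  Z <- matrix(z[perm], nrow = n)
  qf <- colSums((w %*% Z) * Z)
  i_perm <- (n / sum(w)) * qf / sum(z^2)
  p <- (1 + sum(abs(i_perm) >= abs(i_obs))) / (1 + n_permutations)
  list(morans_i = i_obs, p_value = p, n_cells = n)
}
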