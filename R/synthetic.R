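## Synthetic study system: environmental layers, survey effort and a
## two-layer virtual species with known truth, so the whole modelling chain
## can be exercised offline against parameters that are actually known.

# Deterministic child seed per named stream, so one master seed governs all
# stages without coupling their draws. Kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) *
             (31 ^ (seq_along(utf8ToInt(as.character(stream))) %% 7)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Season-year schedule
#'
#' Builds the list of season-year strata the generators iterate over. Seasons
#' follow the austral coastal convention used throughout the package: summer
#' (Jan-Mar), autumn (Apr-Jun), winter (Jul-Sep), spring (Oct-Dec).
#'
#' @param years Integer vector of survey years.
#' @param seasons Either a character vector of seasons applied to every year,
#'   or a named list mapping year (as character) to its surveyed seasons.
#' @return Data frame with columns `year`, `season`.
#' @examples
#' make_schedule(2006:2007)                       # 8 strata
#' make_schedule(2008, seasons = c("winter", "spring"))
#' @export
make_schedule <- function(years, seasons = season_levels()) {
  if (length(years) == 0) stop("schedule must be non-empty", call. = FALSE)
  if (is.list(seasons)) {
    out <- do.call(rbind, lapply(years, function(y) {
      s <- seasons[[as.character(y)]]
      if (is.null(s)) s <- season_levels()
      data.frame(year = as.integer(y), season = s)
    }))
  } else {
    out <- expand.grid(season = seasons, year = as.integer(years),
                       stringsAsFactors = FALSE)[, c("year", "season")]
  }
  if (!all(out$season %in% season_levels()))
    stop("unknown season label in schedule", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Default schedule emulating the study system
#'
#' Four survey years with four seasons each, except the third year which has
#' only two surveyed seasons (a mid-year survey suspension), giving 14
#' season-year strata.
#' @return Data frame with columns `year`, `season` (14 rows).
#' @export
default_schedule <- function() {
  make_schedule(2006:2009,
                seasons = list(`2008` = c("winter", "spring")))
}

## ---- environmental layers -------------------------------------------------

#' Default environmental-layer configuration
#'
#' Ten predictors: five static (BAT, GRAD, COAST, REEF, BATH100) and five
#' dynamic (CHL, CHLT, SST, SSTT, FRONT). Field layers (BAT, GRAD, CHL, CHLT,
#' SST, SSTT) are smoothed Gaussian random fields rescaled to the configured
#' (min, max) range; distance layers (COAST, REEF, BATH100, FRONT) are raw
#' Euclidean distances (km) from randomly placed feature polylines. Dynamic
#' layers are redrawn per season-year stratum with a seasonal mean component.
#'
#' @return A named list of per-variable configs (`kind`, `static`, `range`,
#'   `smooth`, `seasonal` weights where applicable).
#' @export
default_env_config <- function() {
  list(
    BAT     = list(kind = "field", static = TRUE,  range = c(0.12, 102.12),
                   smooth = 2),
    GRAD    = list(kind = "field", static = TRUE,  range = c(3.48, 100.00),
                   smooth = 1.5),
    CHL     = list(kind = "field", static = FALSE, range = c(0.22, 1.39),
                   smooth = 2,
                   seasonal = c(summer = 0.3, autumn = 0.6, winter = 0.8,
                                spring = 0.5)),
    CHLT    = list(kind = "field", static = FALSE, range = c(6.82, 88.59),
                   smooth = 1,
                   seasonal = c(summer = 0.5, autumn = 0.5, winter = 0.5,
                                spring = 0.5)),
    SST     = list(kind = "field", static = FALSE, range = c(25.43, 29.95),
                   smooth = 2,
                   seasonal = c(summer = 0.85, autumn = 0.5, winter = 0.15,
                                spring = 0.5)),
    SSTT    = list(kind = "field", static = FALSE, range = c(5.71, 15.74),
                   smooth = 1,
                   seasonal = c(summer = 0.5, autumn = 0.5, winter = 0.5,
                                spring = 0.5)),
    COAST   = list(kind = "distance", static = TRUE,  n_feature = 40),
    REEF    = list(kind = "distance", static = TRUE,  n_feature = 25),
    BATH100 = list(kind = "distance", static = TRUE,  n_feature = 30),
    FRONT   = list(kind = "distance", static = FALSE, n_feature = 20)
  )
}

#' @return character vector of the ten predictor names.
#' @rdname default_env_config
#' @export
predictor_names <- function() names(default_env_config())

# Separable Gaussian smoothing of an n_y x n_x white-noise matrix.
smooth_field_matrix <- function(n_x, n_y, sigma) {
  z <- matrix(stats::rnorm(n_x * n_y), nrow = n_y, ncol = n_x)
  if (sigma <= 0) return(z)
  k <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    w <- exp(-d^2 / (2 * sigma^2))
    sweep(w, 1, rowSums(w), "/")
  }
  k(n_y) %*% z %*% t(k(n_x))
}

rescale_range <- function(u, range) {
  span <- diff(range(u))
  if (span == 0) return(rep(mean(range), length(u)))
  range[1] + (u - min(u)) / span * (range[2] - range[1])
}

# Random feature polyline: a smooth random walk across the grid extent,
# densified so that min-distance to its vertices approximates distance to
# the line itself.
random_polyline <- function(grid, n_pts) {
  ext_x <- grid$origin[1] + c(0, grid$n_x * grid$cell_size)
  ext_y <- grid$origin[2] + c(0, grid$n_y * grid$cell_size)
  t0 <- seq(0, 1, length.out = max(4, ceiling(n_pts / 5)))
  x0 <- stats::runif(1, ext_x[1], ext_x[2]) +
    cumsum(stats::rnorm(length(t0), 0, diff(ext_x) / 8))
  y0 <- seq(ext_y[1], ext_y[2], length.out = length(t0)) +
    stats::rnorm(length(t0), 0, diff(ext_y) / 10)
  tt <- seq(0, 1, length.out = n_pts)
  cbind(x = stats::approx(t0, x0, xout = tt)$y,
        y = stats::approx(t0, y0, xout = tt)$y)
}

#' Minimum distance from each grid cell center to a set of feature points
#'
#' @param grid An `sdm_grid`.
#' @param pts Two-column matrix of feature coordinates (km).
#' @return Numeric vector, one distance (km) per cell, ordered by `cell_id`.
#' @export
distance_to_features <- function(grid, pts) {
  ctr <- cell_centers(grid)
  pts <- matrix(as.numeric(pts), ncol = 2)
  dx <- outer(ctr[, 1], pts[, 1], "-")
  dy <- outer(ctr[, 2], pts[, 2], "-")
  sqrt(apply(dx^2 + dy^2, 1, min))
}

#' Generate an environmental layer stack
#'
#' Builds per-cell predictor values for every season-year stratum. Static
#' layers are drawn once; dynamic field layers combine a stratum-specific
#' smoothed random field with a seasonal mean component before rescaling to
#' the configured range; dynamic distance layers (fronts) are re-drawn
#' polylines per stratum. Identical inputs and seed give a bit-identical
#' stack.
#'
#' @param grid An `sdm_grid`.
#' @param schedule Data frame with columns `year`, `season`
#'   (see [make_schedule()]).
#' @param config Per-variable configuration, see [default_env_config()].
#' @param seed Master integer seed.
#' @return An `"env_stack"`: data frame with `cell_id`, `season`, `year` and
#'   one column per predictor; attributes `grid`, `static_vars`, `config`.
#' @export
generate_environment <- function(grid, schedule, config = default_env_config(),
                                 seed = 1) {
  stopifnot(inherits(grid, "sdm_grid"))
  if (NROW(schedule) == 0) stop("schedule must be non-empty", call. = FALSE)
  for (v in names(config)) {
    rg <- config[[v]]$range
    if (!is.null(rg) && rg[1] >= rg[2])
      stop("config range for ", v, " must satisfy min < max", call. = FALSE)
  }
  n <- grid$n_cells
  strata <- paste(schedule$season, schedule$year, sep = "-")
  out <- data.frame(
    cell_id = rep(grid$cells$cell_id, times = nrow(schedule)),
    season = rep(schedule$season, each = n),
    year = rep(schedule$year, each = n)
  )
  for (v in names(config)) {
    cf <- config[[v]]
    col <- numeric(n * nrow(schedule))
    if (isTRUE(cf$static)) {
      set.seed(child_seed(seed, paste0("static-", v)))
      vals <- if (cf$kind == "field") {
        rescale_range(as.vector(t(smooth_field_matrix(grid$n_x, grid$n_y,
                                                      cf$smooth))), cf$range)
      } else {
        distance_to_features(grid, random_polyline(grid, cf$n_feature))
      }
      col <- rep(vals, times = nrow(schedule))
    } else {
      for (s in seq_len(nrow(schedule))) {
        set.seed(child_seed(seed, paste0(v, "-", strata[s])))
        vals <- if (cf$kind == "field") {
          u <- as.vector(t(smooth_field_matrix(grid$n_x, grid$n_y, cf$smooth)))
          u <- (u - min(u)) / max(diff(range(u)), .Machine$double.eps)
          sw <- cf$seasonal[[schedule$season[s]]]
          rescale_range(0.6 * u + 0.4 * sw, cf$range)
        } else {
          distance_to_features(grid, random_polyline(grid, cf$n_feature))
        }
        col[(s - 1) * n + seq_len(n)] <- vals
      }
    }
    out[[v]] <- col
  }
  structure(out, grid = grid,
            static_vars = names(config)[vapply(config, function(z)
              isTRUE(z$static), logical(1))],
            config = config, class = c("env_stack", "data.frame"))
}

## ---- survey effort --------------------------------------------------------

#' Simulate survey effort per cell-season-year
#'
#' Emulates non-systematic vessel surveys with uneven coverage: each cell is
#' surveyed in a stratum with a probability calibrated so that the expected
#' fraction of cells receiving at least 1 km of effort equals
#' `params$coverage`; surveyed cells draw effort from a gamma distribution
#' (or a constant), so some surveyed cells fall below the 1 km
#' minimum-effort threshold and exercise the filtering stage.
#'
#' @param grid An `sdm_grid`.
#' @param schedule Data frame `year`, `season`.
#' @param params List: `coverage` in (0, 1] (target fraction of cells with
#'   effort >= 1 km per stratum), `dist` one of `"gamma"`, `"constant"`,
#'   `mean` mean effort (km) in surveyed cells, `shape` gamma shape.
#' @param seed Master integer seed.
#' @return Data frame `cell_id`, `season`, `year`, `effort_km` (0 for
#'   unsurveyed cells).
#' @export
simulate_effort <- function(grid, schedule,
                            params = list(coverage = 0.69, dist = "gamma",
                                          mean = 4, shape = 2),
                            seed = 1) {
  stopifnot(inherits(grid, "sdm_grid"))
  cov <- params$coverage
  if (is.null(cov) || cov <= 0 || cov > 1)
    stop("coverage must be in (0, 1]", call. = FALSE)
  dist <- if (is.null(params$dist)) "gamma" else params$dist
  m <- params$mean
  p_ge1 <- switch(dist,
    gamma = stats::pgamma(1, shape = params$shape,
                          rate = params$shape / m, lower.tail = FALSE),
    constant = as.numeric(m >= 1),
    stop("unknown effort distribution: ", dist, call. = FALSE))
  p_survey <- min(1, cov / max(p_ge1, .Machine$double.eps))
  n <- grid$n_cells
  out <- vector("list", nrow(schedule))
  for (s in seq_len(nrow(schedule))) {
    set.seed(child_seed(seed, paste0("effort-", schedule$season[s], "-",
                                     schedule$year[s])))
    surveyed <- stats::runif(n) < p_survey
    eff <- numeric(n)
    k <- sum(surveyed)
    if (k > 0)
      eff[surveyed] <- switch(dist,
        gamma = stats::rgamma(k, shape = params$shape,
                              rate = params$shape / m),
        constant = rep(m, k))
    out[[s]] <- data.frame(cell_id = grid$cells$cell_id,
                           season = schedule$season[s],
                           year = schedule$year[s], effort_km = eff)
  }
  do.call(rbind, out)
}

## ---- virtual species ------------------------------------------------------

#' Define the generative truth for a virtual species
#'
#' A two-layer virtual species, the standard device for benchmarking
#' distribution models against known parameters: a latent suitability layer
#' `Z ~ Bernoulli(plogis(eta_occ))` and a conditional encounter layer
#' `N_raw ~ NegBin(mu = effort * exp(eta_sgt), theta)`; realized sightings in
#' a cell-stratum are `N = Z * N_raw`, so the expected count is linear in
#' effort. Linear predictors act on internally z-standardized predictors.
#' Group size per sighting is zero-truncated negative binomial, reproducing
#' the heavy right tail typical of delphinid group-size data.
#'
#' @param beta_occ Named numeric: `(Intercept)` plus coefficients (on the
#'   standardized predictor scale) for the suitability layer.
#' @param beta_sgt Named numeric: same structure, encounter-rate layer.
#' @param theta Negative-binomial dispersion of the encounter layer (> 0).
#' @param group_mean,group_theta Mean and dispersion of the (untruncated)
#'   group-size distribution.
#' @return A `"truth_scenario"` list.
#' @export
truth_scenario <- function(beta_occ = c(`(Intercept)` = 0.3, BATH100 = -1.0,
                                        FRONT = -0.8, REEF = -0.6,
                                        SST = -0.3),
                           beta_sgt = c(`(Intercept)` = -0.7, BATH100 = -0.8,
                                        FRONT = -0.6, REEF = -0.5,
                                        CHL = -0.3),
                           theta = 1, group_mean = 23.26,
                           group_theta = 0.2) {
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  if (group_theta <= 0) stop("group_theta must be > 0", call. = FALSE)
  if (!"(Intercept)" %in% names(beta_occ) ||
      !"(Intercept)" %in% names(beta_sgt))
    stop("coefficient vectors need an (Intercept) entry", call. = FALSE)
  structure(list(beta_occ = beta_occ, beta_sgt = beta_sgt, theta = theta,
                 group_mean = group_mean, group_theta = group_theta),
            class = "truth_scenario")
}

# z-standardize env predictors over the whole stack (generation-time scale).
standardize_env <- function(env, vars) {
  for (v in vars) {
    x <- env[[v]]
    env[[v]] <- (x - mean(x)) / stats::sd(x)
  }
  env
}

linpred <- function(env_std, beta) {
  eta <- rep(beta[["(Intercept)"]], nrow(env_std))
  for (v in setdiff(names(beta), "(Intercept)")) {
    if (is.null(env_std[[v]]))
      stop("truth coefficient references unknown predictor: ", v,
           call. = FALSE)
    eta <- eta + beta[[v]] * env_std[[v]]
  }
  eta
}

# Zero-truncated negative binomial via the inverse-cdf trick.
rztnbinom <- function(n, mu, theta) {
  p0 <- stats::dnbinom(0, mu = mu, size = theta)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qnbinom(pmin(u, 1 - 1e-12), mu = mu, size = theta)
}

season_months <- function(season) {
  switch(season, summer = 1:3, autumn = 4:6, winter = 7:9, spring = 10:12)
}

#' Simulate survey observations from a truth scenario
#'
#' Draws the virtual species over every cell-season-year stratum with
#' positive effort and emits record-level sightings (date within the
#' stratum's season, a uniform position inside the cell, a group size) plus
#' the latent per-cell truth needed for parameter-recovery checks. Cells
#' with zero effort yield no records.
#'
#' @param env An `env_stack` from [generate_environment()].
#' @param effort Effort table from [simulate_effort()].
#' @param truth A [truth_scenario()].
#' @param seed Master integer seed.
#' @return A `"survey_dataset"` list: `records` (data frame `date`, `x_km`,
#'   `y_km`, `group_size`), `cells` (per-stratum truth: `cell_id`, `season`,
#'   `year`, `effort_km`, `presence_latent`, `n_raw`, `n_sightings`,
#'   `eta_occ`, `eta_sgt`), and the `grid`.
#' @export
simulate_observations <- function(env, effort, truth = truth_scenario(),
                                  seed = 1) {
  stopifnot(inherits(env, "env_stack"), inherits(truth, "truth_scenario"))
  if (truth$theta <= 0) stop("theta must be > 0", call. = FALSE)
  grid <- attr(env, "grid")
  vars <- intersect(predictor_names(), names(env))
  env_std <- standardize_env(env, vars)
  key <- paste(env$cell_id, env$season, env$year)
  idx <- match(paste(effort$cell_id, effort$season, effort$year), key)
  if (anyNA(idx))
    stop("effort table contains strata absent from the env stack",
         call. = FALSE)
  cells <- data.frame(cell_id = effort$cell_id, season = effort$season,
                      year = effort$year, effort_km = effort$effort_km)
  cells$eta_occ <- linpred(env_std, truth$beta_occ)[idx]
  cells$eta_sgt <- linpred(env_std, truth$beta_sgt)[idx]

  set.seed(child_seed(seed, "species"))
  n <- nrow(cells)
  cells$presence_latent <- as.integer(stats::runif(n) <
                                        stats::plogis(cells$eta_occ))
  mu <- cells$effort_km * exp(cells$eta_sgt)
  cells$n_raw <- stats::rnbinom(n, mu = mu, size = truth$theta)
  cells$n_raw[cells$effort_km <= 0] <- 0L
  cells$n_sightings <- cells$presence_latent * cells$n_raw

  set.seed(child_seed(seed, "records"))
  tot <- sum(cells$n_sightings)
  rec_row <- rep(seq_len(n), cells$n_sightings)
  gx <- grid$cells$x[match(cells$cell_id[rec_row], grid$cells$cell_id)]
  gy <- grid$cells$y[match(cells$cell_id[rec_row], grid$cells$cell_id)]
  half <- grid$cell_size / 2
  dates <- as.Date(character(0))
  if (tot > 0) {
    mo <- 3L * (match(cells$season[rec_row], season_levels()) - 1L) +
      sample(3L, tot, replace = TRUE)
    dy <- sample(28, tot, replace = TRUE)
    dates <- as.Date(sprintf("%d-%02d-%02d", cells$year[rec_row], mo, dy))
  }
  records <- data.frame(
    date = dates,
    x_km = if (tot > 0) gx + stats::runif(tot, -half, half) else numeric(0),
    y_km = if (tot > 0) gy + stats::runif(tot, -half, half) else numeric(0),
    group_size = if (tot > 0)
      rztnbinom(tot, truth$group_mean, truth$group_theta) else integer(0)
  )
  structure(list(records = records, cells = cells, grid = grid),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("<survey_dataset> %d sighting records over %d cell-strata (%d with effort > 0)\n",
              nrow(x$records), nrow(x$cells), sum(x$cells$effort_km > 0)))
  invisible(x)
}

## ---- writers --------------------------------------------------------------

#' Write a survey dataset and effort table as CSV
#'
#' @param dataset A `survey_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_survey_csv <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sf <- file.path(dir, "sightings.csv")
  ef <- file.path(dir, "effort.csv")
  utils::write.csv(dataset$records, sf, row.names = FALSE)
  utils::write.csv(dataset$cells[, c("cell_id", "season", "year",
                                     "effort_km")], ef, row.names = FALSE)
  invisible(c(sightings = sf, effort = ef))
}

#' Write every layer of an environmental stack as ASCII grids
#'
#' One `.asc` file per predictor per season-year stratum (static predictors
#' are written once with label `static`).
#'
#' @param env An `env_stack`.
#' @param dir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
write_env_asc <- function(env, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid <- attr(env, "grid")
  statics <- attr(env, "static_vars")
  strata <- unique(env[, c("season", "year")])
  files <- character(0)
  for (v in intersect(predictor_names(), names(env))) {
    if (v %in% statics) {
      sub <- env[env$season == strata$season[1] & env$year == strata$year[1], ]
      f <- file.path(dir, sprintf("%s_static.asc", v))
      write_asc(sdm_surface(sub[[v]][order(sub$cell_id)], grid, v, "static"), f)
      files <- c(files, f)
    } else {
      for (s in seq_len(nrow(strata))) {
        sub <- env[env$season == strata$season[s] & env$year == strata$year[s], ]
        lab <- paste0(strata$season[s], "-", strata$year[s])
        f <- file.path(dir, sprintf("%s_%s.asc", v, lab))
        write_asc(sdm_surface(sub[[v]][order(sub$cell_id)], grid, v, lab), f)
        files <- c(files, f)
      }
    }
  }
  invisible(files)
}
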