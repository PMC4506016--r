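## Gridding of raw survey data into the modelling frame: one row per
## cell-season-year stratum carrying effort, the three ecological
## measurements (presence/absence, number of sightings, summed group size)
## and, after joining, the environmental predictors.

#' Season labels used throughout the package
#' @return `c("summer", "autumn", "winter", "spring")`.
#' @export
season_levels <- function() c("summer", "autumn", "winter", "spring")

#' Assign a calendar date to a season
#'
#' Austral coastal convention: summer = Jan-Mar, autumn = Apr-Jun,
#' winter = Jul-Sep, spring = Oct-Dec.
#'
#' @param date A `Date` vector, or strings parsable as ISO dates.
#' @return Character vector of season labels.
#' @examples
#' assign_season("2007-02-15")  # "summer"
#' @export
assign_season <- function(date) {
  d <- tryCatch(as.Date(date), error = function(e) NA)
  if (any(is.na(d)))
    stop("unparsable date(s): ",
         paste(utils::head(date[is.na(d)], 3), collapse = ", "),
         call. = FALSE)
  m <- as.integer(format(d, "%m"))
  season_levels()[(m - 1L) %/% 3L + 1L]
}

#' Map sighting records onto grid cell-season-year strata
#'
#' Each record is assigned to the cell containing its position (half-open
#' cells: a point on an interior edge belongs to the higher-index cell), the
#' season of its date, and its calendar year. Out-of-bounds records are
#' excluded and counted, not fatal.
#'
#' @param records Data frame with columns `date`, `x_km`, `y_km`,
#'   `group_size` (`group_size >= 1`).
#' @param grid An `sdm_grid`.
#' @return A list: `assigned` (the in-bounds records with added `cell_id`,
#'   `season`, `year`) and `n_out_of_bounds`.
#' @export
rasterize_observations <- function(records, grid) {
  stopifnot(inherits(grid, "sdm_grid"))
  need <- c("date", "x_km", "y_km", "group_size")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(records) > 0 && any(records$group_size < 1))
    stop("group_size must be >= 1", call. = FALSE)
  cid <- locate_cells(grid, records$x_km, records$y_km)
  oob <- is.na(cid)
  assigned <- records[!oob, , drop = FALSE]
  assigned$cell_id <- cid[!oob]
  if (nrow(assigned) > 0) {
    assigned$season <- assign_season(assigned$date)
    assigned$year <- as.integer(format(as.Date(assigned$date), "%Y"))
  } else {
    assigned$season <- character(0)
    assigned$year <- integer(0)
  }
  list(assigned = assigned, n_out_of_bounds = sum(oob))
}

#' Compute the three ecological measurements per stratum
#'
#' Aggregates rasterized sightings over each (cell, season, year) stratum of
#' the effort table: `n_sightings` (count of records), `group_size_sum`
#' (summed individuals) and binary `presence` (at least one sighting).
#' Strata with recorded effort but no sightings are genuine absences.
#' Sightings falling in strata with zero recorded effort trigger a
#' consistency warning (they indicate mismatched inputs).
#'
#' @param rasterized Output of [rasterize_observations()].
#' @param effort Data frame `cell_id`, `season`, `year`, `effort_km`.
#' @return Data frame (`cell_season_table`) with one row per effort stratum:
#'   `cell_id`, `season`, `year`, `effort_km`, `presence`, `n_sightings`,
#'   `group_size_sum`.
#' @export
compute_ecological_measurements <- function(rasterized, effort) {
  a <- rasterized$assigned
  key_eff <- paste(effort$cell_id, effort$season, effort$year)
  out <- data.frame(cell_id = effort$cell_id, season = effort$season,
                    year = effort$year, effort_km = effort$effort_km)
  if (nrow(a) > 0) {
    key_obs <- paste(a$cell_id, a$season, a$year)
    i <- match(key_obs, key_eff)
    if (anyNA(i))
      warning(sum(is.na(i)), " sighting(s) in strata with no effort record",
              call. = FALSE)
    ns <- tapply(rep(1L, length(i)), factor(i, seq_along(key_eff)), sum)
    gs <- tapply(a$group_size, factor(i, seq_along(key_eff)), sum)
    ns <- as.vector(ns); gs <- as.vector(gs)
    out$n_sightings <- as.integer(ifelse(is.na(ns), 0L, ns))
    out$group_size_sum <- as.numeric(ifelse(is.na(gs), 0, gs))
    zero_eff <- !is.na(i) & effort$effort_km[i] <= 0
    if (any(zero_eff))
      warning(sum(zero_eff), " sighting(s) fall in strata with zero effort",
              call. = FALSE)
  } else {
    out$n_sightings <- 0L
    out$group_size_sum <- 0
  }
  out$presence <- as.integer(out$n_sightings >= 1L)
  out[, c("cell_id", "season", "year", "effort_km", "presence",
          "n_sightings", "group_size_sum")]
}

#' Apply the minimum-effort filter
#'
#' Drops strata surveyed for less than `min_km` of track, the guard against
#' small-sample bias in sparsely covered cells. The threshold is inclusive:
#' exactly `min_km` is retained.
#'
#' @param table A cell-season table.
#' @param min_km Minimum effort in km (default 1).
#' @return The filtered table; the number of removed rows is attached as
#'   attribute `n_removed`.
#' @export
filter_min_effort <- function(table, min_km = 1) {
  keep <- table$effort_km >= min_km
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Join environmental predictors onto a cell-season table
#'
#' @param table Cell-season table (e.g. from
#'   [compute_ecological_measurements()]).
#' @param env An `env_stack`.
#' @return The table with one added column per predictor present in `env`.
#' @export
join_environment <- function(table, env) {
  key_env <- paste(env$cell_id, env$season, env$year)
  i <- match(paste(table$cell_id, table$season, table$year), key_env)
  if (anyNA(i))
    stop("environmental stack lacks ", sum(is.na(i)), " required strata",
         call. = FALSE)
  for (v in intersect(predictor_names(), names(env)))
    table[[v]] <- env[[v]][i]
  table
}

#' Build the modelling frame from raw survey inputs
#'
#' Convenience chain: rasterize records, aggregate the three ecological
#' measurements, filter by minimum effort, and join predictors.
#'
#' @param records Sighting records (`date`, `x_km`, `y_km`, `group_size`).
#' @param effort Effort table (`cell_id`, `season`, `year`, `effort_km`).
#' @param grid An `sdm_grid`.
#' @param env Optional `env_stack` to join.
#' @param min_km Minimum-effort threshold (km).
#' @return A filtered cell-season table, with predictors if `env` given.
#' @export
build_model_frame <- function(records, effort, grid, env = NULL, min_km = 1) {
  rast <- rasterize_observations(records, grid)
  tab <- compute_ecological_measurements(rast, effort)
  tab <- filter_min_effort(tab, min_km)
  if (!is.null(env)) tab <- join_environment(tab, env)
  tab
}

#' Yearly survey summary
#'
#' Aggregates a cell-season table to one row per year: number of surveyed
#' seasons, total searching effort (km), number of cell-strata with
#' presence, total sightings and total individuals; plus a final `Total`
#' row summing each column.
#'
#' @param table A cell-season table (filtered or not).
#' @return Data frame with columns `year`, `seasons`, `effort_km`,
#'   `cells_present`, `sightings`, `group_size`; last row is the total.
#' @export
summarize_survey_by_year <- function(table) {
  yrs <- sort(unique(table$year))
  rows <- lapply(yrs, function(y) {
    t2 <- table[table$year == y, ]
    data.frame(year = as.character(y),
               seasons = length(unique(t2$season)),
               effort_km = sum(t2$effort_km),
               cells_present = sum(t2$presence),
               sightings = sum(t2$n_sightings),
               group_size = sum(t2$group_size_sum))
  })
  out <- do.call(rbind, rows)
  tot <- data.frame(year = "Total", seasons = sum(out$seasons),
                    effort_km = sum(out$effort_km),
                    cells_present = sum(out$cells_present),
                    sightings = sum(out$sightings),
                    group_size = sum(out$group_size))
  rbind(out, tot)
}

#' Simulate a survey dataset consistent with a printed yearly summary
#'
#' Builds record-level sightings and an effort table whose yearly
#' aggregation reproduces a given summary exactly: for each year,
#' `sightings` records are spread over exactly `cells_present` distinct
#' cell-season strata, group sizes sum to `group_size`, and effort sums to
#' `effort_km` over `seasons` surveyed seasons. Used to check the
#' aggregation machinery against published survey-summary tables.
#'
#' @param summary Data frame with columns `year`, `seasons`, `effort_km`,
#'   `cells_present`, `sightings`, `group_size` (no total row).
#' @param grid An `sdm_grid` with at least `max(cells_present)` cells per
#'   season.
#' @param seed Integer seed.
#' @return A list `records`, `effort` suitable for [build_model_frame()].
#' @export
simulate_survey_from_summary <- function(summary, grid, seed = 1) {
  stopifnot(inherits(grid, "sdm_grid"))
  set.seed(seed)
  recs <- list(); effs <- list()
  for (r in seq_len(nrow(summary))) {
    y <- as.integer(summary$year[r])
    seasons <- season_levels()[seq_len(summary$seasons[r])]
    n_sgt <- summary$sightings[r]
    n_pres <- summary$cells_present[r]
    if (n_sgt < n_pres) stop("sightings < cells_present for year ", y,
                             call. = FALSE)
    if (n_pres < length(seasons))
      stop("cells_present < seasons for year ", y, call. = FALSE)
    # spread presence strata over (cell, season) pairs, each season used
    first <- data.frame(cell = sample(grid$cells$cell_id, length(seasons)),
                        season = seasons, stringsAsFactors = FALSE)
    pool <- expand.grid(cell = grid$cells$cell_id, season = seasons,
                        stringsAsFactors = FALSE)
    pool <- pool[!paste(pool$cell, pool$season) %in%
                   paste(first$cell, first$season), ]
    strat <- rbind(first, pool[sample(nrow(pool), n_pres - length(seasons)), ])
    # one sighting per presence stratum, remainder distributed at random
    extra <- sample(n_pres, n_sgt - n_pres, replace = TRUE)
    idx <- c(seq_len(n_pres), extra)
    # integer group sizes >= 1 summing to the printed total
    gs <- rep(1L, n_sgt)
    left <- summary$group_size[r] - n_sgt
    if (left > 0) {
      add <- tabulate(sample(n_sgt, left, replace = TRUE), nbins = n_sgt)
      gs <- gs + add
    }
    ctr <- grid$cells[match(strat$cell[idx], grid$cells$cell_id), ]
    mo <- vapply(strat$season[idx],
                 function(s) sample(season_months(s), 1), integer(1))
    recs[[r]] <- data.frame(
      date = as.Date(sprintf("%d-%02d-%02d", y, mo,
                             sample(28, n_sgt, replace = TRUE))),
      x_km = ctr$x, y_km = ctr$y, group_size = gs)
    # effort: >= 1 km in every stratum that has sightings, summing exactly
    surveyed <- unique(strat[, c("cell", "season")])
    n_str <- nrow(surveyed)
    base <- summary$effort_km[r] / n_str
    if (base < 1) stop("effort too small to cover presence strata in year ",
                       y, call. = FALSE)
    w <- stats::runif(n_str, 0.5, 1.5)
    eff <- 1 + (w / sum(w)) * (summary$effort_km[r] - n_str)
    effs[[r]] <- data.frame(cell_id = surveyed$cell, season = surveyed$season,
                            year = y, effort_km = eff)
  }
  list(records = do.call(rbind, recs), effort = do.call(rbind, effs))
}
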