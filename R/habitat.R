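## Summary maps, habitat classification into recurrent / occasional /
## unfavourable areas, derived abundance surfaces, and the protected-area
## overlap assessment.

#' Mean and SD maps over a prediction stack
#'
#' Per-cell mean and sample SD across season-year prediction layers. A cell
#' missing a prediction in any layer is no-data in both summaries (such
#' cells stay uncategorized downstream).
#'
#' @param stack List of `sdm_surface` layers on a common grid.
#' @return List of two `sdm_surface`s: `mean`, `sd`.
#' @export
prediction_summary <- function(stack) {
  if (length(stack) == 0) stop("empty prediction stack", call. = FALSE)
  if (length(stack) < 2)
    stop("need at least 2 layers for an SD map", call. = FALSE)
  g <- attr(stack[[1]], "grid")
  for (m in stack[-1])
    if (!same_grid(g, attr(m, "grid")))
      stop("stack layers are on different grids", call. = FALSE)
  m <- do.call(cbind, lapply(stack, as.numeric))
  complete <- rowSums(is.na(m)) == 0
  mu <- sdv <- rep(NA_real_, nrow(m))
  mu[complete] <- rowMeans(m[complete, , drop = FALSE])
  sdv[complete] <- apply(m[complete, , drop = FALSE], 1, stats::sd)
  resp <- attr(stack[[1]], "response")
  list(mean = sdm_surface(mu, g, resp, "mean"),
       sd = sdm_surface(sdv, g, resp, "sd"))
}

#' Classify cells into recurrent, occasional and unfavourable habitat
#'
#' Thresholds are the grid-wide averages of the mean map and SD map over
#' categorizable cells. Rules: SD above the SD threshold -> occasional
#' (high inter-annual variability takes precedence); otherwise mean above
#' the mean threshold -> recurrent; otherwise unfavourable. Strict
#' inequalities: values equal to a threshold fall to the low side. Cells
#' with incomplete prediction stacks are uncategorized. Recurrent plus
#' occasional cells constitute the key areas.
#'
#' @param mean_map,sd_map Aligned `sdm_surface`s from
#'   [prediction_summary()].
#' @return A `"habitat_map"` list: `category` (character per cell),
#'   `mean_threshold`, `sd_threshold`, `grid`, `counts`.
#' @export
classify_habitat <- function(mean_map, sd_map) {
  g <- attr(mean_map, "grid")
  if (!same_grid(g, attr(sd_map, "grid")))
    stop("mean and SD maps are on different grids", call. = FALSE)
  mu <- as.numeric(mean_map); sdv <- as.numeric(sd_map)
  ok <- !is.na(mu) & !is.na(sdv)
  if (!any(ok)) stop("no categorizable cells", call. = FALSE)
  mu_thr <- mean(mu[ok]); sd_thr <- mean(sdv[ok])
  cat <- rep("uncategorized", length(mu))
  cat[ok] <- ifelse(sdv[ok] > sd_thr, "occasional",
                    ifelse(mu[ok] > mu_thr, "recurrent", "unfavourable"))
  structure(list(category = cat, mean_threshold = mu_thr,
                 sd_threshold = sd_thr, grid = g,
                 counts = table(factor(cat, c("recurrent", "occasional",
                                              "unfavourable",
                                              "uncategorized")))),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  n <- length(x$category)
  cat("<habitat_map>", n, "cells:\n")
  for (k in names(x$counts))
    cat(sprintf("  %-13s %5d (%.1f%%)\n", k, x$counts[[k]],
                100 * x$counts[[k]] / n))
  invisible(x)
}

#' Habitat map as a numeric surface
#'
#' Encodes categories for raster export: recurrent = 1, occasional = 2,
#' unfavourable = 3, uncategorized = no-data.
#'
#' @param map A `habitat_map`.
#' @return An `sdm_surface`.
#' @export
habitat_surface <- function(map) {
  v <- match(map$category, c("recurrent", "occasional", "unfavourable"))
  sdm_surface(v, map$grid, "habitat", "category")
}

#' Derived abundance surface
#'
#' Multiplies the ensemble sightings surface by the ensemble group-size
#' surface cell by cell; the total is the sum over cells with both values.
#' By default the group-size member is the per-cell summed-individuals
#' response, mirroring how the measurements are defined; set
#' `per_sighting = TRUE` when the second surface is a mean group size per
#' sighting instead (see the methods vignette for the units caveat).
#'
#' @param sightings,group_size Aligned `sdm_surface`s at a common reference
#'   effort.
#' @param per_sighting Informational flag recorded on the result.
#' @return List: `surface` (`sdm_surface`), `total`, `mean_density`
#'   (per km^2 over categorizable cells).
#' @export
abundance_surface <- function(sightings, group_size, per_sighting = FALSE) {
  g <- attr(sightings, "grid")
  if (!same_grid(g, attr(group_size, "grid")))
    stop("surfaces are on different grids", call. = FALSE)
  ab <- as.numeric(sightings) * as.numeric(group_size)
  out <- sdm_surface(ab, g, "abundance",
                     if (per_sighting) "per-sighting" else "summed")
  ok <- !is.na(ab)
  area <- sum(ok) * g$cell_size^2
  list(surface = out, total = sum(ab[ok]), mean_density = sum(ab[ok]) / area)
}

## ---- protected-area mask and assessment -----------------------------------

# Ray casting for one point against one ring (planar, even-odd rule).
point_in_ring <- function(px, py, rx, ry) {
  n <- length(rx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((ry[i] > py) != (ry[j] > py)) {
      xint <- rx[i] + (py - ry[i]) / (ry[j] - ry[i]) * (rx[j] - rx[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Build a protected-area mask from planar polygon rings
#'
#' A cell belongs to the protected area iff its center falls inside any
#' ring (even-odd rule, no partial-cell weighting). Rings must be closed
#' (first vertex repeated last, or they are closed implicitly).
#'
#' @param rings A two-column matrix of ring vertices, or a list of such
#'   matrices for a multi-part area.
#' @param grid An `sdm_grid`.
#' @return An `"mpa_mask"`: logical vector per cell (attribute `grid`).
#' @export
build_mask <- function(rings, grid) {
  stopifnot(inherits(grid, "sdm_grid"))
  if (!is.list(rings)) rings <- list(rings)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2 || nrow(r) < 3)
      stop("each ring needs >= 3 (x, y) vertices", call. = FALSE)
    # drop an explicit closing vertex; ray casting closes implicitly
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(r) < 3) stop("degenerate ring", call. = FALSE)
    r
  })
  ctr <- cell_centers(grid)
  inside <- vapply(seq_len(nrow(ctr)), function(i) {
    any(vapply(rings, function(r)
      point_in_ring(ctr[i, 1], ctr[i, 2], r[, 1], r[, 2]), logical(1)))
  }, logical(1))
  structure(inside, grid = grid, class = "mpa_mask")
}

#' Read a planar-GeoJSON polygon as a mask
#'
#' Supports Polygon and MultiPolygon geometries with planar (km)
#' coordinates, either bare or as the first feature of a
#' FeatureCollection.
#'
#' @param path GeoJSON file path.
#' @param grid An `sdm_grid`.
#' @return An `mpa_mask`.
#' @export
read_mask_geojson <- function(path, grid) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  geom <- if (!is.null(j$type) && j$type == "FeatureCollection")
    j$features[[1]]$geometry
  else if (!is.null(j$type) && j$type == "Feature") j$geometry
  else j
  ring_mat <- function(rg)
    do.call(rbind, lapply(rg, function(p) c(p[[1]], p[[2]])))
  rings <- switch(geom$type,
    Polygon = lapply(geom$coordinates, ring_mat),
    MultiPolygon = unlist(lapply(geom$coordinates, function(poly)
      lapply(poly, ring_mat)), recursive = FALSE),
    stop("unsupported geometry type: ", geom$type, call. = FALSE))
  build_mask(rings, grid)
}

#' Compare habitat categories and predictions inside vs outside an MPA
#'
#' Per category: the percentage of that category's cells lying inside the
#' mask. Per supplied summary surface: a Welch two-sample t test (two-sided)
#' of per-cell values, ordered outside minus inside, so preference for the
#' protected area yields a negative t. Also reports the percentage of key
#' (recurrent + occasional) area captured by the MPA.
#'
#' @param map A `habitat_map`.
#' @param mask An `mpa_mask` on the same grid.
#' @param surfaces Optional named list of `sdm_surface`s (e.g. the mean
#'   maps) to t-test inside vs outside.
#' @return An `"mpa_report"` list: `category_pct` (data frame), `key_inside_pct`,
#'   `t_tests` (data frame), `n_inside`, `n_outside`.
#' @export
mpa_comparison <- function(map, mask, surfaces = list()) {
  stopifnot(inherits(map, "habitat_map"), inherits(mask, "mpa_mask"))
  if (!same_grid(map$grid, attr(mask, "grid")))
    stop("mask and habitat map are on different grids", call. = FALSE)
  inside <- as.logical(mask)
  if (all(inside) || !any(inside))
    warning("mask is degenerate (all inside or all outside)", call. = FALSE)
  cats <- c("recurrent", "occasional", "unfavourable", "uncategorized")
  category_pct <- do.call(rbind, lapply(cats, function(k) {
    idx <- map$category == k
    n <- sum(idx)
    data.frame(category = k, n = n,
               pct_inside = if (n > 0) 100 * sum(idx & inside) / n else NA,
               pct_outside = if (n > 0) 100 * sum(idx & !inside) / n else NA)
  }))
  key <- map$category %in% c("recurrent", "occasional")
  key_inside <- if (any(key)) 100 * sum(key & inside) / sum(key) else NA
  t_tests <- NULL
  if (length(surfaces)) {
    t_tests <- do.call(rbind, lapply(names(surfaces), function(nm) {
      v <- as.numeric(surfaces[[nm]])
      a <- v[!inside & !is.na(v)]; b <- v[inside & !is.na(v)]
      if (length(a) < 2 || length(b) < 2)
        stop("empty inside or outside partition for surface ", nm,
             call. = FALSE)
      tt <- stats::t.test(a, b)  # Welch; outside - inside
      data.frame(surface = nm, t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 mean_outside = mean(a), mean_inside = mean(b))
    }))
  }
  structure(list(category_pct = category_pct, key_inside_pct = key_inside,
                 t_tests = t_tests, n_inside = sum(inside),
                 n_outside = sum(!inside)),
            class = "mpa_report")
}

#' @export
print.mpa_report <- function(x, ...) {
  cat(sprintf("<mpa_report> %d cells inside, %d outside\n", x$n_inside,
              x$n_outside))
  print(x$category_pct, digits = 3, row.names = FALSE)
  cat(sprintf("key area (recurrent + occasional) inside MPA: %.1f%%\n",
              x$key_inside_pct))
  if (!is.null(x$t_tests)) {
    cat("Welch t tests (outside - inside):\n")
    print(x$t_tests, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Write an MPA assessment report as JSON
#'
#' @param report An `mpa_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mpa_report <- function(report, path) {
  jsonlite::write_json(
    list(category_pct = report$category_pct,
         key_inside_pct = report$key_inside_pct,
         t_tests = report$t_tests,
         n_inside = report$n_inside, n_outside = report$n_outside),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
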