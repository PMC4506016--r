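#' Construct a per-cell prediction surface
#'
#' A surface is one value per grid cell (ordered by `cell_id`), for one
#' response, one model or ensemble, and one season-year stratum or a summary.
#' `NA` marks no-data cells (not surveyed / not predictable).
#'
#' @param values Numeric vector, length `grid$n_cells`.
#' @param grid The `sdm_grid` the values live on.
#' @param response Response label, e.g. `"presence"`.
#' @param label Stratum label, e.g. `"summer-2007"` or `"summary"`.
#' @return An `"sdm_surface"` object (numeric vector with metadata).
#' @export
sdm_surface <- function(values, grid, response = "value", label = "summary") {
  stopifnot(inherits(grid, "sdm_grid"))
  if (length(values) != grid$n_cells)
    stop("values must have one entry per grid cell", call. = FALSE)
  structure(as.numeric(values), grid = grid, response = response,
            label = label, class = "sdm_surface")
}

#' @export
print.sdm_surface <- function(x, ...) {
  g <- attr(x, "grid")
  v <- as.numeric(x)
  cat(sprintf("<sdm_surface> %s [%s] on %dx%d grid; %d no-data cells\n",
              attr(x, "response"), attr(x, "label"), g$n_x, g$n_y,
              sum(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  range %.4g .. %.4g, mean %.4g\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE),
                mean(v, na.rm = TRUE)))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) && a$n_x == b$n_x &&
    a$n_y == b$n_y && isTRUE(all.equal(a$cell_size, b$cell_size))
}

#' Write a surface as an ESRI ASCII grid
#'
#' Plain-text `.asc` raster (ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value header, rows written north to south).
#'
#' @param surface An `sdm_surface`.
#' @param path Output file path.
#' @param nodata No-data sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(surface, path, nodata = -9999) {
  stopifnot(inherits(surface, "sdm_surface"))
  g <- attr(surface, "grid")
  v <- as.numeric(surface)
  v[is.na(v)] <- nodata
  m <- matrix(v, nrow = g$n_y, ncol = g$n_x, byrow = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_x),
    sprintf("nrows %d", g$n_y),
    sprintf("xllcorner %.10g", g$origin[1]),
    sprintf("yllcorner %.10g", g$origin[2]),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  for (r in g$n_y:1)  # top row first
    writeLines(paste(formatC(m[r, ], format = "g", digits = 10),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid as a surface
#'
#' @param path `.asc` file path.
#' @param response,label Metadata labels for the returned surface.
#' @return An `sdm_surface` on the grid described by the file header.
#' @export
read_asc <- function(path, response = "value", label = "summary") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  n_x <- as.integer(hdr$ncols); n_y <- as.integer(hdr$nrows)
  if (length(vals) != n_x * n_y)
    stop("ASCII grid body does not match header dimensions", call. = FALSE)
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  m <- matrix(vals, nrow = n_y, ncol = n_x, byrow = TRUE)
  m <- m[n_y:1, , drop = FALSE]  # back to south-first row order
  grid <- generate_grid(n_x, n_y, hdr$cellsize,
                        c(hdr$xllcorner, hdr$yllcorner))
  sdm_surface(as.numeric(t(m)), grid, response = response, label = label)
}
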