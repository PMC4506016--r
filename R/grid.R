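#' Build a regular planar analysis grid
#'
#' Defines the common spatial grid on which sightings, effort and
#' environmental layers are standardized. Cells are square, indexed row-major
#' from the lower-left corner (cell 0 has its lower-left corner at `origin`),
#' and treated as half-open intervals `[x, x + cell_size) x [y, y + cell_size)`
#' so that every point maps to exactly one cell.
#'
#' @param n_x,n_y Number of cells along x and y (>= 1).
#' @param cell_size Cell edge length in km (> 0). Default 1, a 1 km grid.
#' @param origin Numeric length-2, planar (x, y) of the grid's lower-left
#'   corner in km.
#' @return An object of class `"sdm_grid"`: a list with `n_x`, `n_y`,
#'   `cell_size`, `origin`, `n_cells`, and a data frame `cells` with columns
#'   `cell_id` (0-based), `ix`, `iy` (0-based column/row), `x`, `y` (centers).
#' @examples
#' g <- generate_grid(2, 2)
#' g$cells$x  # 0.5 1.5 0.5 1.5
#' @export
generate_grid <- function(n_x, n_y, cell_size = 1, origin = c(0, 0)) {
  if (length(n_x) != 1L || length(n_y) != 1L || n_x < 1 || n_y < 1 ||
      n_x != floor(n_x) || n_y != floor(n_y))
    stop("n_x and n_y must be integers >= 1", call. = FALSE)
  if (length(cell_size) != 1L || !is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be a single positive number", call. = FALSE)
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("origin must be a finite (x, y) pair", call. = FALSE)
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  ix <- rep(seq_len(n_x) - 1L, times = n_y)
  iy <- rep(seq_len(n_y) - 1L, each = n_x)
  cells <- data.frame(
    cell_id = iy * n_x + ix,
    ix = ix, iy = iy,
    x = origin[1] + (ix + 0.5) * cell_size,
    y = origin[2] + (iy + 0.5) * cell_size
  )
  structure(
    list(n_x = n_x, n_y = n_y, cell_size = cell_size,
         origin = as.numeric(origin), n_cells = n_x * n_y, cells = cells),
    class = "sdm_grid"
  )
}

#' @export
print.sdm_grid <- function(x, ...) {
  cat(sprintf("<sdm_grid> %d x %d cells of %g km (origin %g, %g)\n",
              x$n_x, x$n_y, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Locate planar points on a grid
#'
#' Maps planar coordinates to cell ids using the half-open cell convention:
#' a point exactly on an interior cell edge belongs to the higher-index cell.
#'
#' @param grid An `sdm_grid`.
#' @param x,y Numeric vectors of planar coordinates (km).
#' @return Integer vector of 0-based cell ids, `NA` for out-of-bounds points.
#' @export
locate_cells <- function(grid, x, y) {
  stopifnot(inherits(grid, "sdm_grid"), length(x) == length(y))
  ix <- floor((x - grid$origin[1]) / grid$cell_size)
  iy <- floor((y - grid$origin[2]) / grid$cell_size)
  out <- iy * grid$n_x + ix
  bad <- ix < 0 | ix >= grid$n_x | iy < 0 | iy >= grid$n_y
  out[bad] <- NA_integer_
  as.integer(out)
}

#' Cell centers of a grid
#'
#' @param grid An `sdm_grid`.
#' @return A two-column matrix (x, y) of cell centers ordered by `cell_id`.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "sdm_grid"))
  cbind(x = grid$cells$x, y = grid$cells$y)
}
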