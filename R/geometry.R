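#' Equal-area grid geometry
#'
#' Describes a regular equal-area raster grid: dimensions, cell size in
#' projected metres, and the projected coordinate of the upper-left corner of
#' the upper-left cell. Cell centres sit at half-cell offsets; rows count from
#' the top (north), columns from the left (west).
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in metres (> 0). Cells are square, so the
#'   cell area is `cell_size^2`.
#' @param origin Numeric length-2: (easting, northing) of the upper-left grid
#'   corner in metres.
#' @param crs_label Free-text label for the projected CRS (informational; the
#'   package never reprojects).
#' @return An object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry(10, 10, cell_size = 270)
#' cell_area_km2(g)
#' @export
grid_geometry <- function(n_rows, n_cols, cell_size,
                          origin = c(0, n_rows * cell_size),
                          crs_label = "local equal-area (m)") {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1, length(cell_size) == 1)
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop("n_rows and n_cols must be >= 1", call. = FALSE)
  }
  if (!is.finite(cell_size) || cell_size <= 0) {
    stop("cell_size must be a positive number of metres", call. = FALSE)
  }
  if (length(origin) != 2 || any(!is.finite(origin))) {
    stop("origin must be two finite coordinates (easting, northing)", call. = FALSE)
  }
  structure(
    list(
      n_rows = n_rows, n_cols = n_cols,
      cell_size = as.numeric(cell_size),
      origin = as.numeric(origin),
      crs_label = as.character(crs_label)
    ),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf(
    "<grid_geometry> %d x %d cells of %g m (%.4f km^2 each), origin (%g, %g), CRS: %s\n",
    x$n_rows, x$n_cols, x$cell_size, cell_area_km2(x),
    x$origin[1], x$origin[2], x$crs_label
  ))
  invisible(x)
}

#' @export
format.grid_geometry <- function(x, ...) {
  sprintf("%dx%d @ %gm", x$n_rows, x$n_cols, x$cell_size)
}

#' Area of one grid cell in square kilometres
#'
#' Always derived from the geometry (`cell_size^2 / 1e6`), never stored.
#'
#' @param geometry A [grid_geometry()].
#' @return Scalar area in km^2.
#' @export
cell_area_km2 <- function(geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  (geometry$cell_size^2) / 1e6
}

#' Cell-centre coordinate table for a grid
#'
#' One row per cell in row-major order with a stable integer `cell` id
#' (`(row - 1) * n_cols + col`), grid indices, and projected centre
#' coordinates.
#'
#' @param geometry A [grid_geometry()].
#' @return Tibble with columns `cell`, `row`, `col`, `x`, `y`.
#' @export
grid_cells <- function(geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  row <- rep(seq_len(geometry$n_rows), each = geometry$n_cols)
  col <- rep(seq_len(geometry$n_cols), times = geometry$n_rows)
  tibble::tibble(
    cell = (row - 1L) * geometry$n_cols + col,
    row = row,
    col = col,
    x = geometry$origin[1] + (col - 0.5) * geometry$cell_size,
    y = geometry$origin[2] - (row - 0.5) * geometry$cell_size
  )
}

#' Test two geometries for equality
#'
#' Grids match when dimensions, cell size and origin agree (origin to
#' millimetre tolerance). The CRS label is informational and not compared.
#'
#' @param a,b [grid_geometry()] objects.
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b) {
  stopifnot(inherits(a, "grid_geometry"), inherits(b, "grid_geometry"))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size, tolerance = 1e-9)) &&
    all(abs(a$origin - b$origin) < 1e-3)
}

stop_if_geometry_mismatch <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b)) {
    stop("grid mismatch: ", what, " are not on the same geometry", call. = FALSE)
  }
  invisible(TRUE)
}
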