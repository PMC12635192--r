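#' Georeferenced grid geometry
#'
#' Describes the spatial frame of a north-up raster: shape, origin (the map
#' coordinate of the *top-left corner* of the top-left cell), cell size, and a
#' coordinate reference system identifier. `cell_size_y` is negative for
#' north-up grids (row index increases southward), matching the GeoTIFF
#' convention.
#'
#' @param n_rows,n_cols Grid shape (positive integers).
#' @param origin_x,origin_y Map coordinates of the top-left corner, in the
#'   units of `crs_id` (degrees for geographic CRSs, metres for projected).
#' @param cell_size_x Cell width (> 0).
#' @param cell_size_y Cell height; negative for north-up grids.
#' @param crs_id Text CRS identifier, e.g. `"EPSG:4326"`.
#' @return A `grid_geometry` object.
#' @examples
#' grid_geometry(10, 20, -130, 60, 0.25, -0.25)
#' @export
grid_geometry <- function(n_rows, n_cols, origin_x, origin_y,
                          cell_size_x, cell_size_y, crs_id = "EPSG:4326") {
  if (!is_count(n_rows) || n_rows < 1) stop_pn("n_rows must be a positive integer")
  if (!is_count(n_cols) || n_cols < 1) stop_pn("n_cols must be a positive integer")
  if (!is.numeric(cell_size_x) || cell_size_x <= 0) {
    stop_pn("cell_size_x must be > 0")
  }
  if (!is.numeric(cell_size_y) || cell_size_y == 0) {
    stop_pn("cell_size_y must be nonzero (negative for north-up grids)")
  }
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
      cell_size_x = as.numeric(cell_size_x), cell_size_y = as.numeric(cell_size_y),
      crs_id = as.character(crs_id)
    ),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf(
    "<grid_geometry> %d x %d cells, origin (%g, %g), cell %g x %g, crs %s\n",
    x$n_rows, x$n_cols, x$origin_x, x$origin_y,
    x$cell_size_x, x$cell_size_y, x$crs_id
  ))
  invisible(x)
}

#' Test whether two grid geometries are aligned
#'
#' Two grids are aligned iff every geometry field (shape, origin, cell size,
#' CRS) is equal; all multi-grid operations in the package require pre-aligned
#' inputs and never resample.
#'
#' @param a,b `grid_geometry` objects.
#' @param tol Numeric tolerance on origin and cell size comparisons.
#' @return Logical.
#' @export
geometry_aligned <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "grid_geometry"), inherits(b, "grid_geometry"))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_x - b$origin_x) <= tol && abs(a$origin_y - b$origin_y) <= tol &&
    abs(a$cell_size_x - b$cell_size_x) <= tol &&
    abs(a$cell_size_y - b$cell_size_y) <= tol &&
    identical(a$crs_id, b$crs_id)
}

#' Map coordinates of cell centres
#'
#' @param geom A `grid_geometry`.
#' @param row,col 1-based cell indices (row 1 is the northern edge).
#' @return Data frame with columns `x`, `y`.
#' @export
cell_center <- function(geom, row, col) {
  stopifnot(inherits(geom, "grid_geometry"))
  data.frame(
    x = geom$origin_x + (col - 0.5) * geom$cell_size_x,
    y = geom$origin_y + (row - 0.5) * geom$cell_size_y
  )
}

#' Locate points on a grid
#'
#' Converts map coordinates to 1-based (row, col) indices of the containing
#' cell. The coordinate convention is cell-centre with row 1 at the northern
#' edge; a point lying exactly on a cell boundary belongs to the cell to its
#' south-east. Points outside the grid extent get `NA` indices.
#'
#' @param geom A `grid_geometry`.
#' @param x,y Numeric vectors of map coordinates (same length).
#' @return Data frame with integer columns `row`, `col` (`NA` outside extent).
#' @export
point_to_cell <- function(geom, x, y) {
  stopifnot(inherits(geom, "grid_geometry"), length(x) == length(y))
  col <- floor((x - geom$origin_x) / geom$cell_size_x) + 1
  row <- floor((y - geom$origin_y) / geom$cell_size_y) + 1
  bad <- !is.finite(row) | !is.finite(col) |
    row < 1 | row > geom$n_rows | col < 1 | col > geom$n_cols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}
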