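#' A georeferenced single-variable raster
#'
#' The basic gridded container of the package: a real-valued matrix (row 1 =
#' north) plus a [grid_geometry()], a variable name, units, and a nodata
#' sentinel. Internally nodata cells are stored as `NA`; the sentinel is only
#' used on disk. Climate variables must be one of [CLIMATE_VARIABLES]; other
#' grids (land masks, host volumes, suitability classes, richness counts) use
#' free-form variable names and units.
#'
#' @param values Numeric matrix (`n_rows` x `n_cols`), `NA` for nodata.
#' @param geometry A [grid_geometry()] matching `dim(values)`.
#' @param variable Variable name; one of [CLIMATE_VARIABLES] for climate
#'   grids, any label otherwise.
#' @param units Units string; inferred for the six climate variables.
#' @param nodata Nodata sentinel written to disk (default `-3.4e38`).
#' @return A `climate_grid` object.
#' @export
climate_grid <- function(values, geometry, variable,
                         units = NULL, nodata = -3.4e38) {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as.matrix(values)
  if (nrow(values) != geometry$n_rows || ncol(values) != geometry$n_cols) {
    stop_pn(
      "values shape (%d x %d) does not match geometry (%d x %d)",
      nrow(values), ncol(values), geometry$n_rows, geometry$n_cols
    )
  }
  storage.mode(values) <- "double"
  variable <- as.character(variable)
  if (is.null(units)) {
    units <- if (variable %in% CLIMATE_VARIABLES) {
      unname(CLIMATE_UNITS[variable])
    } else {
      ""
    }
  }
  g <- structure(
    list(
      values = values, geometry = geometry, variable = variable,
      units = units, nodata = as.numeric(nodata)
    ),
    class = "climate_grid"
  )
  validate_climate_grid(g)
  g
}

# precipitation non-negativity is a hard invariant for the three PREC grids
validate_climate_grid <- function(g) {
  if (g$variable %in% PREC_VARIABLES) {
    v <- g$values
    if (any(v < 0, na.rm = TRUE)) {
      stop_pn("%s grid has negative precipitation values", g$variable)
    }
  }
  invisible(g)
}

#' @export
print.climate_grid <- function(x, ...) {
  n_valid <- sum(!is.na(x$values))
  rng <- if (n_valid) range(x$values, na.rm = TRUE) else c(NA, NA)
  cat(sprintf(
    "<climate_grid> %s [%s]: %d x %d, %d valid cells, range [%g, %g]\n",
    x$variable, x$units, x$geometry$n_rows, x$geometry$n_cols,
    n_valid, rng[1], rng[2]
  ))
  invisible(x)
}

#' @export
dim.climate_grid <- function(x) dim(x$values)

grid_aligned <- function(a, b, tol = 1e-9) {
  geometry_aligned(a$geometry, b$geometry, tol = tol)
}

#' An aligned set of the six climate variable grids
#'
#' @param grids List of six [climate_grid()]s, one per [CLIMATE_VARIABLES]
#'   entry, pairwise aligned. May be named or ordered arbitrarily; stored in
#'   canonical order.
#' @param label Text label for the stack, e.g. `"baseline-1971-2000"` or a
#'   GCM/SSP/period combination.
#' @return A `climate_stack` object.
#' @export
climate_stack <- function(grids, label = "baseline") {
  stopifnot(is.list(grids))
  vars <- vapply(grids, function(g) g$variable, character(1))
  if (!setequal(vars, CLIMATE_VARIABLES) || anyDuplicated(vars)) {
    stop_pn(
      "a climate_stack needs each of %s exactly once (got: %s)",
      paste(CLIMATE_VARIABLES, collapse = ", "), paste(vars, collapse = ", ")
    )
  }
  grids <- grids[match(CLIMATE_VARIABLES, vars)]
  names(grids) <- CLIMATE_VARIABLES
  for (v in CLIMATE_VARIABLES[-1]) {
    if (!grid_aligned(grids[[v]], grids[[1]])) {
      stop_pn("grid %s is not aligned with %s", v, CLIMATE_VARIABLES[1])
    }
  }
  structure(
    list(grids = grids, label = as.character(label)),
    class = "climate_stack"
  )
}

#' @export
print.climate_stack <- function(x, ...) {
  g <- x$grids[[1]]$geometry
  cat(sprintf(
    "<climate_stack> '%s': %d x %d cells, %d variables\n",
    x$label, g$n_rows, g$n_cols, length(x$grids)
  ))
  invisible(x)
}

#' Check the physical consistency of a climate stack
#'
#' Verifies, cell-wise over valid cells, that `MINTCM <= MAT <= MAXTHM` and
#' `PRECCP + PRECHP <= PREC`. Grids generated by [make_climate_stack()]
#' satisfy this by construction; external inputs should be checked.
#'
#' @param stack A [climate_stack()].
#' @param tol Numeric slack for the comparisons.
#' @return `TRUE` invisibly, or an error describing the violated relation.
#' @export
check_stack_consistency <- function(stack, tol = 1e-6) {
  stopifnot(inherits(stack, "climate_stack"))
  g <- stack$grids
  both <- function(a, b) !is.na(a) & !is.na(b)
  mat <- g$MAT$values
  if (any((g$MINTCM$values > mat + tol)[both(g$MINTCM$values, mat)])) {
    stop_pn("MINTCM exceeds MAT on some valid cells")
  }
  if (any((g$MAXTHM$values < mat - tol)[both(g$MAXTHM$values, mat)])) {
    stop_pn("MAXTHM is below MAT on some valid cells")
  }
  seas <- g$PRECCP$values + g$PRECHP$values
  ok <- both(seas, g$PREC$values)
  if (any((seas > g$PREC$values + tol)[ok])) {
    stop_pn("PRECCP + PRECHP exceeds PREC on some valid cells")
  }
  invisible(TRUE)
}

#' Sample raster values at point locations
#'
#' Returns the value of the cell containing each point (nearest-cell lookup,
#' no interpolation), mirroring extraction of gridded climate at occurrence
#' locations. Points outside the grid extent, or falling on a nodata cell,
#' yield `NA` — missingness is a value here, not an error.
#'
#' @param grid A [climate_grid()].
#' @param x,y Point coordinates in the grid's CRS (lon/lat for geographic
#'   grids). `x` may also be a two-column matrix or data frame of (x, y).
#' @return Numeric vector, `NA` where the point misses the grid or hits
#'   nodata.
#' @export
sample_at_points <- function(grid, x, y = NULL) {
  stopifnot(inherits(grid, "climate_grid"))
  if (is.null(y)) {
    xy <- as.matrix(x)
    stopifnot(ncol(xy) == 2)
    x <- as.numeric(xy[, 1])
    y <- as.numeric(xy[, 2])
  }
  rc <- point_to_cell(grid$geometry, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- grid$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Extract the six climate variables at points
#'
#' @param stack A [climate_stack()].
#' @param x,y Point coordinates (see [sample_at_points()]).
#' @return Data frame with one column per climate variable, `NA` where a
#'   point misses the grid or hits nodata.
#' @export
extract_climate <- function(stack, x, y = NULL) {
  stopifnot(inherits(stack, "climate_stack"))
  as.data.frame(lapply(stack$grids, sample_at_points, x = x, y = y))
}

#' Cell-wise algebra over aligned grids
#'
#' Applies a vectorized cell-wise function to one or more aligned grids and
#' returns the result as a new grid. Any nodata operand makes the output cell
#' nodata, whatever `fn` would return.
#'
#' @param grids A [climate_grid()] or list of aligned grids.
#' @param fn Vectorized function of as many numeric arguments as there are
#'   grids.
#' @param variable,units Metadata for the result grid (defaults to the first
#'   input's).
#' @return A [climate_grid()] aligned with the inputs.
#' @examples
#' # future = baseline + anomaly, by hand:
#' # map_algebra(list(base_grid, delta_grid), `+`)
#' @export
map_algebra <- function(grids, fn, variable = NULL, units = NULL) {
  if (inherits(grids, "climate_grid")) grids <- list(grids)
  stopifnot(length(grids) >= 1, all(vapply(grids, inherits, TRUE, "climate_grid")))
  for (g in grids[-1]) {
    if (!grid_aligned(g, grids[[1]])) stop_pn("map_algebra inputs are misaligned")
  }
  fn <- match.fun(fn)
  vals <- lapply(grids, function(g) g$values)
  res <- do.call(fn, vals)
  res <- matrix(as.numeric(res), nrow = nrow(vals[[1]]), ncol = ncol(vals[[1]]))
  any_na <- Reduce(`|`, lapply(vals, is.na))
  res[any_na] <- NA_real_
  out_var <- variable %||% grids[[1]]$variable
  g <- grids[[1]]
  out <- climate_grid(res, g$geometry, out_var,
                      units = units %||% g$units, nodata = g$nodata)
  out
}

#' Per-cell area of a grid, in km2
#'
#' For geographic (degree) grids the east-west cell length shrinks with the
#' cosine of latitude, so area is computed per row on the authalic sphere
#' (R = 6371.0072 km). For projected grids the cell size is taken at face
#' value in metres.
#'
#' @param geom A [grid_geometry()].
#' @return Numeric vector of length `n_rows`: the area of one cell in each
#'   row, km2.
#' @export
cell_area_km2 <- function(geom) {
  stopifnot(inherits(geom, "grid_geometry"))
  if (is_geographic_crs(geom$crs_id)) {
    km_per_deg <- pi * 6371.0072 / 180
    lat <- cell_center(geom, seq_len(geom$n_rows), 1)$y
    (geom$cell_size_x * km_per_deg) *
      (abs(geom$cell_size_y) * km_per_deg) * cos(lat * pi / 180)
  } else {
    rep((geom$cell_size_x / 1000) * (abs(geom$cell_size_y) / 1000), geom$n_rows)
  }
}

is_geographic_crs <- function(crs_id) {
  grepl("4326|WGS\\s*84|CRS84|longlat", crs_id, ignore.case = TRUE)
}
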