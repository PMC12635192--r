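# shared fixture builders; worlds are cached per (size, seed) so test files
# that reuse the same configuration do not regenerate it

.world_cache <- new.env(parent = emptyenv())

test_world <- function(n = 40, seed = 101, land_fraction = 0.7) {
  key <- paste(n, seed, land_fraction, sep = "_")
  if (is.null(.world_cache[[key]])) {
    cfg <- synthetic_world_config(
      n_rows = n, n_cols = n, seed = seed, land_fraction = land_fraction
    )
    .world_cache[[key]] <- make_climate_stack(cfg)
  }
  .world_cache[[key]]
}

land_climate <- function(world) {
  pestniche:::stack_cell_table(world$stack)
}

# a niche constrained mostly in MAT, weakly in the other five variables
mat_niche <- function(world, mat_quantile = 0.3, mat_spread = 2.5,
                      rate = 0.9) {
  cells <- land_climate(world)
  centre <- vapply(CLIMATE_VARIABLES, function(v) {
    stats::median(cells[[v]])
  }, numeric(1))
  centre["MAT"] <- stats::quantile(cells$MAT, mat_quantile, names = FALSE)
  spread <- vapply(CLIMATE_VARIABLES, function(v) {
    3 * stats::sd(cells[[v]]) + 1e-6
  }, numeric(1))
  spread["MAT"] <- mat_spread
  true_niche(centre = centre, spread = spread, max_occurrence_rate = rate)
}

# random climate table (not tied to any landscape) for unit-level tests
random_climate <- function(n, seed = 1) {
  withr::with_seed(seed, {
    data.frame(
      MAT = rnorm(n, 5, 4),
      MINTCM = rnorm(n, -8, 4),
      MAXTHM = rnorm(n, 18, 4),
      PREC = rlnorm(n, log(800), 0.3),
      PRECCP = rlnorm(n, log(180), 0.4),
      PRECHP = rlnorm(n, log(200), 0.4)
    )
  })
}

# tiny all-land constant-geometry grid for hand-constructed cases
toy_grid <- function(values, cell = 1, origin_x = 0, origin_y = nrow(values),
                     variable = "MASK", crs = "EPSG:4326") {
  geom <- grid_geometry(nrow(values), ncol(values), origin_x, origin_y,
                        cell, -cell, crs_id = crs)
  climate_grid(values, geom, variable)
}

# constant-valued six-variable stack on a toy geometry
toy_stack <- function(n_rows = 5, n_cols = 5, values = NULL, label = "toy") {
  geom <- grid_geometry(n_rows, n_cols, 0, n_rows, 1, -1)
  values <- values %||% c(MAT = 5, MINTCM = -5, MAXTHM = 15,
                          PREC = 800, PRECCP = 200, PRECHP = 220)
  grids <- lapply(CLIMATE_VARIABLES, function(v) {
    climate_grid(matrix(values[[v]], n_rows, n_cols), geom, v)
  })
  climate_stack(grids, label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
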