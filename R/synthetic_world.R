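# Synthetic study system: spatially autocorrelated climate surfaces, a land
# mask, species with known Gaussian niches, deliberately dirty occurrence
# records, GCM anomaly fields, and host-volume surfaces. Everything is
# deterministic given (config, seed), so every downstream stage can be tested
# against generator ground truth with no external data.

#' Configuration of a synthetic world
#'
#' @param n_rows,n_cols Grid shape (default 100 x 100).
#' @param seed Integer seed; the whole world is reproducible from it.
#' @param temperature_gradient North-to-south span of mean annual
#'   temperature, degrees C (default 25: roughly boreal-to-subtropical).
#' @param noise_sd Named numeric: spatial noise scale for `MAT` (degC) and
#'   for `PREC` (log scale).
#' @param land_fraction Fraction of cells that are land, in (0, 1].
#' @param smooth_width Width (odd integer, cells) of the separable
#'   moving-average kernel used to autocorrelate the noise fields.
#' @param origin_x,origin_y,cell_size Geographic frame of the world
#'   (degrees; defaults span 35-60 N, 130-105 W at 0.25 degrees).
#' @return A `synthetic_world_config` list.
#' @export
synthetic_world_config <- function(n_rows = 100, n_cols = 100, seed = 1,
                                   temperature_gradient = 25,
                                   noise_sd = c(MAT = 1.5, PREC = 0.4),
                                   land_fraction = 0.7,
                                   smooth_width = 7,
                                   origin_x = -130, origin_y = 60,
                                   cell_size = 0.25) {
  stopifnot(land_fraction > 0, land_fraction <= 1, all(noise_sd >= 0),
            smooth_width >= 1, smooth_width %% 2 == 1)
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      seed = as.integer(seed),
      temperature_gradient = temperature_gradient,
      noise_sd = noise_sd, land_fraction = land_fraction,
      smooth_width = as.integer(smooth_width),
      origin_x = origin_x, origin_y = origin_y, cell_size = cell_size
    ),
    class = "synthetic_world_config"
  )
}

# running mean with edge replication, length preserved
running_mean <- function(x, w) {
  if (w <= 1) return(x)
  half <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(half + 1):(half + length(x))]
}

# separable moving-average smoothing of a matrix
smooth_matrix <- function(m, w) {
  if (w <= 1) return(m)
  m <- apply(m, 2, running_mean, w = w)
  t(apply(m, 1, running_mean, w = w))
}

# standardized smooth Gaussian field: white noise, separable moving average,
# rescaled to mean 0 / sd 1 so callers control amplitude directly
smooth_field <- function(n_rows, n_cols, w) {
  f <- smooth_matrix(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols), w)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic baseline climate stack and land mask
#'
#' Builds six mutually consistent climate surfaces on a geographic grid:
#' `MAT` is a smooth north-south gradient plus autocorrelated noise;
#' `MINTCM`/`MAXTHM` are `MAT` minus/plus strictly positive seasonal offset
#' fields; `PREC` is lognormal-smooth (hence nonnegative); `PRECCP` and
#' `PRECHP` are fractions of `PREC` whose sum stays below it. A smooth field
#' thresholded at the configured land fraction defines the land mask; ocean
#' cells are nodata in every climate grid. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [synthetic_world_config()].
#' @return List with elements `stack` (a [climate_stack()]) and `landmask`
#'   (a [climate_grid()] with value 1 on land and nodata on ocean).
#' @export
make_climate_stack <- function(config) {
  stopifnot(inherits(config, "synthetic_world_config"))
  nr <- config$n_rows
  nc <- config$n_cols
  w <- config$smooth_width
  geom <- grid_geometry(nr, nc, config$origin_x, config$origin_y,
                        config$cell_size, -config$cell_size)
  with_seed(config$seed, {
    row_frac <- matrix((seq_len(nr) - 0.5) / nr, nr, nc) # 0 north -> 1 south
    mat <- -3 + config$temperature_gradient * row_frac +
      config$noise_sd[["MAT"]] * smooth_field(nr, nc, w)
    winter_off <- pmax(1, 9 + 2.5 * smooth_field(nr, nc, w))
    summer_off <- pmax(1, 8 + 2.0 * smooth_field(nr, nc, w))
    prec <- exp(log(800) + config$noise_sd[["PREC"]] * smooth_field(nr, nc, w))
    frac_cold <- 0.10 + 0.30 * stats::plogis(1.5 * smooth_field(nr, nc, w))
    frac_hot <- 0.10 + 0.30 * stats::plogis(1.5 * smooth_field(nr, nc, w))
    land_f <- smooth_field(nr, nc, max(w, 9))
    thresh <- stats::quantile(land_f, 1 - config$land_fraction, names = FALSE)
    land <- land_f >= thresh
    surfaces <- list(
      MAT = mat,
      MINTCM = mat - winter_off,
      MAXTHM = mat + summer_off,
      PREC = prec,
      PRECCP = prec * frac_cold,
      PRECHP = prec * frac_hot
    )
    surfaces <- lapply(surfaces, function(m) {
      m[!land] <- NA_real_
      m
    })
    mask_vals <- matrix(NA_real_, nr, nc)
    mask_vals[land] <- 1
    list(
      stack = climate_stack(
        Map(function(v, m) climate_grid(m, geom, v), CLIMATE_VARIABLES,
            surfaces[CLIMATE_VARIABLES]),
        label = "baseline"
      ),
      landmask = climate_grid(mask_vals, geom, "LAND", units = "mask")
    )
  })
}

#' A Gaussian climate niche with known ground truth
#'
#' Defines the true suitability surface used by the synthetic species and
#' host generators: a bell-shaped function of the six climate variables,
#' `exp(-0.5 * sum(((x - centre) / spread)^2))`, in (0, 1]. Because the true
#' surface is analytic, fitted models can be scored against it (rank
#' correlation, importance recovery).
#'
#' @param centre Named 6-vector of niche optima (variable units).
#' @param spread Named 6-vector of strictly positive niche widths; a large
#'   spread makes the corresponding variable unconstraining.
#' @param max_occurrence_rate Occurrence probability at the niche centre,
#'   in (0, 1].
#' @return A `true_niche` object.
#' @export
true_niche <- function(centre, spread, max_occurrence_rate = 1) {
  centre <- centre[CLIMATE_VARIABLES]
  spread <- spread[CLIMATE_VARIABLES]
  stopifnot(
    !anyNA(centre), !anyNA(spread), all(spread > 0),
    max_occurrence_rate > 0, max_occurrence_rate <= 1
  )
  structure(
    list(centre = centre, spread = spread,
         max_occurrence_rate = max_occurrence_rate),
    class = "true_niche"
  )
}

#' True suitability of climates under a known niche
#'
#' @param niche A [true_niche()].
#' @param climate Data frame or matrix with the six climate variable
#'   columns.
#' @return Numeric vector in `[0, 1]` (`NA` where climate is missing).
#' @export
niche_suitability <- function(niche, climate) {
  stopifnot(inherits(niche, "true_niche"))
  climate <- as.matrix(as.data.frame(climate)[, CLIMATE_VARIABLES])
  z <- sweep(climate, 2, niche$centre, `-`)
  z <- sweep(z, 2, niche$spread, `/`)
  exp(-0.5 * rowSums(z^2))
}

# valid-cell table for a stack: row/col/lon/lat plus the six variables
stack_cell_table <- function(stack) {
  g <- stack$grids[[1]]
  geom <- g$geometry
  vals <- lapply(stack$grids, function(x) as.numeric(x$values))
  ok <- Reduce(`&`, lapply(vals, function(v) !is.na(v)))
  idx <- which(ok)
  row <- ((idx - 1) %% geom$n_rows) + 1
  col <- ((idx - 1) %/% geom$n_rows) + 1
  ctr <- cell_center(geom, row, col)
  out <- data.frame(row = row, col = col, lon = ctr$x, lat = ctr$y)
  for (v in CLIMATE_VARIABLES) out[[v]] <- vals[[v]][idx]
  out
}

#' Sample occurrence records of a synthetic species
#'
#' Draws presences by rejection over valid land cells: a candidate cell with
#' climate `x` is accepted with probability
#' `max_occurrence_rate * exp(-0.5 * sum(((x - centre)/spread)^2))`, and each
#' accepted draw becomes one record with coordinates uniform inside the cell,
#' a year uniform on 1960-2020, and `basisOfRecord = "HUMAN_OBSERVATION"`.
#'
#' @param stack A [climate_stack()] whose nodata cells define the ocean.
#' @param niche A [true_niche()].
#' @param n_records Number of records to return (exactly).
#' @param seed Integer seed.
#' @param species Species name placed in the output column.
#' @return Data frame in the Darwin-Core-inspired occurrence dialect:
#'   `species`, `decimalLongitude`, `decimalLatitude`, `year`,
#'   `basisOfRecord`, `hasGeospatialIssue`.
#' @export
sample_species <- function(stack, niche, n_records, seed,
                           species = "Synthetica exemplaris") {
  stopifnot(inherits(stack, "climate_stack"), inherits(niche, "true_niche"),
            is_count(n_records), n_records >= 1)
  cells <- stack_cell_table(stack)
  p <- niche$max_occurrence_rate *
    niche_suitability(niche, cells[CLIMATE_VARIABLES])
  if (max(p) < 1e-6) {
    stop_pn("niche has negligible support on this landscape (max acceptance %.2e)",
            max(p))
  }
  geom <- stack$grids[[1]]$geometry
  with_seed(seed, {
    picked <- integer(0)
    while (length(picked) < n_records) {
      m <- max(2L * n_records, 1000L)
      cand <- sample.int(nrow(cells), m, replace = TRUE)
      keep <- stats::runif(m) < p[cand]
      picked <- c(picked, cand[keep])
    }
    picked <- picked[seq_len(n_records)]
    jx <- stats::runif(n_records, -0.5, 0.5) * geom$cell_size_x
    jy <- stats::runif(n_records, -0.5, 0.5) * abs(geom$cell_size_y)
    data.frame(
      species = species,
      decimalLongitude = cells$lon[picked] + jx,
      decimalLatitude = cells$lat[picked] + jy,
      year = sample(1960:2020, n_records, replace = TRUE),
      basisOfRecord = "HUMAN_OBSERVATION",
      hasGeospatialIssue = FALSE,
      stringsAsFactors = FALSE
    )
  })
}

#' Append records that violate each occurrence quality filter
#'
#' Adds, in order, records violating exactly one screening clause each:
#' missing coordinates; a flagged geospatial issue; a year of 1950 or
#' earlier; a fossil `basisOfRecord`. Violators (and the clean originals)
#' are marked in a hidden `.injected` provenance column so tests can verify
#' filter counts without trusting the filter itself;
#' [read_occurrences()] strips the column on ingest.
#'
#' @param rows Occurrence data frame (the [sample_species()] dialect).
#' @param n_missing_coords,n_geo_issue,n_pre1951,n_fossil Number of
#'   violators of each clause to append.
#' @param seed Integer seed.
#' @return The input with violators appended; unchanged if all counts are 0.
#' @export
inject_dirty_records <- function(rows, n_missing_coords = 0, n_geo_issue = 0,
                                 n_pre1951 = 0, n_fossil = 0, seed = 1) {
  counts <- c(n_missing_coords, n_geo_issue, n_pre1951, n_fossil)
  stopifnot(all(counts >= 0), all(vapply(counts, is_count, TRUE)))
  if (sum(counts) == 0) return(rows)
  with_seed(seed, {
    template <- function(n) {
      i <- sample.int(nrow(rows), n, replace = TRUE)
      rows[i, , drop = FALSE]
    }
    dirty <- list()
    if (n_missing_coords > 0) {
      d <- template(n_missing_coords)
      d$decimalLongitude <- NA_real_
      d$decimalLatitude <- NA_real_
      d$.injected <- "missing_coords"
      dirty <- c(dirty, list(d))
    }
    if (n_geo_issue > 0) {
      d <- template(n_geo_issue)
      d$hasGeospatialIssue <- TRUE
      d$.injected <- "geo_issue"
      dirty <- c(dirty, list(d))
    }
    if (n_pre1951 > 0) {
      d <- template(n_pre1951)
      d$year <- sample(1900:1950, n_pre1951, replace = TRUE)
      d$.injected <- "pre1951"
      dirty <- c(dirty, list(d))
    }
    if (n_fossil > 0) {
      d <- template(n_fossil)
      d$basisOfRecord <- "FOSSIL_SPECIMEN"
      d$.injected <- "fossil"
      dirty <- c(dirty, list(d))
    }
    clean <- rows
    clean$.injected <- "clean"
    out <- rbind(clean, do.call(rbind, dirty))
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic GCM anomaly field
#'
#' Builds a [delta_field()] whose temperature anomalies vary smoothly around
#' `warming` and whose precipitation ratios vary smoothly around
#' `precip_ratio`. The spatial variation is multiplicative
#' (`warming * (1 + 0.1 * field)`, `precip_ratio ^ (1 + 0.1 * field)`), so a
#' zero-warming / unit-ratio delta is exactly the identity. The random
#' stream is salted with `gcm_id`, so different GCMs under the same seed
#' give different (but reproducible) fields.
#'
#' @param stack Baseline [climate_stack()] providing the grid frame.
#' @param gcm_id Text GCM identifier.
#' @param warming Nominal warming, degrees C (applied to the three
#'   temperature variables).
#' @param precip_ratio Nominal precipitation ratio (> 0; applied to the
#'   three precipitation variables).
#' @param seed Integer seed.
#' @param ssp,period Scenario labels (see [delta_field()]).
#' @param smooth_width Kernel width for the anomaly fields.
#' @return A [delta_field()].
#' @export
make_gcm_delta <- function(stack, gcm_id, warming, precip_ratio, seed,
                           ssp = "SSP2-4.5", period = "2041-2070",
                           smooth_width = 11) {
  stopifnot(inherits(stack, "climate_stack"), precip_ratio > 0)
  geom <- stack$grids[[1]]$geometry
  nr <- geom$n_rows
  nc <- geom$n_cols
  child <- derive_seed(seed, paste(gcm_id, ssp, period))
  with_seed(child, {
    grids <- lapply(CLIMATE_VARIABLES, function(v) {
      f <- smooth_field(nr, nc, smooth_width)
      m <- if (v %in% TEMP_VARIABLES) {
        warming * (1 + 0.1 * f)
      } else {
        precip_ratio^(1 + 0.1 * f)
      }
      climate_grid(m, geom, v,
                   units = if (v %in% TEMP_VARIABLES) "degC" else "ratio")
    })
    delta_field(gcm_id, ssp, period, grids)
  })
}

#' Generate a host wood-volume surface
#'
#' Distributes `total_volume` cubic metres of host wood over the landscape
#' proportionally to the host niche's true suitability (times smooth
#' lognormal abundance noise), emulating a forest-inventory volume grid.
#' Ocean cells are nodata; the grid sums exactly to `total_volume`.
#'
#' @param stack Baseline [climate_stack()].
#' @param host_niche A [true_niche()] for the host tree species.
#' @param total_volume Total wood volume, m3.
#' @param seed Integer seed.
#' @param host_species Name stored in the grid's variable field.
#' @return A [climate_grid()] of m3 per cell.
#' @export
make_host_volume <- function(stack, host_niche, total_volume, seed,
                             host_species = "Hostia arborea") {
  stopifnot(inherits(stack, "climate_stack"), total_volume > 0)
  geom <- stack$grids[[1]]$geometry
  cells <- stack_cell_table(stack)
  suit <- niche_suitability(host_niche, cells[CLIMATE_VARIABLES])
  with_seed(derive_seed(seed, host_species), {
    f <- smooth_field(geom$n_rows, geom$n_cols, 9)
    noise <- exp(0.2 * f[cbind(cells$row, cells$col)])
    w <- suit * noise
    if (sum(w) <= 0) stop_pn("host niche has no support on this landscape")
    vol <- total_volume * w / sum(w)
    m <- matrix(NA_real_, geom$n_rows, geom$n_cols)
    m[cbind(cells$row, cells$col)] <- vol
    climate_grid(m, geom, host_species, units = "m3")
  })
}
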