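# Host-volume-at-risk accounting and stacked-envelope richness maps: given
# a binary suitability mask for a pest and the wood-volume grids of its
# host trees, how much host volume (m3) and area (km2) sit inside the
# climatically suitable region — and, stacking masks across species, how
# many species find a cell suitable, now and under future climate.

# binary mask helper: valid cells are 0/1, nodata allowed
as_mask_values <- function(grid, what) {
  v <- grid$values
  ok <- is.na(v) | v %in% c(0, 1)
  if (!all(ok)) stop_pn("%s must be binary (0/1/nodata)", what)
  v
}

#' Host volume and area at risk under a suitability mask
#'
#' Sums host wood volume over the cells that are climatically suitable
#' (mask value 1) and, optionally, inside a region mask. Also reports the
#' suitable-with-host area (cells with nonzero host volume) in cells and
#' km2, using cosine-latitude cell areas for geographic grids.
#'
#' @param suitable_mask Binary [climate_grid()] (1 = suitable).
#' @param hosts List of host volume [climate_grid()]s (m3 per cell), or a
#'   single grid.
#' @param region_mask Optional binary [climate_grid()] restricting the
#'   accounting region.
#' @param pest_species,scenario,rule Labels recorded in the summary.
#' @return A `risk_summary`: `volume_at_risk` (m3), `area_cells`,
#'   `area_km2`, `total_host_volume`, labels and host list.
#' @export
volume_at_risk <- function(suitable_mask, hosts, region_mask = NULL,
                           pest_species = "pest", scenario = "baseline",
                           rule = "envelope") {
  stopifnot(inherits(suitable_mask, "climate_grid"))
  if (inherits(hosts, "climate_grid")) hosts <- list(hosts)
  if (length(hosts) == 0) stop_pn("volume_at_risk needs at least one host grid")
  stopifnot(all(vapply(hosts, inherits, TRUE, "climate_grid")))
  for (h in hosts) {
    if (!grid_aligned(h, suitable_mask)) stop_pn("host grid is misaligned with the mask")
  }
  suit <- as_mask_values(suitable_mask, "suitable_mask")
  sel <- !is.na(suit) & suit == 1
  if (!is.null(region_mask)) {
    stopifnot(inherits(region_mask, "climate_grid"))
    if (!grid_aligned(region_mask, suitable_mask)) {
      stop_pn("region_mask is misaligned with the suitability mask")
    }
    reg <- as_mask_values(region_mask, "region_mask")
    sel <- sel & !is.na(reg) & reg == 1
  }
  host_sum <- Reduce(`+`, lapply(hosts, function(h) {
    v <- h$values
    v[is.na(v)] <- 0
    v
  }))
  volume <- sum(host_sum[sel])
  with_host <- sel & host_sum > 0
  areas <- cell_area_km2(suitable_mask$geometry)
  area_km2 <- sum(areas[row(host_sum)[with_host]])
  structure(
    list(
      pest_species = pest_species, scenario = scenario, rule = rule,
      volume_at_risk = volume,
      area_cells = sum(with_host),
      area_km2 = area_km2,
      total_host_volume = sum(host_sum),
      hosts = vapply(hosts, function(h) h$variable, character(1))
    ),
    class = "risk_summary"
  )
}

#' @export
print.risk_summary <- function(x, ...) {
  cat(sprintf(
    "<risk_summary> %s [%s, %s]: %.4g m3 at risk over %d cells (%.4g km2); hosts: %s\n",
    x$pest_species, x$scenario, x$rule, x$volume_at_risk,
    x$area_cells, x$area_km2, paste(x$hosts, collapse = ", ")
  ))
  invisible(x)
}

#' @export
as.data.frame.risk_summary <- function(x, ...) {
  data.frame(
    pest_species = x$pest_species, scenario = x$scenario, rule = x$rule,
    volume_at_risk = x$volume_at_risk, area_cells = x$area_cells,
    area_km2 = x$area_km2, total_host_volume = x$total_host_volume,
    hosts = paste(x$hosts, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Serialize a risk summary to JSON
#'
#' @param summary A `risk_summary`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_risk_summary <- function(summary, path) {
  stopifnot(inherits(summary, "risk_summary"))
  write_json_file(unclass(summary), path)
}

#' Load a pest-to-host lookup table
#'
#' The table is a CSV with columns `pest_species`, `host_species`. A pest
#' with no listed host, or a host with no volume grid, is an error rather
#' than a silent skip.
#'
#' @param path CSV path.
#' @return Data frame with the two columns.
#' @export
read_pest_hosts <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pest_species", "host_species") %in% names(tab))) {
    stop_pn("pest-host table needs columns pest_species, host_species")
  }
  tab
}

#' Select the host volume grids of one pest
#'
#' @param pest_hosts A [read_pest_hosts()] table.
#' @param pest Pest species name.
#' @param host_grids Named list of host volume [climate_grid()]s, keyed by
#'   host species.
#' @return List of host grids for the pest (errors on unknown hosts).
#' @export
hosts_for_pest <- function(pest_hosts, pest, host_grids) {
  hosts <- pest_hosts$host_species[pest_hosts$pest_species == pest]
  if (length(hosts) == 0) stop_pn("no hosts listed for pest '%s'", pest)
  unknown <- setdiff(hosts, names(host_grids))
  if (length(unknown)) {
    stop_pn("no volume grid for host(s): %s", paste(unknown, collapse = ", "))
  }
  host_grids[hosts]
}

#' Stack binary suitability masks into a richness map
#'
#' Cell-wise count of species whose suitable region covers the cell. A mask
#' cell that is nodata contributes 0; the output is nodata only where every
#' input is nodata.
#'
#' @param species_masks List of aligned binary [climate_grid()]s.
#' @param labels Species names (default: the grids' variable fields).
#' @param scenario Label recorded on the result.
#' @return A `richness_grid`: a [climate_grid()] of counts with `species`
#'   and `scenario` attributes.
#' @export
stack_richness <- function(species_masks, labels = NULL, scenario = "baseline") {
  stopifnot(length(species_masks) >= 1,
            all(vapply(species_masks, inherits, TRUE, "climate_grid")))
  for (m in species_masks[-1]) {
    if (!grid_aligned(m, species_masks[[1]])) stop_pn("species masks are misaligned")
  }
  labels <- labels %||% vapply(species_masks, function(g) g$variable, character(1))
  vals <- lapply(species_masks, as_mask_values, what = "species mask")
  all_na <- Reduce(`&`, lapply(vals, is.na))
  counts <- Reduce(`+`, lapply(vals, function(v) {
    v[is.na(v)] <- 0
    v
  }))
  counts[all_na] <- NA_real_
  g <- climate_grid(counts, species_masks[[1]]$geometry, "RICHNESS",
                    units = "species")
  structure(
    c(unclass(g), list(species = labels, scenario = scenario)),
    class = c("richness_grid", "climate_grid")
  )
}

#' Change in stacked richness between two scenarios
#'
#' @param current,future [stack_richness()] grids over the same species
#'   list and geometry.
#' @return A signed [climate_grid()] (`future - current` per cell).
#' @export
richness_change <- function(current, future) {
  stopifnot(inherits(current, "richness_grid"), inherits(future, "richness_grid"))
  if (!setequal(current$species, future$species)) {
    stop_pn("richness grids cover different species lists")
  }
  if (!geometry_aligned(current$geometry, future$geometry)) {
    stop_pn("richness grids are misaligned")
  }
  vals <- future$values - current$values
  climate_grid(vals, current$geometry, "RICHNESS_CHANGE", units = "species")
}

#' Area where richness changes by at least k species
#'
#' @param change A [richness_change()] grid.
#' @param k Threshold on the signed change (the headline gain uses
#'   `k = 5`).
#' @return List with `cells` and `km2`.
#' @export
area_with_change <- function(change, k = 5) {
  stopifnot(inherits(change, "climate_grid"))
  sel <- !is.na(change$values) & change$values >= k
  areas <- cell_area_km2(change$geometry)
  list(cells = sum(sel), km2 = sum(areas[row(change$values)[sel]]))
}
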