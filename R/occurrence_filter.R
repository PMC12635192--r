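# Occurrence-record screening: metadata quality filters, landmass
# restriction, equal-area 10-km thinning, and the minimum-record gate for
# modelling, with exact bookkeeping at every stage.

# canonical internal columns; the reader also accepts Darwin-Core headers
OCC_COLUMNS <- c("species", "lon", "lat", "year", "basis", "geo_issue")

#' Normalize an occurrence table to canonical columns
#'
#' Accepts either the canonical columns (`species`, `lon`, `lat`, `year`,
#' `basis`, `geo_issue`) or the Darwin-Core-style headers used in the
#' occurrence CSV dialect (`decimalLongitude`, `decimalLatitude`, `year`,
#' `basisOfRecord`, `hasGeospatialIssue`). Hidden provenance columns
#' (names starting with `.`) are preserved if present.
#'
#' @param records Data frame of occurrence records.
#' @return Data frame with the canonical columns (plus any `.`-columns).
#' @export
as_occurrence_records <- function(records) {
  records <- as.data.frame(records)
  map <- c(
    decimalLongitude = "lon", decimalLatitude = "lat",
    basisOfRecord = "basis", hasGeospatialIssue = "geo_issue"
  )
  for (dc in names(map)) {
    if (dc %in% names(records) && !(map[[dc]] %in% names(records))) {
      names(records)[names(records) == dc] <- map[[dc]]
    }
  }
  missing <- setdiff(OCC_COLUMNS, names(records))
  if (length(missing)) {
    stop_pn("occurrence table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  records$lon <- as.numeric(records$lon)
  records$lat <- as.numeric(records$lat)
  records$year <- suppressWarnings(as.integer(records$year))
  records$geo_issue <- as.logical(records$geo_issue)
  bad_lon <- !is.na(records$lon) & abs(records$lon) > 180
  bad_lat <- !is.na(records$lat) & abs(records$lat) > 90
  if (any(bad_lon) || any(bad_lat)) {
    stop_pn("coordinates out of range in %d record(s)", sum(bad_lon | bad_lat))
  }
  keep <- c(OCC_COLUMNS, grep("^\\.", names(records), value = TRUE))
  records[, keep, drop = FALSE]
}

#' Read and write occurrence CSV files
#'
#' The on-disk dialect uses Darwin-Core-inspired headers (`species`,
#' `decimalLongitude`, `decimalLatitude`, `year`, `basisOfRecord`,
#' `hasGeospatialIssue`). `read_occurrences()` strips any hidden
#' provenance columns (names starting with `.`) that a synthetic file may
#' carry for test bookkeeping.
#'
#' @param path CSV path.
#' @param records Occurrence data frame (canonical or Darwin-Core columns).
#' @return `read_occurrences`: canonical data frame; `write_occurrences`:
#'   `path`, invisibly.
#' @export
read_occurrences <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[, !grepl("^\\.", names(tab)), drop = FALSE]
  as_occurrence_records(tab)
}

#' @rdname read_occurrences
#' @export
write_occurrences <- function(records, path) {
  records <- as.data.frame(records)
  back <- c(
    lon = "decimalLongitude", lat = "decimalLatitude",
    basis = "basisOfRecord", geo_issue = "hasGeospatialIssue"
  )
  for (cn in names(back)) {
    if (cn %in% names(records)) names(records)[names(records) == cn] <- back[[cn]]
  }
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Metadata quality screen
#'
#' Keeps a record iff it (1) has geospatial coordinates, (2) carries no
#' geospatial-issue flag, (3) has a year strictly greater than 1950, and
#' (4) is not based on a fossil specimen (`basisOfRecord` equal to
#' `FOSSIL_SPECIMEN`, case-insensitively). A record failing several clauses
#' is counted once, against the first failing clause in that order; totals
#' are unaffected by the attribution rule.
#'
#' @param records Occurrence data frame.
#' @return List with `records` (survivors) and `removals`, a named integer
#'   vector of per-clause removal counts
#'   (`no_coordinates`, `geospatial_issue`, `year_not_after_1950`, `fossil`).
#' @export
screen_metadata <- function(records) {
  records <- as_occurrence_records(records)
  fail_coords <- is.na(records$lon) | is.na(records$lat)
  fail_issue <- !fail_coords & !is.na(records$geo_issue) & records$geo_issue
  fail_year <- !fail_coords & !fail_issue &
    (is.na(records$year) | records$year <= 1950)
  fail_fossil <- !fail_coords & !fail_issue & !fail_year &
    toupper(trimws(records$basis)) == "FOSSIL_SPECIMEN"
  removals <- c(
    no_coordinates = sum(fail_coords),
    geospatial_issue = sum(fail_issue),
    year_not_after_1950 = sum(fail_year),
    fossil = sum(fail_fossil)
  )
  keep <- !(fail_coords | fail_issue | fail_year | fail_fossil)
  list(records = records[keep, , drop = FALSE], removals = removals)
}

#' Restrict records to a landmass
#'
#' Keeps records whose containing cell is valid (non-nodata) in the land
#' mask; everything over ocean/nodata, or outside the mask extent, is
#' dropped.
#'
#' @param records Occurrence data frame with coordinates.
#' @param landmask A [climate_grid()] land mask (nodata = not land).
#' @return Data frame of surviving records.
#' @export
filter_landmass <- function(records, landmask) {
  stopifnot(inherits(landmask, "climate_grid"))
  records <- as_occurrence_records(records)
  if (anyNA(records$lon) || anyNA(records$lat)) {
    stop_pn("filter_landmass expects records with coordinates; screen first")
  }
  on_land <- !is.na(sample_at_points(landmask, records$lon, records$lat))
  records[on_land, , drop = FALSE]
}

# world cylindrical (Lambert) equal-area projection on the authalic sphere;
# returns coordinates in km so thinning cells are equal-area everywhere
EARTH_RADIUS_KM <- 6371.0072

cea_project <- function(lon, lat) {
  data.frame(
    x = EARTH_RADIUS_KM * lon * pi / 180,
    y = EARTH_RADIUS_KM * sin(lat * pi / 180)
  )
}

thinning_cell_index <- function(lon, lat, cell_km) {
  p <- cea_project(lon, lat)
  paste(floor(p$x / cell_km), floor(p$y / cell_km), sep = ":")
}

#' Spatial thinning on an equal-area grid
#'
#' Assigns records to cells of a fixed global equal-area grid (default
#' 10 km x 10 km, world cylindrical equal-area with origin at (0, 0)) and
#' keeps exactly one record per occupied cell, to damp artefacts from
#' intensive localized surveys. Retention is deterministic and invariant to
#' input order: within a cell the record with the lexicographically smallest
#' (year, lon, lat) wins, falling back to input position only between
#' byte-identical duplicates.
#'
#' @param records Occurrence data frame with coordinates.
#' @param cell_km Thinning cell edge in km (> 0; default 10).
#' @return Data frame of surviving records (one per occupied cell).
#' @export
thin_to_grid <- function(records, cell_km = 10) {
  if (!is.numeric(cell_km) || cell_km <= 0) stop_pn("cell_km must be > 0")
  records <- as_occurrence_records(records)
  if (anyNA(records$lon) || anyNA(records$lat)) {
    stop_pn("thin_to_grid expects records with coordinates; screen first")
  }
  if (nrow(records) == 0) return(records)
  cell <- thinning_cell_index(records$lon, records$lat, cell_km)
  ord <- order(cell, records$year, records$lon, records$lat, seq_len(nrow(records)))
  first <- ord[!duplicated(cell[ord])]
  records[sort(first), , drop = FALSE]
}

#' Minimum-record gate for modelling
#'
#' A species is modelled only if at least `threshold` records survive the
#' full screen (inclusive: exactly 30 survivors passes the default gate).
#'
#' @param records Surviving occurrence data frame.
#' @param threshold Minimum record count (default 30).
#' @return List with `modelled` (logical) and `n` (survivor count).
#' @export
apply_min_records <- function(records, threshold = 30) {
  n <- nrow(as.data.frame(records))
  list(modelled = n >= threshold, n = n)
}

#' Full occurrence screen with an audit trail
#'
#' Runs the fixed pipeline metadata screen -> landmass restriction ->
#' equal-area thinning -> minimum-record gate and returns both the
#' survivors and a `filter_report` reconciling every stage
#' (input - removals = output at each step).
#'
#' @param records Occurrence data frame (any accepted dialect).
#' @param landmask A [climate_grid()] land mask.
#' @param cell_km Thinning cell edge, km.
#' @param min_records Modelling gate threshold.
#' @return List with `records` (final survivors) and `report`
#'   (a `filter_report`).
#' @export
filter_occurrences <- function(records, landmask, cell_km = 10,
                               min_records = 30) {
  records <- as_occurrence_records(records)
  n_input <- nrow(records)
  meta <- screen_metadata(records)
  on_land <- filter_landmass(meta$records, landmask)
  thinned <- thin_to_grid(on_land, cell_km = cell_km)
  gate <- apply_min_records(thinned, threshold = min_records)
  report <- structure(
    list(
      input = n_input,
      metadata_removals = as.list(meta$removals),
      after_metadata = nrow(meta$records),
      after_landmass = nrow(on_land),
      after_thinning = nrow(thinned),
      min_records = min_records,
      modelled = gate$modelled
    ),
    class = "filter_report"
  )
  list(records = thinned, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<filter_report> input %d -> metadata %d (removed: %s) -> ",
      "landmass %d -> thinned %d; modelled: %s (gate %d)\n"
    ),
    x$input, x$after_metadata,
    paste(sprintf("%s=%d", names(x$metadata_removals),
                  unlist(x$metadata_removals)), collapse = ", "),
    x$after_landmass, x$after_thinning, x$modelled, x$min_records
  ))
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report A `filter_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  write_json_file(unclass(report), path)
}
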