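# Single-band GeoTIFF input/output.
#
# The package reads and writes plain uncompressed single-band float32
# GeoTIFFs: baseline TIFF 6.0 plus the GeoTIFF georeferencing tags
# (ModelPixelScale 33550, ModelTiepoint 33922, GeoKeyDirectory 34735,
# GeoAsciiParams 34737) and the GDAL nodata convention (tag 42113).
# Values are stored in float32; a write/read round trip is therefore exact
# to float32 precision (relative error <= 2^-24, i.e. well within 1e-6).
# Grid metadata (CRS id, variable, units) travels in GeoAsciiParams as
# "crs|variable|units|". Compressed, tiled, or multi-band TIFFs are out of
# scope and rejected with distinct errors.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                    `11` = 4L, `12` = 8L)

# float32 representation of a double, as R doubles (used to match nodata
# sentinels after a round trip through 4-byte storage)
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "numeric", n = length(x), size = 4L, endian = "little")
}

#' Write a grid as a single-band GeoTIFF
#'
#' Writes an uncompressed float32 GeoTIFF with georeferencing
#' (ModelPixelScale + ModelTiepoint), a CRS/variable/units citation string,
#' and a GDAL-style nodata tag. `NA` cells are stored as the grid's nodata
#' sentinel. The payload round-trips through [read_raster()] exactly at
#' float32 precision.
#'
#' @param grid A [climate_grid()].
#' @param path Output file path (conventionally ending in
#'   `_<VARIABLE>.tif` so the variable can also be recovered from the name).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "climate_grid"))
  geom <- grid$geometry
  vals <- as.numeric(t(grid$values)) # TIFF stores row-major, top row first
  vals[is.na(vals)] <- grid$nodata

  n_px <- length(vals)
  data_bytes <- 4L * n_px
  px_scale <- c(geom$cell_size_x, abs(geom$cell_size_y), 0)
  tiepoint <- c(0, 0, 0, geom$origin_x, geom$origin_y, 0)
  citation <- paste0(geom$crs_id, "|", grid$variable, "|", grid$units, "|")
  geo_ascii <- c(charToRaw(citation), as.raw(0L))
  # GeoKeyDirectory: version 1.1.0, one key: GTCitationGeoKey -> GeoAsciiParams
  geo_keys <- as.integer(c(1, 1, 0, 1, 1026, 34737, nchar(citation), 0))
  nodata_ascii <- c(charToRaw(sprintf("%.9g", grid$nodata)), as.raw(0L))

  pad_even <- function(r) if (length(r) %% 2L) c(r, as.raw(0L)) else r
  geo_ascii <- pad_even(geo_ascii)
  nodata_ascii <- pad_even(nodata_ascii)

  # layout: header(8) | pixels | scale(24) | tiepoint(48) | keys(16) |
  #         geo_ascii | nodata_ascii | IFD
  off_pixels <- 8L
  off_scale <- off_pixels + data_bytes
  off_tie <- off_scale + 24L
  off_keys <- off_tie + 48L
  off_geoascii <- off_keys + 16L
  off_nodata <- off_geoascii + length(geo_ascii)
  off_ifd <- off_nodata + length(nodata_ascii)

  entry <- function(tag, type, count, value, offset = NULL) {
    list(tag = tag, type = type, count = count, value = value, offset = offset)
  }
  entries <- list(
    entry(256L, 4L, 1L, geom$n_cols),
    entry(257L, 4L, 1L, geom$n_rows),
    entry(258L, 3L, 1L, 32L),
    entry(259L, 3L, 1L, 1L),            # no compression
    entry(262L, 3L, 1L, 1L),            # BlackIsZero
    entry(273L, 4L, 1L, off_pixels),    # single strip
    entry(277L, 3L, 1L, 1L),            # single band
    entry(278L, 4L, 1L, geom$n_rows),
    entry(279L, 4L, 1L, data_bytes),
    entry(339L, 3L, 1L, 3L),            # IEEE float
    entry(33550L, 12L, 3L, off_scale),
    entry(33922L, 12L, 6L, off_tie),
    entry(34735L, 3L, 8L, off_keys),
    entry(34737L, 2L, length(geo_ascii), off_geoascii),
    entry(42113L, 2L, length(nodata_ascii), off_nodata)
  )

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_pn("cannot open '%s' for writing", path),
                  warning = function(w) stop_pn("cannot open '%s' for writing", path))
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  writeBin(charToRaw("II"), con)
  wb(42L, 2L)
  wb(off_ifd, 4L)
  wb(vals, 4L)
  writeBin(px_scale, con, size = 8L, endian = "little")
  writeBin(tiepoint, con, size = 8L, endian = "little")
  wb(geo_keys, 2L)
  writeBin(geo_ascii, con)
  writeBin(nodata_ascii, con)
  wb(length(entries), 2L)
  for (e in entries) {
    wb(as.integer(e$tag), 2L)
    wb(as.integer(e$type), 2L)
    wb(as.integer(e$count), 4L)
    size <- TIFF_TYPE_SIZE[[as.character(e$type)]] * e$count
    if (size <= 4L && e$type %in% c(3L, 4L)) {
      if (e$type == 3L) { wb(as.integer(e$value), 2L); wb(0L, 2L) }
      else wb(as.integer(e$value), 4L)
    } else {
      wb(as.integer(e$value), 4L) # value IS the offset for out-of-line data
    }
  }
  wb(0L, 4L) # no next IFD
  invisible(path)
}

# parse one IFD entry's values from a connection positioned anywhere
read_tag_values <- function(con, type, count, value_raw, endian) {
  size <- TIFF_TYPE_SIZE[[as.character(type)]]
  if (is.null(size)) return(NULL)
  total <- size * count
  get_raw <- function() {
    if (total <= 4L) {
      value_raw[seq_len(total)]
    } else {
      offset <- readBin(value_raw, "integer", size = 4L, endian = endian)
      seek(con, offset)
      readBin(con, "raw", n = total)
    }
  }
  r <- get_raw()
  switch(as.character(type),
    `2` = rawToChar(r[r != as.raw(0L)]),
    `3` = readBin(r, "integer", n = count, size = 2L, signed = FALSE, endian = endian),
    `4` = readBin(r, "integer", n = count, size = 4L, endian = endian),
    `11` = readBin(r, "numeric", n = count, size = 4L, endian = endian),
    `12` = readBin(r, "numeric", n = count, size = 8L, endian = endian),
    r
  )
}

#' Read a single-band GeoTIFF
#'
#' Loads an uncompressed single-band GeoTIFF (as produced by
#' [write_raster()], or by other writers observing the same baseline layout)
#' into a [climate_grid()]. Georeferencing (pixel scale + tiepoint) and a
#' CRS tag are required; the nodata value is taken from the GDAL nodata tag.
#' The variable is taken from, in order of precedence: the `variable`
#' argument, the embedded citation string, or a filename suffix
#' `_<VARIABLE>.tif`.
#'
#' @param path Path to the GeoTIFF.
#' @param variable Optional explicit variable name.
#' @return A [climate_grid()].
#' @export
read_raster <- function(path, variable = NULL) {
  if (!file.exists(path)) stop_pn("raster file not found: '%s'", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = 2L))
  endian <- switch(magic, II = "little", MM = "big",
                   stop_pn("'%s' is not a TIFF file", path))
  if (readBin(con, "integer", size = 2L, signed = FALSE, endian = endian) != 42L) {
    stop_pn("'%s' is not a TIFF file", path)
  }
  ifd_offset <- readBin(con, "integer", size = 4L, endian = endian)
  seek(con, ifd_offset)
  n_entries <- readBin(con, "integer", size = 2L, signed = FALSE, endian = endian)
  raw_entries <- lapply(seq_len(n_entries), function(i) {
    list(
      tag = readBin(con, "integer", size = 2L, signed = FALSE, endian = endian),
      type = readBin(con, "integer", size = 2L, signed = FALSE, endian = endian),
      count = readBin(con, "integer", size = 4L, endian = endian),
      value_raw = readBin(con, "raw", n = 4L)
    )
  })
  tags <- list()
  for (e in raw_entries) {
    tags[[as.character(e$tag)]] <-
      read_tag_values(con, e$type, e$count, e$value_raw, endian)
  }
  need <- function(tag) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) stop_pn("'%s': required TIFF tag %d missing", path, tag)
    v
  }
  n_cols <- need(256)[1]
  n_rows <- need(257)[1]
  spp <- (tags[["277"]] %||% 1L)[1]
  bits <- tags[["258"]] %||% 32L
  if (spp > 1L || length(bits) > 1L) {
    stop_pn("'%s' is a multi-band TIFF; only single-band rasters are supported", path)
  }
  if ((tags[["259"]] %||% 1L)[1] != 1L) {
    stop_pn("'%s' uses TIFF compression, which is not supported", path)
  }
  scale <- tags[["33550"]]
  tie <- tags[["33922"]]
  if (is.null(scale) || is.null(tie)) {
    stop_pn("'%s' has no georeferencing (ModelPixelScale/ModelTiepoint missing)", path)
  }
  fmt <- (tags[["339"]] %||% 1L)[1]
  if (!(fmt == 3L && bits[1] %in% c(32L, 64L))) {
    stop_pn("'%s': only IEEE float (32/64 bit) samples are supported", path)
  }
  citation <- tags[["34737"]]
  if (is.null(citation) && is.null(tags[["34735"]])) {
    stop_pn("'%s' has no CRS tag", path)
  }
  meta <- if (is.null(citation)) character(0) else strsplit(citation, "|", fixed = TRUE)[[1]]
  crs_id <- if (length(meta) >= 1) meta[1] else stop_pn("'%s' has no CRS tag", path)
  nodata_tag <- tags[["42113"]]
  if (is.null(nodata_tag)) stop_pn("'%s' has no nodata tag", path)
  nodata <- suppressWarnings(as.numeric(nodata_tag))
  if (is.na(nodata)) stop_pn("'%s': unparseable nodata tag '%s'", path, nodata_tag)

  # origin = map coordinate of raster point (0,0) via the tiepoint
  origin_x <- tie[4] - tie[1] * scale[1]
  origin_y <- tie[5] + tie[2] * scale[2]
  geom <- grid_geometry(n_rows, n_cols, origin_x, origin_y,
                        scale[1], -scale[2], crs_id = crs_id)

  offsets <- need(273)
  counts <- need(279)
  sample_size <- bits[1] / 8L
  vals <- numeric(0)
  for (i in seq_along(offsets)) {
    seek(con, offsets[i])
    vals <- c(vals, readBin(con, "numeric", n = counts[i] / sample_size,
                            size = sample_size, endian = endian))
  }
  if (length(vals) != n_rows * n_cols) {
    stop_pn("'%s': strip data has %d samples, expected %d",
            path, length(vals), n_rows * n_cols)
  }
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  nodata_f32 <- as_float32(nodata)
  m[is.nan(m) | m == nodata | m == nodata_f32] <- NA_real_

  var <- variable %||%
    (if (length(meta) >= 2 && nzchar(meta[2])) meta[2] else NULL) %||%
    variable_from_filename(path) %||%
    stop_pn("cannot determine the variable of '%s'; pass `variable=`", path)
  units <- if (length(meta) >= 3) meta[3] else NULL
  climate_grid(m, geom, var, units = units, nodata = nodata)
}

variable_from_filename <- function(path) {
  m <- regmatches(
    basename(path),
    regexpr("_(MINTCM|MAXTHM|PRECCP|PRECHP|PREC|MAT)\\.(tif|tiff)$",
            basename(path))
  )
  if (length(m) == 0) return(NULL)
  sub("^_", "", sub("\\.(tif|tiff)$", "", m))
}

#' Read or write a climate stack via a manifest
#'
#' A stack on disk is a set of six GeoTIFFs plus a manifest CSV with columns
#' `path` (relative to the manifest), `variable`, `label`.
#'
#' @param stack A [climate_stack()] (for writing).
#' @param dir Directory to write the six GeoTIFFs into.
#' @param manifest Path of the manifest CSV.
#' @return `write_stack`: the manifest path, invisibly. `read_stack`: a
#'   [climate_stack()].
#' @export
write_stack <- function(stack, dir, manifest = file.path(dir, "stack_manifest.csv")) {
  stopifnot(inherits(stack, "climate_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  safe <- gsub("[^A-Za-z0-9._-]+", "_", stack$label)
  rows <- lapply(CLIMATE_VARIABLES, function(v) {
    fn <- sprintf("%s_%s.tif", safe, v)
    write_raster(stack$grids[[v]], file.path(dir, fn))
    data.frame(path = fn, variable = v, label = stack$label)
  })
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_stack
#' @export
read_stack <- function(manifest) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("path", "variable", "label") %in% names(tab)))
  base <- dirname(manifest)
  grids <- Map(function(p, v) read_raster(file.path(base, p), variable = v),
               tab$path, tab$variable)
  climate_stack(unname(grids), label = tab$label[1])
}
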