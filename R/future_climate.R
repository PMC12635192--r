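# Delta-method downscaling: coarse GCM change fields applied to a
# high-resolution baseline. Temperature anomalies are additive (degC);
# precipitation anomalies are multiplicative ratios — the standard delta
# convention, which keeps precipitation nonnegative by construction.

#' @rdname delta_field
#' @export
SSP_LEVELS <- c("SSP1-2.6", "SSP2-4.5", "SSP5-8.5")

#' @rdname delta_field
#' @export
PERIOD_LEVELS <- c("2011-2040", "2041-2070", "2071-2100")

#' A per-GCM anomaly field for one scenario and period
#'
#' Holds six anomaly grids aligned to the baseline: additive anomalies
#' (degC) for `MAT`/`MINTCM`/`MAXTHM`, multiplicative ratios (unitless,
#' strictly positive) for `PREC`/`PRECCP`/`PRECHP`. Ratios are capped to
#' `[0.1, 10]` at construction (with a message) to guard against division
#' artefacts from near-dry cells in GCM output.
#'
#' @param gcm_id Text identifier of the GCM (or `"composite"`).
#' @param ssp One of `SSP_LEVELS`.
#' @param period One of `PERIOD_LEVELS`.
#' @param grids List of six anomaly [climate_grid()]s, one per climate
#'   variable, pairwise aligned.
#' @return A `delta_field` object.
#' @export
delta_field <- function(gcm_id, ssp, period, grids) {
  ssp <- match.arg(ssp, SSP_LEVELS)
  period <- match.arg(period, PERIOD_LEVELS)
  vars <- vapply(grids, function(g) g$variable, character(1))
  if (!setequal(vars, CLIMATE_VARIABLES) || anyDuplicated(vars)) {
    stop_pn("a delta_field needs one anomaly grid per climate variable")
  }
  grids <- grids[match(CLIMATE_VARIABLES, vars)]
  names(grids) <- CLIMATE_VARIABLES
  for (v in CLIMATE_VARIABLES[-1]) {
    if (!grid_aligned(grids[[v]], grids[[1]])) {
      stop_pn("anomaly grid %s is misaligned", v)
    }
  }
  for (v in PREC_VARIABLES) {
    vals <- grids[[v]]$values
    if (any(vals <= 0, na.rm = TRUE)) {
      stop_pn("precipitation ratio anomalies must be strictly positive (%s)", v)
    }
    n_cap <- sum(vals < 0.1 | vals > 10, na.rm = TRUE)
    if (n_cap > 0) {
      message(sprintf("delta_field: capping %d %s ratio cells to [0.1, 10]",
                      n_cap, v))
      vals <- pmin(pmax(vals, 0.1), 10)
      grids[[v]] <- climate_grid(vals, grids[[v]]$geometry, v,
                                 units = grids[[v]]$units,
                                 nodata = grids[[v]]$nodata)
    }
  }
  structure(
    list(gcm_id = as.character(gcm_id), ssp = ssp, period = period,
         grids = grids),
    class = "delta_field"
  )
}

#' @export
print.delta_field <- function(x, ...) {
  cat(sprintf("<delta_field> %s %s %s\n", x$gcm_id, x$ssp, x$period))
  invisible(x)
}

delta_label <- function(delta) {
  sprintf("%s_%s_%s", delta$ssp, delta$period, delta$gcm_id)
}

#' Downscale a baseline climate with a GCM anomaly field
#'
#' Applies the delta method cell-wise: `future = baseline + anomaly` for the
#' temperature variables and `future = baseline * ratio` for the
#' precipitation variables. Nodata propagates from either operand; a
#' zero/unit delta reproduces the baseline exactly.
#'
#' @param baseline A [climate_stack()].
#' @param delta A [delta_field()] aligned with the baseline.
#' @return A [climate_stack()] labelled `"<ssp>_<period>_<gcm>"`.
#' @export
downscale <- function(baseline, delta) {
  stopifnot(inherits(baseline, "climate_stack"), inherits(delta, "delta_field"))
  grids <- lapply(CLIMATE_VARIABLES, function(v) {
    b <- baseline$grids[[v]]
    d <- delta$grids[[v]]
    if (!grid_aligned(b, d)) stop_pn("delta grid %s is not aligned with the baseline", v)
    op <- if (v %in% TEMP_VARIABLES) `+` else `*`
    map_algebra(list(b, d), op, variable = v, units = b$units)
  })
  climate_stack(grids, label = delta_label(delta))
}

#' Composite several GCM anomaly fields
#'
#' Combines anomalies across GCMs for one scenario and period: cell-wise
#' mean (or median) of the additive temperature anomalies, and of the
#' precipitation ratios in log space (so the mean back-transforms to the
#' geometric mean, keeping x2 and x0.5 symmetric around 1).
#'
#' @param deltas List of [delta_field()]s sharing `ssp` and `period`.
#' @param method `"mean"` or `"median"`.
#' @return A [delta_field()] with `gcm_id = "composite"`.
#' @export
composite_delta <- function(deltas, method = c("mean", "median")) {
  method <- match.arg(method)
  if (length(deltas) == 0) stop_pn("composite_delta needs at least one delta")
  stopifnot(all(vapply(deltas, inherits, TRUE, "delta_field")))
  ssp <- unique(vapply(deltas, `[[`, character(1), "ssp"))
  period <- unique(vapply(deltas, `[[`, character(1), "period"))
  if (length(ssp) != 1 || length(period) != 1) {
    stop_pn("composite_delta inputs must share ssp and period")
  }
  agg <- function(mats) {
    arr <- simplify2array(mats)
    apply(arr, c(1, 2), method)
  }
  grids <- lapply(CLIMATE_VARIABLES, function(v) {
    mats <- lapply(deltas, function(d) d$grids[[v]]$values)
    g1 <- deltas[[1]]$grids[[v]]
    m <- if (v %in% TEMP_VARIABLES) agg(mats) else exp(agg(lapply(mats, log)))
    climate_grid(m, g1$geometry, v, units = g1$units, nodata = g1$nodata)
  })
  delta_field("composite", ssp, period, grids)
}

#' Expand a baseline and a set of deltas into labelled future stacks
#'
#' Downscales every supplied delta, returning one future stack per delta
#' (each GCM, composite, scenario and period present in the input), keyed by
#' a unique label.
#'
#' @param baseline A [climate_stack()].
#' @param deltas List of [delta_field()]s.
#' @return Named list of [climate_stack()]s (empty if `deltas` is empty).
#' @export
scenario_matrix <- function(baseline, deltas) {
  stopifnot(inherits(baseline, "climate_stack"))
  labels <- vapply(deltas, delta_label, character(1))
  if (anyDuplicated(labels)) {
    stop_pn("duplicate scenario labels: %s",
            paste(labels[duplicated(labels)], collapse = ", "))
  }
  out <- lapply(deltas, downscale, baseline = baseline)
  names(out) <- labels
  out
}
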