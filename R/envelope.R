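# Rectilinear climate envelopes: per-variable order statistics of the
# climate at occurrence points, envelope classification (core / marginal /
# unsuitable), and a continuous percentile suitability score. The suitable
# region in climate space is by construction a Cartesian product of
# per-variable intervals.

ENVELOPE_STATS <- c("min", "p05", "mean", "median", "p95", "max")

#' Fit a rectilinear climate envelope
#'
#' Computes per-variable summaries (min, 5th percentile, mean, median, 95th
#' percentile, max; quantiles by linear interpolation, R type 7) of the
#' climate at occurrence points, together with the sorted training values
#' needed for percentile scoring.
#'
#' @param climate_at_points Data frame or matrix with the six climate
#'   variable columns and no missing values (extraction already drops
#'   points on nodata).
#' @param core_percentiles Lower/upper percentile pair bounding the "core"
#'   envelope (default `c(5, 95)`, the classic Bioclim convention).
#' @return A `bioclim_envelope` object.
#' @export
fit_envelope <- function(climate_at_points, core_percentiles = c(5, 95)) {
  x <- as.data.frame(climate_at_points)
  missing <- setdiff(CLIMATE_VARIABLES, names(x))
  if (length(missing)) {
    stop_pn("climate table lacks variable(s): %s", paste(missing, collapse = ", "))
  }
  x <- x[, CLIMATE_VARIABLES]
  if (nrow(x) < 1) stop_pn("fit_envelope needs at least one point")
  if (anyNA(x)) stop_pn("fit_envelope input contains missing values")
  lo <- core_percentiles[1] / 100
  hi <- core_percentiles[2] / 100
  stats_tab <- lapply(x, function(v) {
    q <- stats::quantile(v, c(lo, 0.5, hi), names = FALSE, type = 7)
    c(min = min(v), p05 = q[1], mean = mean(v), median = q[2],
      p95 = q[3], max = max(v))
  })
  structure(
    list(
      stats = stats_tab,
      training = lapply(x, sort),
      n_points = nrow(x),
      core_percentiles = core_percentiles,
      percentile_method = "hazen_linear_interpolation",
      quantile_method = "type7"
    ),
    class = "bioclim_envelope"
  )
}

#' @export
print.bioclim_envelope <- function(x, ...) {
  cat(sprintf("<bioclim_envelope> %d points; core percentiles %g/%g\n",
              x$n_points, x$core_percentiles[1], x$core_percentiles[2]))
  tab <- do.call(rbind, x$stats)
  print(round(tab, 3))
  invisible(x)
}

# empirical percentile of values v within sorted training sample s, using
# Hazen plotting positions 100*(i - 0.5)/n with linear interpolation; values
# beyond the training range clamp to 0 / 100. With Hazen positions every
# in-range value (including the training min/max themselves) maps strictly
# inside (0, 100), so the percentile score is positive everywhere inside
# the envelope and zero exactly outside it.
empirical_percentile <- function(v, s) {
  n <- length(s)
  pos <- 100 * (seq_len(n) - 0.5) / n
  if (n == 1) return(ifelse(v < s, 0, ifelse(v > s, 100, 50)))
  if (anyDuplicated(s)) {
    ds <- unique(s)
    pos <- as.numeric(tapply(pos, match(s, ds), mean))
    s <- ds
  }
  if (length(s) == 1) return(ifelse(v < s, 0, ifelse(v > s, 100, 50)))
  p <- stats::approx(s, pos, xout = v, rule = 2)$y
  p[v < s[1]] <- 0
  p[v > s[length(s)]] <- 100
  p
}

#' Classify climates against an envelope
#'
#' A cell is `unsuitable` if any variable falls outside the envelope's
#' [min, max] interval (score 0), `core` if every variable lies within the
#' core percentile interval, and `marginal` otherwise. The continuous score
#' is `min` over variables of `min(p, 100 - p) / 50`, where `p` is the
#' empirical percentile of the cell value within the training values of
#' that variable: 1 at the per-variable medians, decaying to 0 at the
#' envelope edges.
#'
#' @param env A [fit_envelope()] result.
#' @param cell_values A 6-vector, or a matrix/data frame with the six
#'   climate variable columns (no missing values).
#' @return List with `class` (factor: unsuitable/marginal/core) and `score`
#'   (numeric in `[0, 1]`), each of one element per input row.
#' @export
classify_cell <- function(env, cell_values) {
  stopifnot(inherits(env, "bioclim_envelope"))
  x <- cell_values
  if (is.null(dim(x))) {
    x <- matrix(as.numeric(x), nrow = 1,
                dimnames = list(NULL, names(cell_values) %||% CLIMATE_VARIABLES))
  }
  x <- as.data.frame(x)
  if (!all(CLIMATE_VARIABLES %in% names(x))) names(x) <- CLIMATE_VARIABLES
  x <- x[, CLIMATE_VARIABLES]
  if (anyNA(x)) stop_pn("classify_cell input contains missing values")
  inside <- matrix(TRUE, nrow(x), 6)
  in_core <- matrix(TRUE, nrow(x), 6)
  score_v <- matrix(NA_real_, nrow(x), 6)
  for (j in seq_along(CLIMATE_VARIABLES)) {
    v <- CLIMATE_VARIABLES[j]
    st <- env$stats[[v]]
    vals <- x[[v]]
    inside[, j] <- vals >= st[["min"]] & vals <= st[["max"]]
    in_core[, j] <- vals >= st[["p05"]] & vals <= st[["p95"]]
    p <- empirical_percentile(vals, env$training[[v]])
    score_v[, j] <- pmin(p, 100 - p) / 50
  }
  ok <- rowSums(inside) == 6
  core <- ok & rowSums(in_core) == 6
  score <- apply(score_v, 1, min)
  score[!ok] <- 0
  cls <- factor(
    ifelse(!ok, "unsuitable", ifelse(core, "core", "marginal")),
    levels = c("unsuitable", "marginal", "core")
  )
  list(class = cls, score = score)
}

#' Map an envelope over a climate stack
#'
#' Applies [classify_cell()] to every valid cell of an aligned stack,
#' propagating nodata.
#'
#' @param env A [fit_envelope()] result.
#' @param stack A [climate_stack()].
#' @return List of two aligned [climate_grid()]s: `class` (codes 0
#'   unsuitable, 1 marginal, 2 core) and `score` (in `[0, 1]`).
#' @export
map_envelope <- function(env, stack) {
  stopifnot(inherits(env, "bioclim_envelope"), inherits(stack, "climate_stack"))
  cells <- stack_cell_table(stack)
  geom <- stack$grids[[1]]$geometry
  cls_m <- matrix(NA_real_, geom$n_rows, geom$n_cols)
  sc_m <- matrix(NA_real_, geom$n_rows, geom$n_cols)
  if (nrow(cells) > 0) {
    res <- classify_cell(env, cells[CLIMATE_VARIABLES])
    idx <- cbind(cells$row, cells$col)
    cls_m[idx] <- as.integer(res$class) - 1L
    sc_m[idx] <- res$score
  }
  list(
    class = climate_grid(cls_m, geom, "ENVELOPE_CLASS", units = "class"),
    score = climate_grid(sc_m, geom, "ENVELOPE_SCORE", units = "score")
  )
}

#' Serialize an envelope to and from JSON
#'
#' @param env A `bioclim_envelope`.
#' @param path JSON path.
#' @return `write_envelope`: `path` invisibly; `read_envelope`: the
#'   envelope.
#' @export
write_envelope <- function(env, path) {
  stopifnot(inherits(env, "bioclim_envelope"))
  obj <- unclass(env)
  obj$stats <- lapply(obj$stats, as.list) # keep stat names through JSON
  write_json_file(obj, path)
}

#' @rdname write_envelope
#' @export
read_envelope <- function(path) {
  obj <- read_json_file(path)
  obj$stats <- lapply(obj$stats, function(s) unlist(s))
  obj$training <- lapply(obj$training, as.numeric)
  obj$core_percentiles <- as.numeric(obj$core_percentiles)
  structure(obj, class = "bioclim_envelope")
}
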