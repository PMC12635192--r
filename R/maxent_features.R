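# Feature construction for the presence-background maximum-entropy model:
# linear, quadratic, product, forward/reverse hinge and threshold transforms
# of the six climate variables, min-max standardized to [0, 1] over the
# background sample. (Categorical features are not needed: all six
# predictors are continuous.)

FEATURE_KINDS <- c("linear", "quadratic", "product",
                   "forward_hinge", "reverse_hinge", "threshold")

#' Draw a uniform background sample over the landmass
#'
#' Samples cells uniformly at random among valid land cells (without
#' replacement while the sample fits, with replacement once `m` exceeds the
#' number of land cells), placing each point at its cell centre and
#' attaching the six climate values. 10,000 points over the whole landmass
#' is the package default for global-extent fits.
#'
#' @param landmask A [climate_grid()] land mask (nodata = not land).
#' @param stack A [climate_stack()] aligned with the mask.
#' @param m Number of background points (default 10000).
#' @param seed Integer seed.
#' @return A `background_sample`: list with `points` (lon/lat data frame),
#'   `climate_values` (m x 6 data frame), `m`, `seed`.
#' @export
draw_background <- function(landmask, stack, m = 10000, seed = 1) {
  stopifnot(inherits(landmask, "climate_grid"), inherits(stack, "climate_stack"),
            is_count(m), m >= 1)
  if (!grid_aligned(landmask, stack$grids[[1]])) {
    stop_pn("landmask is not aligned with the climate stack")
  }
  cells <- stack_cell_table(stack)
  mask_ok <- !is.na(sample_at_points(landmask, cells$lon, cells$lat))
  cells <- cells[mask_ok, , drop = FALSE]
  if (nrow(cells) == 0) stop_pn("landmask has no valid land cell with climate")
  idx <- with_seed(seed, {
    if (m <= nrow(cells)) {
      sample.int(nrow(cells), m)
    } else {
      sample.int(nrow(cells), m, replace = TRUE)
    }
  })
  structure(
    list(
      points = data.frame(lon = cells$lon[idx], lat = cells$lat[idx]),
      climate_values = cells[idx, CLIMATE_VARIABLES],
      m = as.integer(m), seed = as.integer(seed)
    ),
    class = "background_sample"
  )
}

#' @export
print.background_sample <- function(x, ...) {
  cat(sprintf("<background_sample> %d points (seed %d)\n", x$m, x$seed))
  invisible(x)
}

background_values <- function(background) {
  if (inherits(background, "background_sample")) {
    background$climate_values
  } else {
    as.data.frame(background)
  }
}

climate_matrix <- function(x) {
  x <- as.data.frame(x)
  if (!all(CLIMATE_VARIABLES %in% names(x))) {
    stop_pn("climate table lacks variable(s): %s",
            paste(setdiff(CLIMATE_VARIABLES, names(x)), collapse = ", "))
  }
  as.matrix(x[, CLIMATE_VARIABLES])
}

#' Default feature classes for a given presence count
#'
#' Smaller samples support fewer feature shapes: linear only below 10
#' presences, plus quadratic below 15, plus hinge below 80, and all classes
#' (adding product and threshold) from 80 presences up.
#'
#' @param n_presence Number of presence records.
#' @return Character vector of feature kinds.
#' @export
auto_feature_classes <- function(n_presence) {
  if (n_presence < 10) return("linear")
  if (n_presence < 15) return(c("linear", "quadratic"))
  if (n_presence < 80) return(c("linear", "quadratic", "forward_hinge", "reverse_hinge"))
  FEATURE_KINDS
}

# raw (unstandardized) evaluation of one feature on a climate matrix
feature_raw <- function(def, X) {
  switch(def$kind,
    linear = X[, def$variables[1]],
    quadratic = X[, def$variables[1]]^2,
    product = X[, def$variables[1]] * X[, def$variables[2]],
    forward_hinge = pmax(0, X[, def$variables[1]] - def$knot),
    reverse_hinge = pmax(0, def$knot - X[, def$variables[1]]),
    threshold = as.numeric(X[, def$variables[1]] > def$knot),
    stop_pn("unknown feature kind '%s'", def$kind)
  )
}

#' Build the feature set for a maximum-entropy fit
#'
#' Constructs feature definitions over the six climate variables: 6 linear,
#' 6 quadratic, and 15 pairwise products when enabled, plus hinge
#' (forward and reverse) and step (threshold) features with knots at
#' equally spaced background quantiles. Every feature is min-max
#' standardized to `[0, 1]` over the background; the standardization
#' constants are stored with each definition, and features that are
#' constant on the background are dropped.
#'
#' @param presence_values Climate at presences (n x 6); used only to
#'   auto-select classes when `classes = NULL`.
#' @param background A [draw_background()] sample, or a data frame of
#'   background climate values.
#' @param classes Subset of
#'   `c("linear","quadratic","product","forward_hinge","reverse_hinge","threshold")`,
#'   or `NULL` to auto-select from the presence count.
#' @param knots_per_variable Number of hinge/threshold knots per variable
#'   (default 32).
#' @return List of `feature_definition` objects (with a `variables`
#'   attribute naming the predictors).
#' @export
build_features <- function(presence_values, background, classes = NULL,
                           knots_per_variable = 32) {
  Xp <- climate_matrix(presence_values)
  Xb <- climate_matrix(background_values(background))
  classes <- classes %||% auto_feature_classes(nrow(Xp))
  if (length(classes) == 0) stop_pn("no feature classes requested")
  bad <- setdiff(classes, FEATURE_KINDS)
  if (length(bad)) stop_pn("unknown feature class(es): %s", paste(bad, collapse = ", "))

  defs <- list()
  add <- function(kind, vars, knot = NA_real_) {
    defs[[length(defs) + 1]] <<- list(kind = kind, variables = vars, knot = knot)
  }
  if ("linear" %in% classes) for (v in CLIMATE_VARIABLES) add("linear", v)
  if ("quadratic" %in% classes) for (v in CLIMATE_VARIABLES) add("quadratic", v)
  if ("product" %in% classes) {
    pairs <- utils::combn(CLIMATE_VARIABLES, 2)
    for (k in seq_len(ncol(pairs))) add("product", pairs[, k])
  }
  knot_kinds <- intersect(classes, c("forward_hinge", "reverse_hinge", "threshold"))
  if (length(knot_kinds)) {
    probs <- seq_len(knots_per_variable) / (knots_per_variable + 1)
    for (v in CLIMATE_VARIABLES) {
      knots <- unique(stats::quantile(Xb[, v], probs, names = FALSE, type = 7))
      for (kind in knot_kinds) for (k in knots) add(kind, v, k)
    }
  }

  kept <- list()
  for (def in defs) {
    raw <- feature_raw(def, Xb)
    lo <- min(raw)
    hi <- max(raw)
    if (hi - lo < 1e-12) next # constant on background: uninformative
    def$offset <- lo
    def$range <- hi - lo
    class(def) <- "feature_definition"
    kept[[length(kept) + 1]] <- def
  }
  if (length(kept) == 0) stop_pn("all requested features are constant on the background")
  attr(kept, "variables") <- CLIMATE_VARIABLES
  kept
}

#' Evaluate a feature set on climate values
#'
#' @param features A [build_features()] result.
#' @param climate Climate table/matrix with the six variable columns.
#' @return Numeric matrix (rows x features), each column in `[0, 1]` on the
#'   background used to build the features.
#' @export
feature_matrix <- function(features, climate) {
  X <- climate_matrix(climate)
  out <- vapply(features, function(def) {
    (feature_raw(def, X) - def$offset) / def$range
  }, numeric(nrow(X)))
  matrix(out, nrow = nrow(X))
}

feature_labels <- function(features) {
  vapply(features, function(d) {
    if (!is.na(d$knot)) {
      sprintf("%s(%s@%.4g)", d$kind, d$variables[1], d$knot)
    } else {
      sprintf("%s(%s)", d$kind, paste(d$variables, collapse = "*"))
    }
  }, character(1))
}
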