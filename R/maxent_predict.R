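# Prediction outputs of the maximum-entropy model. "raw" is the Gibbs
# probability over the training background (sums to 1 across background
# cells); "cumulative" is the percent of background raw mass at cells
# scoring no higher; "logistic" is the standard entropy-calibrated
# transform e^H * raw / (1 + e^H * raw), which maps a typical background
# cell of a near-uniform model to about 0.5.

clamp_climate <- function(x, bounds) {
  X <- climate_matrix(x)
  for (v in CLIMATE_VARIABLES) {
    X[, v] <- pmin(pmax(X[, v], bounds$min[[v]]), bounds$max[[v]])
  }
  X
}

#' Predict suitability from a maximum-entropy model
#'
#' @param object A [fit_maxent()] model.
#' @param newdata Climate table/matrix with the six variable columns (no
#'   missing values).
#' @param type Output scale: `"logistic"` (default, in (0, 1)),
#'   `"raw"` (Gibbs probability), or `"cumulative"` (percent, in [0, 100]).
#' @param clamp Clamp predictors to the training range before evaluating
#'   features (default `TRUE`; recommended when projecting onto new
#'   climates).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.maxent_model <- function(object, newdata,
                                 type = c("logistic", "raw", "cumulative"),
                                 clamp = TRUE, ...) {
  type <- match.arg(type)
  X <- if (clamp) clamp_climate(newdata, object$clamp_bounds) else climate_matrix(newdata)
  f <- feature_matrix(object$features, X)
  raw <- exp(as.numeric(f %*% object$weights) - object$log_partition)
  switch(type,
    raw = raw,
    logistic = {
      eh <- exp(object$entropy_H) * raw
      eh / (1 + eh)
    },
    cumulative = {
      bg <- sort(object$background_raw)
      cum <- c(0, cumsum(bg))
      100 * cum[findInterval(raw, bg) + 1] / cum[length(cum)]
    }
  )
}

#' Training AUC of a suitability model
#'
#' Rank-based area under the ROC curve: the probability that a random
#' presence point scores above a random background point, with ties
#' counting one half. Computed on the training data (no held-out split).
#'
#' @param model A [fit_maxent()] model (or any object with a
#'   `predict(model, x, type = "raw")` method).
#' @param presence_values Climate at presences.
#' @param background Background sample or climate table.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(model, presence_values, background) {
  sp <- predict(model, presence_values, type = "raw")
  sb <- predict(model, background_values(background), type = "raw")
  auc_from_scores(sp, sb)
}

# Mann-Whitney form of the AUC with tie correction
auc_from_scores <- function(score_presence, score_background) {
  n <- length(score_presence)
  m <- length(score_background)
  r <- rank(c(score_presence, score_background))
  (sum(r[seq_len(n)]) - n * (n + 1) / 2) / (n * m)
}

#' Permutation importance of the climate variables
#'
#' For each variable, permutes its column jointly across the presence and
#' background rows, re-scores the model, and measures the mean drop in
#' training AUC over `n_permutations` shuffles. Negative drops are floored
#' at zero and the six drops are normalized to sum to 100 (uniform 100/6 if
#' every drop is zero).
#'
#' @param model A [fit_maxent()] model.
#' @param presence_values,background Training data.
#' @param n_permutations Shuffles per variable (default 5).
#' @param seed Integer seed.
#' @return Named numeric vector (percent, sums to 100).
#' @export
variable_importance <- function(model, presence_values, background,
                                n_permutations = 5, seed = 1) {
  Xp <- climate_matrix(presence_values)
  Xb <- climate_matrix(background_values(background))
  n <- nrow(Xp)
  base_auc <- evaluate_auc(model, Xp, Xb)
  all_x <- rbind(Xp, Xb)
  drops <- with_seed(seed, {
    vapply(CLIMATE_VARIABLES, function(v) {
      d <- vapply(seq_len(n_permutations), function(k) {
        perm <- all_x
        perm[, v] <- perm[sample.int(nrow(perm)), v]
        base_auc - auc_from_scores(
          predict(model, perm[seq_len(n), , drop = FALSE], type = "raw"),
          predict(model, perm[-seq_len(n), , drop = FALSE], type = "raw")
        )
      }, numeric(1))
      mean(d)
    }, numeric(1))
  })
  drops <- pmax(drops, 0)
  if (sum(drops) == 0) {
    out <- rep(100 / 6, 6)
    names(out) <- CLIMATE_VARIABLES
    return(out)
  }
  100 * drops / sum(drops)
}

#' Map a maximum-entropy model over a climate stack
#'
#' Predicts per valid cell (with clamping to the training range) and
#' propagates nodata.
#'
#' @param model A [fit_maxent()] model.
#' @param stack A [climate_stack()].
#' @param type Output scale (see [predict.maxent_model()]).
#' @return A [climate_grid()] of suitability values.
#' @export
map_maxent <- function(model, stack, type = "logistic") {
  stopifnot(inherits(model, "maxent_model"), inherits(stack, "climate_stack"))
  cells <- stack_cell_table(stack)
  geom <- stack$grids[[1]]$geometry
  m <- matrix(NA_real_, geom$n_rows, geom$n_cols)
  if (nrow(cells) > 0) {
    m[cbind(cells$row, cells$col)] <-
      predict(model, cells[CLIMATE_VARIABLES], type = type, clamp = TRUE)
  }
  climate_grid(m, geom, paste0("MAXENT_", toupper(type)), units = type)
}
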