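# L1-regularized maximum-entropy fit. The model is the Gibbs distribution
# over background cells p(x) = exp(lambda . f(x)) / Z that matches the
# presence feature means as closely as the L1 penalty allows; equivalently,
# the weights minimize the convex objective
#
#   F(lambda) = -mean_presence[lambda . f(x)] + log Z_background(lambda)
#               + sum_j beta_j |lambda_j|
#
# with per-feature penalties beta_j = reg_multiplier * max(sd_j, 1e-4)/sqrt(n)
# (sd_j: presence-sample standard deviation of the standardized feature).
# The solver is monotone FISTA: accelerated proximal gradient
# (soft-thresholding) with a backtracking line search and the monotone
# safeguard of keeping the best iterate, so the recorded objective is
# non-increasing by construction; convergence requires both a small
# objective improvement and the KKT stationarity conditions within 10 * tol.

maxent_smooth_objective <- function(lambda, fbar, Fb) {
  eta <- as.numeric(Fb %*% lambda)
  -sum(fbar * lambda) + log_sum_exp(eta)
}

maxent_gradient <- function(lambda, fbar, Fb) {
  eta <- as.numeric(Fb %*% lambda)
  p <- exp(eta - log_sum_exp(eta))
  -fbar + as.numeric(crossprod(Fb, p))
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# maximal KKT stationarity violation at lambda: for inactive weights the
# smooth gradient must lie within [-beta, beta]; for active weights the
# subgradient -grad must equal beta * sign(lambda)
kkt_violation <- function(lambda, grad, beta) {
  active <- lambda != 0
  viol <- pmax(abs(grad) - beta, 0)
  viol[active] <- abs(grad[active] + beta[active] * sign(lambda[active]))
  max(viol, 0)
}

#' Fit a presence-background maximum-entropy model
#'
#' Finds the feature weights of the Gibbs suitability distribution over the
#' background that minimize the L1-penalized maximum-entropy objective (see
#' Details in the package vignette). The fit is deterministic given its
#' inputs; the objective trace is stored and is non-increasing by
#' construction of the line search.
#'
#' @param presence_values Climate at presence records (n x 6, no missing).
#' @param background A [draw_background()] sample or data frame of
#'   background climate values (m x 6).
#' @param features A [build_features()] result (default: built from the
#'   inputs with auto-selected classes).
#' @param reg_multiplier Scalar multiplying every per-feature penalty
#'   (default 1).
#' @param tol Convergence tolerance on the objective improvement; the KKT
#'   conditions must additionally hold within `10 * tol`.
#' @param max_iter Iteration cap; hitting it raises a warning reporting the
#'   final KKT violation.
#' @return A `maxent_model`: features, `weights`, `log_partition` (log Z
#'   over the background), `entropy_H` (entropy of the fitted background
#'   distribution, nats), `clamp_bounds`, penalties, counts, objective
#'   trace, and the fitted background raw distribution.
#' @export
fit_maxent <- function(presence_values, background, features = NULL,
                       reg_multiplier = 1, tol = 1e-6, max_iter = 2000) {
  Xp <- climate_matrix(presence_values)
  Xb <- climate_matrix(background_values(background))
  if (nrow(Xp) < 1) stop_pn("fit_maxent needs at least one presence")
  if (nrow(unique(Xb)) < 2) {
    stop_pn("fit_maxent needs at least 2 distinct background climate profiles")
  }
  if (anyNA(Xp) || anyNA(Xb)) stop_pn("fit_maxent inputs must have no missing values")
  if (reg_multiplier < 0) stop_pn("reg_multiplier must be >= 0")
  features <- features %||% build_features(Xp, Xb)

  Fp <- feature_matrix(features, Xp)
  Fb <- feature_matrix(features, Xb)
  n <- nrow(Fp)
  fbar <- colMeans(Fp)
  sd_j <- apply(Fp, 2, stats::sd)
  sd_j[is.na(sd_j)] <- 0
  beta <- reg_multiplier * pmax(sd_j, 1e-4) / sqrt(n)

  J <- ncol(Fb)
  full_obj <- function(l) {
    maxent_smooth_objective(l, fbar, Fb) + sum(beta * abs(l))
  }
  lambda <- numeric(J) # best (monotone) iterate
  prev <- lambda
  y <- lambda          # extrapolation point
  objective <- full_obj(lambda)
  trace <- objective
  step <- 1
  t_acc <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g_y <- maxent_smooth_objective(y, fbar, Fb)
    grad_y <- maxent_gradient(y, fbar, Fb)
    repeat {
      z <- soft_threshold(y - step * grad_y, step * beta)
      d <- z - y
      g_z <- maxent_smooth_objective(z, fbar, Fb)
      if (is.finite(g_z) &&
          g_z <= g_y + sum(grad_y * d) + sum(d^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    obj_z <- g_z + sum(beta * abs(z))
    # monotone safeguard: the accepted iterate never increases the objective
    if (is.finite(obj_z) && obj_z <= objective) {
      new_lambda <- z
      new_obj <- obj_z
    } else {
      new_lambda <- lambda
      new_obj <- objective
    }
    t_next <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    y <- new_lambda + (t_acc / t_next) * (z - new_lambda) +
      ((t_acc - 1) / t_next) * (new_lambda - prev)
    t_acc <- t_next
    prev <- lambda
    improvement <- objective - new_obj
    lambda <- new_lambda
    objective <- new_obj
    trace <- c(trace, objective)
    if (improvement < tol) {
      grad <- maxent_gradient(lambda, fbar, Fb)
      if (kkt_violation(lambda, grad, beta) <= 10 * tol) {
        converged <- TRUE
        break
      }
      # objective has stalled without stationarity: restart the momentum
      if (improvement == 0) {
        y <- lambda
        t_acc <- 1
      }
    }
    step <- min(step * 1.1, 1e6)
  }
  grad <- maxent_gradient(lambda, fbar, Fb)
  kkt <- kkt_violation(lambda, grad, beta)
  if (!converged) {
    warning(sprintf(
      "fit_maxent did not converge in %d iterations (KKT violation %.3g, gradient norm %.3g)",
      max_iter, kkt, sqrt(sum(grad^2))
    ), call. = FALSE)
  }

  eta <- as.numeric(Fb %*% lambda)
  log_z <- log_sum_exp(eta)
  p_bg <- exp(eta - log_z)
  entropy <- -sum(ifelse(p_bg > 0, p_bg * log(p_bg), 0))
  all_x <- rbind(Xp, Xb)
  clamp_bounds <- list(
    min = apply(all_x, 2, min),
    max = apply(all_x, 2, max)
  )
  structure(
    list(
      features = features,
      weights = as.numeric(lambda),
      log_partition = log_z,
      entropy_H = entropy,
      clamp_bounds = clamp_bounds,
      reg_multiplier = reg_multiplier,
      beta = as.numeric(beta),
      n_presence = n,
      n_background = nrow(Xb),
      background_raw = p_bg,
      objective_trace = trace,
      converged = converged,
      kkt_violation = kkt,
      tol = tol
    ),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<maxent_model> %d features (%d active), %d presences / %d background,\n",
      "  reg_multiplier %g, objective %.6f, entropy %.3f nats, converged: %s\n"
    ),
    length(x$weights), sum(x$weights != 0), x$n_presence, x$n_background,
    x$reg_multiplier, x$objective_trace[length(x$objective_trace)],
    x$entropy_H, x$converged
  ))
  invisible(x)
}

#' Serialize a maximum-entropy model to and from JSON
#'
#' @param model A `maxent_model`.
#' @param path JSON path.
#' @return `write_maxent`: `path` invisibly; `read_maxent`: the model.
#' @export
write_maxent <- function(model, path) {
  stopifnot(inherits(model, "maxent_model"))
  obj <- unclass(model)
  obj$features <- lapply(model$features, function(d) {
    list(kind = d$kind, variables = as.character(d$variables),
         knot = d$knot, offset = d$offset, range = d$range)
  })
  obj$clamp_bounds <- lapply(obj$clamp_bounds, as.list) # keep variable names
  write_json_file(obj, path)
}

#' @rdname write_maxent
#' @export
read_maxent <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- lapply(raw$features, function(d) {
    def <- list(kind = d$kind, variables = unlist(d$variables),
                knot = if (is.null(d$knot)) NA_real_ else as.numeric(d$knot),
                offset = as.numeric(d$offset), range = as.numeric(d$range))
    class(def) <- "feature_definition"
    def
  })
  attr(feats, "variables") <- CLIMATE_VARIABLES
  raw$features <- feats
  for (fld in c("weights", "background_raw", "beta", "objective_trace")) {
    raw[[fld]] <- as.numeric(unlist(raw[[fld]]))
  }
  for (fld in c("log_partition", "entropy_H", "reg_multiplier", "n_presence",
                "n_background", "kkt_violation", "tol")) {
    raw[[fld]] <- as.numeric(raw[[fld]])
  }
  raw$converged <- isTRUE(as.logical(raw$converged))
  raw$clamp_bounds <- lapply(raw$clamp_bounds, function(b) unlist(b))
  structure(raw, class = "maxent_model")
}
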