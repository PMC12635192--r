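# Maximum-entropy model: feature construction, the convex fit and its KKT
# contract, the three output scales, AUC, permutation importance, and
# niche recovery against generator ground truth.

fit_quiet <- function(...) suppressWarnings(fit_maxent(...))

test_that("background sampling is uniform over land, reproducible, exact in size", {
  world <- test_world(n = 40)
  bg <- draw_background(world$landmask, world$stack, m = 500, seed = 3)
  expect_identical(nrow(bg$climate_values), 500L)
  expect_false(anyNA(bg$climate_values))
  expect_identical(bg$points,
                   draw_background(world$landmask, world$stack, m = 500, seed = 3)$points)
  # single-land-cell mask: every point identical
  geom <- world$landmask$geometry
  one <- matrix(NA_real_, geom$n_rows, geom$n_cols)
  land_cell <- which(!is.na(world$landmask$values), arr.ind = TRUE)[1, ]
  one[land_cell[1], land_cell[2]] <- 1
  bg1 <- draw_background(climate_grid(one, geom, "LAND"), world$stack,
                         m = 50, seed = 4)
  expect_identical(nrow(unique(bg1$points)), 1L)
  empty <- climate_grid(matrix(NA_real_, geom$n_rows, geom$n_cols), geom, "LAND")
  expect_error(draw_background(empty, world$stack, m = 10, seed = 1), "no valid land")
})

test_that("background cell frequencies pass a chi-square uniformity check", {
  world <- test_world(n = 40)
  geom <- world$landmask$geometry
  land_idx <- which(!is.na(world$landmask$values), arr.ind = TRUE)
  fifty <- land_idx[seq_len(50), , drop = FALSE]
  m50 <- matrix(NA_real_, geom$n_rows, geom$n_cols)
  m50[fifty] <- 1
  bg <- draw_background(climate_grid(m50, geom, "LAND"), world$stack,
                        m = 10000, seed = 5)
  counts <- table(paste(round(bg$points$lon, 6), round(bg$points$lat, 6)))
  expect_identical(length(counts), 50L)
  expect_gt(stats::chisq.test(as.numeric(counts))$p.value, 0.01)
})

test_that("feature counts follow the class selection", {
  x <- random_climate(100, seed = 51)
  bg <- random_climate(200, seed = 52)
  expect_identical(length(build_features(x, bg, classes = "linear")), 6L)
  expect_identical(
    length(build_features(x, bg, classes = c("linear", "quadratic", "product"))),
    27L
  )
  hinge <- build_features(x, bg, classes = c("forward_hinge", "reverse_hinge"),
                          knots_per_variable = 8)
  expect_identical(length(hinge), 2L * 8L * 6L)
  expect_error(build_features(x, bg, classes = character(0)), "feature class")
  expect_error(build_features(x, bg, classes = "cubic"), "unknown feature class")
})

test_that("feature auto-selection widens with the presence count", {
  expect_identical(auto_feature_classes(5), "linear")
  expect_identical(auto_feature_classes(12), c("linear", "quadratic"))
  expect_true("forward_hinge" %in% auto_feature_classes(50))
  expect_false("product" %in% auto_feature_classes(50))
  expect_identical(sort(auto_feature_classes(200)),
                   sort(c("linear", "quadratic", "product", "forward_hinge",
                          "reverse_hinge", "threshold")))
})

test_that("features are min-max standardized to [0,1] on the background", {
  x <- random_climate(50, seed = 53)
  bg <- random_climate(300, seed = 54)
  feats <- build_features(x, bg, classes = c("linear", "quadratic", "product",
                                             "forward_hinge", "threshold"))
  Fb <- feature_matrix(feats, bg)
  expect_true(all(Fb >= 0 & Fb <= 1))
  expect_true(all(abs(apply(Fb, 2, max) - 1) < 1e-12))
  expect_true(all(abs(apply(Fb, 2, min)) < 1e-12))
})

test_that("the null fit stays at zero when presences equal the background", {
  bg <- random_climate(100, seed = 55)
  feats <- build_features(bg, bg, classes = "linear")
  m <- fit_quiet(bg, bg, features = feats)
  expect_identical(m$weights, rep(0, 6))
  expect_true(m$converged)
  # a lambda = 0 model predicts raw = 1/m everywhere on its background
  expect_equal(predict(m, bg, type = "raw"), rep(1 / 100, 100), tolerance = 1e-12)
  expect_equal(evaluate_auc(m, bg, bg), 0.5, tolerance = 1e-12)
})

test_that("heavy regularization drives every weight to exactly zero", {
  x <- random_climate(40, seed = 56)
  bg <- random_climate(150, seed = 57)
  m <- fit_quiet(x, bg, features = build_features(x, bg, classes = "linear"),
                 reg_multiplier = 1e6)
  expect_identical(m$weights, rep(0, 6))
})

test_that("raw scores over the training background sum to one", {
  world <- test_world(n = 40)
  occ <- sample_species(world$stack, mat_niche(world), 80, seed = 58)
  clim <- extract_climate(world$stack, occ$decimalLongitude, occ$decimalLatitude)
  bg <- draw_background(world$landmask, world$stack, m = 800, seed = 6)
  m <- fit_quiet(clim, bg, tol = 1e-5, max_iter = 3000)
  expect_equal(sum(m$background_raw), 1, tolerance = 1e-8)
  expect_equal(sum(predict(m, bg$climate_values, type = "raw")), 1,
               tolerance = 1e-8)
})

test_that("the objective trace is monotonically non-increasing", {
  world <- test_world(n = 40)
  occ <- sample_species(world$stack, mat_niche(world), 60, seed = 59)
  clim <- extract_climate(world$stack, occ$decimalLongitude, occ$decimalLatitude)
  bg <- draw_background(world$landmask, world$stack, m = 500, seed = 7)
  m <- fit_quiet(clim, bg, tol = 1e-6, max_iter = 2000)
  expect_true(all(diff(m$objective_trace) <= 1e-12))
})

test_that("the fit matches an independent convex-minimization oracle", {
  # small instance: 20 background profiles, linear + quadratic features
  bg <- random_climate(20, seed = 60)
  x <- bg[withr::with_seed(61, sample.int(20, 8, replace = TRUE)), ]
  feats <- build_features(x, bg, classes = c("linear", "quadratic"))
  m <- fit_maxent(x, bg, features = feats, tol = 1e-8, max_iter = 50000)
  expect_true(m$converged)
  obj_fit <- m$objective_trace[length(m$objective_trace)]

  # oracle: smooth reformulation lambda = a - b with a, b >= 0 solved by
  # box-constrained quasi-Newton (L-BFGS-B), entirely independent of the
  # proximal solver
  Fp <- feature_matrix(feats, x)
  Fb <- feature_matrix(feats, bg)
  fbar <- colMeans(Fp)
  beta <- m$beta
  J <- length(beta)
  obj_split <- function(par) {
    l <- par[1:J] - par[(J + 1):(2 * J)]
    eta <- as.numeric(Fb %*% l)
    mx <- max(eta)
    -sum(fbar * l) + mx + log(sum(exp(eta - mx))) + sum(beta * (par[1:J] + par[(J + 1):(2 * J)]))
  }
  grad_split <- function(par) {
    l <- par[1:J] - par[(J + 1):(2 * J)]
    eta <- as.numeric(Fb %*% l)
    p <- exp(eta - max(eta)); p <- p / sum(p)
    gs <- -fbar + as.numeric(crossprod(Fb, p))
    c(gs + beta, -gs + beta)
  }
  opt <- stats::optim(rep(0, 2 * J), obj_split, grad_split, method = "L-BFGS-B",
                      lower = 0, control = list(maxit = 2000, factr = 10))
  expect_lt(abs(obj_fit - opt$value), 1e-5)
  # KKT stationarity at the reported solution
  expect_lte(m$kkt_violation, 10 * 1e-8)
})

test_that("with vanishing penalty, background expectations match presence means", {
  bg <- random_climate(60, seed = 62)
  x <- random_climate(25, seed = 63)
  feats <- build_features(x, bg, classes = "linear")
  # with beta = 0 the KKT condition IS the moment match: |grad| <= 10 * tol
  # already bounds the mismatch far below the 1e-4 assertion
  m <- fit_maxent(x, bg, features = feats, reg_multiplier = 0,
                  tol = 1e-7, max_iter = 100000)
  Fb <- feature_matrix(feats, bg)
  expect_equal(as.numeric(crossprod(Fb, m$background_raw)),
               colMeans(feature_matrix(feats, x)), tolerance = 1e-4)
})

test_that("sparsity is non-increasing along the regularization path", {
  world <- test_world(n = 40)
  occ <- sample_species(world$stack, mat_niche(world), 60, seed = 64)
  clim <- extract_climate(world$stack, occ$decimalLongitude, occ$decimalLatitude)
  bg <- draw_background(world$landmask, world$stack, m = 400, seed = 8)
  feats <- build_features(clim, bg, classes = c("linear", "quadratic"))
  active <- vapply(c(0.25, 0.5, 1, 2.5, 8), function(r) {
    sum(fit_quiet(clim, bg, features = feats, reg_multiplier = r,
                  tol = 1e-6, max_iter = 5000)$weights != 0)
  }, numeric(1))
  expect_true(all(diff(active) <= 0))
})

test_that("output scales behave: logistic monotone in raw, cumulative tops at 100", {
  world <- test_world(n = 40)
  occ <- sample_species(world$stack, mat_niche(world), 70, seed = 65)
  clim <- extract_climate(world$stack, occ$decimalLongitude, occ$decimalLatitude)
  bg <- draw_background(world$landmask, world$stack, m = 600, seed = 9)
  m <- fit_quiet(clim, bg, tol = 1e-5, max_iter = 3000)
  raw <- predict(m, bg$climate_values, type = "raw")
  lgs <- predict(m, bg$climate_values, type = "logistic")
  cml <- predict(m, bg$climate_values, type = "cumulative")
  expect_true(all(lgs > 0 & lgs < 1))
  ord <- order(raw)
  expect_true(all(diff(lgs[ord]) >= 0))
  expect_true(all(diff(cml[ord]) >= 0))
  expect_equal(max(cml), 100, tolerance = 1e-9)
  expect_true(all(cml >= 0 & cml <= 100))
  expect_error(predict(m, bg$climate_values, type = "nonsense"), "arg")
})

test_that("training AUC equals the brute-force pair count", {
  world <- test_world(n = 40)
  occ <- sample_species(world$stack, mat_niche(world), 50, seed = 66)
  clim <- extract_climate(world$stack, occ$decimalLongitude, occ$decimalLatitude)
  bg <- draw_background(world$landmask, world$stack, m = 50, seed = 10)
  m <- fit_quiet(clim, bg, tol = 1e-5, max_iter = 2000)
  sp <- predict(m, clim, type = "raw")
  sb <- predict(m, bg$climate_values, type = "raw")
  pairs <- 0
  for (i in seq_along(sp)) {
    for (j in seq_along(sb)) {
      pairs <- pairs + (sp[i] > sb[j]) + 0.5 * (sp[i] == sb[j])
    }
  }
  expect_equal(evaluate_auc(m, clim, bg), pairs / (length(sp) * length(sb)),
               tolerance = 1e-12)
  # degenerate extremes
  flat <- fit_quiet(bg$climate_values, bg, features = build_features(
    bg$climate_values, bg, classes = "linear"
  ))
  expect_equal(evaluate_auc(flat, bg$climate_values, bg), 0.5, tolerance = 1e-12)
})

test_that("permutation importance sums to 100 and ignores unused variables", {
  world <- test_world(n = 40)
  occ <- sample_species(world$stack, mat_niche(world), 80, seed = 67)
  clim <- extract_climate(world$stack, occ$decimalLongitude, occ$decimalLatitude)
  bg <- draw_background(world$landmask, world$stack, m = 500, seed = 11)
  m <- fit_quiet(clim, bg, tol = 1e-5, max_iter = 3000)
  vi <- variable_importance(m, clim, bg, n_permutations = 3, seed = 12)
  expect_equal(sum(vi), 100, tolerance = 1e-9)
  expect_true(all(vi >= 0))
  # zero out every weight touching PREC: its importance must be exactly 0
  m0 <- m
  touches_prec <- vapply(m$features, function(d) "PREC" %in% d$variables, logical(1))
  m0$weights[touches_prec] <- 0
  vi0 <- variable_importance(m0, clim, bg, n_permutations = 3, seed = 12)
  expect_identical(unname(vi0[["PREC"]]), 0)
  # an all-zero model has no signal: uniform shares
  mz <- m
  mz$weights[] <- 0
  expect_equal(unname(variable_importance(mz, clim, bg, n_permutations = 2, seed = 13)),
               rep(100 / 6, 6))
})

test_that("gridded prediction equals the per-cell loop and respects nodata", {
  world <- test_world(n = 20, seed = 56)
  occ <- sample_species(world$stack, mat_niche(world), 40, seed = 68)
  clim <- extract_climate(world$stack, occ$decimalLongitude, occ$decimalLatitude)
  bg <- draw_background(world$landmask, world$stack, m = 300, seed = 14)
  m <- fit_quiet(clim, bg, tol = 1e-4, max_iter = 2000)
  surf <- map_maxent(m, world$stack, type = "logistic")
  vals <- lapply(world$stack$grids, function(g) g$values)
  for (r in seq_len(20)) {
    for (c in seq_len(20)) {
      x <- vapply(CLIMATE_VARIABLES, function(v) vals[[v]][r, c], numeric(1))
      if (anyNA(x)) {
        expect_true(is.na(surf$values[r, c]))
      } else {
        expect_equal(surf$values[r, c],
                     predict(m, matrix(x, 1, dimnames = list(NULL, CLIMATE_VARIABLES)),
                             type = "logistic"),
                     tolerance = 1e-12)
      }
    }
  }
  # null model maps to a constant surface
  mz <- m
  mz$weights[] <- 0
  mz$log_partition <- log(m$n_background)
  flat <- map_maxent(mz, world$stack, type = "raw")
  expect_identical(length(unique(stats::na.omit(as.numeric(flat$values)))), 1L)
})

test_that("fitted suitability recovers the generator's niche", {
  world <- test_world(n = 40)
  niche <- mat_niche(world, mat_quantile = 0.3)
  occ <- sample_species(world$stack, niche, 200, seed = 69)
  clim <- extract_climate(world$stack, occ$decimalLongitude, occ$decimalLatitude)
  bg <- draw_background(world$landmask, world$stack, m = 2000, seed = 15)
  m <- fit_quiet(clim, bg, tol = 1e-4, max_iter = 2000)
  cells <- land_climate(world)
  fitted <- predict(m, cells[CLIMATE_VARIABLES], type = "logistic")
  truth <- niche_suitability(niche, cells)
  expect_gt(stats::cor(fitted, truth, method = "spearman"), 0.8)
  expect_gt(evaluate_auc(m, clim, bg), 0.85)
  # suitability inside the true core beats outside
  core <- truth > 0.5
  expect_gt(mean(fitted[core]), mean(fitted[!core]))
  vi <- variable_importance(m, clim, bg, n_permutations = 3, seed = 16)
  expect_identical(names(which.max(vi)), "MAT")
})

test_that("models round-trip through JSON with identical predictions", {
  world <- test_world(n = 40)
  occ <- sample_species(world$stack, mat_niche(world), 60, seed = 70)
  clim <- extract_climate(world$stack, occ$decimalLongitude, occ$decimalLatitude)
  bg <- draw_background(world$landmask, world$stack, m = 300, seed = 17)
  m <- fit_quiet(clim, bg, tol = 1e-4, max_iter = 2000)
  path <- withr::local_tempfile(fileext = ".json")
  write_maxent(m, path)
  back <- read_maxent(path)
  probes <- land_climate(world)[1:25, CLIMATE_VARIABLES]
  for (ty in c("raw", "logistic", "cumulative")) {
    expect_equal(predict(back, probes, type = ty),
                 predict(m, probes, type = ty), tolerance = 1e-12)
  }
})

test_that("degenerate inputs are rejected with clear errors", {
  bg <- random_climate(10, seed = 71)
  expect_error(fit_maxent(bg[0, ], bg), "at least one presence")
  one_profile <- bg[rep(1, 5), ]
  expect_error(fit_maxent(bg[1, ], one_profile), "distinct background")
})
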