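# Rectilinear envelopes: order statistics, percentile scoring, corner-wise
# rectilinearity, and gridded classification.

test_that("envelope statistics are exact order statistics", {
  x <- random_climate(50, seed = 31)
  env <- fit_envelope(x)
  for (v in CLIMATE_VARIABLES) {
    st <- env$stats[[v]]
    expect_identical(st[["min"]], min(x[[v]]))
    expect_identical(st[["max"]], max(x[[v]]))
    expect_equal(st[["mean"]], mean(x[[v]]))
    expect_equal(st[["median"]], stats::median(x[[v]]))
    expect_equal(st[["p05"]], stats::quantile(x[[v]], 0.05, names = FALSE))
    expect_equal(st[["p95"]], stats::quantile(x[[v]], 0.95, names = FALSE))
    expect_true(st[["min"]] <= st[["p05"]] && st[["p05"]] <= st[["median"]] &&
                  st[["median"]] <= st[["p95"]] && st[["p95"]] <= st[["max"]])
  }
  small <- data.frame(MAT = c(1, 2, 3), MINTCM = c(1, 2, 3), MAXTHM = c(1, 2, 3),
                      PREC = c(1, 2, 3), PRECCP = c(1, 2, 3), PRECHP = c(1, 2, 3))
  st <- fit_envelope(small)$stats$MAT
  expect_identical(unname(st[c("min", "mean", "max")]), c(1, 2, 3))
  expect_error(fit_envelope(small[0, ]), "at least one")
})

test_that("quantiles of heavy samples approach the generating distribution", {
  set.seed(32)
  n <- 200
  x <- data.frame(
    MAT = rnorm(n, 5, 2), MINTCM = rnorm(n, -8, 2), MAXTHM = rnorm(n, 18, 2),
    PREC = rnorm(n, 800, 50), PRECCP = rnorm(n, 200, 20), PRECHP = rnorm(n, 220, 20)
  )
  env <- fit_envelope(x)
  # Monte-Carlo tolerance: se of the empirical 5% quantile of N(5, 2) at
  # n = 200 is about sqrt(p(1-p)/n)/f(q) ~ 0.3; allow 3 se
  expect_lt(abs(env$stats$MAT[["p05"]] - stats::qnorm(0.05, 5, 2)), 0.9)
  expect_lt(abs(env$stats$MAT[["p95"]] - stats::qnorm(0.95, 5, 2)), 0.9)
})

test_that("all-identical points give a degenerate but valid envelope", {
  x <- random_climate(1, seed = 33)
  x <- x[rep(1, 10), ]
  env <- fit_envelope(x)
  st <- env$stats$PREC
  expect_identical(length(unique(unname(st[c("min", "p05", "median", "p95", "max")]))), 1L)
  res <- classify_cell(env, unlist(x[1, ]))
  expect_identical(as.character(res$class), "core")
  expect_gt(res$score, 0)
})

test_that("classification follows the rectilinear rule with a percentile score", {
  x <- random_climate(60, seed = 34)
  env <- fit_envelope(x)
  medians <- vapply(x, stats::median, numeric(1))
  at_median <- classify_cell(env, medians)
  expect_identical(as.character(at_median$class), "core")
  expect_equal(at_median$score, 1)
  above <- replace(medians, "MAT", env$stats$MAT[["max"]] + 1)
  res <- classify_cell(env, above)
  expect_identical(as.character(res$class), "unsuitable")
  expect_identical(res$score, 0)
  # between p95 and max: marginal with a positive score
  marg <- replace(medians, "MAT",
                  (env$stats$MAT[["p95"]] + env$stats$MAT[["max"]]) / 2)
  res_m <- classify_cell(env, marg)
  expect_identical(as.character(res_m$class), "marginal")
  expect_gt(res_m$score, 0)
})

test_that("the percentile score matches a direct order-statistic oracle", {
  x <- random_climate(80, seed = 35)
  env <- fit_envelope(x)
  set.seed(36)
  probes <- as.data.frame(lapply(x, function(v) {
    runif(50, min(v), max(v))
  }))
  got <- classify_cell(env, probes)$score
  # oracle: per-variable Hazen percentile interpolated between sorted
  # training values, assembled with explicit loops
  oracle <- vapply(seq_len(50), function(i) {
    s_min <- Inf
    for (v in CLIMATE_VARIABLES) {
      s <- sort(x[[v]])
      n <- length(s)
      val <- probes[[v]][i]
      pos <- 100 * (seq_len(n) - 0.5) / n
      p <- if (val <= s[1]) {
        if (val < s[1]) 0 else pos[1]
      } else if (val >= s[n]) {
        if (val > s[n]) 100 else pos[n]
      } else {
        k <- max(which(s <= val))
        if (s[k] == val) {
          mean(pos[s == val])
        } else {
          pos[k] + (pos[k + 1] - pos[k]) * (val - s[k]) / (s[k + 1] - s[k])
        }
      }
      s_min <- min(s_min, min(p, 100 - p) / 50)
    }
    s_min
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("score is zero exactly on the unsuitable class", {
  x <- random_climate(40, seed = 37)
  env <- fit_envelope(x)
  set.seed(38)
  probes <- as.data.frame(lapply(x, function(v) {
    runif(200, min(v) - diff(range(v)), max(v) + diff(range(v)))
  }))
  res <- classify_cell(env, probes)
  expect_identical(res$score == 0, as.character(res$class) == "unsuitable")
  expect_true(all(res$score[as.character(res$class) == "core"] > 0))
})

test_that("the suitable region is a Cartesian product of intervals (corner probing)", {
  x <- random_climate(30, seed = 39)
  env <- fit_envelope(x)
  lows <- vapply(env$stats, function(s) s[["min"]], numeric(1))
  highs <- vapply(env$stats, function(s) s[["max"]], numeric(1))
  mids <- vapply(env$stats, function(s) s[["median"]], numeric(1))
  # every corner of the [min, max] box is suitable...
  for (k in 0:(2^6 - 1)) {
    corner <- ifelse(bitwAnd(k, 2^(0:5)) > 0, highs, lows)
    names(corner) <- CLIMATE_VARIABLES
    expect_false(as.character(classify_cell(env, corner)$class) == "unsuitable")
  }
  # ...and pushing any single variable past its interval is always fatal,
  # whatever the other variables do
  for (v in CLIMATE_VARIABLES) {
    out <- replace(mids, v, highs[[v]] + 1e-6 * (1 + abs(highs[[v]])))
    expect_identical(as.character(classify_cell(env, out)$class), "unsuitable")
  }
})

test_that("envelopes only widen under data augmentation", {
  x <- random_climate(40, seed = 40)
  extra <- random_climate(40, seed = 41)
  env1 <- fit_envelope(x)
  env2 <- fit_envelope(rbind(x, extra))
  for (v in CLIMATE_VARIABLES) {
    expect_lte(env2$stats[[v]][["min"]], env1$stats[[v]][["min"]])
    expect_gte(env2$stats[[v]][["max"]], env1$stats[[v]][["max"]])
  }
})

test_that("gridded classification equals the per-cell loop", {
  world <- test_world(n = 20, seed = 55)
  occ <- sample_species(world$stack, mat_niche(world), 60, seed = 42)
  clim <- extract_climate(world$stack, occ$decimalLongitude, occ$decimalLatitude)
  env <- fit_envelope(clim[stats::complete.cases(clim), ])
  maps <- map_envelope(env, world$stack)
  vals <- lapply(world$stack$grids, function(g) g$values)
  for (r in seq_len(20)) {
    for (c in seq_len(20)) {
      x <- vapply(CLIMATE_VARIABLES, function(v) vals[[v]][r, c], numeric(1))
      if (anyNA(x)) {
        expect_true(is.na(maps$class$values[r, c]))
      } else {
        one <- classify_cell(env, x)
        expect_identical(maps$class$values[r, c], as.numeric(as.integer(one$class) - 1L))
        expect_identical(maps$score$values[r, c], one$score)
      }
    }
  }
})

test_that("a constant stack at the envelope medians maps all-core", {
  x <- random_climate(25, seed = 43)
  env <- fit_envelope(x)
  meds <- vapply(x, stats::median, numeric(1))
  st <- toy_stack(4, 4, values = meds)
  maps <- map_envelope(env, st)
  expect_true(all(maps$class$values == 2))
})

test_that("warming shrinks the suitable range of a cold-adapted species", {
  world <- test_world(n = 40)
  cold <- mat_niche(world, mat_quantile = 0.15, mat_spread = 2)
  occ <- sample_species(world$stack, cold, 120, seed = 44)
  clim <- extract_climate(world$stack, occ$decimalLongitude, occ$decimalLatitude)
  env <- fit_envelope(clim[stats::complete.cases(clim), ])
  now <- map_envelope(env, world$stack)$class$values
  delta <- make_gcm_delta(world$stack, "GCM-W", warming = 5, precip_ratio = 1,
                          seed = 45)
  future <- downscale(world$stack, delta)
  then <- map_envelope(env, future)$class$values
  expect_lt(mean(then > 0, na.rm = TRUE), mean(now > 0, na.rm = TRUE))
})

test_that("envelopes round-trip through JSON", {
  x <- random_climate(20, seed = 46)
  env <- fit_envelope(x)
  path <- withr::local_tempfile(fileext = ".json")
  write_envelope(env, path)
  back <- read_envelope(path)
  probes <- random_climate(10, seed = 47)
  expect_equal(classify_cell(back, probes)$score,
               classify_cell(env, probes)$score, tolerance = 1e-12)
  expect_equal(back$stats$MAT[["p95"]], env$stats$MAT[["p95"]])
})
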