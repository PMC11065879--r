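test_that("series statistics match their definitions", {
  const <- grid_from_fun(function(d) rep(0.3, length(d)))
  s <- series_statistics(const)
  expect_equal(unname(s), c(0.3, 0.3, 0, 0.3, 0.3, 0.3))

  s2 <- series_statistics(1:10)
  expect_equal(s2[["p50"]], 5.5)   # linear-interpolation percentile
  expect_equal(s2[["min"]], 1)
  expect_equal(s2[["max"]], 10)

  set.seed(5)
  for (i in 1:10) {
    s3 <- series_statistics(rnorm(30))
    expect_true(s3[["min"]] <= s3[["p15"]] && s3[["p15"]] <= s3[["p50"]] &&
                  s3[["p50"]] <= s3[["p90"]] && s3[["p90"]] <= s3[["max"]])
    expect_gte(s3[["std"]], 0)
  }
  expect_error(series_statistics(numeric(0)), "empty")
})

test_that("harmonic fit recovers noiseless parameters", {
  t <- seq(5, 365, 5)   # full annual cycle keeps the basis well conditioned
  w <- 1 / 365
  y <- 2 + 3 * cos(2 * pi * w * t) + 4 * sin(2 * pi * w * t)
  hf <- harmonic_fit(t, y, M = 2)
  expect_equal(hf$amplitude[1], 5, tolerance = 1e-6)
  expect_equal(hf$phase[1], atan2(4, 3), tolerance = 1e-6)
  expect_equal(hf$amplitude[2], 0, tolerance = 1e-6)
  expect_lt(max(abs(hf$fitted - y)), 1e-9)

  # pure trend leaves the harmonics empty
  hf2 <- harmonic_fit(t, 0.01 * t, M = 2)
  expect_equal(hf2$amplitude, c(0, 0), tolerance = 1e-6)
  expect_equal(hf2$b, 0.01, tolerance = 1e-9)

  # small white noise perturbs the amplitude only slightly
  set.seed(8)
  reps <- replicate(20, {
    hfn <- harmonic_fit(t, y + rnorm(length(t), 0, 0.01), M = 2)
    abs(hfn$amplitude[1] - 5)
  })
  expect_lt(max(reps), 0.05)

  expect_error(harmonic_fit(t[1:4], y[1:4], M = 2), "at least")
})

test_that("accumulated EVI splits the seasonal integral at the peak", {
  g <- triangular_evi(205, 0.1, 0.9)
  p <- extract_phenology(g)
  acc <- accumulated_evi(g, p)
  expect_equal(acc[["accum_green"]], acc[["accum_senes"]],
               tolerance = 1e-9)        # symmetric curve: equal halves
  expect_equal(sum(acc), seasonal_integral(g, p), tolerance = 1e-9)

  const <- grid_from_fun(function(d) rep(0.4, length(d)))
  phen <- list(sos = 100, pos = 180, eos = 300)
  acc2 <- accumulated_evi(const, phen)
  expect_equal(unname(acc2), c(0.4 * 80, 0.4 * 120), tolerance = 1e-9)
})

test_that("temporal PCA is deterministic and recovers known structure", {
  set.seed(31)
  # rank-1 matrix: one component carries all variance
  u <- rnorm(40); v <- rnorm(12)
  pc <- suppressWarnings(temporal_pca(u %o% v, k = 3))
  expect_equal(pc$var_explained[1], 1, tolerance = 1e-9)

  # orthogonal two-pattern mixture: variance fractions match construction
  n <- 300
  p1 <- rep(c(1, -1), 6) / sqrt(12)
  p2 <- rep(c(1, 1, -1, -1), 3) / sqrt(12)
  X <- cbind(rnorm(n, sd = 3)) %*% rbind(p1) +
    cbind(rnorm(n, sd = 1)) %*% rbind(p2)
  pc2 <- temporal_pca(X, k = 2)
  expect_equal(pc2$var_explained[1] / pc2$var_explained[2], 9,
               tolerance = 0.35)

  # deterministic sign rule: identical runs give identical scores
  pc3 <- temporal_pca(X, k = 2)
  expect_identical(pc2$scores, pc3$scores)
  expect_true(all(apply(pc2$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))
})

test_that("feature selection ranks an informative feature first", {
  set.seed(77)
  n <- 120
  labels <- rep(c("a", "b"), each = n / 2)
  X <- as.data.frame(matrix(rnorm(n * 8), n))
  names(X) <- paste0("f", 1:8)
  X$f3 <- ifelse(labels == "a", 0, 5) + rnorm(n, 0, 0.1)
  sel <- select_features(X, labels, fraction = 0.25, seed = 1)
  expect_equal(sel[1], "f3")
  expect_length(sel, 2)
  expect_identical(sel, select_features(X, labels, fraction = 0.25,
                                        seed = 1))
  expect_setequal(select_features(X, labels, fraction = 1, seed = 1),
                  names(X))
  expect_error(select_features(X, rep("a", n)), "2 classes")
})

test_that("the feature table carries the documented optical and SAR counts", {
  scene <- simulate_region(n_per_crop = c(soybean = 4, corn = 4),
                           n_reference = 30, seed = 13)
  cfg <- pipeline_config(seed = 13)
  ft <- build_feature_table(scene$candidates$series, scene$candidates$sar,
                            cfg)
  expect_equal(nrow(ft), 8)
  sar_cols <- grepl("^sar_", names(ft))
  expect_equal(sum(!sar_cols), 69)   # 5x6 + 5x6 + 3 + 4 + 2
  expect_equal(sum(sar_cols), 50)    # 7x5 statistics + 3x5 PCA scores
  expect_true(all(is.finite(as.matrix(ft))))
  # per-series ordering invariant on a few sampled blocks
  expect_true(all(ft$evi_min <= ft$evi_p15 & ft$evi_p15 <= ft$evi_p50 &
                    ft$evi_p50 <= ft$evi_p90 & ft$evi_p90 <= ft$evi_max))
})
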