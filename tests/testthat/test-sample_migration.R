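test_that("Mahalanobis distance matches hand-worked cases", {
  m <- dist_model(c(1, 2, 3), diag(3))
  expect_equal(mahalanobis_distance(c(1, 2, 3), m), 0)
  expect_equal(mahalanobis_distance(c(4, 6, 3), m), 5)   # Euclidean (3,4,0)
  m2 <- dist_model(c(0, 0, 0), diag(c(4, 1, 1)))
  expect_equal(mahalanobis_distance(c(2, 0, 0), m2), 1)
  expect_error(mahalanobis_distance(c(NA, 0, 0), m), "non-finite")
})

test_that("Mahalanobis agrees with the matrix-inverse oracle on random SPD", {
  set.seed(101)
  for (i in 1:100) {
    S <- random_spd()
    mu <- rnorm(3)
    x <- rnorm(3, sd = 2)
    oracle <- sqrt(drop(t(x - mu) %*% solve(S) %*% (x - mu)))
    expect_equal(mahalanobis_distance(x, dist_model(mu, S)), oracle,
                 tolerance = 1e-8)
  }
})

test_that("Mahalanobis is invariant under joint affine transforms", {
  set.seed(202)
  for (i in 1:20) {
    X <- MASS::mvrnorm(200, mu = c(1, -2, 0.5), Sigma = random_spd())
    x <- rnorm(3)
    m1 <- dist_model(colMeans(X), cov(X))
    A <- matrix(rnorm(9), 3) + 2 * diag(3)   # invertible w.h.p.
    b <- rnorm(3)
    XT <- X %*% t(A) + rep(b, each = 200)
    m2 <- dist_model(colMeans(XT), cov(XT))
    expect_equal(mahalanobis_distance(drop(A %*% x + b), m2),
                 mahalanobis_distance(x, m1), tolerance = 1e-8)
  }
})

test_that("group-model p50 and r50 match the chi-square(3) closed form", {
  set.seed(99)
  X <- MASS::mvrnorm(10000, mu = rep(0, 3), Sigma = diag(3))
  fit <- fit_group_model(X, "high", n_mc = 1e5, seed = 5)
  r50_true <- sqrt(qchisq(0.5, df = 3))
  p50_true <- (2 * pi)^(-1.5) * exp(-qchisq(0.5, 3) / 2)
  expect_equal(fit$p50, p50_true, tolerance = 0.01 * 2)  # MC + sampling noise
  expect_equal(fit$r50, r50_true, tolerance = 0.02)
  # robust points are exactly those inside the r50 radius, about half
  d <- mahalanobis_distance(X, fit)
  expect_equal(fit$n_robust, sum(d < fit$r50))
  expect_equal(fit$n_robust / nrow(X), 0.5, tolerance = 0.02)
  # threshold ordering invariants
  expect_lte(fit$soy_thresh, fit$r50)
  expect_gte(fit$nonsoy_thresh, fit$soy_thresh)
})

test_that("group-model preconditions are enforced", {
  set.seed(1)
  expect_error(fit_group_model(matrix(rnorm(60), 20), "high"),
               "at least 30")
  X <- MASS::mvrnorm(50, rep(0, 3), diag(3))
  X[3, 1] <- NA
  expect_error(fit_group_model(X, "low"), "non-finite")
})

test_that("CCI reproduces hand-worked concavity cases", {
  grid <- temporal_grid()
  phen <- list(sos = 125, pos = 205, eos = 285)
  # concave ratio: 0.5 at the shoulders, 0.1 at the peak
  concave <- grid_from_fun(function(d) 0.5 - 0.4 * pmax(0, 1 - abs(d - 205) / 80))
  expect_equal(compute_cci(concave, phen), -0.8, tolerance = 1e-9)
  convex <- gridded_series(grid, 0.6 - concave$values)
  expect_equal(compute_cci(convex, phen), 0.8, tolerance = 1e-9)
  const <- grid_from_fun(function(d) rep(0.3, length(d)))
  expect_equal(compute_cci(const, phen), 0)
})

test_that("candidate decision rules implement the admission criteria", {
  hm <- list(soy_thresh = 1.2, nonsoy_thresh = 2.5)
  lm_ <- list(soy_thresh = 1.0, nonsoy_thresh = 2.2)
  expect_equal(classify_candidate(-0.5, 1.0, 0.8, hm, lm_), "soybean")
  expect_equal(classify_candidate(-0.5, 1.5, 0.8, hm, lm_),
               "cropland_unknown")        # d_high above soy threshold
  expect_equal(classify_candidate(0.3, 1.0, 0.8, hm, lm_),
               "cropland_unknown")        # CCI >= 0 blocks soybean
  expect_equal(classify_candidate(-0.5, 3.0, 2.3, hm, lm_),
               "non_soybean")             # both above non-soy thresholds
  expect_equal(classify_candidate(0.7, 2.6, 2.4, hm, lm_),
               "non_soybean")             # CCI ignored for non-soybean
  expect_equal(classify_candidate(-0.5, 2.6, 1.5, hm, lm_),
               "cropland_unknown")
})

test_that("reference-set selection follows the migration priority order", {
  inv <- data.frame(region = c("R1", "R1", "R2"),
                    year = c(2020, 2019, 2020),
                    climate_zone = c(1, 1, 2))
  # same region, different year: temporal
  ch <- select_reference_set("R1", 2021, inv)
  expect_equal(ch$strategy, "temporal")
  expect_equal(ch$year, 2020)
  # own region-year present: temporal with zero year gap
  ch0 <- select_reference_set("R1", 2019, inv)
  expect_equal(ch0$strategy, "temporal")
  expect_equal(ch0$delta_year, 0)
  # no surveys in target region, same year elsewhere: spatial
  ch2 <- select_reference_set("R3", 2020,
                              inv[inv$region != "R3", , drop = FALSE])
  expect_equal(ch2$strategy, "spatial")
  expect_equal(ch2$region, "R1")   # nearest climate zone wins
  # neither region nor year matches: spatiotemporal, nearest year first
  ch3 <- select_reference_set("R3", 2022, inv)
  expect_equal(ch3$strategy, "spatiotemporal")
  expect_equal(ch3$year, 2020)
  expect_error(select_reference_set("R1", 2020, inv[0, ]), "empty")
})

test_that("migration labels a well-separated synthetic scene precisely", {
  scene <- simulate_region(n_per_crop = c(soybean = 40, corn = 40,
                                          peanut = 40),
                           n_reference = 50, seed = 11)
  cfg <- pipeline_config(seed = 11, n_mc = 2e4)
  mig <- migrate_samples(scene$reference, scene$candidates, cfg)
  lab <- mig$labels
  soy <- lab$id[lab$label == "soybean"]
  non <- lab$id[lab$label == "non_soybean"]
  expect_gt(length(soy), 0)
  expect_gt(length(non), 0)
  expect_gte(mean(scene$truth[soy] == "soybean"), 0.95)
  expect_gte(mean(scene$truth[non] != "soybean"), 0.95)
  # audit is complete and consistent
  expect_equal(nrow(mig$audit), 120)
  expect_true(all(mig$audit$d_high >= 0 & mig$audit$d_low >= 0))
  expect_equal(sum(mig$counts[c("n_soybean", "n_non_soybean",
                                "n_discarded")]),
               mig$counts[["n_candidates"]])
})

test_that("migration is deterministic and candidates equal to references pass", {
  scene <- simulate_region(n_per_crop = c(soybean = 10, corn = 10),
                           n_reference = 35, seed = 21)
  cfg <- pipeline_config(seed = 21, n_mc = 1e4)
  m1 <- migrate_samples(scene$reference, scene$candidates, cfg)
  m2 <- migrate_samples(scene$reference, scene$candidates, cfg)
  expect_identical(m1$audit, m2$audit)
  expect_equal(coef(m1), coef(m2))

  # empty candidate list: valid models, empty audit
  m0 <- migrate_samples(scene$reference, list(), cfg)
  expect_s3_class(m0$high_model, "soy_group_model")
  expect_equal(nrow(m0$audit), 0)

  # the reference points themselves are mostly admitted as soybean
  pr <- predict(m1, scene$reference)
  expect_gt(mean(pr$decision == "soybean"), 0.2)
  expect_equal(mean(pr$decision == "non_soybean"), 0)
})

test_that("hexagonal cropland sampling respects purity and determinism", {
  # uniform cropland raster: everything retained
  lc <- soy_raster(matrix(40, 60, 60), cellsize = 10)
  pts <- sample_cropland(lc, 40, hex_spacing = 150, points_per_hex = 2,
                         seed = 3)
  expect_gt(nrow(pts), 0)
  expect_true(all(pts$label == "cropland_unknown"))

  pts2 <- sample_cropland(lc, 40, hex_spacing = 150, points_per_hex = 2,
                          seed = 3)
  expect_identical(pts, pts2)

  # a half-and-half raster: points near the boundary are discarded
  half <- matrix(40, 60, 60); half[, 31:60] <- 10
  lc2 <- soy_raster(half, cellsize = 10)
  pts3 <- sample_cropland(lc2, 40, hex_spacing = 120, points_per_hex = 3,
                          seed = 4)
  # retained points sit well inside the cropland half (x < 300 m minus buffer)
  expect_true(all(pts3$x < 300))
  expect_error(sample_cropland(lc, 99, seed = 1), "cropland code")
  expect_error(sample_cropland(lc, 40, purity = 0.4), "purity")
})
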