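test_that("stratified split is balanced, disjoint and seeded", {
  labels <- rep(c("soybean", "non_soybean"), c(40, 60))
  sp <- split_train_test(labels, seed = 999)
  expect_length(sp$train, 50)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:100)
  # per-class proportions preserved to one sample
  expect_equal(sum(labels[sp$train] == "soybean"), 20)
  expect_identical(sp, split_train_test(labels, seed = 999))
  expect_false(identical(sp$train,
                         split_train_test(labels, seed = 1000)$train))
  # regional stratification
  regions <- rep(c("A", "B"), 50)
  sp2 <- split_train_test(labels, regions, seed = 1)
  for (r in c("A", "B"))
    expect_equal(abs(sum(regions[sp2$train] == r) -
                       sum(regions[sp2$test] == r)) <= 2, TRUE)
  expect_error(split_train_test(c("a", "b")), "at least 2")
})

test_that("tree-count choice takes the first local maximum above 100", {
  trees <- as.character(seq(50, 500, 50))
  plateau <- setNames(c(.8, .85, .9, .92, .92, .92, .92, .92, .92, .92),
                      trees)
  expect_equal(choose_tree_count(plateau), 200)
  rising <- setNames(seq(0.8, 0.89, 0.01), trees)
  expect_warning(ct <- choose_tree_count(rising), "500")
  expect_equal(ct, 500L)
  # a local max at 100 is skipped; the next one is taken
  dip <- setNames(c(.8, .9, .85, .84, .88, .86, .86, .86, .86, .86), trees)
  expect_equal(choose_tree_count(dip), 250)
  expect_error(choose_tree_count(plateau[-3]), "cover")
})

test_that("the forest separates separable data and collapses on null labels", {
  set.seed(55)
  n <- 200
  labels <- rep(c("soybean", "non_soybean"), each = n / 2)
  X <- data.frame(f1 = rnorm(n) + ifelse(labels == "soybean", 4, 0),
                  f2 = rnorm(n), f3 = rnorm(n))
  rf <- train_soy_rf(X, labels, trees = seq(50, 500, 50))
  expect_gte(rf$accuracy_curve[[as.character(rf$ntree)]], 0.99)
  expect_true(rf$ntree %in% seq(50, 500, 50))

  # permuted labels: held-out accuracy near the class prior
  set.seed(56)
  perm <- sample(labels)
  rfp <- suppressWarnings(train_soy_rf(X, perm, trees = seq(50, 500, 50)))
  expect_lt(abs(rfp$accuracy_curve[[as.character(rfp$ntree)]] - 0.5), 0.1)

  # seeded: identical refits give identical predictions
  rf2 <- train_soy_rf(X, labels, trees = seq(50, 500, 50))
  expect_identical(predict(rf, X), predict(rf2, X))
})

test_that("prediction enforces the feature manifest and missing-data rule", {
  set.seed(60)
  labels <- rep(c("soybean", "non_soybean"), each = 30)
  X <- data.frame(a = rnorm(60) + ifelse(labels == "soybean", 6, 0),
                  b = rnorm(60))
  rf <- suppressWarnings(train_soy_rf(X, labels))
  expect_error(predict(rf, X[, "a", drop = FALSE]), "\\bb\\b")
  Xna <- X; Xna$a[2] <- NA
  p <- predict(rf, Xna)
  expect_true(is.na(p[2]))
  expect_false(anyNA(p[-2]))
  # training rows reproduced on separable data
  expect_gte(mean(as.character(p[-2]) == labels[-2]), 0.95)
})

test_that("raster prediction agrees with the table path", {
  set.seed(61)
  labels <- rep(c("soybean", "non_soybean"), each = 30)
  X <- data.frame(a = rnorm(60) + ifelse(labels == "soybean", 3, 0),
                  b = rnorm(60))
  rf <- suppressWarnings(train_soy_rf(X, labels))
  va <- matrix(rnorm(25, 1.5), 5); vb <- matrix(rnorm(25), 5)
  va[2, 2] <- NA
  rasters <- list(a = soy_raster(va), b = soy_raster(vb))
  rp <- predict(rf, rasters)
  tp <- predict(rf, data.frame(a = as.vector(va), b = as.vector(vb)))
  expect_s3_class(rp, "soy_raster")
  expect_true(is.na(rp$values[2, 2]))
  expect_equal(as.vector(rp$values == 1)[!is.na(tp)],
               (tp == "soybean")[!is.na(tp)])
})

test_that("majority filter removes speckle, fills holes, and is conservative", {
  m <- matrix(0, 9, 9)
  m[5, 5] <- 1                       # isolated soybean pixel
  f <- majority_filter(soy_raster(m))
  expect_equal(f$values[5, 5], 0)

  plot_ <- matrix(1, 9, 9)
  plot_[4, 6] <- 0                   # hole inside a soybean plot
  f2 <- majority_filter(soy_raster(plot_))
  expect_equal(f2$values[4, 6], 1)

  # homogeneous rasters are fixed points
  for (v in c(0, 1)) {
    h <- soy_raster(matrix(v, 7, 7))
    expect_equal(majority_filter(h)$values, h$values)
  }

  # nodata stays nodata and is excluded from votes
  mn <- matrix(1, 5, 5); mn[3, 3] <- NA; mn[1, 1] <- 0
  fn <- majority_filter(soy_raster(mn))
  expect_true(is.na(fn$values[3, 3]))
  expect_equal(fn$values[1, 1], 1)

  # a straight boundary between two homogeneous halves is preserved
  hb <- matrix(rep(c(0, 1), each = 5), 10, 10, byrow = FALSE)
  hb2 <- majority_filter(soy_raster(hb))
  expect_equal(hb2$values, hb)
  expect_error(majority_filter(soy_raster(matrix(2, 3, 3))), "binary")
})
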