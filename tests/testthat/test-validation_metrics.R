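test_that("accuracy metrics reproduce worked confusion-matrix examples", {
  perfect <- list(TP = 30, FP = 0, FN = 0, TN = 70)
  m <- accuracy_metrics(perfect)
  expect_equal(unlist(m[c("recall", "precision", "f1", "oa", "kappa")]),
               c(recall = 1, precision = 1, f1 = 1, oa = 1, kappa = 1))

  worked <- list(TP = 40, FN = 10, FP = 10, TN = 40)
  m2 <- accuracy_metrics(worked)
  expect_equal(m2$recall, 0.8)
  expect_equal(m2$precision, 0.8)
  expect_equal(m2$f1, 0.8)
  expect_equal(m2$oa, 0.8)
  expect_equal(m2$kappa, 0.6)   # pe = 0.5

  # everything predicted one class: chance-level kappa
  onec <- list(TP = 0, FP = 0, FN = 25, TN = 75)
  expect_equal(accuracy_metrics(onec)$kappa, 0)

  # zero denominators are flagged, never silent NaN
  m3 <- accuracy_metrics(list(TP = 0, FP = 0, FN = 5, TN = 5))
  expect_true(is.na(m3$precision))
  expect_true("precision" %in% m3$undefined)
})

test_that("the swapped producer/user convention is available and labelled", {
  cm <- list(TP = 30, FP = 20, FN = 5, TN = 45)
  std <- accuracy_metrics(cm, "standard")
  sw <- accuracy_metrics(cm, "swapped")
  expect_equal(std$recall, 30 / 35)
  expect_equal(sw$recall, 30 / 50)     # PA printed as TP/(TP+FP)
  expect_equal(sw$precision, 30 / 35)  # UA printed as TP/(TP+FN)
  expect_equal(std$oa, sw$oa)
  expect_equal(sw$convention, "swapped")
})

test_that("F1 is the harmonic mean and kappa respects its identities", {
  set.seed(17)
  for (i in 1:1000) {
    cm <- as.list(setNames(sample(0:50, 4, replace = TRUE),
                           c("TP", "FP", "FN", "TN")))
    if (sum(unlist(cm)) == 0) next
    m <- accuracy_metrics(cm)
    if (!is.na(m$f1))
      expect_equal(m$f1, 2 / (1 / m$recall + 1 / m$precision),
                   tolerance = 1e-12)
    if (!is.na(m$kappa)) {
      expect_lte(m$kappa, m$oa + 1e-12)
      # kappa invariant under swapping the positive/negative classes
      swp <- accuracy_metrics(list(TP = cm$TN, FP = cm$FN, FN = cm$FP,
                                   TN = cm$TP))
      expect_equal(m$kappa, swp$kappa, tolerance = 1e-12)
    }
  }
})

test_that("confusion matrices count soybean as the positive class", {
  truth <- c("soybean", "soybean", "non_soybean", "non_soybean", "soybean")
  pred <- c("soybean", "non_soybean", "non_soybean", "soybean", NA)
  cm <- confusion_matrix(truth, pred)
  expect_equal(unlist(cm[c("TP", "FP", "FN", "TN")]),
               c(TP = 1, FP = 1, FN = 1, TN = 1))
})

test_that("area agreement matches closed forms and flags degeneracy", {
  mapped <- c(A = 120, B = 340, C = 80, D = 210)
  same <- area_agreement(mapped, mapped)
  expect_equal(same$r2, 1)
  expect_equal(same$rmse, 0)
  expect_equal(same$mae, 0)

  off <- area_agreement(mapped + 15, mapped)
  expect_equal(off$r2, 1)
  expect_equal(off$rmse, 15)
  expect_equal(off$mae, 15)

  deg <- area_agreement(mapped, c(A = 5, B = 5, C = 5, D = 5))
  expect_true(is.na(deg$r2))
  expect_true("r2" %in% deg$undefined)
  expect_error(area_agreement(mapped, mapped[1:3]), "keys")
})

test_that("pixel areas aggregate per zone and sum over partitions", {
  v <- matrix(0, 10, 10)
  v[1:2, 1:5] <- 1           # 10 soybean pixels
  r <- soy_raster(v, cellsize = 10)  # 100 m2 pixels
  zones <- matrix("Z1", 10, 10)
  expect_equal(pixel_area(r, zones), c(Z1 = 1000))

  zones2 <- zones; zones2[, 6:10] <- "Z2"
  a <- pixel_area(r, zones2)
  expect_equal(sum(a), 1000)
  expect_equal(a[["Z1"]], 1000)

  empty <- soy_raster(matrix(0, 10, 10), cellsize = 10)
  expect_equal(sum(pixel_area(empty, zones)), 0)

  # polygon zones: split the raster down the middle
  polys <- list(L = cbind(c(0, 50, 50, 0), c(0, 0, 100, 100)),
                R = cbind(c(50, 100, 100, 50), c(0, 0, 100, 100)))
  ap <- pixel_area(r, polys)
  expect_equal(sum(ap), 1000)

  # geodesic cell areas in degrees: a 10x10 map of 0.001-degree cells
  rg <- soy_raster(matrix(1, 10, 10), xll = 126, yll = 45,
                   cellsize = 0.001, crs = "EPSG:4326")
  ag <- pixel_area(rg, matrix("Z", 10, 10))
  # WGS84 oracle: 100 cells of ~111 m x ~79 m at 45 N
  expect_equal(unname(ag), 876163.4, tolerance = 1e-3)
  expect_equal(pixel_area(rg, matrix("Z", 10, 10), unit = "ha"),
               ag / 1e4)
})
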