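# Random-forest classification with the tree-count selection protocol.

#' Stratified 50/50 train/test split
#'
#' Samples are split per region and class so that both halves preserve the
#' class proportions within each region (to one sample). Deterministic
#' under the seed.
#'
#' @param labels class vector.
#' @param regions optional region id per sample (one stratum if omitted).
#' @param seed integer seed.
#' @param train_fraction fraction assigned to training (default 0.5).
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, regions = NULL, seed = 999L,
                             train_fraction = 0.5) {
  n <- length(labels)
  if (is.null(regions)) regions <- rep("all", n)
  tab <- table(labels)
  if (any(tab < 2)) stop("need at least 2 samples per class")
  set.seed(seed)
  train <- integer(0)
  for (st in split(seq_len(n), list(regions, labels), drop = TRUE)) {
    k <- ceiling(train_fraction * length(st))
    train <- c(train, sort(sample(st, k)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Choose the random-forest tree count from an accuracy curve
#'
#' Returns the smallest tree count above 100 that is a local maximum of the
#' accuracy curve (at least as accurate as both neighbouring counts; the
#' 500 boundary compares left only). If no interior count qualifies the
#' full 500 trees are used with a warning.
#'
#' @param accuracy named numeric vector with names `"50", "100", ..., "500"`.
#' @return Integer tree count.
#' @export
choose_tree_count <- function(accuracy) {
  trees <- seq(50, 500, 50)
  if (!all(as.character(trees) %in% names(accuracy)))
    stop("accuracy curve must cover tree counts 50 to 500 in steps of 50")
  acc <- accuracy[as.character(trees)]
  for (i in which(trees > 100 & trees < 500)) {
    if (acc[i] >= acc[i - 1] && acc[i] >= acc[i + 1]) return(trees[i])
  }
  if (acc[length(acc)] >= acc[length(acc) - 1]) {
    warning("no interior local maximum above 100 trees; using 500")
    return(500L)
  }
  warning("accuracy curve has no local maximum above 100 trees; using 500")
  500L
}

#' Train the soybean random-forest classifier
#'
#' Implements the classification protocol: a stratified 50/50 split per
#' region, forests fitted with a fixed seed (default 999) at every
#' candidate tree count from 50 to 500 in steps of 50, held-out accuracy
#' recorded for each, the tree count chosen by [choose_tree_count()], and
#' the final model refitted at that count. All other forest parameters are
#' left at their \pkg{randomForest} defaults.
#'
#' @param features data frame of classification features.
#' @param labels class vector (e.g. soybean / non_soybean).
#' @param regions optional per-sample region ids for stratification.
#' @param selected optional character vector of feature names to use (e.g.
#'   from [select_features()]); defaults to all columns.
#' @param seed forest seed (default 999).
#' @param trees candidate tree counts.
#' @return An object of class `soy_rf`: the fitted forest, `ntree`,
#'   `accuracy_curve`, the split, the feature `manifest` and seed.
#' @export
train_soy_rf <- function(features, labels, regions = NULL, selected = NULL,
                         seed = 999L, trees = seq(50, 500, 50)) {
  features <- as.data.frame(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("training labels contain a single class")
  if (is.null(selected)) selected <- colnames(features)
  missing_f <- setdiff(selected, colnames(features))
  if (length(missing_f))
    stop("selected features absent from table: ",
         paste(missing_f, collapse = ", "))
  x <- features[, selected, drop = FALSE]
  sp <- split_train_test(labels, regions, seed = seed)
  xtr <- x[sp$train, , drop = FALSE]; ytr <- droplevels(labels[sp$train])
  xte <- x[sp$test, , drop = FALSE];  yte <- labels[sp$test]
  acc <- vapply(trees, function(nt) {
    set.seed(seed)
    rf <- randomForest::randomForest(xtr, ytr, ntree = nt)
    mean(predict(rf, xte) == yte)
  }, numeric(1))
  names(acc) <- as.character(trees)
  ntree <- choose_tree_count(acc)
  set.seed(seed)
  forest <- randomForest::randomForest(xtr, ytr, ntree = ntree)
  structure(list(forest = forest, ntree = ntree, seed = seed,
                 accuracy_curve = acc, split = sp, manifest = selected,
                 levels = levels(labels)),
            class = "soy_rf")
}

#' @export
print.soy_rf <- function(x, ...) {
  cat("<soy_rf> random forest,", x$ntree, "trees (seed", x$seed, "),",
      length(x$manifest), "features\n")
  cat("  held-out accuracy at chosen count:",
      sprintf("%.4f", x$accuracy_curve[as.character(x$ntree)]), "\n")
  invisible(x)
}

#' Predict soybean labels from features or a raster stack
#'
#' For a data frame, returns one label per row; rows with any missing
#' feature get `NA` (nodata). For a named list of feature rasters
#' (`soy_raster` per feature, identical shapes), returns a binary
#' [soy_raster()] where 1 = soybean and everything else (including pixels
#' with missing features) is nodata.
#'
#' @param object a fitted `soy_rf`.
#' @param newdata feature data frame or named list of feature rasters.
#' @param ... unused.
#' @return Factor of labels, or a [soy_raster()].
#' @export
predict.soy_rf <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.data.frame(newdata) &&
      all(vapply(newdata, inherits, logical(1), "soy_raster"))) {
    template <- newdata[[1]]
    tab <- as.data.frame(lapply(newdata, function(r) as.vector(r$values)))
    names(tab) <- names(newdata)
    lab <- predict(object, tab)
    v <- matrix(NA_real_, nrow(template$values), ncol(template$values))
    v[!is.na(lab) & lab == "soybean"] <- 1
    v[!is.na(lab) & lab != "soybean"] <- 0
    return(soy_raster(v, template$xll, template$yll, template$cellsize,
                      template$crs, template$nodata))
  }
  newdata <- as.data.frame(newdata)
  extra <- setdiff(object$manifest, colnames(newdata))
  if (length(extra))
    stop("feature columns missing from newdata: ",
         paste(extra, collapse = ", "))
  x <- newdata[, object$manifest, drop = FALSE]
  complete <- stats::complete.cases(x)
  out <- factor(rep(NA_character_, nrow(x)), levels = object$levels)
  if (any(complete))
    out[complete] <- predict(object$forest, x[complete, , drop = FALSE])
  out
}
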