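# Classification features: per-series statistics, harmonic fit of the
# raw EVI observations, accumulated-biomass integrals, temporal PCA of SAR
# parameters, and random-forest feature selection.

# Indices and bands whose gridded statistics enter the optical feature set.
FEATURE_INDICES <- c("EVI", "GCVI", "LSWI", "REPI", "NDPI")
FEATURE_BANDS <- c(re1 = "b5", re2 = "b6", re3 = "b7",
                   swir1 = "b11", swir2 = "b12")
STAT_NAMES <- c("min", "max", "std", "p15", "p50", "p90")

#' Six summary statistics of a gridded series
#'
#' Minimum, maximum, standard deviation and the 15th/50th/90th percentiles
#' (linear interpolation between order statistics).
#'
#' @param x gap-free [gridded_series()] or numeric vector.
#' @return Named numeric vector `min, max, std, p15, p50, p90`.
#' @export
series_statistics <- function(x) {
  v <- if (inherits(x, "gridded_series")) x$values else as.numeric(x)
  if (!length(v)) stop("empty series")
  if (anyNA(v)) stop("series_statistics requires a gap-free series")
  q <- stats::quantile(v, c(0.15, 0.50, 0.90), names = FALSE, type = 7)
  c(min = min(v), max = max(v), std = stats::sd(v),
    p15 = q[1], p50 = q[2], p90 = q[3])
}

#' Harmonic (trend + Fourier) fit of a time series
#'
#' Ordinary least squares on the basis `{1, t, cos(2 pi m w t),
#' sin(2 pi m w t)}` for harmonics `m = 1..M` with `w = 1/365`, fitted to
#' the valid raw observations. The per-harmonic amplitude is the magnitude
#' of the coefficient vector `(C_m, D_m)` and the phase its angle
#' (`atan2(D_m, C_m)`, radians in (-pi, pi]).
#'
#' @param times day-of-year vector (or an [index_series()], in which case
#'   `values` is ignored).
#' @param values observations (`NA` dropped).
#' @param M number of harmonics (default 2).
#' @param omega base frequency, default `1/365`.
#' @return An object of class `harmonic_fit` with `a`, `b`, `C`, `D`,
#'   `amplitude`, `phase`, `residual_sd`, `fitted`.
#' @export
harmonic_fit <- function(times, values = NULL, M = 2, omega = 1 / 365) {
  if (inherits(times, "index_series")) {
    values <- times$values
    times <- times$times
  }
  ok <- is.finite(values)
  t <- times[ok]; y <- values[ok]
  if (length(y) < 2 * M + 2)
    stop("harmonic fit with M = ", M, " needs at least ", 2 * M + 2,
         " observations, got ", length(y))
  X <- cbind(1, t)
  for (m in seq_len(M))
    X <- cbind(X, cos(2 * pi * m * omega * t), sin(2 * pi * m * omega * t))
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) stop("rank-deficient harmonic design matrix")
  cf <- fit$coefficients
  C <- cf[2 + 2 * seq_len(M) - 1]
  D <- cf[2 + 2 * seq_len(M)]
  structure(list(a = unname(cf[1]), b = unname(cf[2]),
                 C = unname(C), D = unname(D),
                 amplitude = unname(sqrt(C^2 + D^2)),
                 phase = unname(atan2(D, C)),
                 residual_sd = stats::sd(fit$residuals),
                 fitted = unname(fit$fitted.values), M = M, omega = omega),
            class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat("<harmonic_fit> M =", x$M, "\n")
  cat(sprintf("  a = %.4f, b = %.5f\n", x$a, x$b))
  for (m in seq_len(x$M))
    cat(sprintf("  harmonic %d: amplitude %.4f, phase %.4f rad\n",
                m, x$amplitude[m], x$phase[m]))
  invisible(x)
}

#' Accumulated-biomass EVI integrals
#'
#' Trapezoidal EVI integrals over the green-up phase `[SOS, POS]` and the
#' senescence phase `[POS, EOS]`; their sum equals the full
#' [seasonal_integral()].
#'
#' @param evi gap-free EVI [gridded_series()].
#' @param phen the sample's `phenology`.
#' @return Named numeric vector `accum_green, accum_senes`.
#' @export
accumulated_evi <- function(evi, phen) {
  green <- seasonal_integral(evi, list(sos = phen$sos, eos = phen$pos))
  senes <- seasonal_integral(evi, list(sos = phen$pos, eos = phen$eos))
  c(accum_green = green, accum_senes = senes)
}

#' Temporal principal-component scores
#'
#' Centres each time step (column) across samples and projects onto the
#' leading eigenvectors of the temporal covariance. Eigenvector signs
#' follow a deterministic rule — the largest-magnitude loading is made
#' positive — so scores are reproducible.
#'
#' @param x samples-by-time numeric matrix, gap-free.
#' @param k number of components (default 3).
#' @return List with `scores` (n x k), `loadings`, `var_explained`.
#' @export
temporal_pca <- function(x, k = 3) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("temporal_pca requires a gap-free matrix")
  if (ncol(x) < k) stop("need at least k = ", k, " time steps")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (rank < k) {
    warning("matrix rank ", rank, " < k = ", k, "; returning ", rank,
            " components")
    k <- rank
  }
  L <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(L, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  L <- sweep(L, 2, flip, `*`)
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  colnames(scores) <- paste0("pc", seq_len(k))
  list(scores = scores, loadings = L,
       var_explained = pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2))
}

#' Select the top-ranked features by random-forest importance
#'
#' Fits a seeded importance-ranking random forest and keeps the
#' `ceiling(fraction * N)` features with the highest mean impurity
#' importance (ties broken by name for determinism).
#'
#' @param x feature data frame or matrix.
#' @param labels class factor (>= 2 classes).
#' @param fraction fraction of features to keep (default 0.5).
#' @param seed integer seed.
#' @param ntree trees in the ranking forest.
#' @return Character vector of selected feature names.
#' @export
select_features <- function(x, labels, fraction = 0.5, seed = 999L,
                            ntree = 200) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("feature selection needs >= 2 classes")
  x <- as.data.frame(x)
  set.seed(seed)
  rf <- randomForest::randomForest(x, labels, ntree = ntree,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 2)[, 1]
  ord <- order(-imp, names(imp))
  keep <- ceiling(fraction * length(imp))
  names(imp)[ord][seq_len(keep)]
}

# --- feature-table assembly ----------------------------------------------

# Optical feature vector (69 features) for one sample.
optical_features <- function(refl, config = pipeline_config()) {
  grid <- config$grid
  w <- config$sg_window; o <- config$sg_order
  gb <- lapply(BAND_NAMES, function(b)
    regularize(band_series(refl, b), grid, w, o,
               smooth = config$smooth_before_indices))
  names(gb) <- BAND_NAMES
  bl <- lapply(gb, `[[`, "values")
  out <- numeric(0)
  for (nm in FEATURE_INDICES) {
    g <- gridded_series(grid, .index_value(bl, nm, config$osavi_standard,
                                           config$div_eps), name = nm)
    if (!config$smooth_before_indices)
      g <- sg_smooth(g, w, o)
    s <- series_statistics(g)
    names(s) <- paste(tolower(nm), STAT_NAMES, sep = "_")
    out <- c(out, s)
  }
  for (b in names(FEATURE_BANDS)) {
    s <- series_statistics(gb[[b]])
    names(s) <- paste(FEATURE_BANDS[b], STAT_NAMES, sep = "_")
    out <- c(out, s)
  }
  evi_g <- gridded_series(grid, .index_value(bl, "EVI", FALSE,
                                             config$div_eps), name = "EVI")
  if (!config$smooth_before_indices) evi_g <- sg_smooth(evi_g, w, o)
  phen <- extract_phenology(evi_g)
  out <- c(out, sos = phen$sos, eos = phen$eos, los = phen$los)
  # harmonics are fitted to the raw (unsmoothed) valid EVI observations
  hf <- harmonic_fit(compute_index(refl, "EVI",
                                   osavi_standard = config$osavi_standard,
                                   eps = config$div_eps), M = 2)
  out <- c(out, evi_amp1 = hf$amplitude[1], evi_phase1 = hf$phase[1],
           evi_amp2 = hf$amplitude[2], evi_phase2 = hf$phase[2])
  c(out, stats::setNames(accumulated_evi(evi_g, phen),
                         c("evi_accum_green", "evi_accum_senes")))
}

# SAR statistical features (35) for one sample; PCA scores are appended at
# table level by build_feature_table().
sar_stat_features <- function(sar, config = pipeline_config()) {
  out <- numeric(0)
  for (p in SAR_PARAMS) {
    g <- fill_gaps(composite(sar_parameter(sar, p,
                                           db_domain = config$sar_db_domain,
                                           eps = config$div_eps),
                             config$grid))
    v <- g$values
    s <- c(max = max(v), min = min(v), mean = mean(v), std = stats::sd(v),
           stats::setNames(stats::quantile(v, c(0.15, 0.5, 0.9),
                                           names = FALSE, type = 7),
                           c("p15", "p50", "p90")))
    names(s) <- paste("sar", tolower(p), names(s), sep = "_")
    out <- c(out, s)
  }
  out
}

# gridded SAR parameter values for the temporal PCA (one row per sample)
sar_gridded_values <- function(sar, param, config) {
  fill_gaps(composite(sar_parameter(sar, param,
                                    db_domain = config$sar_db_domain,
                                    eps = config$div_eps),
                      config$grid))$values
}

#' Build the full classification feature table
#'
#' Assembles, per sample, the 69 optical features (six statistics for each
#' of five indices and five bands, SOS/EOS/LOS, amplitude and phase of two
#' EVI harmonics, and two accumulated-EVI integrals) and the 50 SAR
#' features (seven statistics for each of five parameters plus three
#' temporal principal-component scores per parameter). SAR PCA is computed
#' across the whole table, so scores are only defined relative to the set
#' of samples passed in.
#'
#' @param series named list of [refl_series()].
#' @param sar named list of [sar_series()] (same names); omit for an
#'   optical-only table.
#' @param config a [pipeline_config()].
#' @return Data frame, one row per sample (rownames = ids).
#' @export
build_feature_table <- function(series, sar = NULL,
                                config = pipeline_config()) {
  ids <- names(series)
  if (is.null(ids)) ids <- as.character(seq_along(series))
  opt <- do.call(rbind, lapply(series, optical_features, config = config))
  out <- as.data.frame(opt)
  if (!is.null(sar)) {
    stopifnot(length(sar) == length(series))
    sar_stats <- do.call(rbind, lapply(sar, sar_stat_features,
                                       config = config))
    out <- cbind(out, as.data.frame(sar_stats))
    for (p in SAR_PARAMS) {
      m <- do.call(rbind, lapply(sar, sar_gridded_values, param = p,
                                 config = config))
      sc <- temporal_pca(m, k = 3)$scores
      colnames(sc) <- paste("sar", tolower(p), colnames(sc), sep = "_")
      out <- cbind(out, as.data.frame(sc))
    }
  }
  rownames(out) <- ids
  out
}
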