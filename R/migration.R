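# Training-sample migration: CCI screening of candidate cropland points and
# confirmation against two trivariate Gaussian models of growing-season
# curve integrals fitted to reference soybean points.

#' Concave-Convexity Index of the TCARI/OSAVI curve
#'
#' `CCI = 2 ratio(POS) - [ratio(SOS) + ratio(EOS)]`, evaluated on the
#' gridded TCARI/OSAVI ratio by linear interpolation at the (possibly
#' fractional) phenological dates. High-chlorophyll crops (soybean, corn,
#' rice) trace a concave ratio curve, so `CCI < 0` flags a potential
#' soybean point; `CCI >= 0` flags a potential non-soybean point.
#'
#' @param ratio gap-free [gridded_series()] of TCARI/OSAVI.
#' @param phen the sample's `phenology`.
#' @return Numeric scalar.
#' @export
compute_cci <- function(ratio, phen) {
  stopifnot(inherits(ratio, "gridded_series"))
  v <- interp_grid(ratio, c(phen$sos, phen$pos, phen$eos))
  if (anyNA(v) || any(!is.finite(v)))
    stop("TCARI/OSAVI ratio is not finite at SOS/POS/EOS")
  2 * v[2] - (v[1] + v[3])
}

#' Mahalanobis distance to a fitted group model
#'
#' `sqrt((x - mu)' Sigma^-1 (x - mu))`, computed through the Cholesky
#' factor of the covariance (no explicit inverse).
#'
#' @param x numeric vector of length 3, or a matrix with 3 columns (one row
#'   per point).
#' @param model a `soy_group_model` (or any list with `mu` and `chol`, the
#'   upper-triangular Cholesky factor of `Sigma`).
#' @return Numeric distance(s), `>= 0`.
#' @export
mahalanobis_distance <- function(x, model) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (any(!is.finite(x))) stop("non-finite input to mahalanobis_distance")
  d <- sweep(x, 2, model$mu)
  z <- backsolve(model$chol, t(d), transpose = TRUE)
  sqrt(colSums(z^2))
}

# log density of the fitted trivariate Gaussian at squared distance d2
.log_density <- function(model, d2) {
  -0.5 * d2 - 1.5 * log(2 * pi) - 0.5 * model$logdet
}

#' Fit a trivariate Gaussian group model with migration thresholds
#'
#' Fits the multivariate Gaussian assumed for one integral group (high or
#' low) of reference soybean points: `mu` is the sample mean and `Sigma`
#' the sample covariance (ridge-regularized when ill-conditioned). The
#' density level `p50` bounding the central 50%-probability region is
#' estimated by Monte Carlo as the median density of `n_mc` seeded draws
#' from the fitted Gaussian; reference points denser than `p50` are the
#' "robust" exemplars (equivalently, points within the Mahalanobis radius
#' `r50` implied by `p50`). The soybean admission threshold is the 90th
#' percentile of the robust points' Mahalanobis distances and the
#' non-soybean rejection threshold the 95th percentile over all reference
#' points.
#'
#' @param reference_integrals matrix (n x 3) of group integral vectors for
#'   the reference soybean points, `n >= min_n`.
#' @param group `"high"` or `"low"`.
#' @param n_mc Monte-Carlo draws for `p50` (default 1e5).
#' @param seed integer seed for the Monte-Carlo draws.
#' @param soy_pct,nonsoy_pct threshold percentiles (defaults 0.90, 0.95).
#' @param min_n minimum reference count (default 30).
#' @param ridge_lambda,cond_max ridge `lambda * trace(Sigma)/3` is added to
#'   the diagonal when the condition number exceeds `cond_max`.
#' @return An object of class `soy_group_model`.
#' @export
fit_group_model <- function(reference_integrals, group = c("high", "low"),
                            n_mc = 1e5, seed = 1L, soy_pct = 0.90,
                            nonsoy_pct = 0.95, min_n = 30,
                            ridge_lambda = 1e-6, cond_max = 1e8) {
  group <- match.arg(group)
  X <- as.matrix(reference_integrals)
  if (ncol(X) != 3) stop("reference integrals must have 3 columns")
  if (nrow(X) < min_n)
    stop("need at least ", min_n, " reference points to fit a 3-D Gaussian, ",
         "got ", nrow(X), "; supply more ground-survey soybean samples")
  if (any(!is.finite(X))) stop("non-finite reference integrals")
  mu <- colMeans(X)
  Sigma <- stats::cov(X)
  if (kappa(Sigma, exact = TRUE) > cond_max)
    Sigma <- Sigma + ridge_lambda * mean(diag(Sigma)) * diag(3)
  R <- tryCatch(chol(Sigma),
                error = function(e) stop("singular covariance after ",
                                         "regularization: ", conditionMessage(e)))
  model <- list(group = group, mu = mu, Sigma = Sigma, chol = R,
                logdet = 2 * sum(log(diag(R))), n_fit = nrow(X))

  # Monte-Carlo estimate of the median density of the fitted Gaussian
  set.seed(seed)
  draws <- MASS::mvrnorm(n_mc, mu = mu, Sigma = Sigma)
  d2 <- mahalanobis_distance(draws, model)^2
  p50 <- stats::median(exp(.log_density(model, d2)))
  # Mahalanobis radius at which the density equals p50
  r50 <- sqrt(-2 * (log(p50) + 1.5 * log(2 * pi) + 0.5 * model$logdet))

  d_ref <- mahalanobis_distance(X, model)
  robust <- d_ref < r50
  if (!any(robust)) stop("no robust reference points below the p50 radius")
  soy_thresh <- unname(stats::quantile(d_ref[robust], soy_pct))
  nonsoy_thresh <- unname(stats::quantile(d_ref, nonsoy_pct))
  if (soy_thresh > r50 + 1e-9)
    stop("internal invariant violated: soy threshold exceeds r50")
  if (nonsoy_thresh < soy_thresh)
    stop("internal invariant violated: non-soy threshold below soy threshold")
  model$p50 <- p50
  model$r50 <- r50
  model$soy_thresh <- soy_thresh
  model$nonsoy_thresh <- nonsoy_thresh
  model$n_robust <- sum(robust)
  model$n_mc <- n_mc
  model$seed <- seed
  class(model) <- "soy_group_model"
  model
}

#' @export
print.soy_group_model <- function(x, ...) {
  cat("<soy_group_model> ", x$group, "-value group, fitted on ", x$n_fit,
      " reference points (", x$n_robust, " robust)\n", sep = "")
  cat(sprintf("  mu = (%.3f, %.3f, %.3f)\n", x$mu[1], x$mu[2], x$mu[3]))
  cat(sprintf("  p50 = %.4g  r50 = %.4f\n", x$p50, x$r50))
  cat(sprintf("  D_Soy-Thresh = %.4f  D_NonSoy-Thresh = %.4f\n",
              x$soy_thresh, x$nonsoy_thresh))
  invisible(x)
}

#' @export
coef.soy_group_model <- function(object, ...) {
  c(stats::setNames(object$mu, paste0("mu", 1:3)),
    p50 = object$p50, r50 = object$r50,
    soy_thresh = object$soy_thresh, nonsoy_thresh = object$nonsoy_thresh)
}

#' Decision rule for one candidate point
#'
#' A candidate is admitted as soybean iff its CCI is negative and both
#' Mahalanobis distances fall below the respective soybean thresholds; it is
#' admitted as non-soybean iff both distances exceed the respective
#' non-soybean thresholds (CCI plays no role in the non-soybean rule).
#' Anything else remains `cropland_unknown` and is discarded from training.
#'
#' @param cci the candidate's Concave-Convexity Index.
#' @param d_high,d_low Mahalanobis distances to the two group models.
#' @param high_model,low_model fitted `soy_group_model`s.
#' @return One of `"soybean"`, `"non_soybean"`, `"cropland_unknown"`.
#' @export
classify_candidate <- function(cci, d_high, d_low, high_model, low_model) {
  if (cci < 0 && d_high < high_model$soy_thresh &&
      d_low < low_model$soy_thresh) return("soybean")
  if (d_high > high_model$nonsoy_thresh &&
      d_low > low_model$nonsoy_thresh) return("non_soybean")
  "cropland_unknown"
}

#' Choose the reference survey set for a target region-year
#'
#' Implements the migration-priority strategy: ground-survey samples from
#' the same region are preferred (temporal migration; smallest year gap
#' first), then samples from the same year in the climatically nearest
#' other region (spatial migration), then samples differing in both
#' (spatiotemporal migration; nearest year, then nearest climate zone).
#' Ties break by smaller absolute year gap, then lexicographic region id.
#'
#' @param region,year the target region id and year.
#' @param inventory data frame with columns `region`, `year` and optionally
#'   a numeric `climate_zone`.
#' @return List with `region`, `year` (the chosen source set), `strategy`
#'   (`"temporal"`, `"spatial"` or `"spatiotemporal"`) and `delta_year`.
#' @export
select_reference_set <- function(region, year, inventory) {
  if (!nrow(inventory)) stop("empty survey inventory")
  inv <- unique(inventory[, intersect(c("region", "year", "climate_zone"),
                                      names(inventory)), drop = FALSE])
  if (is.null(inv$climate_zone)) inv$climate_zone <- 0
  tz <- inv$climate_zone[match(region, inv$region)]
  if (is.na(tz)) tz <- 0
  inv$dyear <- abs(inv$year - year)
  inv$dzone <- abs(inv$climate_zone - tz)

  pick <- function(rows, ord) rows[ord, , drop = FALSE][1, , drop = FALSE]
  same_r <- inv[inv$region == region, , drop = FALSE]
  if (nrow(same_r)) {
    ch <- pick(same_r, order(same_r$dyear, same_r$region))
    strategy <- "temporal"
  } else {
    same_y <- inv[inv$year == year, , drop = FALSE]
    if (nrow(same_y)) {
      ch <- pick(same_y, order(same_y$dzone, same_y$dyear, same_y$region))
      strategy <- "spatial"
    } else {
      ch <- pick(inv, order(inv$dyear, inv$dzone, inv$region))
      strategy <- "spatiotemporal"
    }
  }
  list(region = ch$region, year = ch$year, strategy = strategy,
       delta_year = ch$year - year)
}

# Full per-sample time-series workflow: smooth the nine bands, derive the
# curves needed for screening, extract phenology, integrals and CCI.
process_sample <- function(refl, config = pipeline_config()) {
  grid <- config$grid
  w <- config$sg_window; o <- config$sg_order
  gb <- lapply(BAND_NAMES, function(b)
    regularize(band_series(refl, b), grid, w, o,
               smooth = config$smooth_before_indices))
  names(gb) <- BAND_NAMES
  bl <- lapply(gb, `[[`, "values")
  idx <- function(nm) {
    v <- .index_value(bl, nm, config$osavi_standard, config$div_eps)
    gridded_series(grid, v, name = nm)
  }
  curves <- list(EVI = idx("EVI"), LSWI = idx("LSWI"),
                 RENDVI = idx("RENDVI"), REPI = idx("REPI"),
                 ratio = idx("TCARI_OSAVI"),
                 re2 = gb$re2, swir2 = gb$swir2)
  if (!config$smooth_before_indices)
    curves <- lapply(curves, sg_smooth, window = w, order = o)
  phen <- extract_phenology(curves$EVI)
  ints <- integral_vectors(curves, phen)
  cci <- compute_cci(curves$ratio, phen)
  list(phen = phen, integrals = ints, cci = cci)
}

#' Migrate soybean training samples to a candidate pool
#'
#' The central fit of the package. From reference (ground-survey) soybean
#' points with optical time series, the two trivariate Gaussian group
#' models are fitted on growing-season curve integrals — the high-value
#' group (EVI, RE2, SWIR2) and the low-value group (LSWI, RENDVI, REPI) —
#' together with Monte-Carlo `p50` density levels and Mahalanobis-distance
#' thresholds. Every candidate cropland point is then screened by its CCI
#' and its distances to the two models, and labelled soybean, non-soybean
#' or discarded.
#'
#' @param reference list of [refl_series()] for the reference soybean
#'   points (named by point id), or a list with elements `series` and
#'   `points` (a data frame with at least `id`).
#' @param candidates same structure for the candidate cropland points; may
#'   be empty.
#' @param config a [pipeline_config()].
#' @return An object of class `soy_migration`: fitted `high_model` and
#'   `low_model`, a per-candidate `audit` data frame (id, cci, d_high,
#'   d_low, decision), `labels` (the soybean/non-soybean subset with
#'   provenance `"generated"`), per-stage `counts`, and the reference
#'   integral matrices.
#' @export
migrate_samples <- function(reference, candidates = list(),
                            config = pipeline_config()) {
  unwrap <- function(x) if (!is.null(x$series)) x$series else x
  ref_series <- unwrap(reference)
  cand_series <- unwrap(candidates)
  if (length(ref_series) < config$min_ref)
    stop("need at least ", config$min_ref, " reference soybean points, got ",
         length(ref_series))

  ref_proc <- lapply(ref_series, process_sample, config = config)
  ref_int <- do.call(rbind, lapply(ref_proc, `[[`, "integrals"))
  high_model <- fit_group_model(ref_int[, 1:3], "high", n_mc = config$n_mc,
                                seed = config$mc_seed,
                                soy_pct = config$soy_pct,
                                nonsoy_pct = config$nonsoy_pct,
                                min_n = config$min_ref)
  low_model <- fit_group_model(ref_int[, 4:6], "low", n_mc = config$n_mc,
                               seed = config$mc_seed,
                               soy_pct = config$soy_pct,
                               nonsoy_pct = config$nonsoy_pct,
                               min_n = config$min_ref)

  audit <- data.frame(id = character(0), cci = numeric(0),
                      d_high = numeric(0), d_low = numeric(0),
                      decision = character(0), stringsAsFactors = FALSE)
  if (length(cand_series)) {
    cand_proc <- lapply(cand_series, process_sample, config = config)
    cand_int <- do.call(rbind, lapply(cand_proc, `[[`, "integrals"))
    cci <- vapply(cand_proc, `[[`, numeric(1), "cci")
    d_high <- mahalanobis_distance(cand_int[, 1:3], high_model)
    d_low <- mahalanobis_distance(cand_int[, 4:6], low_model)
    decision <- mapply(classify_candidate, cci, d_high, d_low,
                       MoreArgs = list(high_model = high_model,
                                       low_model = low_model))
    ids <- names(cand_series)
    if (is.null(ids)) ids <- as.character(seq_along(cand_series))
    audit <- data.frame(id = ids, cci = unname(cci),
                        d_high = unname(d_high), d_low = unname(d_low),
                        decision = unname(decision),
                        stringsAsFactors = FALSE)
  }
  labels <- audit[audit$decision != "cropland_unknown",
                  c("id", "decision"), drop = FALSE]
  names(labels) <- c("id", "label")
  if (nrow(labels)) labels$provenance <- "generated"
  counts <- c(n_reference = length(ref_series),
              n_candidates = nrow(audit),
              n_cci_soy = sum(audit$cci < 0),
              n_soybean = sum(audit$decision == "soybean"),
              n_non_soybean = sum(audit$decision == "non_soybean"),
              n_discarded = sum(audit$decision == "cropland_unknown"))
  structure(list(high_model = high_model, low_model = low_model,
                 audit = audit, labels = labels, counts = counts,
                 reference_integrals = ref_int, config = config),
            class = "soy_migration")
}

#' @export
print.soy_migration <- function(x, ...) {
  cat("<soy_migration> fitted on", x$counts["n_reference"],
      "reference soybean points\n")
  cat("  candidates:", x$counts["n_candidates"],
      "| soybean:", x$counts["n_soybean"],
      "| non-soybean:", x$counts["n_non_soybean"],
      "| discarded:", x$counts["n_discarded"], "\n")
  invisible(x)
}

#' @export
summary.soy_migration <- function(object, ...) {
  cat("Training-sample migration\n")
  cat("=========================\n")
  print(object$high_model)
  print(object$low_model)
  cat("Filter-stage counts:\n")
  print(object$counts)
  if (nrow(object$audit)) {
    cat("CCI range: [", sprintf("%.3f", min(object$audit$cci)), ", ",
        sprintf("%.3f", max(object$audit$cci)), "]\n", sep = "")
  }
  invisible(object)
}

#' @export
coef.soy_migration <- function(object, ...) {
  list(high = coef(object$high_model), low = coef(object$low_model))
}

#' Classify new candidate points with fitted migration models
#'
#' @param object a fitted `soy_migration`.
#' @param newdata list of [refl_series()] (named by id), or a list with a
#'   `series` element.
#' @param ... unused.
#' @return Audit data frame (id, cci, d_high, d_low, decision).
#' @export
predict.soy_migration <- function(object, newdata, ...) {
  series <- if (!is.null(newdata$series)) newdata$series else newdata
  proc <- lapply(series, process_sample, config = object$config)
  ints <- do.call(rbind, lapply(proc, `[[`, "integrals"))
  cci <- vapply(proc, `[[`, numeric(1), "cci")
  d_high <- mahalanobis_distance(ints[, 1:3], object$high_model)
  d_low <- mahalanobis_distance(ints[, 4:6], object$low_model)
  decision <- mapply(classify_candidate, cci, d_high, d_low,
                     MoreArgs = list(high_model = object$high_model,
                                     low_model = object$low_model))
  ids <- names(series)
  if (is.null(ids)) ids <- as.character(seq_along(series))
  data.frame(id = ids, cci = unname(cci), d_high = unname(d_high),
             d_low = unname(d_low), decision = unname(decision),
             stringsAsFactors = FALSE)
}

#' Plot the migration feature space
#'
#' Scatter of candidate Mahalanobis distances with the admission/rejection
#' thresholds of both group models.
#'
#' @param x a `soy_migration`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.soy_migration <- function(x, ...) {
  a <- x$audit
  if (!nrow(a)) stop("no candidates to plot")
  cols <- c(soybean = "forestgreen", non_soybean = "tan3",
            cropland_unknown = "grey60")
  graphics::plot(a$d_high, a$d_low, col = cols[a$decision], pch = 16,
                 xlab = "Mahalanobis distance, high-value group",
                 ylab = "Mahalanobis distance, low-value group", ...)
  graphics::abline(v = x$high_model$soy_thresh, col = "forestgreen",
                   lty = 2)
  graphics::abline(h = x$low_model$soy_thresh, col = "forestgreen", lty = 2)
  graphics::abline(v = x$high_model$nonsoy_thresh, col = "tan3", lty = 3)
  graphics::abline(h = x$low_model$nonsoy_thresh, col = "tan3", lty = 3)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16,
                   bty = "n")
  invisible(x)
}

# --- cropland point generation -------------------------------------------

# uniform points inside a flat-topped hexagon centred at (cx, cy)
.hex_points <- function(cx, cy, radius, n) {
  pts <- matrix(numeric(0), 0, 2)
  while (nrow(pts) < n) {
    x <- stats::runif(2 * n, -radius, radius)
    y <- stats::runif(2 * n, -radius, radius)
    # point-in-hexagon (pointy-top, circumradius = radius)
    q <- abs(x) * sqrt(3) / 2 + abs(y) / 2
    keep <- q <= radius * sqrt(3) / 2 & abs(y) <= radius * sqrt(3) / 2
    pts <- rbind(pts, cbind(x[keep], y[keep]))
  }
  cbind(cx + pts[1:n, 1], cy + pts[1:n, 2])
}

#' Generate candidate cropland points by hexagonal sampling
#'
#' Tessellates the land-cover raster extent with hexagons, scatters uniform
#' random points inside each, and keeps a point as `cropland_unknown` iff
#' the cropland class covers more than `purity` of the raster cells whose
#' centres fall within `buffer_radius` of the point.
#'
#' @param landcover a categorical [soy_raster()] in metric coordinates.
#' @param cropland_code raster value denoting cropland.
#' @param hex_spacing hexagon centre spacing in metres.
#' @param points_per_hex random points per hexagon.
#' @param buffer_radius purity buffer radius in metres (default 50).
#' @param purity minimum cropland fraction in the buffer (default 0.90,
#'   must be in (0.5, 1]).
#' @param seed integer seed; the point set is deterministic given the seed.
#' @return Data frame of retained points: `id`, `x`, `y`, `label`
#'   (`"cropland_unknown"`), `provenance` (`"generated"`).
#' @export
sample_cropland <- function(landcover, cropland_code, hex_spacing = 300,
                            points_per_hex = 3, buffer_radius = 50,
                            purity = 0.90, seed = 1L) {
  stopifnot(inherits(landcover, "soy_raster"))
  if (purity <= 0.5 || purity > 1) stop("purity must be in (0.5, 1]")
  if (!any(landcover$values == cropland_code, na.rm = TRUE))
    stop("raster contains no cells with the cropland code ", cropland_code)
  set.seed(seed)
  co <- raster_coords(landcover)
  xr <- range(co$x); yr <- range(co$y)
  r_hex <- hex_spacing / sqrt(3)   # circumradius for given centre spacing
  dy <- hex_spacing * sqrt(3) / 2
  rows <- seq(yr[1], yr[2], by = dy)
  out <- list()
  k <- 0L
  for (i in seq_along(rows)) {
    offs <- if (i %% 2 == 0) hex_spacing / 2 else 0
    for (cx in seq(xr[1] + offs, xr[2], by = hex_spacing)) {
      k <- k + 1L
      out[[k]] <- .hex_points(cx, rows[i], r_hex, points_per_hex)
    }
  }
  pts <- do.call(rbind, out)
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    dx <- abs(co$x - pts[i, 1])
    dyv <- abs(co$y - pts[i, 2])
    ix <- which(dx <= buffer_radius)
    iy <- which(dyv <= buffer_radius)
    if (!length(ix) || !length(iy)) return(FALSE)
    sub <- landcover$values[iy, ix, drop = FALSE]
    dmat <- outer(dyv[iy]^2, dx[ix]^2, `+`)
    inb <- dmat <= buffer_radius^2
    if (!any(inb)) return(FALSE)
    mean(sub[inb] == cropland_code, na.rm = TRUE) > purity
  }, logical(1))
  pts <- pts[keep, , drop = FALSE]
  if (!nrow(pts)) warning("no points met the cropland purity criterion")
  data.frame(id = sprintf("pt%05d", seq_len(nrow(pts))),
             x = pts[, 1], y = pts[, 2],
             label = "cropland_unknown", provenance = "generated",
             stringsAsFactors = FALSE)
}
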