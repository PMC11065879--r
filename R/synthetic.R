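# Synthetic multi-crop scene generator: seasonal reflectance and SAR
# trajectories, patchy land cover, and labelled desk-scale scenes with
# known truth for scoring migration and classification.

#' Load the crop archetype catalogue
#'
#' Archetypes are defined in one configuration file
#' (`inst/extdata/archetypes.yaml`): per-crop double-logistic phenology,
#' per-band base/peak reflectance, a chlorophyll-dynamics exponent that
#' makes the TCARI/OSAVI curve concave (high-chlorophyll crops: soybean,
#' corn, rice) or convex (peanut, cotton, potato), observation noise and
#' cloud-gap probability, plus shared SAR trajectory parameters.
#'
#' @param path alternative YAML file; defaults to the packaged catalogue.
#' @return List with `crops` (named archetype list), `base_reflectance`,
#'   `optical`, `sar` and `jitter` settings.
#' @export
crop_archetypes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "archetypes.yaml",
                        package = "phenomigrate")
  cfg <- yaml::read_yaml(path)
  cfg$base_reflectance <- unlist(cfg$base_reflectance)[BAND_NAMES]
  cfg$crops <- lapply(cfg$crops, function(a) {
    a$peak <- unlist(a$peak)[BAND_NAMES]
    a
  })
  cfg
}

# normalized double-logistic canopy development driver on [0, 1]
.canopy_driver <- function(t, a) {
  g <- 1 / (1 + exp(-(t - a$sos50) / a$growth_rate)) -
    1 / (1 + exp(-(t - a$eos50) / a$senescence_rate))
  gmax <- max(1 / (1 + exp(-(seq(60, 340, 0.5) - a$sos50) / a$growth_rate)) -
                1 / (1 + exp(-(seq(60, 340, 0.5) - a$eos50) /
                               a$senescence_rate)))
  pmax(g, 0) / gmax
}

# noiseless band reflectance matrix for archetype `a` at times `t`
.archetype_bands <- function(t, a, base) {
  g <- .canopy_driver(t, a)
  sapply(BAND_NAMES, function(b) {
    gg <- if (b %in% c("red", "re1")) g^a$chl_exponent else g
    base[b] + (a$peak[b] - base[b]) * gg
  })
}

#' Simulate one sample's optical and SAR time series
#'
#' Band trajectories follow the archetype's double-logistic canopy driver
#' with band-specific base/peak levels and the chlorophyll-dynamics
#' exponent on the pigment bands, plus Gaussian observation noise.
#' Observation dates run at a 5-day cadence through the season and are
#' thinned by the cloud-gap probability; SAR backscatter rises with canopy
#' development at a 12-day cadence. Deterministic under `seed`.
#'
#' @param crop crop name from the archetype catalogue, or an archetype
#'   list.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param noise,gaps disable to obtain the noiseless / gap-free signal.
#' @param catalogue a [crop_archetypes()] catalogue.
#' @return List with `refl` ([refl_series()]) and `sar` ([sar_series()]).
#' @export
simulate_series <- function(crop = "soybean", seed = NULL, noise = TRUE,
                            gaps = TRUE, catalogue = crop_archetypes()) {
  a <- if (is.character(crop)) {
    if (!crop %in% names(catalogue$crops))
      stop("unknown crop archetype: ", crop)
    catalogue$crops[[crop]]
  } else crop
  if (!is.null(seed)) set.seed(seed)
  opt <- catalogue$optical
  t <- seq(opt$first_doy, opt$last_doy, by = opt$cadence_days)
  if (gaps) {
    keep <- stats::runif(length(t)) > a$gap_prob
    keep[sample(length(t), 3)] <- TRUE   # never lose the whole season
    t <- t[keep]
  }
  bands <- .archetype_bands(t, a, catalogue$base_reflectance)
  if (noise)
    bands <- bands + matrix(stats::rnorm(length(bands), 0, a$noise_sd),
                            nrow(bands))
  bands <- pmax(bands, 0)
  refl <- refl_series(t, bands)

  s <- catalogue$sar
  ts <- seq(opt$first_doy, opt$last_doy, by = s$cadence_days)
  g <- .canopy_driver(ts, a)
  vh <- s$vh_base_db + s$vh_range_db * g
  vv <- s$vv_base_db + s$vv_range_db * g
  if (noise) {
    vh <- vh + stats::rnorm(length(ts), 0, s$noise_db)
    vv <- vv + stats::rnorm(length(ts), 0, s$noise_db)
  }
  list(refl = refl, sar = sar_series(ts, vh, vv))
}

# per-point field variability: season timing shifts, drawn from the
# current RNG stream
.jitter_archetype <- function(a, jit) {
  a$sos50 <- a$sos50 + stats::rnorm(1, 0, jit$season_sd_days)
  a$eos50 <- a$eos50 + stats::rnorm(1, 0, jit$season_sd_days)
  a
}

# canopy vigor scales the dynamic range around the soil base
.apply_vigor <- function(a, base, vigor) {
  a$peak <- base + (a$peak - base) * vigor
  a
}

#' Simulate a patchy categorical land-cover raster
#'
#' Patch seeds are scattered uniformly, each seed receives a class with
#' counts proportional to the requested mix, and every cell takes the
#' class of its nearest seed, producing contiguous irregular patches.
#' Deterministic under `seed`. Class codes follow a WorldCover-like
#' convention: tree 10, grass 30, cropland 40, built 50, water 80.
#'
#' @param nrow,ncol raster dimensions.
#' @param cellsize cell size in metres.
#' @param mix named class fractions summing to 1 (names from `tree`,
#'   `grass`, `cropland`, `built`, `water`).
#' @param n_patches number of patch seeds.
#' @param seed integer seed.
#' @return A categorical [soy_raster()].
#' @export
simulate_landcover <- function(nrow = 100, ncol = 100, cellsize = 10,
                               mix = c(cropland = 0.6, tree = 0.15,
                                       grass = 0.15, water = 0.05,
                                       built = 0.05),
                               n_patches = 150, seed = 1L) {
  codes <- c(tree = 10, grass = 30, cropland = 40, built = 50, water = 80)
  if (is.null(names(mix)) || !all(names(mix) %in% names(codes)))
    stop("mix must be named with classes from: ",
         paste(names(codes), collapse = ", "))
  if (abs(sum(mix) - 1) > 1e-6) stop("class mix must sum to 1")
  set.seed(seed)
  counts <- round(n_patches * mix)
  while (sum(counts) < n_patches) counts[which.max(mix)] <-
      counts[which.max(mix)] + 1
  while (sum(counts) > n_patches) counts[which.max(counts)] <-
      counts[which.max(counts)] - 1
  cls <- sample(rep(codes[names(counts)], counts))
  sx <- stats::runif(n_patches, 0, ncol * cellsize)
  sy <- stats::runif(n_patches, 0, nrow * cellsize)
  xs <- (seq_len(ncol) - 0.5) * cellsize
  ys <- (nrow - seq_len(nrow) + 0.5) * cellsize
  near <- vapply(seq_len(nrow), function(i) {
    d <- outer(rep(1, length(sx)), xs^2) - 2 * sx %o% xs + sx^2 +
      (sy - ys[i])^2
    apply(d, 2, which.min)
  }, integer(ncol))
  v <- matrix(cls[t(near)], nrow, ncol, byrow = FALSE)
  soy_raster(v, xll = 0, yll = 0, cellsize = cellsize,
             crs = "local-metres")
}

#' Simulate a labelled multi-crop scene
#'
#' Builds a complete desk-scale testbed: a candidate pool of points drawn
#' from several crop archetypes (truth labels retained), plus a separate
#' set of reference soybean points standing in for ground surveys. Each
#' point gets its own jittered archetype (season timing and canopy vigor)
#' and seeded optical + SAR series. `separation` scales every non-soybean
#' archetype's distance from the soybean archetype in parameter space
#' (1 = catalogue defaults, 0 = indistinguishable), supporting effect-size
#' sweeps.
#'
#' @param n_per_crop named counts of candidate points per crop; must
#'   include soybean and at least one other crop.
#' @param n_reference number of reference (ground-survey) soybean points.
#' @param region,year region id and year attached to all points.
#' @param seed integer seed; the whole scene is deterministic given it.
#' @param separation effect-size multiplier in (0, 1].
#' @param noise,gaps forwarded to [simulate_series()].
#' @return List with `reference` and `candidates` (each: `points` data
#'   frame, `series`, `sar` named lists), `truth` (named crop vector for
#'   candidates) and the catalogue used.
#' @export
simulate_region <- function(n_per_crop = c(soybean = 200, corn = 200,
                                           rice = 200, peanut = 200),
                            n_reference = 100, region = "R1", year = 2021,
                            seed = 1L, separation = 1, noise = TRUE,
                            gaps = TRUE) {
  if (!"soybean" %in% names(n_per_crop) || length(n_per_crop) < 2)
    stop("scene needs soybean and at least one other crop")
  cat0 <- crop_archetypes()
  base <- cat0$base_reflectance
  soy <- cat0$crops$soybean
  blend <- function(a) {
    # pull archetype parameters toward soybean's by (1 - separation)
    a$peak <- soy$peak + separation * (a$peak - soy$peak)
    for (p in c("sos50", "eos50"))
      a[[p]] <- soy[[p]] + separation * (a[[p]] - soy[[p]])
    a$chl_exponent <- soy$chl_exponent *
      (a$chl_exponent / soy$chl_exponent)^separation
    a
  }
  cat0$crops <- lapply(cat0$crops, blend)

  set.seed(seed)
  gen_points <- function(crops, prefix, provenance, label) {
    ids <- sprintf("%s%04d", prefix, seq_along(crops))
    series <- vector("list", length(crops))
    sar <- vector("list", length(crops))
    for (i in seq_along(crops)) {
      a <- .jitter_archetype(cat0$crops[[crops[i]]], cat0$jitter)
      a <- .apply_vigor(a, base, exp(stats::rnorm(1, 0, cat0$jitter$vigor_sd)))
      sim <- simulate_series(a, seed = NULL, noise = noise, gaps = gaps,
                             catalogue = cat0)
      series[[i]] <- sim$refl
      sar[[i]] <- sim$sar
    }
    names(series) <- ids
    names(sar) <- ids
    pts <- data.frame(id = ids,
                      lon = 126 + stats::runif(length(ids), 0, 0.5),
                      lat = 45 + stats::runif(length(ids), 0, 0.5),
                      year = year, region = region, label = label,
                      provenance = provenance, crop = crops,
                      stringsAsFactors = FALSE)
    list(points = pts, series = series, sar = sar)
  }
  reference <- gen_points(rep("soybean", n_reference), "ref", "ground_survey",
                          "soybean")
  cand_crops <- rep(names(n_per_crop), n_per_crop)
  candidates <- gen_points(cand_crops, "cand", "generated",
                           "cropland_unknown")
  truth <- stats::setNames(cand_crops, candidates$points$id)
  list(reference = reference, candidates = candidates, truth = truth,
       catalogue = cat0, seed = seed, separation = separation)
}
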