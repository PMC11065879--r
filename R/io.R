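# Plain-text I/O: long-form CSV time-series tables, GeoJSON points, and
# JSON model dumps.

#' Write reflectance series to a long-form CSV table
#'
#' Columns: `sample_id`, `doy`, then the nine bands under Sentinel-2 names
#' (`B2, B3, B4, B5, B6, B7, B8A, B11, B12`). Only valid observations are
#' written.
#'
#' @param series named list of [refl_series()].
#' @param path output CSV path.
#' @export
write_series_csv <- function(series, path) {
  rows <- lapply(names(series), function(id) {
    s <- series[[id]]
    b <- s$bands[s$mask, , drop = FALSE]
    colnames(b) <- SENTINEL2_BANDS[colnames(b)]
    data.frame(sample_id = id, doy = s$times[s$mask], b,
               check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read reflectance series from a long-form CSV table
#'
#' @param path CSV written by [write_series_csv()] (band columns may use
#'   Sentinel-2 or internal names).
#' @return Named list of [refl_series()].
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  s2 <- SENTINEL2_BANDS[SENTINEL2_BANDS %in% names(d)]
  if (length(s2)) names(d)[match(s2, names(d))] <- names(s2)
  lapply(split(d, d$sample_id), function(g) {
    g <- g[order(g$doy), ]
    m <- as.matrix(g[, BAND_NAMES])
    dimnames(m) <- list(NULL, BAND_NAMES)
    refl_series(g$doy, m)
  })
}

#' Write SAR series to a long-form CSV table
#'
#' Columns: `sample_id`, `doy`, `vh_db`, `vv_db`.
#'
#' @param sar named list of [sar_series()].
#' @param path output CSV path.
#' @export
write_sar_csv <- function(sar, path) {
  rows <- lapply(names(sar), function(id) {
    s <- sar[[id]]
    data.frame(sample_id = id, doy = s$times[s$mask],
               vh_db = s$vh[s$mask], vv_db = s$vv[s$mask])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read SAR series from a long-form CSV table
#'
#' @param path CSV written by [write_sar_csv()].
#' @return Named list of [sar_series()].
#' @export
read_sar_csv <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$sample_id), function(g) {
    g <- g[order(g$doy), ]
    sar_series(g$doy, g$vh_db, g$vv_db)
  })
}

#' Write sample points as GeoJSON
#'
#' Point features in EPSG:4326 with properties `id`, `year`, `label`,
#' `provenance`, `region` (plus any further columns).
#'
#' @param points data frame with `id`, `lon`, `lat` and property columns.
#' @param path output `.geojson` path.
#' @export
write_points_geojson <- function(points, path) {
  props <- setdiff(names(points), c("lon", "lat"))
  feats <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$lon[i], points$lat[i])),
         properties = as.list(points[i, props, drop = FALSE]))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read sample points from GeoJSON
#'
#' @param path `.geojson` path.
#' @return Data frame with `lon`, `lat` and all feature properties.
#' @export
read_points_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  rows <- lapply(fc$features, function(f) {
    p <- f$properties
    p$lon <- f$geometry$coordinates[[1]]
    p$lat <- f$geometry$coordinates[[2]]
    as.data.frame(p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Dump fitted migration models as JSON
#'
#' Records, per group model: mean vector, covariance, `p50`, `r50`, both
#' thresholds, the Monte-Carlo seed and the reference count.
#'
#' @param migration a `soy_migration` (or a single `soy_group_model`).
#' @param path output `.json` path.
#' @export
write_model_json <- function(migration, path) {
  dump1 <- function(m)
    list(group = m$group, mu = m$mu, Sigma = m$Sigma, p50 = m$p50,
         r50 = m$r50, soy_thresh = m$soy_thresh,
         nonsoy_thresh = m$nonsoy_thresh, n_fit = m$n_fit,
         n_mc = m$n_mc, seed = m$seed)
  obj <- if (inherits(migration, "soy_group_model")) dump1(migration)
  else list(high = dump1(migration$high_model),
            low = dump1(migration$low_model),
            counts = as.list(migration$counts))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# short deterministic polynomial rolling hash of a config (run manifests)
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
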