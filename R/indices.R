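# Optical index formulas and SAR channel combinations.

OPTICAL_INDICES <- c("EVI", "GCVI", "LSWI", "REPI", "RENDVI", "NDPI",
                     "SAVI", "OSAVI", "TCARI", "TCARI_OSAVI")

# Guard against near-zero denominators: the result is a missing value,
# never +-Inf (configurable epsilon).
.safe_div <- function(num, den, eps = 1e-9) {
  out <- num / den
  out[abs(den) < eps] <- NA_real_
  out
}

.index_value <- function(b, name, osavi_standard = FALSE, eps = 1e-9) {
  osavi <- function() {
    den <- if (osavi_standard) b$nir + b$red + 0.16 else b$nir + b$swir1 + 0.16
    .safe_div(1.16 * (b$nir - b$red), den, eps)
  }
  switch(name,
    EVI    = .safe_div(2.5 * (b$nir - b$red),
                       b$nir + 6 * b$red - 7.5 * b$blue + 1, eps),
    GCVI   = .safe_div(b$nir, b$green, eps) - 1,
    LSWI   = .safe_div(b$nir - b$swir1, b$nir + b$swir1, eps),
    REPI   = 705 + 35 * .safe_div((b$red + b$re3) / 2 - b$re1,
                                  b$re2 - b$re1, eps),
    RENDVI = .safe_div(b$nir - b$re2, b$nir + b$re2, eps),
    NDPI   = {
      pseudo <- 0.78 * b$red + 0.22 * b$swir1
      .safe_div(b$nir - pseudo, b$nir + pseudo, eps)
    },
    SAVI   = 1.5 * .safe_div(b$nir - b$red, b$nir + b$red + 0.5, eps),
    OSAVI  = osavi(),
    TCARI  = 3 * ((b$re1 - b$red) -
                  0.2 * (b$re1 - b$green) * .safe_div(b$re1, b$red, eps)),
    TCARI_OSAVI = {
      tc <- .index_value(b, "TCARI", osavi_standard, eps)
      .safe_div(tc, osavi(), eps)
    },
    stop("unknown index name: ", name)
  )
}

#' Compute a spectral index time series
#'
#' Evaluates one of the nine optical vegetation indices (EVI, GCVI, LSWI,
#' REPI, RENDVI, NDPI, SAVI, OSAVI, TCARI) or the chlorophyll-sensitive
#' TCARI/OSAVI ratio, pointwise over a reflectance series. Invalid
#' observations (mask `FALSE`) propagate as `NA`, as do near-zero
#' denominators.
#'
#' OSAVI is implemented with SWIR1 in its denominator by default
#' (`1.16 (NIR - red) / (NIR + SWIR1 + 0.16)`); set `osavi_standard = TRUE`
#' for the literature-standard red-band denominator.
#'
#' @param refl a [refl_series()].
#' @param name index identifier (one of the nine indices or `"TCARI_OSAVI"`).
#' @param osavi_standard use the red-band OSAVI denominator.
#' @param eps denominators with absolute value below `eps` give `NA`.
#' @return An [index_series()]. REPI is in nanometres; others unitless.
#' @export
compute_index <- function(refl, name, osavi_standard = FALSE, eps = 1e-9) {
  stopifnot(inherits(refl, "refl_series"))
  if (!name %in% OPTICAL_INDICES)
    stop("unknown index name: ", name)
  b <- as.list(as.data.frame(refl$bands))
  v <- .index_value(b, name, osavi_standard, eps)
  v[!refl$mask] <- NA_real_
  index_series(name, refl$times, v)
}

#' Compute a SAR parameter time series
#'
#' Returns one of the five dual-polarization parameters: the VH or VV
#' backscatter itself (pass-through, decibels), the cross-polarization ratio
#' `VH/VV`, the cross-polarization sum `VH+VV`, or the radar vegetation index
#' `RVI = 4 VH / (VH + VV)`. Channel combinations are computed in linear
#' power units (dB converted via `10^(dB/10)`) by default, because sums and
#' ratios of logarithmic quantities are not physically meaningful; a
#' dB-domain variant is retained for sensitivity checks.
#'
#' @param sar a [sar_series()].
#' @param name one of `"VH"`, `"VV"`, `"cross_ratio"`, `"cross_sum"`,
#'   `"RVI"`.
#' @param db_domain if `TRUE`, combine channels directly in decibels.
#' @param eps near-zero denominator guard.
#' @return An [index_series()].
#' @export
sar_parameter <- function(sar, name, db_domain = FALSE, eps = 1e-9) {
  stopifnot(inherits(sar, "sar_series"))
  name <- match.arg(name, SAR_PARAMS)
  if (name %in% c("VH", "VV")) {
    v <- if (name == "VH") sar$vh else sar$vv
  } else {
    vh <- if (db_domain) sar$vh else 10^(sar$vh / 10)
    vv <- if (db_domain) sar$vv else 10^(sar$vv / 10)
    v <- switch(name,
      cross_ratio = .safe_div(vh, vv, eps),
      cross_sum   = vh + vv,
      RVI         = .safe_div(4 * vh, vh + vv, eps))
  }
  v[!sar$mask] <- NA_real_
  index_series(name, sar$times, v)
}

#' Extract a single band as an index series
#'
#' Convenience accessor used when raw band reflectance (e.g. RE2, SWIR2)
#' enters the workflow on the same footing as a derived index.
#'
#' @param refl a [refl_series()].
#' @param band one of the nine band names.
#' @return An [index_series()].
#' @export
band_series <- function(refl, band) {
  stopifnot(inherits(refl, "refl_series"))
  band <- match.arg(band, BAND_NAMES)
  v <- refl$bands[, band]
  v[!refl$mask] <- NA_real_
  index_series(band, refl$times, v)
}
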