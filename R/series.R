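#' @keywords internal
"_PACKAGE"

# Canonical band order. Sentinel-2 naming: B2 blue, B3 green, B4 red,
# B5-B7 red edge 1-3, B8A narrow NIR, B11 SWIR1, B12 SWIR2.
BAND_NAMES <- c("blue", "green", "red", "re1", "re2", "re3",
                "nir", "swir1", "swir2")
SENTINEL2_BANDS <- c(blue = "B2", green = "B3", red = "B4", re1 = "B5",
                     re2 = "B6", re3 = "B7", nir = "B8A", swir1 = "B11",
                     swir2 = "B12")
SAR_PARAMS <- c("VH", "VV", "cross_ratio", "cross_sum", "RVI")

#' Multi-band surface-reflectance time series
#'
#' Container for one sample's (or pixel's) optical observations: a vector of
#' acquisition dates (day of year) and one reflectance value per band per
#' date, with a per-date validity mask (cloud-free or not).
#'
#' @param times integer day-of-year vector (1-366), strictly increasing.
#' @param bands numeric matrix, one row per time, columns named
#'   `blue, green, red, re1, re2, re3, nir, swir1, swir2`.
#' @param mask logical vector, `TRUE` where the observation is valid.
#' @return An object of class `refl_series`.
#' @export
refl_series <- function(times, bands, mask = rep(TRUE, length(times))) {
  times <- as.numeric(times)
  bands <- as.matrix(bands)
  if (is.null(colnames(bands)) && ncol(bands) == length(BAND_NAMES))
    colnames(bands) <- BAND_NAMES
  missing_b <- setdiff(BAND_NAMES, colnames(bands))
  if (length(missing_b))
    stop("missing band(s): ", paste(missing_b, collapse = ", "))
  bands <- bands[, BAND_NAMES, drop = FALSE]
  if (nrow(bands) != length(times) || length(mask) != length(times))
    stop("times, bands and mask must share one length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(times < 1 | times > 366)) stop("times must be day-of-year in 1-366")
  ok <- bands[mask, , drop = FALSE]
  if (length(ok) && any(!is.finite(ok) | ok < 0))
    stop("reflectance must be finite and >= 0 where mask is TRUE")
  structure(list(times = times, bands = bands, mask = as.logical(mask)),
            class = "refl_series")
}

#' Dual-polarization SAR backscatter time series
#'
#' @param times day-of-year vector, strictly increasing.
#' @param vh,vv numeric backscatter coefficients (sigma0) in decibels.
#' @param mask logical validity mask.
#' @return An object of class `sar_series`.
#' @export
sar_series <- function(times, vh, vv, mask = rep(TRUE, length(times))) {
  times <- as.numeric(times)
  n <- length(times)
  if (length(vh) != n || length(vv) != n || length(mask) != n)
    stop("times, vh, vv and mask must share one length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(c(vh[mask], vv[mask]))))
    stop("backscatter must be finite where mask is TRUE")
  structure(list(times = times, vh = as.numeric(vh), vv = as.numeric(vv),
                 mask = as.logical(mask)),
            class = "sar_series")
}

#' Named index (or single-parameter) time series
#'
#' @param name index or parameter identifier.
#' @param times day-of-year vector.
#' @param values numeric values; `NA` marks invalid observations. Unitless
#'   except REPI (nanometres) and VH/VV (decibels).
#' @return An object of class `index_series`.
#' @export
index_series <- function(name, times, values) {
  if (length(times) != length(values))
    stop("times and values must share one length")
  structure(list(name = name, times = as.numeric(times),
                 values = as.numeric(values)),
            class = "index_series")
}

#' @export
print.refl_series <- function(x, ...) {
  cat("<refl_series> ", length(x$times), " dates (DOY ",
      min(x$times), "-", max(x$times), "), ",
      sum(x$mask), " valid\n", sep = "")
  invisible(x)
}

#' @export
print.sar_series <- function(x, ...) {
  cat("<sar_series> ", length(x$times), " dates, ",
      sum(x$mask), " valid\n", sep = "")
  invisible(x)
}

#' @export
print.index_series <- function(x, ...) {
  cat("<index_series> ", x$name, ": ", length(x$times), " dates, ",
      sum(is.finite(x$values)), " finite\n", sep = "")
  invisible(x)
}

#' @importFrom stats predict coef median quantile sd cov runif rnorm setNames approx
#' @importFrom utils read.csv write.csv
NULL
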