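# Phenology extraction from the EVI curve and growing-season curve
# integrals.

#' Extract phenological dates from a smoothed EVI curve
#'
#' The peak of season (POS) is the bin centre of the global EVI maximum
#' (earliest bin on ties). Start and end of season follow the amplitude
#' median rule: the level `min + 0.5 (max - min)` is computed from the
#' global extremes over the grid window, SOS is the linearly interpolated
#' DOY of the last upward crossing of that level before POS, and EOS the
#' first downward crossing after POS. When a crossing does not exist the
#' date is clamped to the grid start/end.
#'
#' @param evi gap-free smoothed EVI [gridded_series()].
#' @return An object of class `phenology`: list with `sos`, `pos`, `eos`
#'   (DOY, possibly fractional) and `los = eos - sos` (days).
#' @export
extract_phenology <- function(evi) {
  stopifnot(inherits(evi, "gridded_series"))
  v <- evi$values
  if (anyNA(v)) stop("extract_phenology requires a gap-free series")
  cen <- evi$grid$centres
  rng <- max(v) - min(v)
  if (rng < 1e-6) stop("no seasonal signal: curve amplitude below 1e-6")
  mid <- min(v) + 0.5 * rng
  pos_i <- which.max(v)
  pos <- cen[pos_i]

  cross_at <- function(j) {
    # crossing of `mid` on segment [j, j+1]
    cen[j] + (mid - v[j]) / (v[j + 1] - v[j]) * (cen[j + 1] - cen[j])
  }
  sos <- evi$grid$start
  if (pos_i > 1) {
    j <- which(v[seq_len(pos_i - 1)] < mid & v[2:pos_i] >= mid)
    if (length(j)) sos <- cross_at(max(j))
  }
  eos <- evi$grid$start + evi$grid$n * evi$grid$step
  if (pos_i < length(v)) {
    j <- which(v[pos_i:(length(v) - 1)] >= mid &
                 v[(pos_i + 1):length(v)] < mid) + pos_i - 1L
    if (length(j)) eos <- cross_at(min(j))
  }
  structure(list(sos = sos, pos = pos, eos = eos, los = eos - sos),
            class = "phenology")
}

#' @export
print.phenology <- function(x, ...) {
  cat(sprintf("<phenology> SOS %.1f  POS %.1f  EOS %.1f  LOS %.1f days\n",
              x$sos, x$pos, x$eos, x$los))
  invisible(x)
}

#' Growing-season integral of a gridded curve
#'
#' Trapezoidal integral of the linearly interpolated curve between SOS and
#' EOS, in index-units x days. Exact for piecewise-linear curves.
#'
#' @param x gap-free [gridded_series()].
#' @param phen a `phenology` object (or any list with `sos` and `eos`).
#' @return Numeric scalar.
#' @export
seasonal_integral <- function(x, phen) {
  stopifnot(inherits(x, "gridded_series"))
  sos <- phen$sos; eos <- phen$eos
  if (eos < sos) stop("phenology must satisfy SOS <= EOS")
  lo <- x$grid$start; hi <- x$grid$start + x$grid$n * x$grid$step
  if (sos < lo - 1e-9 || eos > hi + 1e-9)
    stop("phenology dates fall outside the grid span")
  if (eos == sos) return(0)
  cen <- x$grid$centres
  knots <- c(sos, cen[cen > sos & cen < eos], eos)
  vals <- interp_grid(x, knots)
  sum(diff(knots) * (vals[-1] + vals[-length(vals)]) / 2)
}

#' High/low-group integral vector for one sample
#'
#' Assembles the six growing-season curve integrals used for sample
#' confirmation, in fixed order: the high-value group (EVI, RE2, SWIR2),
#' where soybean integrals run high, and the low-value group (LSWI, RENDVI,
#' REPI), where they run low. All six curves are integrated over the same
#' sample's [SOS, EOS].
#'
#' @param curves named list of gap-free [gridded_series()] containing at
#'   least `EVI`, `re2`, `swir2`, `LSWI`, `RENDVI`, `REPI`.
#' @param phen the sample's `phenology`.
#' @return Named numeric vector of length 6 with attribute `groups`.
#' @export
integral_vectors <- function(curves, phen) {
  need <- c("EVI", "re2", "swir2", "LSWI", "RENDVI", "REPI")
  missing_c <- setdiff(need, names(curves))
  if (length(missing_c))
    stop("missing curve(s): ", paste(missing_c, collapse = ", "))
  out <- vapply(need, function(nm) seasonal_integral(curves[[nm]], phen),
                numeric(1))
  names(out) <- c("int_evi", "int_re2", "int_swir2",
                  "int_lswi", "int_rendvi", "int_repi")
  attr(out, "groups") <- c(high = 3L, low = 3L)
  out
}
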