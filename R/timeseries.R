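# Temporal regularization: compositing to a fixed grid, divided-difference
# gap filling, Savitzky-Golay smoothing.

#' Define a regular temporal grid over the growing season
#'
#' The default grid covers the growing season (DOY 90-318, i.e. April to
#' mid-November) in 10-day bins, giving 23 bin centres at DOY 95, 105, ...,
#' 315. This cadence matches what a 5-day optical revisit delivers after
#' cloud loss.
#'
#' @param start_doy,end_doy season window (day of year), `start < end`.
#' @param step_days bin width in days (>= 1).
#' @return An object of class `temporal_grid` with bin `centres`.
#' @export
temporal_grid <- function(start_doy = 90, end_doy = 318, step_days = 10) {
  stopifnot(start_doy < end_doy, step_days >= 1)
  n <- ceiling((end_doy - start_doy) / step_days)
  centres <- start_doy + step_days / 2 + step_days * (0:(n - 1))
  structure(list(start = start_doy, end = end_doy, step = step_days,
                 n = n, centres = centres),
            class = "temporal_grid")
}

#' @export
print.temporal_grid <- function(x, ...) {
  cat("<temporal_grid> DOY ", x$start, "-", x$end, ", ", x$step,
      "-day bins, ", x$n, " centres\n", sep = "")
  invisible(x)
}

#' Gridded (regularized) series
#'
#' @param grid a [temporal_grid()].
#' @param values one value per bin; `NA` = empty bin.
#' @param filled logical per bin: `TRUE` where the value was interpolated
#'   rather than observed.
#' @param name optional series name.
#' @return An object of class `gridded_series`.
#' @export
gridded_series <- function(grid, values, filled = rep(FALSE, grid$n),
                           name = NULL) {
  stopifnot(inherits(grid, "temporal_grid"),
            length(values) == grid$n, length(filled) == grid$n)
  structure(list(grid = grid, values = as.numeric(values),
                 filled = as.logical(filled), name = name),
            class = "gridded_series")
}

#' @export
print.gridded_series <- function(x, ...) {
  cat("<gridded_series>", if (!is.null(x$name)) x$name else "", x$grid$n,
      "bins,", sum(is.na(x$values)), "missing,", sum(x$filled), "filled\n")
  invisible(x)
}

#' Composite an irregular series onto a temporal grid
#'
#' Assigns each valid observation to its bin and takes the per-bin median.
#' Observations outside the grid span are ignored; empty bins are marked
#' missing.
#'
#' @param series an [index_series()], or a list with `times` and `values`.
#' @param grid a [temporal_grid()].
#' @return A [gridded_series()] (possibly with missing bins).
#' @export
composite <- function(series, grid = temporal_grid()) {
  t <- series$times
  v <- series$values
  ok <- is.finite(v) & t >= grid$start & t < grid$start + grid$n * grid$step
  if (!any(ok)) stop("no valid observations within the grid span")
  bin <- floor((t[ok] - grid$start) / grid$step) + 1L
  vals <- rep(NA_real_, grid$n)
  med <- tapply(v[ok], bin, stats::median)
  vals[as.integer(names(med))] <- med
  gridded_series(grid, vals, name = series$name)
}

# Quadratic Newton interpolant through three nodes, evaluated at x0.
.newton_quad <- function(x, f, x0) {
  d12 <- (f[2] - f[1]) / (x[2] - x[1])
  d23 <- (f[3] - f[2]) / (x[3] - x[2])
  d123 <- (d23 - d12) / (x[3] - x[1])
  f[1] + d12 * (x0 - x[1]) + d123 * (x0 - x[1]) * (x0 - x[2])
}

#' Fill empty bins by local quadratic interpolation
#'
#' Each missing bin is estimated from its three nearest observed bins by the
#' Newton divided-difference quadratic through them; the estimate is exact
#' for any underlying polynomial of degree <= 2. Observed bins are left
#' unchanged and filled bins are flagged.
#'
#' @param g a [gridded_series()] with at least 3 observed bins.
#' @return A gap-free [gridded_series()].
#' @export
fill_gaps <- function(g) {
  stopifnot(inherits(g, "gridded_series"))
  obs <- which(!is.na(g$values))
  if (length(obs) < 3)
    stop("gap filling needs at least 3 observed bins, got ", length(obs))
  miss <- which(is.na(g$values))
  if (!length(miss)) return(g)
  cen <- g$grid$centres
  vals <- g$values
  filled <- g$filled
  for (i in miss) {
    nearest <- obs[order(abs(cen[obs] - cen[i]), cen[obs])][1:3]
    nearest <- sort(nearest)
    vals[i] <- .newton_quad(cen[nearest], g$values[nearest], cen[i])
    filled[i] <- TRUE
  }
  gridded_series(g$grid, vals, filled, g$name)
}

#' Savitzky-Golay smoothing of a gridded series
#'
#' Standard Savitzky-Golay least-squares convolution; edge bins are handled
#' by polynomial fits on the truncated end windows, so a polynomial of
#' degree <= `order` is reproduced exactly everywhere.
#'
#' @param g gap-free [gridded_series()].
#' @param window odd number of bins (default 7).
#' @param order polynomial degree (default 2), `order < window`.
#' @return A smoothed [gridded_series()].
#' @export
sg_smooth <- function(g, window = 7, order = 2) {
  stopifnot(inherits(g, "gridded_series"))
  if (anyNA(g$values)) stop("sg_smooth requires a gap-free series")
  if (window %% 2 == 0) stop("window must be odd")
  if (window >= g$grid$n + 1) stop("window must be smaller than the series")
  if (order >= window) stop("order must be smaller than window")
  sm <- signal::sgolayfilt(g$values, p = order, n = window)
  gridded_series(g$grid, sm, g$filled, g$name)
}

#' Linear interpolation of a gridded series at arbitrary DOYs
#'
#' Values between bin centres are linearly interpolated; outside the centre
#' range the nearest end value is held constant.
#'
#' @param g gap-free [gridded_series()].
#' @param doy numeric day(s) of year.
#' @return Numeric vector of interpolated values.
#' @export
interp_grid <- function(g, doy) {
  stopifnot(inherits(g, "gridded_series"))
  if (anyNA(g$values)) stop("interpolation requires a gap-free series")
  stats::approx(g$grid$centres, g$values, xout = doy, rule = 2)$y
}

#' Composite, fill and smooth in one call
#'
#' @param series an [index_series()].
#' @param grid a [temporal_grid()].
#' @param window,order Savitzky-Golay parameters.
#' @param smooth apply Savitzky-Golay after gap filling.
#' @return A gap-free [gridded_series()].
#' @export
regularize <- function(series, grid = temporal_grid(), window = 7,
                       order = 2, smooth = TRUE) {
  g <- fill_gaps(composite(series, grid))
  if (smooth) g <- sg_smooth(g, window, order)
  g
}
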