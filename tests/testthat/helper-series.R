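# Shared fixtures, built in code.

# reflectance series with every band constant
const_refl <- function(values, times = seq(95, 315, 10)) {
  bands <- matrix(rep(values[phenomigrate:::BAND_NAMES],
                      each = length(times)),
                  nrow = length(times),
                  dimnames = list(NULL, phenomigrate:::BAND_NAMES))
  refl_series(times, bands)
}

# single-date reflectance from a named vector of band values
one_shot_refl <- function(values) const_refl(values, times = 180)

# gridded series from a function of DOY evaluated at the default centres
grid_from_fun <- function(f, grid = temporal_grid()) {
  gridded_series(grid, f(grid$centres))
}

# triangular EVI curve: base-to-peak-to-base, linear in DOY
triangular_evi <- function(peak_doy = 205, base = 0.1, peak = 0.9,
                           grid = temporal_grid()) {
  grid_from_fun(function(d) {
    up <- base + (peak - base) * (d - grid$centres[1]) /
      (peak_doy - grid$centres[1])
    down <- base + (peak - base) *
      (grid$centres[grid$n] - d) / (grid$centres[grid$n] - peak_doy)
    pmin(up, down)
  }, grid)
}

# random symmetric positive-definite 3x3 covariance
random_spd <- function() {
  A <- matrix(rnorm(9), 3)
  crossprod(A) + 0.1 * diag(3)
}

# lightweight group-model stand-in for distance computations
dist_model <- function(mu, Sigma) {
  list(mu = mu, Sigma = Sigma, chol = chol(Sigma))
}
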