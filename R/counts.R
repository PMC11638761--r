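#' Number of circles for complete sampling of one partition
#'
#' Smallest number of eccentric circles of radius `R` needed to fully sample
#' one k-space partition of an `n`-point matrix with in-plane extent `kmax`:
#' the ceiling of `pi * n * kmax / (2 * R)`. With `R = kmax/2` on a 64-matrix
#' this gives 202 circles; with `R = kmax` it collapses to the rosette count
#' `ceil(pi*n/2)`.
#'
#' @param n Matrix size (integer >= 2).
#' @param kmax Largest in-plane k-space coordinate (cycles/m).
#' @param R Circle radius (cycles/m), `0 < R <= kmax`.
#' @return Integer circle count.
#' @export
full_sampling_count <- function(n, kmax, R) {
  if (n < 2) stop("n must be >= 2")
  if (!is.numeric(R) || R <= 0) stop("invalid parameter: R must be positive")
  if (!is.numeric(kmax) || kmax <= 0) stop("invalid parameter: kmax must be positive")
  if (R > kmax) stop("invalid parameter: R must not exceed kmax")
  as.integer(ceiling(pi * n * kmax / (2 * R)))
}

#' Number of circles for a fully sampled rosette trajectory
#'
#' A rosette encoding of an `n`-point matrix requires `ceil(pi * n / 2)`
#' circles (101 for n = 64).
#'
#' @param n Matrix size (integer >= 2).
#' @return Integer circle count.
#' @export
rosette_count <- function(n) {
  if (n < 2) stop("n must be >= 2")
  as.integer(ceiling(pi * n / 2))
}

#' Per-partition circle counts of a 3D stack
#'
#' For a stack of eccentric-circle planes the in-plane k-space boundary may
#' shrink with kz to realize an ellipsoid coverage,
#' `kmax(kz) = kmax * sqrt(1 - (kz/kz_max)^2)` with
#' `kz_max = (n_z/2 + 1) * dkz`, or stay constant (cylinder coverage). Each
#' partition uses the effective matrix size
#' `n(kz) = round(2 * fov_xy * kmax(kz))` in the full-sampling formula, and
#' acceleration thins each partition count by rounding to nearest with a
#' floor of one circle.
#'
#' @param grid A [grid_spec()] with `n_z` partitions.
#' @param R Circle radius (cycles/m).
#' @param af Acceleration factor (>= 1).
#' @param coverage `"ellipsoid"` or `"cylinder"`.
#' @return A data frame with one row per partition: `kz_index`, `kz`,
#'   `kmax_kz`, `n_eff`, `R_eff`, `count`, and attribute `"clamped"` naming
#'   partitions where `R` had to be clamped to `kmax(kz)`.
#' @export
stack_circle_counts <- function(grid, R, af = 1, coverage = c("ellipsoid", "cylinder")) {
  coverage <- match.arg(coverage)
  if (af < 1) stop("af must be >= 1")
  nz <- grid$n_z
  idx <- seq.int(-(nz %/% 2L), nz - 1L - nz %/% 2L)
  kz_max_frac <- nz / 2 + 1          # in units of dkz
  frac <- if (coverage == "ellipsoid") sqrt(pmax(0, 1 - (idx / kz_max_frac)^2)) else rep(1, nz)
  kmax_kz <- grid$kmax * frac
  n_eff <- pmax(2L, as.integer(round(2 * grid$fov_xy * kmax_kz)))
  R_eff <- pmin(R, kmax_kz)
  clamped <- idx[R_eff < R]
  full <- mapply(full_sampling_count, n = n_eff, kmax = kmax_kz, R = R_eff)
  count <- pmax(1L, as.integer(round(full / af)))
  out <- data.frame(kz_index = idx, kz = if (is.na(grid$dkz)) idx else idx * grid$dkz,
                    kmax_kz = kmax_kz, n_eff = n_eff, R_eff = R_eff, count = count)
  attr(out, "clamped") <- clamped
  out
}

#' Ellipsoid-over-cylinder coverage acceleration
#'
#' The ratio of total circle counts between cylindrical and ellipsoid 3D
#' k-space coverage. In the continuum limit this is the reciprocal of the
#' mean of `1 - z^2` over `z` in `[-1, 1]`, i.e. 3/2: spherical coverage
#' yields an additional acceleration factor of 1.5.
#'
#' @param grid A [grid_spec()] with `n_z` partitions (pass `fov_z`).
#' @param R Circle radius (cycles/m).
#' @return Scalar ratio cylinder/ellipsoid of total circle counts.
#' @export
coverage_acceleration <- function(grid, R) {
  cyl <- sum(stack_circle_counts(grid, R, af = 1, coverage = "cylinder")$count)
  ell <- sum(stack_circle_counts(grid, R, af = 1, coverage = "ellipsoid")$count)
  cyl / ell
}
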