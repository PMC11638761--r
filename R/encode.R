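#' @title Coil-wise (k,t) forward encoding
#' @description
#' The simulator evaluates the full encoding chain
#' `s_{c,j,tau} = sum_i C_c(r_i) * exp(i 2 pi dB0(r_i) t_tau) *
#' exp(i 2 pi k_j . r_i) * rho(r_i, t_tau) + eps`, where the voxel signal
#' `rho` is the Lorentzian FID model of [synthesize_fid()] evaluated from
#' the scene's concentration, T2* and water-amplitude maps, and `eps` is
#' i.i.d. complex Gaussian noise (std `noise_sigma`, independent across
#' coils). The B0 phase is evaluated exactly per time point.
#' @name forward_encoding
NULL

new_spectro_kdata <- function(values, plan, times, noise_sigma, seed, include) {
  structure(list(values = values, plan = plan, times = times,
                 noise_sigma = noise_sigma, seed = seed, include = include),
            class = "spectro_kdata")
}

#' @export
print.spectro_kdata <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("spectro_kdata: %d samples x %d time points x %d coils (sigma=%g)\n",
              d[1], d[2], d[3], x$noise_sigma))
  invisible(x)
}

# ground-truth image-domain FID series (Nr x T), without B0 phase
scene_rho <- function(scene, basis, times, include, water_scale = 100) {
  n <- scene$grid$n_xy; Nr <- n * n; Tn <- length(times)
  conc <- scene$concentration_maps
  if ("water" %in% include)
    conc$water <- scene$water_amp_map * water_scale
  conc <- conc[intersect(names(conc), include)]
  rho <- matrix(0 + 0i, Nr, Tn)
  for (nm in names(conc)) {
    m <- basis$metabolites[[nm]]
    if (is.null(m)) stop(sprintf("metabolite '%s' not in basis", nm))
    f <- basis_freq_hz(basis, m$ppm)
    osc <- numeric(Tn) + 0i
    for (j in seq_along(f))
      osc <- osc + m$amp[j] * exp((2i * pi * f[j] - m$extra_damping) * times)
    rho <- rho + outer(as.vector(conc[[nm]]), osc)
  }
  rho * exp(outer(-as.vector(1 / scene$t2star_map), times))
}

#' Simulate a coil-wise (k,t) acquisition
#'
#' Forward-encodes a [phantom_scene] along a trajectory plan. By default
#' only the scene's metabolite (and lipid) maps contribute, emulating
#' water-suppressed acquisition; include `"water"` for an unsuppressed
#' scan (water amplitude = `water_amp_map * water_scale`).
#'
#' @param scene A `phantom_scene` on the same grid as `plan`.
#' @param basis A [spectral_basis()].
#' @param plan A `trajectory_plan`.
#' @param noise_sigma Complex-Gaussian noise std per sample (same units as
#'   the signal; `sqrt(E|eps|^2) = noise_sigma`).
#' @param seed RNG seed for the noise draw.
#' @param n_time Number of spectral time points (default `plan$n_time`).
#' @param include Character vector of contributing maps (default: all the
#'   scene's concentration maps, i.e. water-suppressed).
#' @param water_scale Water amplitude per unit `water_amp_map` (default 100).
#' @return A `spectro_kdata` with `values` of dim `(samples, time, coil)`.
#' @export
forward_encode <- function(scene, basis, plan, noise_sigma = 0, seed = 1L,
                           n_time = NULL, include = NULL, water_scale = 100) {
  g <- scene$grid
  if (g$n_xy != plan$grid$n_xy || g$fov_xy != plan$grid$fov_xy)
    stop("scene grid and plan grid differ")
  Tn <- if (is.null(n_time)) plan$n_time else as.integer(n_time)
  times <- (seq_len(Tn) - 1) / plan$sbw
  if (is.null(include)) include <- names(scene$concentration_maps)
  rho <- scene_rho(scene, basis, times, include, water_scale)
  if (any(scene$b0_map != 0))
    rho <- rho * exp(2i * pi * outer(as.vector(scene$b0_map), times))
  pts <- sample_points(plan)
  op <- nuft_matrices(pts, g)
  nC <- dim(scene$coil_maps)[3]
  out <- array(0 + 0i, c(nrow(pts), Tn, nC))
  for (c in seq_len(nC))
    out[, , c] <- nuft_fwd_op(op, as.vector(scene$coil_maps[, , c]) * rho)
  if (noise_sigma > 0) {
    rng <- local_rng(seed); on.exit(rng$restore(), add = TRUE)
    ne <- length(out)
    out <- out + complex(real = stats::rnorm(ne, 0, noise_sigma / sqrt(2)),
                         imaginary = stats::rnorm(ne, 0, noise_sigma / sqrt(2)))
  }
  new_spectro_kdata(out, plan, times, noise_sigma, seed, include)
}

#' Simulate the rapid water-reference calibration scan
#'
#' A short unsuppressed water acquisition on a low-resolution rosette plan
#' (default 24x24 in-plane), used downstream for coil-sensitivity and B0
#' estimation and as the quantification reference. Only the water resonance
#' contributes (at 0 Hz offset, plus the scene's B0 phase).
#'
#' @param scene A `phantom_scene`.
#' @param plan_lowres Optional low-resolution `trajectory_plan`; default a
#'   fully sampled 24x24 rosette with the scene's FoV.
#' @param basis A [spectral_basis()] (supplies the water entry).
#' @param n_time Number of reference time points (default 16).
#' @param noise_sigma,seed Noise parameters as in [forward_encode()].
#' @param water_scale Water amplitude scale (default 100).
#' @param sbw Spectral bandwidth of the reference scan (Hz).
#' @return A `spectro_kdata`.
#' @export
make_water_reference <- function(scene, plan_lowres = NULL,
                                 basis = spectral_basis(), n_time = 16L,
                                 noise_sigma = 0, seed = 1L,
                                 water_scale = 100, sbw = 2280) {
  if (is.null(plan_lowres)) {
    g_lo <- grid_spec(24L, scene$grid$fov_xy)
    plan_lowres <- design_comparators(g_lo, "rosette", af = 1, sbw = sbw,
                                      n_time = n_time)
    plan_lowres$grid <- scene$grid   # sample the same object; low-res k-extent
  }
  forward_encode(scene, basis, plan_lowres, noise_sigma, seed,
                 n_time = n_time, include = "water", water_scale = water_scale)
}

#' Grid k-space data to coil-wise image time series
#'
#' Density-compensated adjoint transform of each coil/time slice onto the
#' plan's image grid; the workhorse behind calibration-map estimation.
#'
#' @param kdata A `spectro_kdata`.
#' @param grid Target [grid_spec()] (default the plan's grid).
#' @return Complex array `(n, n, T, C)`.
#' @export
grid_kdata_images <- function(kdata, grid = NULL) {
  plan <- kdata$plan
  if (is.null(grid)) grid <- plan$grid
  pts <- sample_points(plan)
  w <- voronoi_density(pts, max(sqrt(pts[, 1]^2 + pts[, 2]^2)), grid$dk)
  op <- nuft_matrices(pts, grid)
  d <- dim(kdata$values)
  out <- array(0 + 0i, c(grid$n_xy, grid$n_xy, d[2], d[3]))
  for (c in seq_len(d[3])) {
    img <- nuft_adj_op(op, matrix(kdata$values[, , c], d[1], d[2]) * w)
    out[, , , c] <- array(img, c(grid$n_xy, grid$n_xy, d[2]))
  }
  out / sum(w)
}
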