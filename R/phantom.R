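#' @title Digital structural-metabolic phantoms
#' @description
#' A `phantom_scene` is the ground truth consumed by the forward encoder:
#' a labeled tissue image, per-metabolite concentration maps (mM), a T2*
#' map (s), a B0 offset map (Hz), complex coil sensitivities and a relative
#' water-amplitude map (which absorbs T1 saturation / Gd contrast effects;
#' no Bloch simulation is performed).
#' @name phantom_scene
NULL

new_phantom_scene <- function(grid, tissue_masks, concentration_maps,
                              t2star_map, b0_map, coil_maps, water_amp_map,
                              masks, extra = list()) {
  for (m in concentration_maps)
    if (any(m < 0)) stop("concentrations must be non-negative")
  if (!is.null(masks$brain) && !is.null(masks$lipid) &&
      any(masks$brain & masks$lipid)) stop("masks must be disjoint")
  obj <- masks$object
  if (!is.null(obj)) {
    rss <- sqrt(apply(abs(coil_maps)^2, c(1, 2), sum))
    if (any(rss[obj] == 0)) stop("coil maps vanish inside the object")
  }
  structure(c(list(grid = grid, tissue_masks = tissue_masks,
                   concentration_maps = concentration_maps,
                   t2star_map = t2star_map, b0_map = b0_map,
                   coil_maps = coil_maps, water_amp_map = water_amp_map,
                   masks = masks), extra),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("phantom_scene: %dx%d, %d coils, metabolites: %s\n",
              x$grid$n_xy, x$grid$n_xy, dim(x$coil_maps)[3],
              paste(names(x$concentration_maps), collapse = ", ")))
  invisible(x)
}

#' Smooth complex coil sensitivity maps
#'
#' Virtual receive coils modeled as 2D Gaussian magnitude profiles centered
#' on a ring around the field of view, with a smoothly varying spatial
#' phase per coil. Deterministic.
#'
#' @param grid A [grid_spec()].
#' @param n_coils Number of coils (default 8).
#' @param sigma_frac Gaussian width as a fraction of the FoV (default 0.45).
#' @param ring_frac Coil-center ring radius as a fraction of the FoV.
#' @return Complex array `n x n x n_coils`.
#' @export
make_coil_maps <- function(grid, n_coils = 8L, sigma_frac = 0.45, ring_frac = 0.55) {
  r <- grid_coords(grid); n <- grid$n_xy
  X <- matrix(r, n, n); Y <- matrix(r, n, n, byrow = TRUE)
  sig <- sigma_frac * grid$fov_xy
  out <- array(0 + 0i, c(n, n, n_coils))
  for (c in seq_len(n_coils)) {
    a <- 2 * pi * (c - 1) / n_coils
    px <- ring_frac * grid$fov_xy * cos(a); py <- ring_frac * grid$fov_xy * sin(a)
    mag <- exp(-((X - px)^2 + (Y - py)^2) / (2 * sig^2))
    ph <- a + (0.3 * 2 * pi / grid$fov_xy) * (X * cos(a + 1) + Y * sin(a + 1))
    out[, , c] <- mag * exp(1i * ph)
  }
  out
}

#' Second-order polynomial B0 field map
#'
#' A smooth static-field inhomogeneity map,
#' `b0(x, y) = c0 + c1 x + c2 y + c3 x^2 + c4 y^2 + c5 x y` on normalized
#' coordinates in `[-1, 1]`, rescaled so the peak absolute offset equals
#' `peak_hz`.
#'
#' @param grid A [grid_spec()].
#' @param peak_hz Peak absolute offset (Hz, default 30).
#' @param coeffs Length-6 polynomial coefficients (default a fixed
#'   asymmetric shape).
#' @return Numeric `n x n` matrix (Hz).
#' @export
make_b0_map <- function(grid, peak_hz = 30, coeffs = c(0.1, 0.3, -0.2, 0.5, -0.4, 0.25)) {
  n <- grid$n_xy
  u <- (seq_len(n) - 1 - n / 2) / (n / 2)
  X <- matrix(u, n, n); Y <- matrix(u, n, n, byrow = TRUE)
  b <- coeffs[1] + coeffs[2] * X + coeffs[3] * Y + coeffs[4] * X^2 +
    coeffs[5] * Y^2 + coeffs[6] * X * Y
  if (peak_hz == 0 || max(abs(b)) == 0) return(matrix(0, n, n))
  b * (peak_hz / max(abs(b)))
}

# fractional pixel coverage of a disc, by supersampling
disc_coverage <- function(grid, cx, cy, radius, ss = 4L) {
  n <- grid$n_xy
  h <- grid$fov_xy / n
  off <- ((seq_len(ss) - 0.5) / ss - 0.5) * h
  r <- grid_coords(grid)
  cov <- matrix(0, n, n)
  for (ox in off) for (oy in off) {
    inx <- (r + ox - cx)^2
    iny <- (r + oy - cy)^2
    cov <- cov + (outer(inx, iny, `+`) <= radius^2)
  }
  cov / ss^2
}

derenzo_tube_centers <- function(d, apex_radius, angle) {
  h <- sqrt(3) * d
  local <- rbind(c(0, 0),
                 c(-d, h), c(d, h),
                 c(-2 * d, 2 * h), c(0, 2 * h), c(2 * d, 2 * h))
  local[, 2] <- local[, 2] + apex_radius
  rot <- rbind(c(cos(angle), -sin(angle)), c(sin(angle), cos(angle)))
  # local frame: +y radial; rotate so +y points along `angle`
  pts <- t(rot %*% rbind(local[, 1], local[, 2]))
  colnames(pts) <- c("x", "y")
  pts
}

#' Derenzo-style structural-metabolic phantom
#'
#' Digital analogue of a resolution phantom: five angular sets of tubes
#' with diameters 2, 4, 6, 8 and 10 mm, each set holding six tubes of one
#' diameter in a triangular arrangement with center spacing twice the
#' diameter, immersed in a cylindrical saline bath. Tubes carry creatine
#' (default 10 mM); the bath carries water only. The relative water
#' amplitude is raised inside the tubes (Gd-shortened T1 contrast for
#' water imaging).
#'
#' @param grid A [grid_spec()].
#' @param tube_diameters Tube diameters (m); default `c(2,4,6,8,10)*1e-3`.
#'   An empty vector gives a uniform bath.
#' @param tubes_per_set Tubes per set (6; the triangular layout is fixed).
#' @param container_diameter Inner container diameter (m, default 0.13333).
#' @param creatine_mM Creatine concentration in the tubes (default 10).
#' @param tube_water_amp Relative water amplitude inside tubes (bath = 1).
#'   The default 5 is the gradient-echo steady-state ratio
#'   `(1-E1)/(1-cos(a)E1)` for Gd-shortened T1 of ~0.25 s against ~3 s
#'   saline at TR 100 ms and 40 degree flip angle (T1-weighted water
#'   imaging of the doped tubes).
#' @param t2star T2* (s) used across the phantom (default 0.05).
#' @param n_coils Number of virtual coils (default 8).
#' @param b0_peak_hz Peak B0 offset (Hz, default 0: well-shimmed phantom).
#' @param apex_radius_base,apex_radius_slope Radial placement of each set's
#'   inner tube: `apex = base + slope * diameter`.
#' @param ss Rasterization supersampling factor per axis (default 4).
#' @return A `phantom_scene`; `$tube_table` lists per-tube set, diameter,
#'   center and rasterized area (m^2), `$tube_coverage` the summed
#'   fractional coverage map.
#' @export
build_derenzo <- function(grid, tube_diameters = c(2, 4, 6, 8, 10) * 1e-3,
                          tubes_per_set = 6L, container_diameter = 0.13333,
                          creatine_mM = 10, tube_water_amp = 5,
                          t2star = 0.05, n_coils = 8L, b0_peak_hz = 0,
                          apex_radius_base = 0.008, apex_radius_slope = 1.0,
                          ss = 4L) {
  if (tubes_per_set != 6L)
    stop("the triangular layout is defined for 6 tubes per set")
  n <- grid$n_xy
  Rc <- container_diameter / 2
  n_sets <- length(tube_diameters)

  tube_rows <- list()
  for (s in seq_len(n_sets)) {
    d <- tube_diameters[s]
    a <- apex_radius_base + apex_radius_slope * d
    ang <- pi / 2 + 2 * pi * (s - 1) / max(1, n_sets)
    pts <- derenzo_tube_centers(d, a, ang)
    rad <- sqrt(pts[, 1]^2 + pts[, 2]^2) + d / 2
    if (any(rad > Rc))
      stop(sprintf("geometric overflow: tube set %d (diameter %.1f mm) exceeds the container",
                   s, 1e3 * d))
    tube_rows[[s]] <- data.frame(set = s, diameter = d,
                                 cx = pts[, 1], cy = pts[, 2])
  }
  tube_table <- if (n_sets) do.call(rbind, tube_rows) else
    data.frame(set = integer(), diameter = numeric(), cx = numeric(), cy = numeric())
  if (nrow(tube_table) > 1) {
    dx <- outer(tube_table$cx, tube_table$cx, `-`)
    dy <- outer(tube_table$cy, tube_table$cy, `-`)
    lim <- outer(tube_table$diameter, tube_table$diameter, `+`) / 2
    dd <- sqrt(dx^2 + dy^2); diag(dd) <- Inf
    if (any(dd < lim)) {
      bad <- which(dd < lim, arr.ind = TRUE)[1, ]
      stop(sprintf("geometric overflow: tubes of sets %d and %d overlap",
                   tube_table$set[bad[1]], tube_table$set[bad[2]]))
    }
  }

  container_cov <- disc_coverage(grid, 0, 0, Rc, ss)
  tube_cov <- matrix(0, n, n)
  label <- matrix(0L, n, n)
  label[container_cov > 0.5] <- 1L          # bath
  areas <- numeric(nrow(tube_table))
  pix_area <- (grid$fov_xy / n)^2
  set_cov <- vector("list", n_sets)
  for (s in seq_len(n_sets)) set_cov[[s]] <- matrix(0, n, n)
  for (i in seq_len(nrow(tube_table))) {
    cov <- disc_coverage(grid, tube_table$cx[i], tube_table$cy[i],
                         tube_table$diameter[i] / 2, ss)
    areas[i] <- sum(cov) * pix_area
    tube_cov <- tube_cov + cov
    set_cov[[tube_table$set[i]]] <- set_cov[[tube_table$set[i]]] + cov
  }
  tube_table$rasterized_area <- areas
  for (s in seq_len(n_sets)) label[set_cov[[s]] > 0.5] <- 1L + s
  tube_cov <- pmin(tube_cov, 1)

  conc <- list(cr = creatine_mM * tube_cov)
  water_amp <- container_cov + (tube_water_amp - 1) * tube_cov
  t2map <- matrix(t2star, n, n)
  scene_masks <- list(object = container_cov > 0.5,
                      brain = container_cov > 0.5, lipid = NULL)
  new_phantom_scene(grid, label, conc, t2map,
                    make_b0_map(grid, b0_peak_hz),
                    make_coil_maps(grid, n_coils),
                    water_amp, scene_masks,
                    extra = list(tube_table = tube_table, tube_coverage = tube_cov,
                                 container_coverage = container_cov))
}

#' Brain-like synthetic scene with a lipid ring
#'
#' An elliptical head with a subcutaneous-lipid annulus and a brain
#' interior carrying spatially structured NAA, total-creatine and choline
#' maps, a second-order B0 map and Gaussian coil sensitivities. This is the
#' standard scene for end-to-end metabolite-recovery experiments.
#'
#' @param grid A [grid_spec()].
#' @param n_coils Number of coils (default 8).
#' @param b0_peak_hz Peak B0 offset (Hz, default 30).
#' @param lipid_amp Lipid concentration on the skull annulus (default 200).
#' @param t2star Brain T2* (s, default 0.032; ~10 Hz Lorentzian linewidth).
#' @return A `phantom_scene` with masks `object`, `brain` and `lipid`.
#' @export
build_brain_scene <- function(grid, n_coils = 8L, b0_peak_hz = 30,
                              lipid_amp = 200, t2star = 0.032) {
  n <- grid$n_xy
  r <- grid_coords(grid) / grid$fov_xy            # normalized [-0.5, 0.5)
  X <- matrix(r, n, n); Y <- matrix(r, n, n, byrow = TRUE)
  ell <- function(sx, sy) (X / sx)^2 + (Y / sy)^2 <= 1
  head <- ell(0.42, 0.46)
  ## subcutaneous lipid ring, separated from the brain by a CSF/skull gap
  ## (about one voxel at the default grids), as in a real head
  lipid <- head & !ell(0.37, 0.41)
  brain <- ell(0.32, 0.36)

  blob <- function(cx, cy, s) exp(-((X - cx)^2 + (Y - cy)^2) / (2 * s^2))
  naa <- (10 + 3 * sin(2 * pi * X) + 2 * blob(0.12, 0.1, 0.08) -
            3 * blob(-0.15, -0.05, 0.1))
  cr <- (8 + 2 * cos(2 * pi * Y) + 2 * blob(-0.1, 0.15, 0.09))
  cho <- (3 + 1.5 * sqrt(X^2 + Y^2) / 0.5 + 1 * blob(0.05, -0.18, 0.07))
  conc <- list(naa = pmax(0, naa) * brain,
               cr = pmax(0, cr) * brain,
               cho = pmax(0, cho) * brain,
               lipid = lipid_amp * lipid)
  label <- matrix(0L, n, n); label[lipid] <- 2L; label[brain] <- 1L
  new_phantom_scene(grid, label, conc,
                    matrix(t2star, n, n),
                    make_b0_map(grid, b0_peak_hz),
                    make_coil_maps(grid, n_coils),
                    head * 1.0,
                    list(object = head, brain = brain, lipid = lipid))
}
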