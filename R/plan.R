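#' @title Trajectory plans
#' @description
#' A `trajectory_plan` bundles an encoding grid, an ordered table of circles
#' (one row per excitation) and the sampling parameters shared by all
#' circles: the number of ADC samples per revolution `m`, the spectral
#' bandwidth `sbw` (one revolution per spectral dwell), and the number of
#' spectral time points `n_time`. Circle rows carry the center polar
#' coordinates `(r_c, phi_c)` (cycles/m, rad), the circle radius `R`, the
#' starting phase `theta0` on the circle, the partition index `kz_index`,
#' and a flag `is_rosette` marking the small subset of circles placed in
#' rosette fashion through the k-space origin.
#' @name trajectory_plan
NULL

new_trajectory_plan <- function(grid, circles, family, af, seed,
                                samples_per_rev, sbw = 2280, n_time = 500,
                                warnings = character()) {
  stopifnot(inherits(grid, "grid_spec"))
  structure(list(
    grid = grid, circles = circles, family = family, af = af, seed = seed,
    samples_per_rev = as.integer(samples_per_rev), sbw = sbw,
    n_time = as.integer(n_time), warnings = warnings
  ), class = "trajectory_plan")
}

#' @export
print.trajectory_plan <- function(x, ...) {
  cat(sprintf("trajectory_plan [%s]: %d circles on %dx%d grid (n_z=%d), AF=%g, m=%d, sbw=%g Hz\n",
              x$family, nrow(x$circles), x$grid$n_xy, x$grid$n_xy,
              x$grid$n_z, x$af, x$samples_per_rev, x$sbw))
  if (length(x$warnings)) cat(" warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Number of circles in a plan
#' @param plan A `trajectory_plan`.
#' @return Integer count.
#' @export
n_circles <- function(plan) nrow(plan$circles)

default_samples_per_rev <- function(R, fov) max(4L, as.integer(ceiling(2 * pi * R * fov)))

# Core random placement of `count` circles in one partition. The RNG state
# must already be set by the caller.
place_eccentric_circles <- function(count, kmax, dk, R, rosette_fraction,
                                    kz_index, max_draws = 1000L) {
  n_ros <- min(count, as.integer(ceiling(rosette_fraction * count)))
  rmax <- max(kmax - R, R)
  phi_offset <- stats::runif(1, 0, 2 * pi)
  theta0 <- stats::runif(count, 0, 2 * pi)
  r_c <- numeric(count); phi_c <- numeric(count)
  if (n_ros > 0) {
    r_c[seq_len(n_ros)] <- R
    phi_c[seq_len(n_ros)] <- (phi_offset + 2 * pi * (seq_len(n_ros) - 1) / n_ros) %% (2 * pi)
  }
  if (count > n_ros) {
    prev_x <- if (n_ros > 0) r_c[n_ros] * cos(phi_c[n_ros]) else NA_real_
    prev_y <- if (n_ros > 0) r_c[n_ros] * sin(phi_c[n_ros]) else NA_real_
    batch <- 32L
    for (i in seq.int(n_ros + 1L, count)) {
      placed <- FALSE; drawn <- 0L
      while (!placed && drawn < max_draws) {
        nb <- min(batch, max_draws - drawn)
        cand_r <- stats::runif(nb, 0, rmax)
        cand_p <- stats::runif(nb, 0, 2 * pi)
        drawn <- drawn + nb
        if (is.na(prev_x)) { ok <- 1L } else {
          d2 <- (cand_r * cos(cand_p) - prev_x)^2 + (cand_r * sin(cand_p) - prev_y)^2
          ok <- which(d2 >= dk^2)
          ok <- if (length(ok)) ok[1L] else integer()
        }
        if (length(ok)) {
          r_c[i] <- cand_r[ok]; phi_c[i] <- cand_p[ok]
          prev_x <- r_c[i] * cos(phi_c[i]); prev_y <- r_c[i] * sin(phi_c[i])
          placed <- TRUE
        }
      }
      if (!placed)
        stop(sprintf("placement error: no admissible center found for circle %d after %d draws",
                     i, max_draws))
    }
  }
  data.frame(kz_index = as.integer(kz_index), r_c = r_c, phi_c = phi_c,
             R = R, theta0 = theta0,
             is_rosette = seq_len(count) <= n_ros)
}

#' Design one random eccentric-circle encoding plane
#'
#' Places `max(1, round(N_full / af))` circles of radius `R` in one k-space
#' partition, where `N_full` is [full_sampling_count()]. A small leading
#' subset (fraction `rosette_fraction`, below 5% of the total) is positioned
#' in rosette fashion: center radius `r_c = R` with uniformly spaced
#' azimuths, so each passes through the k-space origin and the center of
#' k-space is always completely sampled. The remaining circle centers are
#' drawn with uniform probability, `r_c ~ U[0, max(kmax - R, R)]` and
#' `phi_c ~ U[0, 2*pi)`, redrawing any candidate whose center lies closer
#' than the Nyquist distance `dk` to the previous circle's center. The
#' homogeneous draw of polar center coordinates yields a sampling density
#' close to `1/||k||` outside the rosette-covered core.
#'
#' @param grid A [grid_spec()].
#' @param R Circle radius (cycles/m), `0 < R <= kmax/2`.
#' @param af Acceleration factor (>= 1).
#' @param rosette_fraction Fraction of circles in the central rosette subset
#'   (default 0.04, must be <= 0.05).
#' @param seed Integer RNG seed; plans are bit-reproducible given the seed.
#' @param kz_index Partition index stored with each circle (default 0).
#' @param max_draws Redraw budget per circle before a placement error.
#' @return A data frame of circles (see [trajectory_plan]).
#' @export
design_eccentric_plane <- function(grid, R, af = 1, rosette_fraction = 0.04,
                                   seed = 1L, kz_index = 0L, max_draws = 1000L) {
  kmax <- grid$kmax
  if (R <= 0 || R > kmax / 2) stop("R must satisfy 0 < R <= kmax/2")
  if (af < 1) stop("af must be >= 1")
  if (rosette_fraction < 0 || rosette_fraction > 0.05)
    stop("rosette_fraction must be in [0, 0.05]")
  count <- max(1L, as.integer(round(full_sampling_count(grid$n_xy, kmax, R) / af)))
  rng <- local_rng(seed)
  on.exit(rng$restore(), add = TRUE)
  place_eccentric_circles(count, kmax, grid$dk, R, rosette_fraction,
                          kz_index, max_draws)
}

#' Design a full 2D eccentric-circle plan
#'
#' Convenience wrapper around [design_eccentric_plane()] returning a
#' [trajectory_plan] for a single partition.
#'
#' @inheritParams design_eccentric_plane
#' @param sbw Spectral bandwidth (Hz); one circle revolution per dwell.
#' @param n_time Number of spectral time points.
#' @param samples_per_rev ADC samples per revolution; default
#'   `ceil(2*pi*R*fov_xy)` (Nyquist along the circumference).
#' @return A `trajectory_plan` of family `"eccentric"`.
#' @export
design_eccentric_2d <- function(grid, R, af = 1, rosette_fraction = 0.04,
                                seed = 1L, sbw = 2280, n_time = 500,
                                samples_per_rev = NULL) {
  circles <- design_eccentric_plane(grid, R, af, rosette_fraction, seed)
  m <- if (is.null(samples_per_rev)) default_samples_per_rev(R, grid$fov_xy)
       else as.integer(samples_per_rev)
  if (m < 4L) stop("samples_per_rev must be >= 4")
  new_trajectory_plan(grid, circles, "eccentric", af, seed, m, sbw, n_time)
}

#' Design a 3D stack of eccentric-circle planes
#'
#' Builds per-partition circle lists with the per-partition counts and
#' extents of [stack_circle_counts()] (ellipsoid or cylinder coverage).
#' Independent per-partition RNG substreams are derived from the master
#' seed, so each partition's plan does not depend on the other partitions.
#' If `R` exceeds half a partition's in-plane extent `kmax(kz)` it is
#' clamped to `kmax(kz)/2` there (keeping every sample of the partition
#' inside its disc) and a warning is recorded in the plan.
#'
#' @inheritParams design_eccentric_2d
#' @param coverage `"ellipsoid"` or `"cylinder"`.
#' @return A `trajectory_plan` with circles from all partitions.
#' @export
design_stack <- function(grid, R, af = 1, rosette_fraction = 0.04, seed = 1L,
                         coverage = c("ellipsoid", "cylinder"),
                         sbw = 2280, n_time = 500, samples_per_rev = NULL) {
  coverage <- match.arg(coverage)
  if (R <= 0 || R > grid$kmax / 2) stop("R must satisfy 0 < R <= kmax/2")
  tab <- stack_circle_counts(grid, R, af, coverage)
  clamp <- tab$kmax_kz < 2 * R
  tab$R_eff <- ifelse(clamp, tab$kmax_kz / 2, pmin(R, tab$kmax_kz))
  warns <- character()
  if (any(clamp))
    warns <- sprintf("R clamped to kmax(kz)/2 for partitions: %s",
                     paste(tab$kz_index[clamp], collapse = ","))
  rng <- local_rng(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, grid$n_z)
  rng$restore()
  parts <- lapply(seq_len(grid$n_z), function(p) {
    prng <- local_rng(sub_seeds[p])
    on.exit(prng$restore(), add = TRUE)
    place_eccentric_circles(tab$count[p], tab$kmax_kz[p], grid$dk,
                            tab$R_eff[p], rosette_fraction, tab$kz_index[p])
  })
  circles <- do.call(rbind, parts)
  m <- if (is.null(samples_per_rev)) default_samples_per_rev(R, grid$fov_xy)
       else as.integer(samples_per_rev)
  new_trajectory_plan(grid, circles, "eccentric", af, seed, m, sbw, n_time,
                      warnings = warns)
}

#' Design comparator circular trajectories
#'
#' Alternative circular encodings used as references for the random
#' eccentric placement:
#' \describe{
#'   \item{rosette}{`ceil(rosette_count(n)/af)` circles of radius `kmax/2`
#'     centered at distance `kmax/2` from the origin with uniformly spaced
#'     azimuths; every circle passes through the k-space center.}
#'   \item{concentric}{Rings centered on the origin with radii `i*dk`,
#'     `i = 1 .. n/2 - 1` (31 rings for n = 64), thinned by taking every
#'     af-th ring.}
#'   \item{uniform}{Same circle count rule as the eccentric family but with
#'     centers drawn uniformly over the disc of radius `kmax - R` (uniform
#'     per area, no density shaping).}
#' }
#'
#' @param grid A [grid_spec()].
#' @param family One of `"rosette"`, `"concentric"`, `"uniform"`.
#' @param af Acceleration factor (>= 1).
#' @param seed RNG seed (used by the uniform family).
#' @param R Circle radius for the uniform family (default `kmax/2`).
#' @inheritParams design_eccentric_2d
#' @return A `trajectory_plan`.
#' @export
design_comparators <- function(grid, family = c("rosette", "concentric", "uniform"),
                               af = 1, seed = 1L, R = NULL,
                               sbw = 2280, n_time = 500, samples_per_rev = NULL) {
  if (af < 1) stop("af must be >= 1")
  family <- match.arg(family)
  kmax <- grid$kmax; dk <- grid$dk; n <- grid$n_xy
  if (family == "rosette") {
    count <- as.integer(ceiling(rosette_count(n) / af))
    Rr <- kmax / 2
    circles <- data.frame(kz_index = 0L,
                          r_c = Rr,
                          phi_c = 2 * pi * (seq_len(count) - 1) / count,
                          R = Rr, theta0 = 0, is_rosette = TRUE)
    m0 <- Rr
  } else if (family == "concentric") {
    radii <- (seq_len(n / 2 - 1)) * dk
    radii <- radii[seq(1, length(radii), by = max(1L, as.integer(round(af))))]
    circles <- data.frame(kz_index = 0L, r_c = 0, phi_c = 0,
                          R = radii, theta0 = 0, is_rosette = FALSE)
    m0 <- max(radii)
  } else {
    if (is.null(R)) R <- kmax / 2
    count <- max(1L, as.integer(round(full_sampling_count(n, kmax, R) / af)))
    rng <- local_rng(seed); on.exit(rng$restore(), add = TRUE)
    r_c <- (kmax - R) * sqrt(stats::runif(count))
    phi_c <- stats::runif(count, 0, 2 * pi)
    theta0 <- stats::runif(count, 0, 2 * pi)
    circles <- data.frame(kz_index = 0L, r_c = r_c, phi_c = phi_c,
                          R = R, theta0 = theta0, is_rosette = FALSE)
    m0 <- R
  }
  m <- if (is.null(samples_per_rev)) default_samples_per_rev(m0, grid$fov_xy)
       else as.integer(samples_per_rev)
  new_trajectory_plan(grid, circles, family, af, seed, m, sbw, n_time)
}

#' k-space sample coordinates of a plan
#'
#' Every circle is sampled at `m = samples_per_rev` uniformly spaced points,
#' `k_j = center + R * (cos(2*pi*j/m + theta0), sin(...))`, `j = 0..m-1`.
#' The same `m` points are revisited on every revolution, i.e. for every
#' spectral time index `t_tau = tau / sbw`.
#'
#' @param plan A `trajectory_plan`.
#' @param circles Optional integer subset of circle rows.
#' @return A matrix with `n_circles * m` rows and columns `kx`, `ky`
#'   (cycles/m), ordered circle-major (all samples of circle 1, then 2, ...).
#' @export
sample_points <- function(plan, circles = NULL) {
  cc <- plan$circles
  if (!is.null(circles)) cc <- cc[circles, , drop = FALSE]
  m <- plan$samples_per_rev
  if (m < 4L) stop("samples_per_rev must be >= 4")
  ang <- 2 * pi * (seq_len(m) - 1) / m
  th <- outer(cc$theta0, ang, `+`)             # nc x m
  kx <- cc$r_c * cos(cc$phi_c) + cc$R * cos(th)
  ky <- cc$r_c * sin(cc$phi_c) + cc$R * sin(th)
  cbind(kx = as.vector(t(kx)), ky = as.vector(t(ky)))
}

#' Retrospectively undersample a plan
#'
#' Keeps the rosette-flagged central circles (they guarantee complete
#' sampling of the k-space center) and a random subset of the remaining
#' circles so that the total count is `round(n_circles / af)`, emulating a
#' retrospective acceleration of an acquired fully sampled data set.
#'
#' @param plan A `trajectory_plan`.
#' @param af Acceleration factor (>= 1).
#' @param seed RNG seed for the subset draw.
#' @param keep_rosette Keep the rosette subset deterministically (default).
#' @return A list with the undersampled `plan` and the integer `index` of
#'   kept circles (for subsetting acquired data).
#' @export
subset_plan <- function(plan, af, seed = 1L, keep_rosette = TRUE) {
  if (af < 1) stop("af must be >= 1")
  nc <- n_circles(plan)
  target <- max(1L, as.integer(round(nc / af)))
  ros <- which(plan$circles$is_rosette)
  if (!keep_rosette) ros <- integer()
  rest <- setdiff(seq_len(nc), ros)
  n_rand <- max(0L, target - length(ros))
  rng <- local_rng(seed); on.exit(rng$restore(), add = TRUE)
  keep <- sort(c(ros, sample(rest, min(n_rand, length(rest)))))
  sub <- plan
  sub$circles <- plan$circles[keep, , drop = FALSE]
  sub$af <- plan$af * af
  list(plan = sub, index = keep)
}

#' Export a plan's circle table to CSV (+ JSON metadata)
#'
#' Writes the circles table as CSV and, alongside it, a small JSON file with
#' the grid and sampling metadata so the plan can be re-imported.
#'
#' @param plan A `trajectory_plan`.
#' @param path Output CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
plan_export <- function(plan, path) {
  utils::write.csv(plan$circles, path, row.names = FALSE)
  meta <- list(n_xy = plan$grid$n_xy, n_z = plan$grid$n_z,
               fov_xy = plan$grid$fov_xy, fov_z = plan$grid$fov_z,
               family = plan$family, af = plan$af, seed = plan$seed,
               samples_per_rev = plan$samples_per_rev, sbw = plan$sbw,
               n_time = plan$n_time, warnings = plan$warnings)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a plan exported by [plan_export()]
#' @param path CSV path written by [plan_export()].
#' @return A `trajectory_plan`.
#' @export
plan_import <- function(path) {
  circles <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- grid_spec(meta$n_xy, meta$fov_xy, meta$n_z,
                    if (meta$n_z > 1) meta$fov_z else NULL)
  new_trajectory_plan(grid, circles, meta$family, meta$af, meta$seed,
                      meta$samples_per_rev, meta$sbw, meta$n_time,
                      warnings = unlist(meta$warnings))
}

# Seed-scoped RNG: sets a local RNG state and restores the caller's on exit.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
}
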