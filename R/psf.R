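#' Point spread function of a sampling plan
#'
#' The image-domain response of the density-compensated adjoint transform to
#' a unit point source at the k-space origin:
#' `PSF(r) = sum_j w_j exp(-i 2 pi k_j . r)` over all sample points of the
#' plan, with Voronoi density-compensation weights `w_j`, evaluated on the
#' plan's image grid and normalized to a unit (real) peak. Incoherent,
#' noise-like sidelobes indicate sampling suited to compressed-sensing
#' reconstruction; coherent sidelobe structure indicates aliasing.
#'
#' @param plan A single-partition `trajectory_plan`.
#' @param weights Optional per-sample weights; default Voronoi
#'   ([voronoi_density()]).
#' @return An object of class `psf_image`: `values` (n x n complex matrix,
#'   unit peak), `peak_location` (row, col), `normalization` (the complex
#'   scalar the raw adjoint was divided by).
#' @export
compute_psf <- function(plan, weights = NULL) {
  if (length(unique(plan$circles$kz_index)) != 1L)
    stop("compute_psf expects a single-partition (2D) plan")
  g <- plan$grid
  pts <- sample_points(plan)
  if (is.null(weights)) weights <- voronoi_density(pts, g$kmax, g$dk)
  img <- nuft_adjoint(as.complex(weights), pts, g)
  v <- matrix(img, g$n_xy, g$n_xy)
  pk <- which.max(abs(v))
  loc <- as.integer(c((pk - 1) %% g$n_xy + 1, (pk - 1) %/% g$n_xy + 1))
  z <- v[pk]
  structure(list(values = v / z, peak_location = loc, normalization = z),
            class = "psf_image")
}

#' @export
print.psf_image <- function(x, ...) {
  cat(sprintf("psf_image: %dx%d, peak at (%d,%d)\n", nrow(x$values),
              ncol(x$values), x$peak_location[1], x$peak_location[2]))
  invisible(x)
}

#' Scalar aliasing metrics of a point spread function
#'
#' Quantifies mainlobe width and sidelobe behaviour: `fwhm` is the full
#' width at half maximum of the angularly averaged radial profile of
#' `|PSF|` through the peak (linear interpolation between radial samples);
#' `peak_sidelobe` is the maximum `|PSF|` at grid points farther than
#' `exclusion_radius` pixels from the peak (relative to the unit peak);
#' `sidelobe_energy` is the fraction of `sum |PSF|^2` outside the exclusion
#' disc.
#'
#' @param psf A `psf_image`.
#' @param exclusion_radius Mainlobe exclusion radius in pixels (>= 1,
#'   default 3).
#' @param n_angles Number of azimuths for the radial profile average.
#' @return A list of class `psf_metrics` with `fwhm` (pixels),
#'   `peak_sidelobe`, `sidelobe_energy`.
#' @export
psf_metrics <- function(psf, exclusion_radius = 3, n_angles = 64L) {
  if (exclusion_radius < 1) stop("exclusion_radius must be >= 1")
  v <- abs(psf$values)
  n <- nrow(v)
  pk <- psf$peak_location

  # angularly averaged radial profile by bilinear interpolation
  radii <- seq(0, n / 2 - 1, by = 0.25)
  ang <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  interp <- function(x, y) {
    x <- pmin(pmax(x, 1), n); y <- pmin(pmax(y, 1), n)
    x0 <- floor(x); y0 <- floor(y)
    x1 <- pmin(x0 + 1, n); y1 <- pmin(y0 + 1, n)
    fx <- x - x0; fy <- y - y0
    v[cbind(x0, y0)] * (1 - fx) * (1 - fy) + v[cbind(x1, y0)] * fx * (1 - fy) +
      v[cbind(x0, y1)] * (1 - fx) * fy + v[cbind(x1, y1)] * fx * fy
  }
  prof <- vapply(radii, function(r) {
    mean(interp(pk[1] + r * cos(ang), pk[2] + r * sin(ang)))
  }, numeric(1))
  prof <- prof / prof[1]
  below <- which(prof < 0.5)
  fwhm <- if (!length(below)) NA_real_ else {
    i <- below[1]
    r0 <- radii[i - 1]; r1 <- radii[i]
    f <- (prof[i - 1] - 0.5) / (prof[i - 1] - prof[i])
    2 * (r0 + f * (r1 - r0))
  }
  fwhm <- max(fwhm, 1)

  d <- sqrt(outer((seq_len(n) - pk[1])^2, (seq_len(n) - pk[2])^2, `+`))
  out <- d > exclusion_radius
  structure(list(fwhm = fwhm,
                 peak_sidelobe = max(v[out]),
                 sidelobe_energy = sum(v[out]^2) / sum(v^2)),
            class = "psf_metrics")
}

#' @export
print.psf_metrics <- function(x, ...) {
  cat(sprintf("psf_metrics: fwhm %.2f px, peak sidelobe %.4f, sidelobe energy %.4f\n",
              x$fwhm, x$peak_sidelobe, x$sidelobe_energy))
  invisible(x)
}
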