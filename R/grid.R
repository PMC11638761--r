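#' Encoding grid specification
#'
#' Describes the Cartesian image/k-space grid of an MRSI encoding: in-plane
#' matrix size, number of kz partitions and fields of view. The in-plane
#' Nyquist distance is `dk = 1/fov_xy` (cycles/m) and the largest in-plane
#' k-space coordinate is `kmax = n_xy / (2 * fov_xy)`. Image coordinates are
#' the centered even-n grid `r_i = (i - n_xy/2) * fov_xy / n_xy` for 0-based
#' voxel index `i`.
#'
#' @param n_xy In-plane matrix size (even integer, >= 4).
#' @param fov_xy In-plane field of view (m).
#' @param n_z Number of kz partitions (default 1, a single plane).
#' @param fov_z Slab field of view (m); required when `n_z > 1`.
#' @return An object of class `grid_spec` with elements `n_xy`, `n_z`,
#'   `fov_xy`, `fov_z`, and derived `dk`, `kmax`, `dkz`.
#' @examples
#' g <- grid_spec(64, 0.22)
#' g$kmax  # 145.45 cycles/m
#' @export
grid_spec <- function(n_xy, fov_xy, n_z = 1L, fov_z = NULL) {
  n_xy <- as.integer(n_xy)
  if (n_xy < 4L || n_xy %% 2L != 0L)
    stop("n_xy must be an even integer >= 4")
  if (!is.numeric(fov_xy) || fov_xy <= 0) stop("fov_xy must be positive")
  n_z <- as.integer(n_z)
  if (n_z < 1L) stop("n_z must be >= 1")
  if (n_z > 1L && (is.null(fov_z) || fov_z <= 0))
    stop("fov_z must be positive when n_z > 1")
  structure(list(
    n_xy = n_xy, n_z = n_z, fov_xy = fov_xy,
    fov_z = if (is.null(fov_z)) fov_xy else fov_z,
    dk = 1 / fov_xy,
    kmax = n_xy / (2 * fov_xy),
    dkz = if (is.null(fov_z)) NA_real_ else 1 / fov_z
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d (x %d partitions), FoV %.3g m, dk %.4g, kmax %.4g cycles/m\n",
              x$n_xy, x$n_xy, x$n_z, x$fov_xy, x$dk, x$kmax))
  invisible(x)
}

#' Centered image-grid coordinates
#'
#' One axis of the centered image grid, `r_i = (i - n/2) * fov / n` for
#' 0-based `i`.
#'
#' @param grid A [grid_spec()].
#' @return Numeric vector of length `n_xy` (m).
#' @export
grid_coords <- function(grid) {
  (seq_len(grid$n_xy) - 1 - grid$n_xy / 2) * grid$fov_xy / grid$n_xy
}

#' Cartesian k-space grid coordinates
#'
#' One axis of the Cartesian k-grid, `k_i = (i - n/2) * dk` for 0-based `i`.
#'
#' @param grid A [grid_spec()].
#' @return Numeric vector of length `n_xy` (cycles/m).
#' @export
grid_kcoords <- function(grid) {
  (seq_len(grid$n_xy) - 1 - grid$n_xy / 2) * grid$dk
}
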