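#' Composed encoding operator W.F.C.B
#'
#' Bundles everything needed to map an image-domain FID series to weighted
#' k-space samples: the non-uniform Fourier transform of the plan's sample
#' points (`F`), coil sensitivities (`C`), the B0 frequency-shift phase
#' `B = exp(i 2 pi t dB0)` evaluated exactly per time point, and the
#' Hamming residual weighting (`W`). Voronoi density-compensation weights
#' are precomputed for adjoint (gridding) reconstructions.
#'
#' @param plan A `trajectory_plan`.
#' @param coil_maps Complex `n x n x C` array, a `coil_maps` object from
#'   [estimate_coil_maps()], or `NULL` for a single uniform coil.
#' @param field_map `n x n` B0 map (Hz), a `field_map` object from
#'   [estimate_b0_map()], or `NULL` for none.
#' @param weighting `"hamming"` (default) or `"none"`.
#' @param n_time Number of time points encoded (default `plan$n_time`).
#' @return An object of class `encoding_operator`.
#' @export
encoding_operator <- function(plan, coil_maps = NULL, field_map = NULL,
                              weighting = c("hamming", "none"), n_time = NULL) {
  weighting <- match.arg(weighting)
  g <- plan$grid; n <- g$n_xy
  pts <- sample_points(plan)
  if (inherits(coil_maps, "coil_maps")) coil_maps <- coil_maps$sensitivities
  if (is.null(coil_maps)) coil_maps <- array(1 + 0i, c(n, n, 1))
  if (inherits(field_map, "field_map")) field_map <- field_map$b0_hz
  Tn <- if (is.null(n_time)) plan$n_time else as.integer(n_time)
  times <- (seq_len(Tn) - 1) / plan$sbw
  nC <- dim(coil_maps)[3]
  coils <- matrix(coil_maps, n * n, nC)
  b0 <- if (is.null(field_map) || all(field_map == 0)) NULL else as.vector(field_map)
  structure(list(
    plan = plan, grid = g, points = pts,
    nuft = nuft_matrices(pts, g),
    coils = coils, n_coils = nC, b0 = b0, times = times, n_time = Tn,
    bphase = if (is.null(b0)) NULL else exp(2i * pi * outer(b0, times)),
    w = if (weighting == "hamming") hamming_weights(pts, g$kmax)
        else rep(1, nrow(pts)),
    weighting = weighting,
    dcf = voronoi_density(pts, g$kmax, g$dk)
  ), class = "encoding_operator")
}

#' @export
print.encoding_operator <- function(x, ...) {
  cat(sprintf("encoding_operator: %d samples x %d time points x %d coils, %s weighting, B0 %s\n",
              nrow(x$points), x$n_time, x$n_coils, x$weighting,
              if (is.null(x$b0)) "off" else "on"))
  invisible(x)
}

#' Apply the forward encoding operator
#'
#' Maps an image-domain series `rho` (`Nr x T`) to unweighted k-space
#' samples for every coil: `F(C_c B rho)`.
#'
#' @param op An [encoding_operator()].
#' @param rho Complex `Nr x T` matrix (or `n x n (x T)` array).
#' @return Complex array `(samples, T, coils)`.
#' @export
op_forward <- function(op, rho) {
  rho <- as_image_matrix(rho, op$grid)
  if (!is.null(op$bphase)) rho <- rho * op$bphase
  out <- array(0 + 0i, c(nrow(op$points), ncol(rho), op$n_coils))
  for (c in seq_len(op$n_coils))
    out[, , c] <- nuft_fwd_op(op$nuft, op$coils[, c] * rho)
  out
}

#' Apply the adjoint encoding operator
#'
#' Exact adjoint of [op_forward()]:
#' `sum_c conj(B) conj(C_c) F^H s_c`.
#'
#' @param op An [encoding_operator()].
#' @param s Complex array `(samples, T, coils)`.
#' @return Complex `Nr x T` matrix.
#' @export
op_adjoint <- function(op, s) {
  d <- dim(s)
  acc <- matrix(0 + 0i, op$grid$n_xy^2, d[2])
  for (c in seq_len(op$n_coils))
    acc <- acc + Conj(op$coils[, c]) * nuft_adj_op(op$nuft, matrix(s[, , c], d[1], d[2]))
  if (!is.null(op$bphase)) acc <- acc * Conj(op$bphase)
  acc
}

#' Density-compensated, B0-corrected adjoint reconstruction
#'
#' Gridding reconstruction of coil-wise (k,t) data: Voronoi weights applied
#' per sample, adjoint NUFT per coil and time point, coil combination with
#' conjugate sensitivities and per-voxel conjugate B0 phase
#' `exp(-i 2 pi t dB0(r))`. This is both a quick-look reconstruction and
#' the initialization of the iterative solver.
#'
#' @param s `spectro_kdata` or a complex array `(samples, T, coils)`.
#' @param op An [encoding_operator()].
#' @return Complex `Nr x T` matrix (normalized by the total density weight).
#' @export
b0_correct_adjoint <- function(s, op) {
  if (inherits(s, "spectro_kdata")) s <- s$values
  d <- dim(s)
  acc <- matrix(0 + 0i, op$grid$n_xy^2, d[2])
  for (c in seq_len(op$n_coils))
    acc <- acc + Conj(op$coils[, c]) *
      nuft_adj_op(op$nuft, op$dcf * matrix(s[, , c], d[1], d[2]))
  if (!is.null(op$bphase)) acc <- acc * Conj(op$bphase)
  acc / sum(op$dcf)
}
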