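#' @title Exact non-uniform Fourier transform (type 1)
#' @description
#' The encoding operator maps a Cartesian image onto arbitrary k-space
#' sample locations, `(F rho)_j = sum_i exp(+i 2 pi k_j . r_i) rho_i`, with
#' `r_i` the centered image grid. The transform is evaluated exactly using
#' the separability of the phase, `exp(i2pi k.r) = exp(i2pi kx x) *
#' exp(i2pi ky y)`: one `M x n` complex matrix per axis and a BLAS matrix
#' product per image column block, which at the matrix sizes of this
#' package is both exact and fast. The adjoint conjugates the exponent.
#' @name nuft
NULL

nuft_matrices <- function(points, grid) {
  r <- grid_coords(grid)
  list(Ex = exp(2i * pi * outer(points[, 1], r)),
       Ey = exp(2i * pi * outer(points[, 2], r)),
       M = nrow(points), n = grid$n_xy)
}

# image Nr x T -> samples M x T
nuft_fwd_op <- function(op, X) {
  n <- op$n; M <- op$M
  Tn <- ncol(X)
  dim(X) <- c(n, n * Tn)
  A <- op$Ex %*% X                       # M x (n*T)
  S <- matrix(0 + 0i, M, Tn)
  off <- n * (seq_len(Tn) - 1L)
  for (iy in seq_len(n))
    S <- S + op$Ey[, iy] * A[, iy + off, drop = FALSE]
  S
}

# samples M x T -> image Nr x T
nuft_adj_op <- function(op, S) {
  n <- op$n
  Tn <- ncol(S)
  ExH <- Conj(t(op$Ex))                  # n x M
  X <- array(0 + 0i, c(n, n, Tn))
  for (iy in seq_len(n)) {
    G <- Conj(op$Ey[, iy]) * S           # M x T
    X[, iy, ] <- ExH %*% G
  }
  dim(X) <- c(n * n, Tn)
  X
}

as_image_matrix <- function(x, grid) {
  n <- grid$n_xy
  if (is.matrix(x) && nrow(x) == n && ncol(x) == n) { dim(x) <- c(n * n, 1L); x }
  else if (length(dim(x)) == 3L) { d <- dim(x); dim(x) <- c(d[1] * d[2], d[3]); x }
  else if (is.matrix(x) && nrow(x) == n * n) x
  else if (length(x) == n * n) matrix(x, n * n, 1L)
  else stop("image shape inconsistent with grid")
}

#' Forward non-uniform Fourier transform
#'
#' Evaluates `(F rho)_{j,t} = sum_i exp(+i 2 pi k_j . r_i) rho_{i,t}`
#' exactly, batched over the columns (time points) of `rho`.
#'
#' @param image Complex image: `n x n` matrix, `n x n x T` array, or
#'   `Nr x T` matrix with `Nr = n^2` (column-major voxel order).
#' @param points Numeric matrix (M x 2) of k-space coordinates (cycles/m).
#' @param grid A [grid_spec()].
#' @return Complex `M x T` matrix of samples.
#' @export
nuft_forward <- function(image, points, grid) {
  op <- nuft_matrices(as.matrix(points), grid)
  nuft_fwd_op(op, as_image_matrix(image, grid))
}

#' Adjoint non-uniform Fourier transform
#'
#' Evaluates `rho_{i,t} = sum_j exp(-i 2 pi k_j . r_i) s_{j,t}`, the exact
#' adjoint of [nuft_forward()].
#'
#' @param samples Complex `M x T` matrix (or length-M vector).
#' @inheritParams nuft_forward
#' @return Complex `Nr x T` matrix (`Nr = n^2`, column-major voxel order).
#' @export
nuft_adjoint <- function(samples, points, grid) {
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1L)
  op <- nuft_matrices(as.matrix(points), grid)
  nuft_adj_op(op, samples)
}
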