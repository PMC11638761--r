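#' Linear-combination fit of voxel FIDs into metabolite maps
#'
#' Per-voxel amplitudes solving `min_c || fid - sum_m c_m b_m(t) ||^2` with
#' real (optionally non-negative) amplitudes, where `b_m` are the
#' unit-concentration basis FIDs of [basis_fids()] evaluated on the same
#' time grid. Amplitudes are divided by the water-reference amplitude to
#' yield institutional units (scale constant 1).
#'
#' @param rho Complex `Nr x T` image time series (e.g. [recon_rho()]).
#' @param basis A [spectral_basis()].
#' @param times Time grid (s) of the series.
#' @param t2star Lineshape T2* (s) used to evaluate the basis (default
#'   0.032).
#' @param metabolites Which basis entries to fit (default all but water).
#' @param water_ref_amp Water-reference amplitude map (matrix or vector),
#'   or `NULL` for no referencing.
#' @param mask Logical voxel mask; outside voxels are `NA`.
#' @param nonneg Enforce non-negative amplitudes (default TRUE, via
#'   non-negative least squares).
#' @return Object of class `metabolite_maps`: named list `maps` of `n x n`
#'   amplitude matrices, `residual` (RMS per voxel), `mask`.
#' @export
fit_basis_maps <- function(rho, basis, times, t2star = 0.032,
                           metabolites = NULL, water_ref_amp = NULL,
                           mask = NULL, nonneg = TRUE) {
  if (is.null(metabolites))
    metabolites <- setdiff(names(basis$metabolites), "water")
  B <- basis_fids(basis, t2star, times, metabolites)
  cn <- svd(B, nu = 0, nv = 0)$d
  if (cn[length(cn)] < 1e-10 * cn[1]) {
    G <- abs(crossprod(Conj(B), B))
    G <- G / sqrt(outer(diag(Re(G)), diag(Re(G))))
    diag(G) <- 0
    bad <- which(Re(G) > 1 - 1e-6, arr.ind = TRUE)
    pairs <- if (nrow(bad)) paste(metabolites[bad[, 1]], metabolites[bad[, 2]],
                                  sep = "~", collapse = ", ") else "unknown"
    stop(sprintf("rank-deficient basis; collinear pairs: %s", pairs))
  }
  A <- rbind(Re(B), Im(B))                     # 2T x M real design
  Nr <- nrow(rho)
  n <- as.integer(sqrt(Nr))
  if (is.null(mask)) mask <- rep(TRUE, Nr)
  mask <- as.vector(mask)
  amps <- matrix(NA_real_, Nr, length(metabolites))
  resid <- rep(NA_real_, Nr)
  qrA <- qr(A)
  for (i in which(mask)) {
    y <- c(Re(rho[i, ]), Im(rho[i, ]))
    cvec <- if (nonneg) pracma::lsqnonneg(A, y)$x else qr.coef(qrA, y)
    amps[i, ] <- cvec
    resid[i] <- sqrt(mean((y - A %*% cvec)^2))
  }
  ref <- if (is.null(water_ref_amp)) 1 else as.vector(water_ref_amp)
  maps <- lapply(seq_along(metabolites), function(j) {
    m <- amps[, j] / ref
    matrix(m, n, n)
  })
  names(maps) <- metabolites
  structure(list(maps = maps, residual = matrix(resid, n, n),
                 mask = matrix(mask, n, n)),
            class = "metabolite_maps")
}

#' @export
print.metabolite_maps <- function(x, ...) {
  cat(sprintf("metabolite_maps: %s over %d voxels\n",
              paste(names(x$maps), collapse = ", "), sum(x$mask)))
  invisible(x)
}
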