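#' HSVD water removal
#'
#' Decomposes an FID into damped complex exponentials via a rank-truncated
#' Hankel singular value decomposition and subtracts the components whose
#' frequencies fall inside the water band. Component poles are recovered
#' with the state-space shift method (eigenvalues of the pseudo-inverse
#' shift of the truncated left singular vectors); component amplitudes are
#' re-fit by complex linear least squares on the full FID before the
#' in-band components are subtracted.
#'
#' @param fid Complex FID vector.
#' @param sbw Spectral bandwidth (Hz); the FID dwell is `1/sbw`.
#' @param water_band Frequency interval (Hz) relative to the carrier,
#'   default `c(-60, 60)`.
#' @param model_order Number of exponential components (default 25; must be
#'   below half the FID length).
#' @return Complex vector of the same length with the in-band components
#'   removed. Attributes `components` (data frame of frequency Hz, damping
#'   1/s, amplitude) and `removed` (logical per component).
#' @export
hsvd_water_removal <- function(fid, sbw, water_band = c(-60, 60), model_order = 25L) {
  N <- length(fid)
  if (model_order >= N / 2) stop("model_order must be < length(fid)/2")
  L <- as.integer(ceiling(N / 2))
  Hk <- sapply(seq_len(N - L + 1L), function(j) fid[j:(j + L - 1L)])
  sv <- svd(Hk, nu = model_order, nv = 0)
  Us <- sv$u
  Ub <- Us[-L, , drop = FALSE]; Ut <- Us[-1, , drop = FALSE]
  Z <- qr.solve(Ub, Ut)
  poles <- eigen(Z, only.values = TRUE)$values
  freq <- Arg(poles) * sbw / (2 * pi)
  damp <- -log(pmax(Mod(poles), 1e-12)) * sbw
  V <- t(vapply(seq_len(N), function(t) poles^(t - 1), complex(model_order)))
  amp <- tryCatch(qr.solve(V, fid),
                  error = function(e) {
                    warning("ill-conditioned amplitude fit; using ridge-regularized solution")
                    G <- Conj(t(V)) %*% V
                    qr.solve(G + diag(1e-10 * max(Mod(diag(G))), model_order),
                             Conj(t(V)) %*% fid)[, 1]
                  })
  inb <- freq >= water_band[1] & freq <= water_band[2]
  cleaned <- fid - if (any(inb)) V[, inb, drop = FALSE] %*% amp[inb] else 0
  cleaned <- as.vector(cleaned)
  attr(cleaned, "components") <- data.frame(freq_hz = freq, damping = damp,
                                            amplitude = Mod(amp))
  attr(cleaned, "removed") <- inb
  cleaned
}

#' Estimate a B0 field map from a water image time series
#'
#' Per-voxel frequency offset as the weighted least-squares slope of the
#' temporal phase evolution, computed from wrap-free inter-frame phase
#' increments `Arg(y_{t+1} conj(y_t))` weighted by `|y_{t+1} y_t|` (a
#' simplified estimator standing in for parametric spectral estimation).
#' Multi-coil input is combined coherently in the phase products.
#'
#' @param images Complex array `(n, n, T)` or `(n, n, T, C)` of
#'   water-dominated images, `T >= 3`.
#' @param dwell Time between frames (s).
#' @param mask_threshold Magnitude threshold for the valid mask, as a
#'   fraction of the maximum mean magnitude (default 0.05).
#' @param wrap_fraction Offsets beyond `wrap_fraction/dwell/2` are flagged
#'   wrap-ambiguous and excluded from the valid mask (default 0.9).
#' @return List of class `field_map`: `b0_hz` (n x n), `valid_mask`.
#' @export
estimate_b0_map <- function(images, dwell, mask_threshold = 0.05,
                            wrap_fraction = 0.9) {
  d <- dim(images)
  if (length(d) == 3L) { dim(images) <- c(d, 1L); d <- dim(images) }
  if (d[3] < 3L) stop("need at least 3 time points")
  n <- d[1]; Tn <- d[3]; nC <- d[4]
  num <- matrix(0 + 0i, n, n)
  mag <- matrix(0, n, n)
  for (c in seq_len(nC)) {
    y <- images[, , , c]
    num <- num + apply(y[, , -1] * Conj(y[, , -Tn]), c(1, 2), sum)
    mag <- mag + apply(abs(y), c(1, 2), mean)
  }
  b0 <- Arg(num) / (2 * pi * dwell)
  valid <- mag > mask_threshold * max(mag)
  wrap_lim <- wrap_fraction / (2 * dwell)
  valid <- valid & abs(b0) < wrap_lim
  structure(list(b0_hz = b0, valid_mask = valid), class = "field_map")
}

# separable Gaussian smoothing with reflecting boundaries
gauss_smooth <- function(img, fwhm) {
  if (fwhm <= 0) return(img)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  rad <- min(nrow(img) - 1L, max(1L, ceiling(3 * sigma)))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2)); k <- k / sum(k)
  smooth1 <- function(m) {
    n <- nrow(m)
    idx <- c(rev(seq_len(rad)), seq_len(n), n + 1 - seq_len(rad))
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + n - 1), , drop = FALSE]
    out
  }
  if (is.complex(img))
    t(smooth1(t(smooth1(Re(img))))) + 1i * t(smooth1(t(smooth1(Im(img)))))
  else t(smooth1(t(smooth1(img))))
}

#' Estimate coil sensitivity maps from water-reference images
#'
#' Smoothed-ratio estimator: each coil's first-time-point image is
#' Gaussian-smoothed and divided by the smoothed root-sum-of-squares
#' combination; the output is exactly RSS-normalized inside the mask.
#'
#' @param images Complex array `(n, n, C)` (first-time-point coil images).
#' @param smoothing_fwhm Gaussian smoothing FWHM in voxels (default 3).
#' @param mask_threshold RSS threshold (fraction of max) below which voxels
#'   are excluded (default 0.05).
#' @return List of class `coil_maps`: `sensitivities` (n x n x C), `mask`.
#' @export
estimate_coil_maps <- function(images, smoothing_fwhm = 3, mask_threshold = 0.05) {
  d <- dim(images)
  if (length(d) == 2L) { dim(images) <- c(d, 1L); d <- dim(images) }
  n <- d[1]; nC <- d[3]
  sm <- array(0 + 0i, d)
  for (c in seq_len(nC)) sm[, , c] <- gauss_smooth(images[, , c], smoothing_fwhm)
  rss <- sqrt(apply(abs(sm)^2, c(1, 2), sum))
  mask <- rss > mask_threshold * max(rss)
  sens <- array(0 + 0i, d)
  for (c in seq_len(nC)) {
    s <- sm[, , c]
    s[mask] <- s[mask] / rss[mask]
    s[!mask] <- 0
    sens[, , c] <- s
  }
  structure(list(sensitivities = sens, mask = mask), class = "coil_maps")
}

#' Backward linear prediction of the missing FID start
#'
#' FID acquisition starts at the echo time TE > 0, which imprints a
#' first-order spectral phase. Backward linear prediction extrapolates the
#' FID to t = 0: prediction coefficients `b` with
#' `x[n] = sum_k b_k x[n+k]` are fit by least squares on the early FID and
#' applied recursively to prepend `n_back` samples. Roots of the
#' prediction polynomial outside the unit circle (components that would
#' blow up under backward recursion) are reflected inside, with a warning.
#'
#' @param fid Complex FID starting at TE.
#' @param n_back Number of samples to prepend (TE / dwell).
#' @param lp_order Prediction order (default 8; must be < length/3).
#' @param n_fit Number of leading samples used for the fit (default
#'   `min(length(fid), max(4*lp_order, 64))`).
#' @return Complex vector of length `length(fid) + n_back`; element
#'   `n_back + 1` is the first acquired sample.
#' @export
backward_predict_fid <- function(fid, n_back, lp_order = 8L, n_fit = NULL) {
  N <- length(fid)
  if (lp_order >= N / 3) stop("lp_order must be < length(fid)/3")
  if (n_back == 0) return(fid)
  if (is.null(n_fit)) n_fit <- min(N, max(4L * lp_order, 64L))
  x <- fid[seq_len(n_fit)]
  # x[n] = sum_k b_k x[n+k], rows n = 1 .. n_fit - lp_order
  nr <- n_fit - lp_order
  A <- sapply(seq_len(lp_order), function(k) x[(1 + k):(nr + k)])
  b <- qr.solve(A, x[seq_len(nr)])
  # roots z of 1 - sum b_k z^k are the signal poles; |z| > 1 is unstable
  rts <- polyroot(c(1, -b))
  if (any(Mod(rts) > 1 + 1e-9)) {
    warning("unstable backward-prediction filter; reflecting roots into the unit circle")
    bad <- Mod(rts) > 1 + 1e-9
    rts[bad] <- 1 / Conj(rts[bad])
    # rebuild coefficients from reflected roots: prod_r (1 - z/r) has roots r
    pol <- c(1 + 0i)
    for (r in rts) pol <- c(pol, 0) - c(0, pol / r)
    b <- -pol[-1] / pol[1]
  }
  ext <- c(rep(0 + 0i, n_back), fid)
  for (i in rev(seq_len(n_back)))
    ext[i] <- sum(b * ext[(i + 1):(i + lp_order)])
  ext
}
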