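#' Structural similarity index (SSIM) within a mask
#'
#' Mean local SSIM with a Gaussian window and the standard stabilization
#' constants `K1 = 0.01`, `K2 = 0.03`. The second image `b` is the
#' reference and defines the dynamic range (`max(b) - min(b)` over the
#' mask, unless given explicitly).
#'
#' @param a,b Numeric image matrices of equal size (`b` the reference).
#' @param mask Logical matrix (default all pixels).
#' @param window_sigma Gaussian window sigma in pixels (default 1.5).
#' @param dynamic_range Optional explicit dynamic range.
#' @return Scalar mean SSIM over the mask.
#' @export
ssim <- function(a, b, mask = NULL, window_sigma = 1.5, dynamic_range = NULL) {
  if (!all(dim(a) == dim(b))) stop("images must have the same shape")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(a), ncol(a))
  if (!any(mask)) stop("empty mask")
  L <- if (is.null(dynamic_range)) diff(range(b[mask])) else dynamic_range
  if (L == 0) L <- .Machine$double.eps
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  fwhm <- window_sigma * 2 * sqrt(2 * log(2))
  mu_a <- gauss_smooth(a, fwhm); mu_b <- gauss_smooth(b, fwhm)
  va <- gauss_smooth(a * a, fwhm) - mu_a^2
  vb <- gauss_smooth(b * b, fwhm) - mu_b^2
  cab <- gauss_smooth(a * b, fwhm) - mu_a * mu_b
  smap <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(smap[mask])
}

#' Pearson correlation of two images within a mask
#'
#' @param a,b Numeric image matrices.
#' @param mask Logical matrix (default all; needs >= 3 voxels).
#' @return Correlation coefficient, or `NA` if either input has zero
#'   variance in the mask.
#' @export
pearson_in_mask <- function(a, b, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(a), ncol(a))
  if (sum(mask) < 3) stop("need at least 3 voxels in the mask")
  x <- a[mask]; y <- b[mask]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Spectral SNR and linewidth of a voxel spectrum
#'
#' `snr` is the maximum magnitude in the signal band divided by the
#' standard deviation of the real part in the (disjoint) noise band.
#' `fwhm` is the full width at half maximum of the tallest peak in the
#' signal band measured on the absorption lineshape (the real part after
#' zero-order phasing at the peak), by linear interpolation between
#' frequency bins; for a Lorentzian this equals `1/(pi*T2*)`, whereas the
#' magnitude lineshape would be `sqrt(3)` times broader.
#'
#' @param spectrum Complex spectrum vector.
#' @param freq_hz Frequency axis (Hz), same length.
#' @param signal_band,noise_band Two-element Hz intervals, disjoint.
#' @return List with `snr` and `fwhm_hz`.
#' @export
spectral_snr_fwhm <- function(spectrum, freq_hz, signal_band, noise_band) {
  inb <- function(b) freq_hz >= b[1] & freq_hz <= b[2]
  si <- inb(signal_band); ni <- inb(noise_band)
  if (!any(si) || !any(ni)) stop("empty signal or noise band")
  if (any(si & ni)) stop("signal and noise bands must be disjoint")
  mag <- abs(spectrum)
  pk_rel <- which.max(mag[si])
  pk <- which(si)[pk_rel]
  snr <- mag[pk] / stats::sd(Re(spectrum[ni]))
  absorp <- Re(spectrum * exp(-1i * Arg(spectrum[pk])))
  half <- absorp[pk] / 2
  cross <- function(dir) {
    i <- pk
    while (i + dir >= 1 && i + dir <= length(absorp) && absorp[i + dir] > half)
      i <- i + dir
    j <- i + dir
    if (j < 1 || j > length(absorp)) return(freq_hz[i])
    f <- (absorp[i] - half) / (absorp[i] - absorp[j])
    freq_hz[i] + f * (freq_hz[j] - freq_hz[i])
  }
  list(snr = snr, fwhm_hz = abs(cross(1L) - cross(-1L)))
}

#' Coefficient of variation by region across repetitions
#'
#' For each region and metabolite: sample standard deviation (ddof = 1) of
#' the region-mean amplitude across repetitions, divided by the mean of
#' the region means.
#'
#' @param maps_list List of repetitions; each a named list of metabolite
#'   amplitude maps (matrices).
#' @param region_labels Integer matrix of region labels (0 = outside).
#' @return Data frame with `region`, `metabolite`, `mean`, `sd`, `cov`
#'   (`cov = NA` for regions with zero mean).
#' @export
cov_by_region <- function(maps_list, region_labels) {
  if (length(maps_list) < 2) stop("need at least 2 repetitions")
  mets <- names(maps_list[[1]])
  regions <- sort(setdiff(unique(as.vector(region_labels)), 0))
  out <- expand.grid(region = regions, metabolite = mets,
                     stringsAsFactors = FALSE)
  out$mean <- out$sd <- out$cov <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- region_labels == out$region[i]
    rm_ <- vapply(maps_list, function(m) mean(m[[out$metabolite[i]]][sel]),
                  numeric(1))
    out$mean[i] <- mean(rm_)
    out$sd[i] <- stats::sd(rm_)
    out$cov[i] <- if (out$mean[i] == 0) NA_real_ else out$sd[i] / out$mean[i]
  }
  out
}
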