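#' Voronoi-cell density compensation weights
#'
#' Per-sample density-compensation weights equal to the area of each
#' sample's Voronoi cell, with cells clipped to the disc of radius
#' `kmax + dk/2`. Cell areas are computed by discrete nearest-sample
#' labeling of an oversampled k-space raster (a discretized Voronoi
#' partition): every raster pixel inside the clipped disc is assigned to its
#' nearest sample and cell area is the pixel count times the pixel area.
#' Exactly coincident (and sub-pixel-coincident) samples are grouped and
#' split their cell's area equally. Weights are renormalized so their sum
#' equals the rasterized disc area exactly (partition property).
#'
#' @param points Numeric matrix (M x 2) of k-space coordinates (cycles/m).
#' @param kmax Disc clipping radius parameter; the disc radius is
#'   `kmax + dk/2`.
#' @param dk Nyquist distance (cycles/m); sets the raster pitch.
#' @param oversample Raster oversampling relative to `dk` (default 8; pixel
#'   size `dk/oversample`).
#' @return Numeric vector of M positive weights (cycles^2/m^2).
#' @export
voronoi_density <- function(points, kmax, dk, oversample = 8L) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("need at least 4 points")
  ctr <- sweep(points, 2, colMeans(points))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] < 1e-12 * max(sv[1], 1e-300)) stop("all points are collinear")

  h <- dk / oversample
  Kc <- kmax + dk / 2
  # group exact/sub-pixel duplicates
  gx <- round(points[, 1] / (h / 2)); gy <- round(points[, 2] / (h / 2))
  key <- paste(gx, gy)
  grp <- match(key, unique(key))
  G <- max(grp)
  ux <- as.vector(tapply(points[, 1], grp, mean))
  uy <- as.vector(tapply(points[, 2], grp, mean))
  gsize <- as.vector(table(grp))

  # raster pixels inside the clipped disc
  Np <- 2L * as.integer(ceiling(Kc / h))
  ax <- (seq_len(Np) - 1 - Np / 2 + 0.5) * h
  px <- rep(ax, times = Np); py <- rep(ax, each = Np)
  inside <- px^2 + py^2 <= Kc^2
  px <- px[inside]; py <- py[inside]
  n_pix <- length(px)

  # binned nearest-neighbour labeling
  b <- dk
  nbin <- as.integer(ceiling(2 * Kc / b))
  binx <- function(v) pmin(nbin, pmax(1L, 1L + as.integer(floor((v + Kc) / b))))
  pb <- (binx(py) - 1L) * nbin + binx(px)
  sb_x <- binx(ux); sb_y <- binx(uy)
  pts_by_bin <- split(seq_len(G), (sb_y - 1L) * nbin + sb_x)

  assign_g <- integer(n_pix)
  dmin <- rep(Inf, n_pix)
  pix_by_bin <- split(seq_len(n_pix), pb)
  bx_of <- function(bin) ((bin - 1L) %% nbin) + 1L
  by_of <- function(bin) ((bin - 1L) %/% nbin) + 1L
  for (bin_chr in names(pix_by_bin)) {
    bin <- as.integer(bin_chr)
    pix <- pix_by_bin[[bin_chr]]
    cbx <- bx_of(bin); cby <- by_of(bin)
    s <- 1L
    repeat {
      xs <- max(1L, cbx - s):min(nbin, cbx + s)
      ys <- max(1L, cby - s):min(nbin, cby + s)
      nb_keys <- as.character(rep((ys - 1L) * nbin, each = length(xs)) + xs)
      cand <- unlist(pts_by_bin[nb_keys], use.names = FALSE)
      if (length(cand)) {
        d2 <- outer(px[pix], ux[cand], `-`)^2 + outer(py[pix], uy[cand], `-`)^2
        j <- max.col(-d2, ties.method = "first")
        dd <- d2[cbind(seq_along(pix), j)]
        assign_g[pix] <- cand[j]
        dmin[pix] <- dd
        if (all(dd <= (s * b)^2) ||
            (length(xs) == nbin && length(ys) == nbin)) break
      } else if (length(xs) == nbin && length(ys) == nbin) {
        stop("internal error: empty candidate set over full grid")
      }
      s <- s + 1L
    }
  }

  cnt <- tabulate(assign_g, nbins = G)
  w_g <- cnt * h^2
  # resolution floor for starved groups, then restore the exact partition sum
  if (any(w_g == 0)) w_g[w_g == 0] <- h^2 / 2
  w_g <- w_g * (n_pix * h^2 / sum(w_g))
  out <- (w_g / gsize)[grp]
  attr(out, "disc_area") <- n_pix * h^2
  out
}

#' Hamming k-space weights
#'
#' The residual weighting operator of the reconstruction: a Hamming-window
#' profile decreasing with distance to the k-space center,
#' `w(k) = 0.54 + 0.46 * cos(pi * ||k|| / kmax)`, equal to 1 at the center
#' and 0.08 at `||k|| = kmax`.
#'
#' @param points Numeric matrix (M x 2) of k-space coordinates (cycles/m).
#' @param kmax Largest k-space coordinate (cycles/m).
#' @return Numeric vector of M weights in (0, 1].
#' @export
hamming_weights <- function(points, kmax) {
  r <- pmin(1, sqrt(points[, 1]^2 + points[, 2]^2) / kmax)
  0.54 + 0.46 * cos(pi * r)
}

#' Apply Hamming weighting to sample values
#'
#' Multiplies per-sample residual values by the [hamming_weights()] of the
#' plan's sample coordinates (mode `"hamming"`), or returns them unchanged
#' (mode `"none"`).
#'
#' @param values Complex vector/matrix of per-sample values (samples in rows).
#' @param plan A `trajectory_plan`.
#' @param weighting `"hamming"` or `"none"`.
#' @return Weighted values, same shape as `values`.
#' @export
apply_weighting <- function(values, plan, weighting = c("hamming", "none")) {
  weighting <- match.arg(weighting)
  if (weighting == "none") return(values)
  w <- hamming_weights(sample_points(plan), plan$grid$kmax)
  if (is.matrix(values)) values * w else values * w
}
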