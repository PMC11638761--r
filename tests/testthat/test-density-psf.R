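test_that("voronoi weights on a Cartesian grid are the Nyquist cell area", {
  g <- fix_grid16()
  kx <- grid_kcoords(g)
  pts <- as.matrix(expand.grid(kx = kx, ky = kx))
  pts <- pts[sqrt(pts[, 1]^2 + pts[, 2]^2) <= g$kmax + g$dk / 2, ]
  w <- voronoi_density(pts, g$kmax, g$dk)
  interior <- sqrt(pts[, 1]^2 + pts[, 2]^2) < g$kmax - 2 * g$dk
  expect_lt(max(abs(w[interior] - g$dk^2)) / g$dk^2, 1e-9)
  # partition property: weights tile the rasterized clipped disc exactly
  expect_lt(rel_diff(sum(w), attr(w, "disc_area")), 1e-9)
})

test_that("coincident samples split their cell and collinear input errors", {
  g <- fix_grid16()
  kx <- grid_kcoords(g)
  pts <- as.matrix(expand.grid(kx = kx, ky = kx))
  pts <- pts[sqrt(pts[, 1]^2 + pts[, 2]^2) <= g$kmax + g$dk / 2, ]
  ctr <- which.min(pts[, 1]^2 + pts[, 2]^2)   # central point, interior cell
  dup <- rbind(pts, pts[ctr, , drop = FALSE])
  w <- voronoi_density(dup, g$kmax, g$dk)
  expect_equal(w[ctr], w[nrow(dup)])
  expect_lt(abs(w[ctr] - g$dk^2 / 2) / g$dk^2, 1e-9)
  line <- cbind(seq(-10, 10, length.out = 12), 2 * seq(-10, 10, length.out = 12))
  expect_error(voronoi_density(line, 20, 1), "collinear")
})

test_that("concentric-ring cell areas grow linearly with ring radius", {
  g <- grid_spec(32L, 0.22)
  cp <- design_comparators(g, "concentric")
  pts <- sample_points(cp)
  w <- voronoi_density(pts, g$kmax, g$dk)
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  ring <- round(r / g$dk)
  ring_w <- tapply(w, ring, mean)
  rr <- as.numeric(names(ring_w))
  sel <- rr >= 2 & rr <= 13   # away from center and clipped boundary
  ratio <- ring_w[sel] / rr[sel]
  # oracle: annulus of width dk at radius r*dk shared by m samples
  expect_lt(diff(range(ratio)) / mean(ratio), 0.1)
})

test_that("random-center circle sampling has 1/|k| density outside the rosette core", {
  # Monte-Carlo draw of the center distribution with points on circles,
  # compared per annulus against the analytic 1/|k| curve
  g <- grid_spec(64L, 0.22)
  R <- g$kmax / 8
  rmax <- g$kmax - R
  set.seed(101)
  nc <- 1e5; m <- 24
  rc <- runif(nc, 0, rmax); ph <- runif(nc, 0, 2 * pi)
  th <- matrix(runif(nc * m, 0, 2 * pi), nc, m)
  rho <- sqrt((rc * cos(ph) + R * cos(th))^2 + (rc * sin(ph) + R * sin(th))^2)
  edges <- seq(2 * R, rmax - R, length.out = 9)
  cnt <- hist(rho, breaks = c(-1, edges, 1e9), plot = FALSE)$counts[2:9]
  dens <- cnt / (pi * diff(edges^2))
  mid <- (edges[-1] + edges[-9]) / 2
  pred <- (1 / mid) * mean(dens) / mean(1 / mid)
  expect_true(all(abs(dens / pred - 1) < 0.10))
})

test_that("the PSF equals the brute-force adjoint sum and peaks at the origin", {
  pl <- fix_plan16()
  g <- pl$grid
  psf <- compute_psf(pl)
  pts <- sample_points(pl)
  w <- voronoi_density(pts, g$kmax, g$dk)
  rc <- grid_coords(g)
  bf <- matrix(0 + 0i, 16, 16)
  for (ix in 1:16) for (iy in 1:16)
    bf[ix, iy] <- sum(w * exp(-2i * pi * (pts[, 1] * rc[ix] + pts[, 2] * rc[iy])))
  bf <- bf / bf[which.max(abs(bf))]
  expect_lt(max(abs(psf$values - bf)), 1e-9)
  expect_identical(psf$peak_location, c(9L, 9L))   # center pixel of even grid
  expect_lt(abs(Im(psf$values[9, 9])), 1e-12)
})

test_that("full Cartesian sampling gives a discrete delta PSF", {
  g <- fix_grid16()
  kx <- grid_kcoords(g)
  pts <- as.matrix(expand.grid(kx = kx, ky = kx))
  # adjoint with uniform weights over the full Cartesian set
  img <- nuft_adjoint(rep(1 + 0i, nrow(pts)), pts, g)
  v <- matrix(img, 16, 16)
  v <- v / v[which.max(abs(v))]
  expect_true(all(abs(v)[-which.max(abs(v))] < 1e-10))
})

test_that("normalization and conjugate symmetry of the PSF", {
  pl <- fix_plan16()
  pts <- sample_points(pl)
  w <- voronoi_density(pts, pl$grid$kmax, pl$grid$dk)
  p1 <- compute_psf(pl, weights = w)
  p2 <- compute_psf(pl, weights = 5.5 * w)
  expect_lt(max(abs(p1$values - p2$values)), 1e-12)
  # PSF(-r) = conj(PSF(r)) on the interior of the even grid
  v <- p1$values
  n <- nrow(v)
  flip <- function(m) m[seq(n, 2, -1), seq(n, 2, -1)]
  expect_lt(max(abs(flip(v) - Conj(v[2:n, 2:n]))), 1e-9)
})

test_that("sidelobe metrics grow with acceleration and are worse for coherent sampling", {
  g <- grid_spec(32L, 0.22)
  med_sidelobe <- function(family, af, seeds) {
    stats::median(vapply(seeds, function(s) {
      pl <- if (family == "eccentric")
        design_eccentric_2d(g, g$kmax / 2, af = af, seed = s)
      else design_comparators(g, family, af = af, seed = s)
      psf_metrics(compute_psf(pl))$peak_sidelobe
    }, numeric(1)))
  }
  ecc1 <- med_sidelobe("eccentric", 1, 1:3)
  ecc3 <- med_sidelobe("eccentric", 3, 1:5)
  con3 <- psf_metrics(compute_psf(design_comparators(g, "concentric", af = 3)))$peak_sidelobe
  expect_gt(ecc3, ecc1)
  expect_gt(con3, ecc3)
  # delta-like PSF of the fully sampled case has near-zero sidelobe energy
  mets1 <- psf_metrics(compute_psf(design_eccentric_2d(g, g$kmax / 2, seed = 1L)))
  expect_lt(mets1$peak_sidelobe, 0.2)
  expect_gte(mets1$fwhm, 1)
})
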