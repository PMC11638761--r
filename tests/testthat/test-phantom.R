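test_that("the Derenzo phantom has 5 sets of 6 disjoint tubes inside the bath", {
  g <- grid_spec(64L, 0.22)
  sc <- build_derenzo(g)
  expect_identical(nrow(sc$tube_table), 30L)
  expect_identical(length(unique(sc$tube_table$diameter)), 5L)
  expect_identical(sort(unique(sc$tube_table$set)), 1:5)
  # labels: 0 outside, 1 bath, 2..6 tube sets; tubes never overlap the
  # container boundary
  expect_true(all(sc$tissue_masks %in% 0:6))
  expect_true(all(sc$concentration_maps$cr >= 0))
  expect_true(all(sc$concentration_maps$cr[sc$tissue_masks == 0L] == 0))
  # tube spacing = twice the diameter within each set
  t10 <- sc$tube_table[sc$tube_table$diameter == 0.010, ]
  d <- as.matrix(dist(t10[, c("cx", "cy")]))
  diag(d) <- Inf
  expect_lt(abs(min(d) - 0.020), 1e-9)
})

test_that("tube rasterization matches analytic circle areas at 1 mm resolution", {
  g <- grid_spec(224L, 0.224)
  sc <- build_derenzo(g)
  a10 <- sc$tube_table$rasterized_area[sc$tube_table$diameter == 0.010]
  expect_true(all(abs(a10 - pi * 0.005^2) / (pi * 0.005^2) < 0.05))
  # empty diameter list leaves a uniform bath
  bath <- build_derenzo(grid_spec(32L, 0.22), tube_diameters = numeric())
  expect_true(all(bath$tissue_masks %in% 0:1))
  expect_true(all(bath$concentration_maps$cr == 0))
})

test_that("impossible tube geometries raise an overflow error", {
  g <- grid_spec(64L, 0.22)
  expect_error(build_derenzo(g, container_diameter = 0.05), "overflow")
})

test_that("the FID model is a linear Lorentzian mixture", {
  b <- spectral_basis()
  tt <- (0:511) / 2000
  expect_true(all(synthesize_fid(b, c(naa = 0), 0.05, tt) == 0))
  expect_error(synthesize_fid(b, c(naa = 1), -0.1, tt))
  # linearity
  f1 <- synthesize_fid(b, c(naa = 2), 0.05, tt)
  f2 <- synthesize_fid(b, c(cho = 1.5), 0.05, tt)
  f12 <- synthesize_fid(b, c(naa = 2, cho = 1.5), 0.05, tt)
  expect_lt(max(abs(f12 - f1 - f2)), 1e-12)
  # single resonance: absorption-lineshape FWHM = 1/(pi T2*) with zero-fill
  t2 <- 0.04
  fid <- synthesize_fid(b, c(cho = 1), t2, (0:1023) / 2000)
  spec <- fft(c(fid, rep(0, 7 * 1024)))
  pk <- which.max(abs(spec))
  absorp <- Re(spec * exp(-1i * Arg(spec[pk])))
  df <- 2000 / (8 * 1024)
  width_bins <- sum(absorp > absorp[pk] / 2)
  expect_lt(abs(width_bins * df - 1 / (pi * t2)) / (1 / (pi * t2)), 0.05)
})

test_that("forward encoding matches the closed form for a single voxel", {
  g <- fix_grid16()
  pl <- fix_plan16()
  sc <- build_brain_scene(g, n_coils = 1L, b0_peak_hz = 0)
  sc$concentration_maps <- list(naa = matrix(0, 16, 16))
  sc$concentration_maps$naa[5, 9] <- 2
  sc$coil_maps[, , 1] <- 1 + 0i
  b <- spectral_basis()
  kd <- forward_encode(sc, b, pl, n_time = 4L)
  rc <- grid_coords(g)
  pts <- sample_points(pl)
  fid <- synthesize_fid(b, c(naa = 2), sc$t2star_map[5, 9], (0:3) / pl$sbw)
  expected <- outer(exp(2i * pi * (pts[, 1] * rc[5] + pts[, 2] * rc[9])), fid)
  expect_lt(max(abs(kd$values[, , 1] - expected)), 1e-9)
})

test_that("encoding noise has the requested complex std, is seeded and coil-independent", {
  g <- fix_grid16()
  pl <- design_eccentric_2d(g, g$kmax / 2, seed = 5L, sbw = 2000, n_time = 40L)
  sc <- build_brain_scene(g, n_coils = 2L)
  sc$concentration_maps <- lapply(sc$concentration_maps, function(m) m * 0)
  b <- spectral_basis()
  kd <- forward_encode(sc, b, pl, noise_sigma = 0.7, seed = 42L, n_time = 40L)
  expect_gt(length(kd$values), 1e5)
  expect_lt(abs(sqrt(mean(abs(kd$values)^2)) - 0.7) / 0.7, 0.03)
  kd2 <- forward_encode(sc, b, pl, noise_sigma = 0.7, seed = 42L, n_time = 40L)
  expect_identical(kd$values, kd2$values)
  expect_lt(abs(cor(as.vector(Re(kd$values[, , 1])),
                    as.vector(Re(kd$values[, , 2])))), 0.05)
})

test_that("the forward model is linear in the scene", {
  g <- fix_grid16()
  pl <- fix_plan16()
  b <- spectral_basis()
  sc <- build_brain_scene(g, n_coils = 2L)
  kd_all <- forward_encode(sc, b, pl, n_time = 4L,
                           include = c("naa", "cr"))
  kd_naa <- forward_encode(sc, b, pl, n_time = 4L, include = "naa")
  kd_cr <- forward_encode(sc, b, pl, n_time = 4L, include = "cr")
  expect_lt(max(abs(kd_all$values - kd_naa$values - kd_cr$values)), 1e-8)
})

test_that("the water reference reflects the water amplitude map", {
  g <- grid_spec(32L, 0.22)
  sc <- build_derenzo(g, n_coils = 4L, b0_peak_hz = 0)
  wr <- make_water_reference(sc, n_time = 4L, sbw = 2000)
  # no B0: per-voxel water phase is constant over time
  imgs <- grid_kdata_images(wr)
  obj <- sc$masks$object
  strong <- obj & abs(imgs[, , 1, 1]) > 0.05 * max(abs(imgs[, , 1, 1]))
  ph4 <- Arg(imgs[, , 4, 1] * Conj(imgs[, , 1, 1]))
  expect_lt(max(abs(ph4[strong])), 1e-6)
  # coil-combined first-point image tracks the coil-shaded water amplitude
  # band-limited to the rosette k-extent (matched-resolution oracle)
  rss <- sqrt(apply(abs(imgs[, , 1, ])^2, c(1, 2), sum))
  n <- 32
  rssc <- sqrt(apply(abs(sc$coil_maps)^2, c(1, 2), sum))
  q <- c(0:(n / 2 - 1), -(n / 2):-1) * g$dk
  km <- outer(q^2, q^2, `+`) <= (24 / (2 * 0.22))^2
  lo <- Re(fft(fft(sc$water_amp_map * rssc) * km, inverse = TRUE)) / n^2
  expect_gt(cor(as.vector(rss[obj]), as.vector(lo[obj])), 0.95)
  # linear scaling of the water amplitude scales the reference
  sc2 <- sc; sc2$water_amp_map <- 3 * sc$water_amp_map
  wr2 <- make_water_reference(sc2, n_time = 4L, sbw = 2000)
  expect_lt(max(abs(wr2$values - 3 * wr$values)) / max(abs(wr$values)), 1e-9)
})
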