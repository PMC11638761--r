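test_that("circle-count formulas reproduce the printed protocol counts", {
  g <- grid_spec(64L, 0.22)
  expect_identical(full_sampling_count(64, g$kmax, g$kmax / 2), 202L)
  expect_identical(full_sampling_count(64, g$kmax, g$kmax), 101L)
  expect_identical(full_sampling_count(64, g$kmax, g$kmax / 4), 403L)
  expect_identical(rosette_count(64), 101L)
  expect_identical(rosette_count(2), 4L)
  expect_identical(rosette_count(32), 51L)
  expect_error(full_sampling_count(64, g$kmax, 0), "invalid")
  expect_error(full_sampling_count(64, -1, 2), "invalid")
})

test_that("eccentric plane design honours count, containment and overlap rules", {
  g <- grid_spec(64L, 0.22)
  cc <- design_eccentric_plane(g, g$kmax / 2, af = 1, seed = 2L)
  expect_identical(nrow(cc), 202L)
  expect_true(all(cc$r_c + cc$R <= g$kmax + 1e-9))
  # rosette subset passes through the origin
  expect_true(all(abs(cc$r_c[cc$is_rosette] - cc$R[cc$is_rosette]) < 1e-12))
  expect_lte(sum(cc$is_rosette) / nrow(cc), 0.05)
  # acceleration to the full count leaves a single circle
  one <- design_eccentric_plane(g, g$kmax / 2, af = 202, seed = 2L)
  expect_identical(nrow(one), 1L)
})

test_that("plans are deterministic in the seed and differ across seeds", {
  g <- grid_spec(32L, 0.2)
  a <- design_eccentric_2d(g, g$kmax / 4, af = 2, seed = 9L)
  b <- design_eccentric_2d(g, g$kmax / 4, af = 2, seed = 9L)
  c <- design_eccentric_2d(g, g$kmax / 4, af = 2, seed = 10L)
  expect_identical(a$circles, b$circles)
  expect_false(isTRUE(all.equal(a$circles$r_c, c$circles$r_c)))
})

test_that("consecutive same-partition centers respect the Nyquist distance over many plans", {
  g <- grid_spec(32L, 0.22)
  for (seed in 1:1000) {
    cc <- design_eccentric_plane(g, g$kmax / 4, af = 4, seed = seed)
    xs <- cc$r_c * cos(cc$phi_c); ys <- cc$r_c * sin(cc$phi_c)
    dd <- sqrt(diff(xs)^2 + diff(ys)^2)
    # the constraint binds the randomly placed circles (rosette circles are
    # regularly spaced by construction)
    ros <- which(cc$is_rosette)
    dd_rand <- dd[seq.int(max(1L, length(ros)), length(dd))]
    expect_true(all(dd_rand >= g$dk - 1e-12))
  }
})

test_that("circle counts shrink with acceleration and grow with matrix size", {
  g <- grid_spec(64L, 0.22)
  counts_af <- sapply(c(1, 2, 3, 4, 6), function(af)
    nrow(design_eccentric_plane(g, g$kmax / 2, af = af, seed = 1L)))
  expect_true(all(diff(counts_af) <= 0))
  counts_n <- sapply(c(16L, 32L, 48L, 64L), function(n) {
    gg <- grid_spec(n, 0.22)
    nrow(design_eccentric_plane(gg, gg$kmax / 4, af = 1, seed = 1L))
  })
  expect_true(all(diff(counts_n) >= 0))
})

test_that("comparator families reproduce the printed comparison counts", {
  g <- grid_spec(64L, 0.22)
  expect_identical(n_circles(design_comparators(g, "rosette", af = 1)), 101L)
  expect_identical(n_circles(design_comparators(g, "rosette", af = 2)), 51L)
  expect_identical(n_circles(design_comparators(g, "rosette", af = 3)), 34L)
  cc <- design_comparators(g, "concentric", af = 1)
  expect_identical(n_circles(cc), 31L)
  expect_true(all(cc$circles$R < g$kmax))
  expect_identical(n_circles(design_comparators(g, "concentric", af = 2)), 16L)
  expect_identical(n_circles(design_comparators(g, "concentric", af = 3)), 11L)
  un <- design_comparators(g, "uniform", af = 1)
  expect_identical(n_circles(un), 202L)
  expect_error(design_comparators(g, "spiral"))
})

test_that("3D stacks give ellipsoid coverage, per-partition seeds and the 1.5x count ratio", {
  g <- grid_spec(64L, 0.22, n_z = 9L, fov_z = 0.105)
  st <- design_stack(g, g$kmax / 8, af = 1, seed = 4L)
  tab <- stack_circle_counts(g, g$kmax / 8, af = 1)
  expect_identical(nrow(st$circles), sum(tab$count))
  # counts shrink towards the edge partitions
  expect_true(tab$count[1] < tab$count[(9 + 1) / 2])
  # different master seeds: same counts, different centers
  st2 <- design_stack(g, g$kmax / 8, af = 1, seed = 5L)
  expect_identical(table(st$circles$kz_index), table(st2$circles$kz_index))
  expect_false(isTRUE(all.equal(st$circles$r_c, st2$circles$r_c)))
  # n_z = 1 degenerates to the 2D designer
  g1 <- grid_spec(64L, 0.22)
  s1 <- design_stack(g1, g1$kmax / 8, af = 1, seed = 4L)
  expect_identical(nrow(s1$circles),
                   nrow(design_eccentric_plane(g1, g1$kmax / 8, af = 1,
                                               seed = s1$seed)))
  # discrete cylinder/ellipsoid ratio approaches 3/2
  gbig <- grid_spec(64L, 0.22, n_z = 257L, fov_z = 0.9)
  expect_lt(abs(coverage_acceleration(gbig, gbig$kmax / 8) - 1.5), 0.02 * 1.5)
})

test_that("sample points lie on circles at the circumference-Nyquist rate", {
  g <- grid_spec(64L, 0.22)
  pl <- design_eccentric_2d(g, g$kmax / 4, seed = 1L)
  expect_identical(pl$samples_per_rev, 51L)   # ceil(2 pi R fov)
  pts <- sample_points(pl)
  expect_identical(nrow(pts), n_circles(pl) * 51L)
  # chord bound between consecutive samples of one circle
  m <- pl$samples_per_rev
  one <- pts[seq_len(m), ]
  gap <- sqrt(diff(one[, 1])^2 + diff(one[, 2])^2)
  expect_true(all(gap <= 2 * pi * pl$circles$R[1] / m + 1e-9))
  expect_error(sample_points(design_eccentric_2d(g, g$kmax / 4, seed = 1L,
                                                 samples_per_rev = 3L)))
})

test_that("gradient demand matches the analytic circle-traversal formulas", {
  gd <- gradient_demand(R = 8 / 0.22, sbw = 2280)
  # oracle: numerical differentiation of the sampled circular waveform
  m <- 4096L; R <- 8 / 0.22; sbw <- 2280; gam <- 42.577e6
  tt <- seq(0, 1 / sbw, length.out = m + 1)
  kx <- R * cos(2 * pi * sbw * tt)
  gx_num <- diff(kx) / diff(tt) / gam
  expect_lt(rel_diff(gd$amplitude, max(abs(gx_num))), 1e-4)
  slew_num <- max(abs(diff(gx_num) / diff(tt)[1]))
  expect_lt(rel_diff(gd$slew, slew_num), 1e-3)
  # linearity in R, quadratic scaling of slew with sbw
  gd_half <- gradient_demand(R / 2, 2280)
  expect_equal(gd_half$amplitude, gd$amplitude / 2)
  expect_equal(gd_half$slew, gd$slew / 2)
  gd2 <- gradient_demand(R, 2 * 2280)
  expect_equal(gd2$amplitude, 2 * gd$amplitude)
  expect_equal(gd2$slew, 4 * gd$slew)
})

test_that("max_sbw inverts gradient_demand under hardware limits", {
  R <- 8 / 0.22
  expect_lt(abs(max_sbw(R, g_max = 80e-3, s_max = 200) - 2435.5), 1)
  bw <- max_sbw(R, g_max = 30e-3, s_max = 150)
  gd <- gradient_demand(R, bw)
  expect_lte(gd$amplitude, 30e-3 * (1 + 1e-9))
  expect_lte(gd$slew, 150 * (1 + 1e-9))
  expect_true(max_sbw(R, g_max = 1e12, s_max = 1e12) > 1e8)
})

test_that("sequence timing reproduces the printed acquisition times", {
  tm <- sequence_timing(NULL, tr = 0.275, n_circles_override = 4072,
                        n_time = 500, sbw = 2280)
  expect_equal(tm$ta, 1119.8)
  expect_equal(round(tm$ta / 60), 19)  # prints as 18 min 40 s
  tm4 <- sequence_timing(NULL, tr = 0.275, n_circles_override = 1018,
                         n_time = 500, sbw = 2280)
  expect_lt(abs(tm4$ta - 280), 0.1)
  expect_lt(abs(tm$fid_duration - 0.2193), 5e-5)
})

test_that("plans survive a CSV export/import round trip", {
  g <- grid_spec(32L, 0.22)
  pl <- design_eccentric_2d(g, g$kmax / 4, af = 2, seed = 7L)
  path <- file.path(tempdir(), "plan.csv")
  plan_export(pl, path)
  pl2 <- plan_import(path)
  expect_equal(pl2$circles$r_c, pl$circles$r_c, tolerance = 1e-12)
  expect_identical(pl2$samples_per_rev, pl$samples_per_rev)
  expect_identical(pl2$family, pl$family)
})
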