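test_that("SSIM behaves as a similarity index", {
  set.seed(41)
  x <- matrix(rnorm(32 * 32), 32, 32)
  expect_equal(ssim(x, x), 1, tolerance = 1e-9)
  # structured image with zero local mean at the window scale against its
  # negative: pure structure term, anticorrelated
  s <- outer(sin(seq(0, 20 * pi, length.out = 32)),
             cos(seq(0, 20 * pi, length.out = 32)))
  expect_lt(ssim(s, -s), 0)
  # symmetric under swap when the dynamic range is fixed externally
  y <- x + matrix(rnorm(32 * 32, 0, 0.3), 32, 32)
  L <- diff(range(x, y))
  expect_equal(ssim(x, y, dynamic_range = L), ssim(y, x, dynamic_range = L),
               tolerance = 1e-12)
  expect_error(ssim(x, y, mask = matrix(FALSE, 32, 32)), "empty")
})

test_that("masked Pearson correlation matches expectations", {
  set.seed(42)
  x <- matrix(rnorm(100 * 100), 100, 100)
  expect_equal(pearson_in_mask(x, x), 1)
  y <- matrix(rnorm(100 * 100), 100, 100)
  expect_lt(abs(pearson_in_mask(x, y)), 0.05)   # 1e4 independent voxels
  expect_true(is.na(pearson_in_mask(x, matrix(1, 100, 100))))
  expect_error(pearson_in_mask(x, y, mask = matrix(FALSE, 100, 100)))
})

test_that("spectral SNR and FWHM follow the Lorentzian closed form", {
  t2 <- 0.04; sbw <- 2000; N <- 8192L
  tt <- (0:1023) / sbw
  fid <- exp((2i * pi * 150 - 1 / t2) * tt)
  spec <- fft(c(fid, rep(0, N - 1024)))
  freq <- (0:(N - 1)) * sbw / N
  freq[freq > sbw / 2] <- freq[freq > sbw / 2] - sbw
  set.seed(43)
  spec <- spec + complex(real = rnorm(N, 0, 1), imaginary = rnorm(N, 0, 1))
  m <- spectral_snr_fwhm(spec, freq, signal_band = c(100, 200),
                         noise_band = c(-900, -500))
  expect_lt(abs(m$fwhm_hz - 1 / (pi * t2)) / (1 / (pi * t2)), 0.05)
  # doubling the signal (same noise) doubles the SNR
  sig <- fft(c(2 * fid, rep(0, N - 1024)))
  m2 <- spectral_snr_fwhm(sig + (spec - fft(c(fid, rep(0, N - 1024)))),
                          freq, c(100, 200), c(-900, -500))
  expect_equal(m2$snr, 2 * m$snr, tolerance = 0.05)
  expect_error(spectral_snr_fwhm(spec, freq, c(100, 200), c(150, 400)),
               "disjoint")
})

test_that("region COV matches the hand-computed value and is scale invariant", {
  lab <- matrix(1L, 4, 4)
  reps <- lapply(c(9, 10, 11), function(v) list(met = matrix(v, 4, 4)))
  tab <- cov_by_region(reps, lab)
  expect_equal(tab$cov, sd(c(9, 10, 11)) / 10, tolerance = 1e-9)
  expect_equal(round(tab$cov, 4), 0.1)      # sd ddof=1 / mean
  reps2 <- lapply(reps, function(r) list(met = 7 * r$met))
  expect_equal(cov_by_region(reps2, lab)$cov, tab$cov, tolerance = 1e-12)
  same <- lapply(1:3, function(i) list(met = matrix(5, 4, 4)))
  expect_equal(cov_by_region(same, lab)$cov, 0)
  expect_error(cov_by_region(reps[1], lab), "2 repetitions")
})

test_that("the linear-combination fit recovers exact in-model voxels", {
  b <- spectral_basis()
  tt <- (0:127) / 2000
  truth <- c(naa = 3.2, cr = 1.5, cho = 0.7)
  fid <- synthesize_fid(b, truth, 0.032, tt)
  rho <- matrix(rep(fid, each = 4), 4, length(tt)) * c(1, 2, 0.5, 1)
  mm <- fit_basis_maps(rho, b, tt, t2star = 0.032,
                       metabolites = c("naa", "cr", "cho"))
  expect_lt(rel_diff(mm$maps$naa[1, 1], 3.2), 1e-6)
  expect_lt(rel_diff(mm$maps$cr[2, 1], 2 * 1.5), 1e-6)
  expect_lt(max(mm$residual, na.rm = TRUE), 1e-8)
  # institutional units: doubling the water reference halves the values
  mm2 <- fit_basis_maps(rho, b, tt, t2star = 0.032,
                        metabolites = c("naa", "cr", "cho"),
                        water_ref_amp = matrix(2, 2, 2))
  expect_equal(mm2$maps$naa[1, 1], mm$maps$naa[1, 1] / 2, tolerance = 1e-9)
  # duplicated basis entries are reported as collinear
  b2 <- spectral_basis(list(a = list(ppm = 2.0, amp = 1),
                            b = list(ppm = 2.0, amp = 1)))
  expect_error(fit_basis_maps(rho, b2, tt, metabolites = c("a", "b")),
               "collinear")
})
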