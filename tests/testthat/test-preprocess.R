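sbw_pp <- 2000

test_that("HSVD removes in-band components and preserves out-of-band ones", {
  tt <- (0:255) / sbw_pp
  water <- 10 * exp((2i * pi * 5 - 25) * tt)
  out <- hsvd_water_removal(water, sbw_pp, c(-60, 60), model_order = 12L)
  expect_lt(sum(abs(out)^2) / sum(abs(water)^2), 1e-6)
  # resonance far outside the band passes through within 1% energy
  naa_f <- (2.01 - 4.7) * 297.2
  naa <- 3 * exp((2i * pi * naa_f - 30) * tt)
  out2 <- hsvd_water_removal(naa, sbw_pp, c(-60, 60), model_order = 12L)
  expect_lt(abs(sum(abs(out2)^2) - sum(abs(naa)^2)) / sum(abs(naa)^2), 0.01)
  expect_error(hsvd_water_removal(naa, sbw_pp, model_order = 200L))
})

test_that("HSVD separates water from a metabolite mixture and is idempotent", {
  tt <- (0:255) / sbw_pp
  naa_f <- (2.01 - 4.7) * 297.2
  water <- 50 * exp((2i * pi * 3 - 20) * tt)
  naa <- 2 * exp((2i * pi * naa_f - 30) * tt)
  mix <- water + naa
  clean <- hsvd_water_removal(mix, sbw_pp, c(-60, 60), model_order = 20L)
  spec_amp <- function(x, f) abs(sum(x * exp(-2i * pi * f * tt)))
  expect_lt(spec_amp(clean, 3) / spec_amp(mix, 3), 1 / 100)
  expect_lt(abs(spec_amp(clean, naa_f) - spec_amp(naa, naa_f)) /
              spec_amp(naa, naa_f), 0.05)
  clean2 <- hsvd_water_removal(as.complex(clean), sbw_pp, c(-60, 60),
                               model_order = 20L)
  extra <- sum(abs(clean - clean2)^2) / max(sum(abs(clean)^2), 1e-30)
  expect_lt(extra, 0.01)
})

test_that("the B0 estimator recovers linear field maps without bias", {
  n <- 24L; Tn <- 6L
  dwell <- 1 / sbw_pp
  b0 <- matrix(seq(-30, 30, length.out = n), n, n)
  tt <- (seq_len(Tn) - 1) * dwell
  imgs <- array(0 + 0i, c(n, n, Tn))
  for (t in seq_len(Tn)) imgs[, , t] <- exp(2i * pi * b0 * tt[t])
  fm <- estimate_b0_map(imgs, dwell)
  expect_lt(sqrt(mean((fm$b0_hz - b0)^2)), 0.1)
  expect_lt(abs(mean(fm$b0_hz - b0)), 0.05)
  # zero offset within 0.1 Hz
  fm0 <- estimate_b0_map(array(1 + 0i, c(n, n, 3)), dwell)
  expect_lt(max(abs(fm0$b0_hz)), 0.1)
  # offsets near +-sbw/2 are flagged wrap-ambiguous
  bad <- matrix(0.49 * sbw_pp, n, n)
  for (t in seq_len(Tn)) imgs[, , t] <- exp(2i * pi * bad * tt[t])
  fmw <- estimate_b0_map(imgs, dwell)
  expect_false(any(fmw$valid_mask))
  expect_error(estimate_b0_map(imgs[, , 1:2], dwell), "3 time points")
})

test_that("coil-map estimation recovers smooth sensitivities up to RSS normalization", {
  g <- grid_spec(32L, 0.22)
  cm_true <- make_coil_maps(g, n_coils = 4L)
  obj <- matrix(1, 32, 32)
  imgs <- array(0 + 0i, c(32, 32, 4))
  for (c in 1:4) imgs[, , c] <- cm_true[, , c] * obj
  est <- estimate_coil_maps(imgs, smoothing_fwhm = 3)
  rss_true <- sqrt(apply(abs(cm_true)^2, c(1, 2), sum))
  for (c in 1:4) {
    a <- abs(est$sensitivities[, , c][est$mask])
    b <- (abs(cm_true[, , c]) / rss_true)[est$mask]
    expect_gt(cor(a, b), 0.98)
  }
  # RSS of the estimate is 1 inside the mask
  rss <- sqrt(apply(abs(est$sensitivities)^2, c(1, 2), sum))
  expect_lt(max(abs(rss[est$mask] - 1)), 1e-6)
  # single flat coil gives unit sensitivity
  one <- estimate_coil_maps(array(2 + 0i, c(8, 8, 1)))
  expect_lt(max(abs(abs(one$sensitivities) - 1)), 1e-9)
  # global complex scaling only rotates the estimate by the same scalar
  est2 <- estimate_coil_maps(imgs * (2 * exp(1i * 0.7)), smoothing_fwhm = 3)
  ratio <- est2$sensitivities[, , 2][est$mask] / est$sensitivities[, , 2][est$mask]
  expect_lt(max(Mod(ratio - exp(1i * 0.7))), 1e-6)
})

test_that("backward linear prediction continues damped exponentials to t = 0", {
  dwell <- 1 / sbw_pp
  te <- 2 * dwell
  tt_acq <- te + (0:199) * dwell
  z <- exp((2i * pi * 180 - 40) * dwell)
  fid <- 5 * exp((2i * pi * 180 - 40) * tt_acq)
  # spurious extra LP roots may be reflected; the physical pole is kept
  ext <- suppressWarnings(backward_predict_fid(fid, n_back = 2L, lp_order = 4L))
  truth <- 5 * exp((2i * pi * 180 - 40) * (0:1) * dwell)
  expect_lt(max(abs(ext[1:2] - truth)) / abs(truth[1]), 1e-6)
  expect_identical(backward_predict_fid(fid, 0L, 4L), fid)
})

test_that("backward prediction removes the first-order spectral phase", {
  dwell <- 1 / sbw_pp
  te <- 2 * dwell
  f1 <- (2.01 - 4.7) * 297.2; f2 <- (3.2 - 4.7) * 297.2
  tt_acq <- te + (0:511) * dwell
  fid <- 3 * exp((2i * pi * f1 - 25) * tt_acq) + 2 * exp((2i * pi * f2 - 25) * tt_acq)
  ext <- suppressWarnings(backward_predict_fid(fid, n_back = 2L, lp_order = 6L))
  # phase at the two resonance frequencies after extension
  tt_full <- (0:(length(ext) - 1)) * dwell
  ph <- sapply(c(f1, f2), function(f) Arg(sum(ext * exp(-2i * pi * f * tt_full))))
  expect_true(all(abs(ph) < 1 * pi / 180))
  # without extension the truncated start leaves a visible first-order phase
  ph_raw <- sapply(c(f1, f2), function(f)
    Arg(sum(fid * exp(-2i * pi * f * (0:511) * dwell))))
  expect_true(any(abs(ph_raw) > 10 * pi / 180))
})
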