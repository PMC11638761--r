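# Shared fixtures, computed once per test run and memoized. All are built
# in code from fixed seeds; the heavier end-to-end experiments are reused
# by both the module tests and the acceptance suite.

.fix <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fix)) assign(name, force(expr), envir = .fix)
  get(name, envir = .fix)
}

# small grid + random plan used across operator tests
fix_grid16 <- function() grid_spec(16L, 0.22)

fix_plan16 <- function() memo("plan16", {
  g <- fix_grid16()
  design_eccentric_2d(g, g$kmax / 2, af = 1, seed = 5L, sbw = 2000, n_time = 6L)
})

# smooth rank-3 ground truth on 32x32 with T = 64 FID-like components
fix_rank3_truth <- function() memo("rank3_truth", {
  n <- 32L; Tn <- 64L
  g <- grid_spec(n, 0.22)
  rc <- grid_coords(g) / 0.22
  X <- matrix(rc, n, n); Y <- matrix(rc, n, n, byrow = TRUE)
  U <- cbind(as.vector(exp(-(X^2 + Y^2) / 0.06)),
             as.vector(exp(-((X - 0.12)^2 + (Y + 0.08)^2) / 0.015)),
             as.vector(sin(3 * pi * X) * cos(2 * pi * Y) *
                         exp(-(X^2 + Y^2) / 0.05))) + 0i
  tt <- (seq_len(Tn) - 1) / 2000
  V <- rbind(exp((2i * pi * 50 - 30) * tt),
             exp((2i * pi * -120 - 20) * tt),
             exp((2i * pi * 200 - 50) * tt))
  list(grid = g, U = U, V = V, rho = U %*% V, n_time = Tn)
})

# noiseless fully sampled single-coil acquisition + recon of the rank-3
# phantom (exact-recovery experiment)
fix_rank3_recovery <- function() memo("rank3_recovery", {
  tr <- fix_rank3_truth()
  plan <- design_eccentric_2d(tr$grid, tr$grid$kmax / 2, af = 1, seed = 11L,
                              sbw = 2000, n_time = tr$n_time)
  op <- encoding_operator(plan, n_time = tr$n_time, weighting = "none")
  s <- op_forward(op, tr$rho)
  cfg <- recon_config(lam = 1e-8, K = 3L, outer_iters = 6L,
                      u_fista_iters = 30L, tol = 1e-10)
  rec <- reconstruct(s, op, cfg = cfg)
  rel_err <- sqrt(sum(abs(recon_rho(rec) - tr$rho)^2) / sum(abs(tr$rho)^2))
  list(rec = rec, rel_err = rel_err, truth = tr)
})

# brain-like metabolite recovery at AF = 2 (full pipeline)
fix_brain_recovery <- function() memo("brain_recovery",
  brain_metabolite_experiment(seed = 3L, af = 2))

# water Derenzo acceleration experiment, AF = 4 vs AF = 1 (64x64)
fix_phantom_accel <- function() memo("phantom_accel",
  phantom_acceleration_experiment(seed = 1L, af = 4))

rel_diff <- function(a, b) abs(a - b) / max(abs(b), .Machine$double.eps)
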