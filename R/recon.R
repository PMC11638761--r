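#' Reconstruction configuration
#'
#' Tunable parameters of the low-rank TGV reconstruction. The
#' regularization weight `lam` is defined relative to data normalized so
#' the density-compensated adjoint image series has unit maximum
#' magnitude. `K` defaults to 15 (2D); rank 40 is the 3D operating point.
#'
#' @param lam TGV regularization weight (default 3e-4).
#' @param K Model rank (spatial/temporal component count).
#' @param outer_iters Outer alternating iterations (default 20).
#' @param v_cg_iters Conjugate-gradient iterations per V update (default 10).
#' @param u_fista_iters Proximal-gradient (monotone FISTA) iterations per U
#'   update (default 15).
#' @param tgv_inner_iters Primal-dual iterations inside each TGV prox
#'   (default 20).
#' @param tgv_value_iters Iterations for objective-trace TGV evaluation.
#' @param alpha_ratio TGV alpha0/alpha1 (default 2).
#' @param lipid_rank Rank of the lipid temporal subspace (default 8).
#' @param tol Relative objective change for early stopping (default 1e-4).
#' @return A list of class `recon_config`.
#' @export
recon_config <- function(lam = 3e-4, K = 15L, outer_iters = 20L,
                         v_cg_iters = 10L, u_fista_iters = 15L,
                         tgv_inner_iters = 20L, tgv_value_iters = 40L,
                         alpha_ratio = 2, lipid_rank = 8L, tol = 1e-4) {
  if (lam < 0) stop("lam must be >= 0")
  if (K < 1) stop("K must be >= 1")
  structure(as.list(environment()), class = "recon_config")
}

# ---- internal solver pieces -------------------------------------------------

# data term ||w (s - model)||^2 summed over coils
.data_obj <- function(op, s, model_s) {
  tot <- 0
  for (c in seq_len(dim(s)[3]))
    tot <- tot + sum(abs(op$w * (matrix(s[, , c], dim(s)[1], dim(s)[2]) -
                                   matrix(model_s[, , c], dim(s)[1], dim(s)[2])))^2)
  tot
}

# adjoint of w^2-weighted residual: 2 * A^H W^2 (A rho - s)
.data_grad_rho <- function(op, s, model_s) {
  r <- model_s
  for (c in seq_len(dim(s)[3]))
    r[, , c] <- op$w^2 * (model_s[, , c] - s[, , c])
  2 * op_adjoint(op, r)
}

# Hermitian PD preconditioner approximating (A^H W^2 A)^{-1}: inverse
# Fourier multiplier of the Cartesian-binned w^2 sample density, wrapped in
# the inverse square-root of the coil sum-of-squares. Unsampled cells are
# floored so null-space modes are not amplified.
.make_gridding_prec <- function(op, floor_frac = 1e-2) {
  n <- op$grid$n_xy
  a <- pmin(n, pmax(1, round(op$points[, 1] / op$grid$dk) + n / 2 + 1))
  b <- pmin(n, pmax(1, round(op$points[, 2] / op$grid$dk) + n / 2 + 1))
  mu <- matrix(0, n, n)
  acc <- rowsum(op$w^2, (b - 1L) * n + a)
  mu[as.integer(rownames(acc))] <- acc
  mu <- pmax(mu, floor_frac * mean(mu[mu > 0]))
  shift <- c((n / 2 + 1):n, 1:(n / 2))
  mu_fft <- mu[shift, shift]
  crss <- sqrt(pmax(rowSums(abs(op$coils)^2), 1e-8))
  function(G) {
    out <- G
    for (k in seq_len(ncol(G))) {
      g <- matrix(G[, k] / crss, n, n)
      gi <- stats::fft(stats::fft(g) / mu_fft, inverse = TRUE) / (n * n)
      out[, k] <- as.vector(gi) / crss
    }
    out
  }
}

# largest eigenvalue of A^H W^2 A (per time column; B is unitary so one
# time column suffices), by power iteration
.op_norm <- function(op, iters = 12L, seed = 7L) {
  rng <- local_rng(seed); on.exit(rng$restore(), add = TRUE)
  Nr <- op$grid$n_xy^2
  z <- matrix(complex(real = stats::rnorm(Nr), imaginary = stats::rnorm(Nr)), Nr, 1)
  z <- z / sqrt(sum(abs(z)^2))
  lam <- 0
  one_t <- op
  one_t$bphase <- NULL; one_t$n_time <- 1L
  for (i in seq_len(iters)) {
    f <- op_forward(one_t, z)
    for (c in seq_len(one_t$n_coils)) f[, , c] <- one_t$w^2 * f[, , c]
    z2 <- op_adjoint(one_t, f)
    lam <- sqrt(sum(abs(z2)^2))
    z <- z2 / lam
  }
  lam
}

#' Lipid temporal subspace from an estimated lipid signal
#'
#' Computes the orthonormal temporal basis spanning the top
#' `subspace_rank` right singular vectors of the lipid-voxel time series.
#' The complement projector `(1 - P)` applied along time removes this
#' subspace from metabolite updates.
#'
#' @param L Complex `Nr x T` lipid signal (supported on the lipid mask).
#' @param lipid_mask Logical vector/matrix of lipid voxels.
#' @param subspace_rank Maximum basis size (default 8).
#' @param sv_tol Relative singular-value threshold: only vectors with
#'   `sigma_i >= sv_tol * sigma_1` enter the projection, so the basis stays
#'   restricted to lipid-dominated temporal behaviour (default 0.05).
#' @return Complex `T x r` matrix with orthonormal columns, or `NULL` (with
#'   a warning) if the mask is empty.
#' @export
lipid_projection_update <- function(L, lipid_mask, subspace_rank = 8L,
                                    sv_tol = 0.05) {
  idx <- which(as.vector(lipid_mask))
  if (!length(idx)) {
    warning("empty lipid mask: identity projection")
    return(NULL)
  }
  X <- L[idx, , drop = FALSE]
  r <- min(subspace_rank, dim(X))
  sv <- svd(X, nu = 0, nv = r)
  keep <- which(sv$d[seq_len(r)] >= sv_tol * sv$d[1])
  sv$v[, keep, drop = FALSE]
}

#' Project out a temporal subspace
#'
#' Applies `(1 - P)` along the time axis: for voxel time series stored as
#' rows and an orthonormal basis `B` of right singular vectors,
#' `x (1 - B B^H) = x - (x B) B^H`; `B = NULL` is the identity.
#'
#' @param x Complex `Nr x T` matrix.
#' @param basis Complex `T x r` orthonormal basis (or `NULL`).
#' @return `x` with the subspace removed from every voxel's time series.
#' @export
project_out_subspace <- function(x, basis) {
  if (is.null(basis)) return(x)
  x - (x %*% basis) %*% Conj(t(basis))
}

rank_truncate <- function(X, r) {
  r <- min(r, dim(X))
  sv <- svd(X, nu = r, nv = r)
  sv$u %*% (sv$d[seq_len(r)] * Conj(t(sv$v)))
}

#' CS-SENSE-LR reconstruction with TGV and lipid suppression
#'
#' Solves the regularized inverse problem
#' `argmin_{U,V,L} ||W(s - F C B (U V + L))||^2 + lam * sum_k TGV2(U_k)`
#' by block alternation:
#' V by conjugate gradient on the weighted normal equations (then
#' re-orthonormalized, absorbing the factor into U); U by monotone FISTA
#' proximal-gradient steps whose data gradient has the lipid temporal
#' subspace projected out and whose prox is the per-component TGV
#' denoiser; L by a monotone gradient step restricted to the lipid mask
#' followed by temporal rank truncation; and a refresh of the lipid
#' projection. The model is initialized from the rank-K SVD of the
#' density-compensated, B0-conjugate adjoint series; data are normalized
#' so that series has unit maximum magnitude (the scale is restored on
#' output). The objective (evaluated with a fixed-iteration TGV value) is
#' recorded per outer iteration and must be non-increasing; an increase
#' beyond 5% aborts with diagnostics.
#'
#' @param s A `spectro_kdata` or complex array `(samples, T, coils)`.
#' @param op An [encoding_operator()] matching `s`.
#' @param masks List with logical `brain` (metabolite support; default all
#'   voxels) and `lipid` (default none) masks; must be disjoint.
#' @param cfg A [recon_config()].
#' @return A list of class `cs_sense_lr` with `U` (Nr x K, original data
#'   scale), `V` (K x T, orthonormal rows), `L` (Nr x T lipid estimate),
#'   `lipid_basis`, `diagnostics` (objective/data traces, scale, iterations)
#'   and accessor-friendly `grid`.
#' @export
reconstruct <- function(s, op, masks = list(), cfg = recon_config(),
                        verbose = FALSE) {
  if (inherits(s, "spectro_kdata")) s <- s$values
  d <- dim(s)
  Tn <- d[2]; Nr <- op$grid$n_xy^2
  if (d[1] != nrow(op$points) || Tn != op$n_time || d[3] != op$n_coils)
    stop("data shape inconsistent with operator")
  brain <- if (is.null(masks$brain)) rep(TRUE, Nr) else as.vector(masks$brain)
  lipid <- if (is.null(masks$lipid)) rep(FALSE, Nr) else as.vector(masks$lipid)
  if (any(brain & lipid)) stop("brain and lipid masks must be disjoint")
  K <- min(cfg$K, Nr, Tn)

  A0 <- b0_correct_adjoint(s, op)
  scale <- max(abs(A0))
  if (scale == 0) {
    U <- matrix(0 + 0i, Nr, K); V <- matrix(0 + 0i, K, Tn); V[cbind(1:K, 1:K)] <- 1
    return(structure(list(U = U, V = V, L = matrix(0 + 0i, Nr, Tn),
                          lipid_basis = NULL, grid = op$grid,
                          diagnostics = list(objective = 0, data = 0, scale = 0)),
                     class = "cs_sense_lr"))
  }
  sn <- s / scale
  A0n <- A0 / scale
  A0b <- A0n; A0b[!brain, ] <- 0
  sv <- svd(A0b, nu = K, nv = K)
  U <- sv$u %*% diag(sv$d[seq_len(K)], K)
  U[!brain, ] <- 0
  V <- Conj(t(sv$v))
  L <- matrix(0 + 0i, Nr, Tn)
  use_lipid <- any(lipid)
  basis <- NULL
  if (use_lipid) {
    ## seed the lipid estimate from the adjoint on its own support, so the
    ## dominant skull signal is explained by L from the first iteration
    L[lipid, ] <- rank_truncate(A0n[lipid, , drop = FALSE], cfg$lipid_rank)
    basis <- lipid_projection_update(L, lipid, cfg$lipid_rank)
  }

  ## the data term is normalized by the spectral norm of A^H W^2 A, so the
  ## proximal step is O(1) and `lam` weighs TGV against a scale-free data
  ## term: modes whose normalized eigenvalue falls below ~lam are governed
  ## by the regularizer (the noise-amplified tail of the sampling operator)
  op_norm <- .op_norm(op)
  data_scale <- 1 / op_norm
  Lip <- 2
  step <- 1 / Lip
  lam <- cfg$lam
  n_xy <- op$grid$n_xy
  w2 <- op$w^2
  ## component-space fast path: without a B0 phase the encoding factors as
  ## (F C_c U) V, so the NUFT acts on K columns instead of T
  fast <- is.null(op$bphase)
  sn_list <- lapply(seq_len(d[3]), function(c) matrix(sn[, , c], d[1], Tn))

  tgv_term <- function(U) {
    if (lam == 0) return(0)
    tot <- 0
    for (k in seq_len(ncol(U)))
      tot <- tot + tgv2_value(matrix(U[, k], n_xy, n_xy),
                              cfg$alpha_ratio, cfg$tgv_value_iters)
    lam * tot
  }

  FL <- NULL  # per-coil forward of the lipid term (fast path cache)
  update_FL <- function(L) {
    if (!use_lipid || !fast) return(NULL)
    lapply(seq_len(d[3]), function(c) nuft_fwd_op(op$nuft, op$coils[, c] * L))
  }
  fcu <- function(U) {
    if (!fast) return(NULL)
    lapply(seq_len(d[3]), function(c) nuft_fwd_op(op$nuft, op$coils[, c] * U))
  }
  ## residual list s - A(UV + L), per coil, given cached FCU / FL
  resid_list <- function(U, V, FCU = NULL, FLm = FL, Lm = L) {
    if (fast) {
      if (is.null(FCU)) FCU <- fcu(U)
      lapply(seq_len(d[3]), function(c) {
        r <- sn_list[[c]] - FCU[[c]] %*% V
        if (!is.null(FLm)) r <- r - FLm[[c]]
        r
      })
    } else {
      ms <- op_forward(op, U %*% V + Lm)
      lapply(seq_len(d[3]), function(c) sn_list[[c]] - matrix(ms[, , c], d[1], Tn))
    }
  }
  dobj <- function(res)
    data_scale * sum(vapply(res, function(r) sum(abs(op$w * r)^2), 0))
  ## gradient of the data term w.r.t. U (2 A^H W^2 (A(UV+L) - s) V^H),
  ## with the lipid temporal subspace projected out of the data gradient
  grad_u_from_resid <- function(res, V) {
    if (fast) {
      G <- matrix(0 + 0i, Nr, K)
      for (c in seq_len(d[3])) {
        RW <- (w2 * res[[c]])
        if (use_lipid && !is.null(basis)) RW <- project_out_subspace(RW, basis)
        G <- G + Conj(op$coils[, c]) * nuft_adj_op(op$nuft, RW %*% Conj(t(V)))
      }
      -2 * data_scale * G
    } else {
      rw <- array(0 + 0i, d)
      for (c in seq_len(d[3])) rw[, , c] <- w2 * res[[c]]
      G <- -2 * data_scale * op_adjoint(op, rw)
      if (use_lipid && !is.null(basis)) G <- project_out_subspace(G, basis)
      G %*% Conj(t(V))
    }
  }

  if (use_lipid) FL <- update_FL(L)
  obj_data <- dobj(resid_list(U, V))
  obj_trace <- obj_data + tgv_term(U)
  data_trace <- obj_data

  for (outer in seq_len(cfg$outer_iters)) {
    ## ---- V update ----
    if (fast) {
      ## exact weighted least squares: the K x K normal matrix is shared by
      ## all time points
      FCU <- fcu(U)
      H <- matrix(0 + 0i, K, K); rhs <- matrix(0 + 0i, K, Tn)
      for (c in seq_len(d[3])) {
        H <- H + Conj(t(FCU[[c]])) %*% (w2 * FCU[[c]])
        sc <- sn_list[[c]]
        if (!is.null(FL)) sc <- sc - FL[[c]]
        rhs <- rhs + Conj(t(FCU[[c]])) %*% (w2 * sc)
      }
      Vc <- tryCatch(solve(H, rhs), error = function(e) NULL)
      if (!is.null(Vc)) {
        ## exact minimizer given U; guard against numerical mishaps
        if (dobj(resid_list(U, Vc, FCU)) <= dobj(resid_list(U, V, FCU)) + 1e-12)
          V <- Vc
      }
    } else {
      normal_v <- function(Vm) {
        f <- op_forward(op, U %*% Vm)
        for (c in seq_len(d[3])) f[, , c] <- w2 * f[, , c]
        Conj(t(U)) %*% op_adjoint(op, f)
      }
      sL <- if (use_lipid) {
        sl <- op_forward(op, L); r <- sn
        for (c in seq_len(d[3])) r[, , c] <- sn[, , c] - sl[, , c]
        r
      } else sn
      f <- sL
      for (c in seq_len(d[3])) f[, , c] <- w2 * sL[, , c]
      rhs <- Conj(t(U)) %*% op_adjoint(op, f)
      r <- rhs - normal_v(V)
      p <- r
      rs <- sum(abs(r)^2)
      for (it in seq_len(cfg$v_cg_iters)) {
        if (rs < 1e-20) break
        Ap <- normal_v(p)
        alpha <- rs / Re(sum(Conj(p) * Ap))
        V <- V + alpha * p
        r <- r - alpha * Ap
        rs_new <- sum(abs(r)^2)
        p <- r + (rs_new / rs) * p
        rs <- rs_new
      }
    }
    ## re-orthonormalize rows of V, absorb factor into U
    ## (complex qr pivots columns: t(V)[, pivot] = Q R)
    qrv <- qr(t(V))
    Q <- qr.Q(qrv); Rm <- qr.R(qrv)
    piv <- if (is.null(qrv$pivot)) seq_len(K) else qrv$pivot
    U <- U[, piv, drop = FALSE] %*% t(Rm)
    V <- t(Q)
    if (verbose)
      cat(sprintf(" outer %d after V: data=%.6g\n", outer,
                  dobj(resid_list(U, V))))

    ## ---- U update: monotone FISTA with TGV prox and lipid projection ----
    prox_u <- function(Um) {
      for (k in seq_len(K))
        Um[, k] <- as.vector(tgv2_denoise(matrix(Um[, k], n_xy, n_xy),
                                          lam * step, cfg$alpha_ratio,
                                          max(10L, cfg$tgv_inner_iters)))
      Um[!brain, ] <- 0
      Um
    }
    Fval <- function(Um) dobj(resid_list(Um, V)) + tgv_term(Um)
    if (lam * step < 1e-7 && !use_lipid) {
      ## the TGV prox is below the numerical resolution of the primal-dual
      ## scheme at this weight (identity in practice): solve the smooth
      ## quadratic in U by conjugate gradient on the brain support.
      ## With orthonormal V rows the normal operator is V-free:
      ## O(U) = sum_c C^H F^H W^2 F C U.
      O_u <- function(Um) {
        G <- matrix(0 + 0i, Nr, K)
        if (fast) {
          for (c in seq_len(d[3]))
            G <- G + Conj(op$coils[, c]) *
              nuft_adj_op(op$nuft, w2 * nuft_fwd_op(op$nuft, op$coils[, c] * Um))
        } else {
          f <- op_forward(op, Um %*% V)
          for (c in seq_len(d[3])) f[, , c] <- w2 * f[, , c]
          G <- op_adjoint(op, f) %*% Conj(t(V))
        }
        G[!brain, ] <- 0
        G
      }
      rhs_u <- matrix(0 + 0i, Nr, K)
      if (fast) {
        for (c in seq_len(d[3])) {
          sc <- sn_list[[c]]
          if (!is.null(FL)) sc <- sc - FL[[c]]
          rhs_u <- rhs_u + Conj(op$coils[, c]) *
            nuft_adj_op(op$nuft, (w2 * sc) %*% Conj(t(V)))
        }
      } else {
        sc <- sn
        if (use_lipid) {
          sl <- op_forward(op, L)
          for (c in seq_len(d[3])) sc[, , c] <- sn[, , c] - sl[, , c]
        }
        for (c in seq_len(d[3])) sc[, , c] <- w2 * sc[, , c]
        rhs_u <- op_adjoint(op, sc) %*% Conj(t(V))
      }
      rhs_u[!brain, ] <- 0
      ## gridding-based preconditioner: the normal operator is approximately
      ## a Fourier multiplier (binned w^2 sample density) scaled by the coil
      ## root-sum-of-squares
      prec <- .make_gridding_prec(op)
      f_before <- dobj(resid_list(U, V))
      U_try <- U
      r <- rhs_u - O_u(U_try)
      z <- prec(r); z[!brain, ] <- 0
      p <- z; rz <- Re(sum(Conj(r) * z))
      for (it in seq_len(cfg$u_fista_iters)) {
        if (rz < 1e-24) break
        Ap <- O_u(p)
        alpha <- rz / Re(sum(Conj(p) * Ap))
        U_try <- U_try + alpha * p
        r <- r - alpha * Ap
        z <- prec(r); z[!brain, ] <- 0
        rz_new <- Re(sum(Conj(r) * z))
        p <- z + (rz_new / rz) * p
        rz <- rz_new
      }
      if (dobj(resid_list(U_try, V)) <= f_before) U <- U_try
    } else {
    Y <- U; t_k <- 1
    F_best <- Fval(U)
    for (it in seq_len(cfg$u_fista_iters)) {
      gY <- grad_u_from_resid(resid_list(Y, V), V)
      U_cand <- prox_u(Y - step * gY)
      F_cand <- Fval(U_cand)
      if (verbose) cat(sprintf("   U it %d: F_cand=%.6g F_best=%.6g\n", it, F_cand, F_best))
      t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
      if (F_cand <= F_best) {
        Y <- U_cand + ((t_k - 1) / t_next) * (U_cand - U)
        U <- U_cand; F_best <- F_cand
      } else {
        # monotone fallback: momentum continues from the rejected candidate
        Y <- U + (t_k / t_next) * (U_cand - U)
      }
      t_k <- t_next
    }
    }

    ## ---- L update: masked gradient steps + temporal rank truncation ----
    if (use_lipid) {
      for (lstep in 1:3) {
        res <- resid_list(U, V)
        f_cur <- dobj(res)
        rw <- array(0 + 0i, d)
        for (c in seq_len(d[3])) rw[, , c] <- w2 * res[[c]]
        G <- -2 * data_scale * op_adjoint(op, rw)
        G[!lipid, ] <- 0
        stl <- step
        accepted <- FALSE
        for (try in 1:3) {
          Lc <- L - stl * G
          Lc[!lipid, ] <- 0
          Lc[lipid, ] <- rank_truncate(Lc[lipid, , drop = FALSE], cfg$lipid_rank)
          FLc <- update_FL(Lc)
          f_new <- dobj(resid_list(U, V, FLm = FLc, Lm = Lc))
          if (f_new <= f_cur) { L <- Lc; FL <- FLc; accepted <- TRUE; break }
          stl <- stl / 4
        }
        if (!accepted) break
      }
      basis <- lipid_projection_update(L, lipid, cfg$lipid_rank)
    }

    ## ---- objective trace ----
    obj_data <- dobj(resid_list(U, V))
    obj <- obj_data + tgv_term(U)
    obj_trace <- c(obj_trace, obj)
    data_trace <- c(data_trace, obj_data)
    no <- length(obj_trace)
    if (no > 2 && obj > 1.05 * obj_trace[no - 1])
      stop(sprintf("divergence: objective increased by %.1f%% at outer iteration %d",
                   100 * (obj / obj_trace[no - 1] - 1), outer))
    if (no > 2 &&
        abs(obj_trace[no - 1] - obj) <= cfg$tol * abs(obj_trace[no - 1])) break
  }

  structure(list(U = U * scale, V = V, L = L * scale, lipid_basis = basis,
                 grid = op$grid,
                 diagnostics = list(objective = obj_trace, data = data_trace,
                                    scale = scale, outer_iters_run = outer)),
            class = "cs_sense_lr")
}

#' @export
print.cs_sense_lr <- function(x, ...) {
  cat(sprintf("cs_sense_lr: rank %d model, %d voxels x %d time points; %d outer iterations\n",
              ncol(x$U), nrow(x$U), ncol(x$V), x$diagnostics$outer_iters_run))
  invisible(x)
}

#' Reconstructed image series of a low-rank model
#'
#' @param model A `cs_sense_lr` result.
#' @param include_lipid Add the lipid estimate `L` (default FALSE).
#' @return Complex `Nr x T` matrix `U V` (optionally `+ L`).
#' @export
recon_rho <- function(model, include_lipid = FALSE) {
  out <- model$U %*% model$V
  if (include_lipid) out <- out + model$L
  out
}
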