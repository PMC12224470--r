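# NODDI-style constrained estimator: Gaussian-noise MLE of a Watson-ODF
# Standard Model with hard constraints Da = Depar = 1.7 um^2/ms and the
# tortuosity relation Deperp = 1.7 * (1 - f). Free parameters are the axonal
# fraction f, the Watson concentration kappa and the bundle axis mu (the
# signal scale s0 is profiled out analytically). Estimation proceeds in two
# stages: a dense deterministic grid of (f, kappa) starts evaluated in a
# single vectorized sweep with the axis fixed at the DTI principal
# eigenvector, followed by a per-voxel Nelder-Mead refinement of
# (f, log kappa, axis angles) from the best start.

NODDI_D <- 1.7          # fixed compartment diffusivity, um^2/ms
NODDI_LMAX <- 8         # Watson forward-model truncation order

# Spline tables of K_l(b; f) under the NODDI constraints for each nonzero
# shell, and of the Watson invariants p_l(log kappa); cached per protocol.
noddi_tables <- function(protocol) {
  nz <- protocol_nonzero_shells(protocol)
  key <- paste0("noddi-", paste(round(nz$b, 6), collapse = "-"))
  if (is.null(.smikit_cache[[key]])) {
    ls <- seq(0, NODDI_LMAX, by = 2)
    fg <- seq(0, 1, length.out = 121)
    Kf <- lapply(nz$b, function(b) {
      K <- kernel_projection_many(fg, rep(NODDI_D, 121), rep(NODDI_D, 121),
                                  NODDI_D * (1 - fg), b = b, ls = ls)
      apply(K, 2, function(col) stats::splinefun(fg, col, method = "natural"))
    })
    lk <- seq(log(1e-3), log(2e4), length.out = 220)
    pk <- watson_invariants(exp(lk), lmax = NODDI_LMAX)
    Pk <- apply(pk, 2, function(col)
      stats::splinefun(lk, col, method = "hyman"))
    .smikit_cache[[key]] <- list(b = nz$b, ls = ls, Kf = Kf, Pk = Pk,
                                 lk_range = range(lk))
  }
  .smikit_cache[[key]]
}

# model coefficients c[l, shell] = (2l+1) * p_l(kappa) * K_l(b_s; f)
noddi_coefs <- function(tab, f, log_kappa) {
  ls <- tab$ls
  lk <- min(max(log_kappa, tab$lk_range[1]), tab$lk_range[2])
  pl <- c(1, vapply(paste0("p", ls[-1]), function(nm) tab$Pk[[nm]](lk),
                    numeric(1)))
  sapply(seq_along(tab$b), function(s)
    (2 * ls + 1) * pl * vapply(seq_along(ls), function(j)
      tab$Kf[[s]][[j]](f), numeric(1)))
}

# single-voxel objective: residual sum of squares with s0 profiled out
noddi_sse <- function(par, y, G, shell_of, b0_rows, tab) {
  f <- min(max(par[1], 0), 1)
  mu <- c(sin(par[3]) * cos(par[4]), sin(par[3]) * sin(par[4]), cos(par[3]))
  x <- as.vector(G %*% mu)
  co <- noddi_coefs(tab, f, par[2])
  m <- numeric(length(y))
  m[b0_rows] <- 1
  for (s in seq_along(tab$b)) {
    rows <- shell_of[[s]]
    mv <- 0
    for (j in seq_along(tab$ls))
      mv <- mv + co[j, s] * legendre_poly(tab$ls[j], x[rows])
    m[rows] <- mv
  }
  s0 <- sum(y * m) / sum(m * m)
  sum((y - s0 * m)^2)
}

#' NODDI-style constrained Standard Model fit
#'
#' Maximum-likelihood estimation under Gaussian noise of the Watson-ODF
#' Standard Model with `Da = Depar` fixed at 1.7 um^2/ms and the tortuosity
#' constraint `Deperp = 1.7 (1 - f)` (no CSF compartment). Returns only the
#' parameters the model actually estimates: the axonal water fraction `f`
#' and the ODF anisotropy `p2` mapped from the fitted Watson concentration.
#'
#' The deterministic multi-start scheme evaluates a `grid_f` x `grid_kappa`
#' grid of starting points (vectorized across voxels, axis initialized at the
#' DTI principal eigenvector) and refines the best start per voxel by
#' Nelder-Mead over `(f, log kappa, axis)`.
#'
#' @param signals (volumes x voxels) matrix or vector.
#' @param protocol an [sm_protocol()].
#' @param grid_f,grid_kappa starting grids for the axonal fraction and the
#'   Watson concentration.
#' @param refine run the per-voxel simplex refinement (default TRUE).
#' @param maxit Nelder-Mead iteration cap.
#' @param chunk voxels per vectorized grid sweep.
#' @return An [sm_estimates] with columns `f`, `p2`; diagnostics carry
#'   `kappa`, `sse`, and convergence flags. Voxels where all starts fail are
#'   flagged.
#' @export
fit_noddi <- function(signals, protocol,
                      grid_f = seq(0.05, 0.95, length.out = 12),
                      grid_kappa = exp(seq(log(0.05), log(64), length.out = 12)),
                      refine = TRUE, maxit = 400, chunk = 2500L) {
  sig <- if (is.matrix(signals)) signals else matrix(signals, ncol = 1)
  n <- ncol(sig)
  tab <- noddi_tables(protocol)
  nz <- protocol_nonzero_shells(protocol)
  b0_rows <- protocol_b0_idx(protocol)
  nvol <- nrow(sig)
  axes <- dti_axes(sig, protocol)

  best_f <- numeric(n); best_k <- numeric(n); best_sse <- rep(Inf, n)
  starts <- expand.grid(f = grid_f, kappa = grid_kappa)
  for (cs in seq(1, n, by = chunk)) {
    jj <- cs:min(n, cs + chunk - 1L)
    y <- sig[, jj, drop = FALSE]
    X <- crossprod(t(protocol$dirs), axes[, jj, drop = FALSE])  # nvol x |jj|
    Pl_x <- lapply(tab$ls, function(l) legendre_poly(l, X))
    ssy <- colSums(y^2)
    for (g in seq_len(nrow(starts))) {
      co <- noddi_coefs(tab, starts$f[g], log(starts$kappa[g]))
      m <- matrix(0, nvol, length(jj))
      m[b0_rows, ] <- 1
      for (s in seq_along(tab$b)) {
        rows <- nz$idx[[s]]
        mv <- 0
        for (j in seq_along(tab$ls))
          mv <- mv + co[j, s] * Pl_x[[j]][rows, , drop = FALSE]
        m[rows, ] <- mv
      }
      num <- colSums(y * m); den <- colSums(m * m)
      sse <- ssy - num^2 / den
      upd <- sse < best_sse[jj]
      if (any(upd)) {
        idx <- jj[upd]
        best_sse[idx] <- sse[upd]
        best_f[idx] <- starts$f[g]
        best_k[idx] <- starts$kappa[g]
      }
    }
  }

  shell_rows <- nz$idx
  fhat <- best_f; khat <- best_k; ssev <- best_sse
  conv <- rep(TRUE, n)
  if (refine) {
    for (v in seq_len(n)) {
      mu <- axes[, v]
      th0 <- acos(min(1, max(-1, mu[3]))); ph0 <- atan2(mu[2], mu[1])
      o <- stats::optim(c(best_f[v], log(best_k[v]), th0, ph0),
                        noddi_sse, y = sig[, v], G = protocol$dirs,
                        shell_of = shell_rows, b0_rows = b0_rows, tab = tab,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
      if (is.finite(o$value) && o$value <= best_sse[v] + 1e-12) {
        fhat[v] <- min(max(o$par[1], 0), 1)
        khat[v] <- exp(min(max(o$par[2], tab$lk_range[1]), tab$lk_range[2]))
        ssev[v] <- o$value
        conv[v] <- o$convergence == 0
      } else conv[v] <- FALSE
    }
  }
  p2 <- vapply(log(pmax(khat, 1e-3)), function(lk) tab$Pk$p2(lk), numeric(1))
  p2[khat <= 1e-3] <- tab$Pk$p2(log(1e-3))
  flags <- !is.finite(ssev)
  sm_estimates(data.frame(f = fhat, p2 = p2), estimator = "noddi",
               flags = flags,
               diagnostics = list(kappa = khat, sse = ssev,
                                  refined = refine, converged = conv))
}
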