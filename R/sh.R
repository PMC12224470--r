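# Real even-order spherical harmonics and per-shell rotational invariants.
#
# Convention: Y_lm is the real spherical-harmonic basis, orthonormal on the
# unit sphere under the solid-angle measure dOmega (integral of Y_lm^2 over
# the sphere = 1), without the Condon-Shortley phase. The ODF is a probability
# density rho on the sphere (integral rho dOmega = 1) and its coefficients are
# stored in the "signal" convention p_lm = 4*pi * <rho, Y_lm>, so that the
# synthesized signal is S(g) = sum_lm p_lm K_l(b) Y_lm(g) with p_00 =
# sqrt(4*pi), and the invariant p_l = sqrt( sum_m p_lm^2 / (4*pi*(2l+1)) )
# equals 1 for a fully aligned (delta) ODF and 0 for an isotropic one.

# (l, m) index table for even orders up to lmax.
sh_index <- function(lmax) {
  ls <- seq(0, lmax, by = 2)
  do.call(rbind, lapply(ls, function(l) data.frame(l = l, m = -l:l)))
}

#' Real even-order spherical-harmonic design matrix
#'
#' Evaluates the real spherical harmonics (orthonormal under the solid-angle
#' measure, Condon-Shortley-free) of even order `l = 0, 2, ..., lmax` at unit
#' direction vectors.
#'
#' @param dirs n x 3 matrix of unit vectors.
#' @param lmax maximum (even) harmonic order.
#' @return n x n_coef matrix; columns ordered by (l, m), m = -l..l.
#' @export
sh_basis <- function(dirs, lmax = 4) {
  if (lmax %% 2 != 0) stop("lmax must be even")
  dirs <- as.matrix(dirs)
  ct <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  idx <- sh_index(lmax)
  out <- matrix(0, nrow(dirs), nrow(idx))
  for (l in unique(idx$l)) {
    if (l == 0) {
      out[, idx$l == 0] <- 1 / sqrt(4 * pi)
      next
    }
    # pracma follows the MATLAB convention (includes Condon-Shortley phase);
    # strip it with (-1)^m.
    P <- pracma::legendre(l, ct)            # (l+1) x n, rows m = 0..l
    for (m in 0:l) {
      Nlm <- sqrt((2 * l + 1) / (4 * pi) *
                    factorial(l - m) / factorial(l + m))
      Pm <- (-1)^m * P[m + 1, ]
      if (m == 0) {
        out[, idx$l == l & idx$m == 0] <- Nlm * Pm
      } else {
        out[, idx$l == l & idx$m == m] <- sqrt(2) * Nlm * Pm * cos(m * phi)
        out[, idx$l == l & idx$m == -m] <- sqrt(2) * Nlm * Pm * sin(m * phi)
      }
    }
  }
  colnames(out) <- paste0("l", idx$l, "m", idx$m)
  out
}

# Cached per-shell SH design and its least-squares pseudoinverse.
shell_sh_design <- function(protocol, shell_idx, lmax) {
  key <- paste0("sh-", protocol_signature(protocol), "-", shell_idx[1], "-",
                length(shell_idx), "-", lmax)
  if (is.null(.smikit_cache[[key]])) {
    Y <- sh_basis(protocol$dirs[shell_idx, , drop = FALSE], lmax)
    qrY <- qr(Y)
    if (qrY$rank < ncol(Y))
      stop("rank-deficient spherical-harmonic design (degenerate directions)")
    d <- svd(Y, nu = 0, nv = 0)$d
    if (d[1] / d[length(d)] > 1e8)
      stop("ill-conditioned spherical-harmonic design (condition number > 1e8)")
    pinv <- solve(crossprod(Y), t(Y))
    .smikit_cache[[key]] <- list(Y = Y, pinv = pinv)
  }
  .smikit_cache[[key]]
}

#' Per-shell spherical-harmonic fit of directional signals
#'
#' Linear least-squares fit of even-order real spherical harmonics to the
#' signals of each nonzero shell; the b = 0 shell is summarized by its mean.
#' If a shell has fewer directions than SH coefficients, `lmax` is lowered for
#' that shell with a warning.
#'
#' @param signals numeric vector (one voxel) or matrix (volumes x voxels).
#' @param protocol an [sm_protocol()] matching the rows of `signals`.
#' @param lmax maximum (even) SH order, default 4.
#' @return An object of class `sh_fit`: list with `b0_mean` (per voxel),
#'   `shells` (named by nominal b; each holds `coef` (n_coef x voxels),
#'   `lmax`, `idx`), and the protocol signature.
#' @export
fit_sh <- function(signals, protocol, lmax = 4) {
  sig <- if (is.matrix(signals)) signals else matrix(signals, ncol = 1)
  if (nrow(sig) != length(protocol$bvals))
    stop("signals have ", nrow(sig), " volumes but protocol has ",
         length(protocol$bvals))
  b0 <- protocol_b0_idx(protocol)
  nz <- protocol_nonzero_shells(protocol)
  shells <- vector("list", length(nz$b))
  names(shells) <- format(nz$b, trim = TRUE)
  for (s in seq_along(nz$b)) {
    idx <- nz$idx[[s]]
    lm <- lmax
    while ((lm / 2 + 1) * (lm + 1) > length(idx) && lm > 0) lm <- lm - 2
    if (lm < lmax)
      warning("shell b = ", nz$b[s], ": only ", length(idx),
              " directions; lowering lmax to ", lm)
    des <- shell_sh_design(protocol, idx, lm)
    shells[[s]] <- list(coef = des$pinv %*% sig[idx, , drop = FALSE],
                        lmax = lm, b = nz$b[s], idx = sh_index(lm))
  }
  structure(list(b0_mean = colMeans(sig[b0, , drop = FALSE]),
                 shells = shells, lmax = lmax,
                 protocol_sig = protocol_signature(protocol)),
            class = "sh_fit")
}

#' Rotational invariants of a spherical-harmonic fit
#'
#' Basis-independent per-shell invariants
#' `S_l(b) = sqrt( sum_m S_lm(b)^2 / (4*pi*(2l+1)) )` for even l. `S_0(b)` is
#' the spherical-mean signal; all invariants are nonnegative and unchanged by
#' any rotation of the direction frame.
#'
#' @param fit an `sh_fit` from [fit_sh()], or a signal vector/matrix if
#'   `protocol` is supplied.
#' @param protocol optional [sm_protocol()] when `fit` is raw signals.
#' @param normalize divide by the b = 0 mean signal (making the proton density
#'   a nuisance parameter)?
#' @return A list of class `signal_invariants`: `S` is an array
#'   (shells x l-orders x voxels), `b0_mean` the per-voxel b = 0 mean,
#'   `b` the shell b-values, `normalized` the flag.
#' @export
rotational_invariants <- function(fit, protocol = NULL, normalize = FALSE) {
  if (!inherits(fit, "sh_fit")) {
    if (is.null(protocol)) stop("need an sh_fit or signals plus a protocol")
    fit <- fit_sh(fit, protocol)
  }
  ls <- seq(0, fit$lmax, by = 2)
  nvox <- length(fit$b0_mean)
  S <- array(0, c(length(fit$shells), length(ls), nvox),
             dimnames = list(names(fit$shells), paste0("S", ls), NULL))
  for (s in seq_along(fit$shells)) {
    sh <- fit$shells[[s]]
    for (j in seq_along(ls)) {
      l <- ls[j]
      rows <- sh$idx$l == l
      if (!any(rows)) next
      S[s, j, ] <- sqrt(colSums(sh$coef[rows, , drop = FALSE]^2) /
                          (4 * pi * (2 * l + 1)))
    }
  }
  if (normalize) S <- sweep(S, 3, fit$b0_mean, "/")
  structure(list(S = S, b0_mean = fit$b0_mean,
                 b = vapply(fit$shells, `[[`, numeric(1), "b"),
                 normalized = normalize),
            class = "signal_invariants")
}

#' Normalized invariant feature matrix
#'
#' The feature set used by the learned estimator: rotational invariants
#' `S_0, S_2, S_4` of each nonzero shell, normalized by the measured b = 0
#' mean — six features for a two-shell acquisition.
#'
#' @param signals vector or (volumes x voxels) matrix.
#' @param protocol an [sm_protocol()].
#' @param lmax maximum SH order (default 4).
#' @return voxels x features matrix; columns like `S2_b1`.
#' @export
signal_features <- function(signals, protocol, lmax = 4) {
  inv <- rotational_invariants(signals, protocol, normalize = TRUE)
  ls <- seq(0, lmax, by = 2)
  nsh <- dim(inv$S)[1]
  feat <- matrix(0, dim(inv$S)[3], nsh * length(ls))
  nm <- character(nsh * length(ls))
  k <- 0
  for (s in seq_len(nsh)) for (j in seq_along(ls)) {
    k <- k + 1
    feat[, k] <- inv$S[s, j, ]
    nm[k] <- paste0("S", ls[j], "_b", format(inv$b[s], trim = TRUE))
  }
  colnames(feat) <- nm
  feat
}
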