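#' Synthesize noise-free Standard Model signals
#'
#' Evaluates the spherical convolution of the fascicle kernel with the ODF
#' through its spherical-harmonic factorization `S_lm(b) = p_lm K_l(b)`:
#' for every volume, `S(g, b) = s0 * sum_lm p_lm K_l(b) Y_lm(g)` (the l = 0
#' term reduces to the spherical-mean kernel `K_0`). b = 0 volumes equal `s0`.
#' For zonal ODFs created by [zonal_odf()] the sum collapses to
#' `sum_l (2l+1) p_l K_l(b) P_l(g . axis)` and no explicit SH evaluation at
#' the stored axis orientation is needed.
#'
#' @param params a [kernel_params()].
#' @param odf an `odf_coefficients` ([zonal_odf()] or general).
#' @param protocol an [sm_protocol()].
#' @return Numeric vector of per-volume signals.
#' @export
synthesize_signals <- function(params, odf, protocol) {
  ls <- seq(0, odf$lmax, by = 2)
  Kl <- stats::setNames(lapply(ls, function(l)
    kernel_projection(params, protocol$bvals, l)), paste0("l", ls))
  axis <- attr(odf, "axis")
  pl <- odf_invariants(odf)
  if (!is.null(axis)) {
    xi <- as.vector(protocol$dirs %*% axis)
    sig <- numeric(length(protocol$bvals))
    for (l in ls) {
      plv <- pl[[paste0("p", l)]]
      sig <- sig + (2 * l + 1) * plv * Kl[[paste0("l", l)]] *
        legendre_poly(l, xi)
    }
  } else {
    Y <- sh_basis(protocol$dirs, odf$lmax)
    idx <- sh_index(odf$lmax)
    plm_full <- c(sqrt(4 * pi), odf$plm)  # prepend fixed p00
    sig <- numeric(length(protocol$bvals))
    for (j in seq_len(nrow(idx))) {
      l <- idx$l[j]
      sig <- sig + plm_full[j] * Kl[[paste0("l", l)]] * Y[, j]
    }
  }
  # K_l(b) above already carries s0 (kernel_projection integrates the full
  # kernel); K_l(0) = 0 for l > 0 and K_0(0) = s0 hold exactly:
  b0 <- protocol_b0_idx(protocol)
  sig[b0] <- params$s0
  sig
}

# Vectorized zonal synthesis for n voxels. params is a data.frame/list with
# f, Da, Depar, Deperp (+ optional s0); pl a matrix with columns p2, p4;
# axes an n x 3 matrix. Returns a (volumes x voxels) matrix.
synthesize_zonal_many <- function(params, pl, axes, protocol,
                                  ls = c(0, 2, 4), chunk = 20000L) {
  n <- length(params$f)
  s0 <- if (is.null(params$s0)) rep(1, n) else params$s0
  nvol <- length(protocol$bvals)
  nz <- protocol_nonzero_shells(protocol)
  out <- matrix(0, nvol, n)
  plmat <- cbind(p0 = rep(1, n),
                 p2 = pl[, "p2"],
                 p4 = if ("p4" %in% colnames(pl)) pl[, "p4"] else 0)
  for (start in seq(1, n, by = chunk)) {
    jj <- start:min(n, start + chunk - 1L)
    X <- protocol$dirs %*% t(axes[jj, , drop = FALSE])  # nvol x |jj|
    acc <- matrix(0, nvol, length(jj))
    for (s in seq_along(nz$b)) {
      rows <- nz$idx[[s]]
      K <- kernel_projection_many(params$f[jj], params$Da[jj],
                                  params$Depar[jj], params$Deperp[jj],
                                  b = nz$b[s], ls = ls)
      for (k in seq_along(ls)) {
        l <- ls[k]
        w <- (2 * l + 1) * K[, k] * plmat[jj, paste0("p", l)]
        acc[rows, ] <- acc[rows, ] +
          legendre_poly(l, X[rows, , drop = FALSE]) *
          rep(w, each = length(rows))
      }
    }
    b0 <- protocol_b0_idx(protocol)
    acc[b0, ] <- 1
    out[, jj] <- acc * rep(s0[jj], each = nvol)
  }
  out
}

#' Add measurement noise to signals
#'
#' Gaussian noise adds `N(0, sigma^2)` with `sigma = s0 / snr` (SNR referenced
#' to the b = 0 signal); Rician noise replaces each signal by
#' `sqrt((s + e1)^2 + e2^2)` with independent `e1, e2 ~ N(0, sigma^2)`, whose
#' high-SNR mean bias is approximately `sigma^2 / (2 s)`.
#'
#' @param signals numeric vector or matrix.
#' @param snr signal-to-noise ratio (> 0) relative to `s0`.
#' @param model `"gaussian"` (benchmark default) or `"rician"`.
#' @param s0 reference b = 0 amplitude defining `sigma`.
#' @return Noisy signals, same shape as the input. Uses the current RNG
#'   state; wrap in a seeded context for reproducibility.
#' @export
add_noise <- function(signals, snr, model = c("gaussian", "rician"), s0 = 1) {
  model <- match.arg(model)
  if (snr <= 0) stop("snr must be positive")
  sigma <- s0 / snr
  if (model == "gaussian") {
    signals + stats::rnorm(length(signals), 0, sigma)
  } else {
    e1 <- stats::rnorm(length(signals), 0, sigma)
    e2 <- stats::rnorm(length(signals), 0, sigma)
    out <- sqrt((signals + e1)^2 + e2^2)
    attributes(out) <- attributes(signals)
    out
  }
}
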