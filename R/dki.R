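# Diffusion and kurtosis tensor estimation (weighted linear least squares on
# the log-signal, with designs in b and b^2), plus directional evaluation
# helpers shared by the WMTI-style estimators and FA masking.

# second-order design rows: D(n) = A6(n) %*% dt, dt = (xx,yy,zz,xy,xz,yz)
design_d2 <- function(dirs) {
  cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
        2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
        2 * dirs[, 2] * dirs[, 3])
}

# fourth-order design rows with multiplicities: V(n) = A15(n) %*% vt
design_d4 <- function(dirs) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  cbind(x^4, y^4, z^4,
        4 * x^3 * y, 4 * x^3 * z, 4 * y^3 * x, 4 * y^3 * z,
        4 * z^3 * x, 4 * z^3 * y,
        6 * x^2 * y^2, 6 * x^2 * z^2, 6 * y^2 * z^2,
        12 * x^2 * y * z, 12 * y^2 * x * z, 12 * z^2 * x * y)
}

dki_design <- function(protocol) {
  b <- protocol$bvals
  cbind(1, -b * design_d2(protocol$dirs), (b^2 / 6) * design_d4(protocol$dirs))
}

#' Diffusion + kurtosis tensor fit
#'
#' Two-pass weighted linear least squares on the log-signal: an unweighted fit
#' provides predicted signals whose squares serve as weights for the second
#' pass (the standard heteroscedasticity correction for log-linearized
#' Gaussian noise). Requires two nonzero shells and at least 22 usable
#' volumes (1 intercept + 6 diffusion + 15 kurtosis coefficients).
#' Non-positive signals are clipped at machine epsilon with a warning.
#'
#' @param signals (volumes x voxels) matrix or vector.
#' @param protocol an [sm_protocol()].
#' @return Object of class `dki_fit`: `dt` (6 x voxels, um^2/ms), `vt`
#'   (15 x voxels; the scaled kurtosis tensor `V = MD^2 W`), `s0`, `md`
#'   (mean diffusivity) and the protocol.
#' @export
dki_fit <- function(signals, protocol) {
  sig <- if (is.matrix(signals)) signals else matrix(signals, ncol = 1)
  if (nrow(sig) != length(protocol$bvals))
    stop("signals/protocol volume mismatch")
  nz <- protocol_nonzero_shells(protocol)
  if (length(nz$b) < 2) stop("kurtosis fit needs at least two nonzero shells")
  if (nrow(sig) < 22) stop("kurtosis fit needs at least 22 volumes")
  if (any(sig <= 0)) {
    warning(sum(sig <= 0), " non-positive signal(s) clipped at machine epsilon")
    sig[sig <= 0] <- .Machine$double.eps
  }
  B <- dki_design(protocol)
  logs <- log(sig)
  beta <- qr.coef(qr(B), logs)                       # unweighted first pass
  pred <- exp(B %*% beta)
  n <- ncol(sig)
  for (v in seq_len(n)) {                            # per-voxel WLLS pass
    w <- pred[, v]^2
    Bw <- B * w
    beta[, v] <- solve(crossprod(B, Bw), crossprod(Bw, logs[, v]))
  }
  dt <- beta[2:7, , drop = FALSE]
  structure(list(s0 = exp(beta[1, ]), dt = dt,
                 vt = beta[8:22, , drop = FALSE],
                 md = colMeans(dt[1:3, , drop = FALSE]),
                 protocol = protocol),
            class = "dki_fit")
}

#' @export
print.dki_fit <- function(x, ...) {
  cat("DKI fit:", length(x$s0), "voxel(s); MD range",
      paste(signif(range(x$md), 3), collapse = " - "), "um^2/ms\n")
  invisible(x)
}

# directional diffusivity / scaled-kurtosis evaluation (grid x voxels)
directional_diffusivity <- function(fit, dirs) design_d2(dirs) %*% fit$dt
directional_kurtosis <- function(fit, dirs) {
  Dn <- design_d2(dirs) %*% fit$dt
  (design_d4(dirs) %*% fit$vt) / Dn^2       # K(n) = V(n) / D(n)^2
}

#' Mean (apparent) kurtosis
#'
#' Average of the directional apparent kurtosis over a quasi-uniform
#' direction grid.
#'
#' @param fit a [dki_fit()].
#' @param n_dirs grid size.
#' @return Per-voxel mean kurtosis.
#' @export
mean_kurtosis <- function(fit, n_dirs = 256) {
  grid <- with_seed(1, fibonacci_directions(n_dirs))
  colMeans(directional_kurtosis(fit, grid))
}

# 3x3 tensor from the 6-vector (xx,yy,zz,xy,xz,yz)
tensor_from_vec <- function(dt6) {
  matrix(c(dt6[1], dt6[4], dt6[5],
           dt6[4], dt6[2], dt6[6],
           dt6[5], dt6[6], dt6[3]), 3, 3)
}

#' Fractional anisotropy of diffusion tensors
#'
#' @param dt 6 x voxels matrix (or length-6 vector) of tensor components
#'   `(xx, yy, zz, xy, xz, yz)`, or a [dki_fit()].
#' @return Per-voxel FA in \[0,1\] (NA for non-finite tensors).
#' @examples
#' fa_from_tensor(c(2, 0.7, 0.7, 0, 0, 0))  # 0.6615
#' @export
fa_from_tensor <- function(dt) {
  if (inherits(dt, "dki_fit")) dt <- dt$dt
  dt <- if (is.matrix(dt)) dt else matrix(dt, ncol = 1)
  unname(apply(dt, 2, function(v) {
    if (any(!is.finite(v))) return(NA_real_)
    ev <- eigen(tensor_from_vec(v), symmetric = TRUE, only.values = TRUE)$values
    md <- mean(ev)
    den <- sum(ev^2)
    if (den <= 0) return(0)
    sqrt(1.5 * sum((ev - md)^2) / den)
  }))
}

#' White-matter mask by FA threshold
#'
#' Strict inequality `FA > threshold`; voxels with non-finite tensors are
#' excluded.
#'
#' @param dt tensors as in [fa_from_tensor()].
#' @param threshold FA cutoff (default 0.2).
#' @return Logical vector.
#' @export
fa_mask <- function(dt, threshold = 0.2) {
  fa <- fa_from_tensor(dt)
  !is.na(fa) & fa > threshold
}

# principal eigenvectors of per-voxel diffusion tensors (3 x voxels), from a
# quick unweighted log-linear DTI fit; used to initialize fascicle axes.
dti_axes <- function(signals, protocol) {
  sig <- if (is.matrix(signals)) signals else matrix(signals, ncol = 1)
  sig <- pmax(sig, .Machine$double.eps)
  B <- cbind(1, -protocol$bvals * design_d2(protocol$dirs))
  beta <- qr.coef(qr(B), log(sig))
  apply(beta[2:7, , drop = FALSE], 2, function(v) {
    if (any(!is.finite(v))) return(c(0, 0, 1))
    eigen(tensor_from_vec(v), symmetric = TRUE)$vectors[, 1]
  })
}
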