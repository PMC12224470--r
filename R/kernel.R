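#' Fascicle kernel parameters
#'
#' Parameters of the two-compartment fiber-fascicle response: an intra-axonal
#' "stick" (volume fraction `f`, axial diffusivity `Da`, zero radial
#' diffusivity) plus an axially symmetric extra-axonal "zeppelin" (`Depar`,
#' `Deperp`). Diffusivities are in um^2/ms. An optional isotropic free-water
#' compartment with fraction `fiso` and diffusivity `D0` = 3 um^2/ms can be
#' included in forward simulations.
#'
#' @param f intra-axonal water fraction in \[0,1\].
#' @param Da intra-axonal axial diffusivity (um^2/ms).
#' @param Depar,Deperp extra-axonal axial and radial diffusivities (um^2/ms);
#'   `Deperp <= Depar` is required.
#' @param s0 proton-density signal scale (b = 0 signal).
#' @param fiso optional free-water fraction; `f + fiso <= 1`.
#' @param D0 free-water diffusivity (um^2/ms).
#' @return A list of class `kernel_params`.
#' @examples
#' kp <- kernel_params(f = 0.5, Da = 2, Depar = 2, Deperp = 0.7)
#' kernel_signal(kp, b = 1, xi = 1)  # exp(-2)
#' @export
kernel_params <- function(f, Da, Depar, Deperp, s0 = 1, fiso = 0,
                          D0 = D0_FREE_WATER) {
  stopifnot(length(f) == 1, length(Da) == 1, length(Depar) == 1,
            length(Deperp) == 1)
  if (f < 0 || f > 1) stop("f must lie in [0,1]")
  if (fiso < 0 || fiso > 1 || f + fiso > 1) stop("need 0 <= fiso and f + fiso <= 1")
  if (any(c(Da, Depar, Deperp) < 0) || any(c(Da, Depar, Deperp) > D0))
    stop("diffusivities must lie in [0, ", D0, "] um^2/ms")
  if (Deperp > Depar + 1e-12) stop("Deperp must not exceed Depar")
  if (s0 <= 0) stop("s0 must be positive")
  structure(list(f = f, Da = Da, Depar = Depar, Deperp = Deperp,
                 s0 = s0, fiso = fiso, D0 = D0),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf(
    "SM fascicle kernel: f = %.3g, Da = %.3g, Depar = %.3g, Deperp = %.3g (um^2/ms)",
    x$f, x$Da, x$Depar, x$Deperp))
  if (x$fiso > 0) cat(sprintf(", fiso = %.3g", x$fiso))
  cat(sprintf(", s0 = %.3g\n", x$s0))
  invisible(x)
}

#' Fascicle kernel signal
#'
#' Signal of a single fiber fascicle at diffusion weighting `b` and direction
#' cosine `xi` = g.n between the gradient and the fascicle axis:
#' `s0 * (f exp(-b Da xi^2) + (1-f) exp(-b Depar xi^2 - b Deperp (1-xi^2)))`.
#' When a free-water compartment is present the extra-axonal fraction becomes
#' `1 - f - fiso` and `fiso * exp(-b D0)` is added, so the b = 0 signal is
#' always `s0`.
#'
#' @param params a [kernel_params()].
#' @param b b-value(s), ms/um^2.
#' @param xi direction cosine(s) in \[0,1\].
#' @return Signal values (recycled over `b` and `xi`).
#' @export
kernel_signal <- function(params, b, xi) {
  if (any(b < 0)) stop("b must be nonnegative")
  if (any(xi < -1e-12 | xi > 1 + 1e-12)) stop("xi must lie in [0,1]")
  xi2 <- pmin(1, pmax(0, xi))^2
  params$s0 * (params$f * exp(-b * params$Da * xi2) +
    (1 - params$f - params$fiso) *
      exp(-b * params$Depar * xi2 - b * params$Deperp * (1 - xi2)) +
    params$fiso * exp(-b * params$D0))
}

#' Legendre projection of the fascicle kernel
#'
#' Computes `K_l(b) = integral_0^1 K(b, xi) P_l(xi) dxi` by fixed-order
#' Gauss-Legendre quadrature on \[0,1\] (order 64 by default; doubling the
#' order moves the result by < 1e-10). `K_0(b)` is the spherical-mean kernel;
#' `K_l(0) = 0` for l > 0 by Legendre orthogonality.
#'
#' @param params a [kernel_params()].
#' @param b b-value(s), ms/um^2.
#' @param l even Legendre order (0, 2, 4, 6 or 8).
#' @param order quadrature order.
#' @return `K_l(b)`, same length as `b`.
#' @examples
#' kp <- kernel_params(f = 1, Da = 2, Depar = 2, Deperp = 0)
#' kernel_projection(kp, b = 1, l = 0)  # sqrt(pi/(4*2))*erf(sqrt(2))
#' @export
kernel_projection <- function(params, b, l, order = 64) {
  if (l %% 2 != 0) stop("l must be even")
  gl <- gauss_legendre_01(order)
  plx <- legendre_poly(l, gl$x)
  unname(vapply(b, function(bb) {
    sum(gl$w * plx * kernel_signal(params, bb, gl$x))
  }, numeric(1)))
}

# Vectorized kernel projections for many voxels: given parameter vectors and a
# single b, returns an n x length(ls) matrix of K_l(b) (s0 = 1, no free water).
kernel_projection_many <- function(f, Da, Depar, Deperp, b, ls = c(0, 2, 4),
                                   order = 64) {
  gl <- gauss_legendre_01(order)
  xi2 <- gl$x^2
  n <- length(f)
  # n x order exponent matrices
  Ei <- exp(-outer(b * Da, xi2))
  Ee <- exp(-(outer(b * Depar, xi2) + outer(b * Deperp, 1 - xi2)))
  K <- Ei * f + Ee * (1 - f)
  out <- matrix(0, n, length(ls))
  for (j in seq_along(ls)) {
    out[, j] <- K %*% (gl$w * legendre_poly(ls[j], gl$x))
  }
  colnames(out) <- paste0("l", ls)
  out
}

# Spherical mean of a stick compartment: h(x) = sqrt(pi/(4x)) erf(sqrt(x)),
# x = b*D, with a series branch for small x (used by the SMT estimator and as
# a closed-form cross-check of the quadrature).
stick_mean <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-4
  xs <- x[small]
  out[small] <- 1 - xs / 3 + xs^2 / 10 - xs^3 / 42 + xs^4 / 216
  xl <- x[!small]
  if (length(xl))
    out[!small] <- sqrt(pi / (4 * xl)) * pracma::erf(sqrt(xl))
  out
}

# Spherical mean of a zeppelin: exp(-b Deperp) * h(b * (Depar - Deperp)).
zeppelin_mean <- function(b, Depar, Deperp) {
  exp(-b * Deperp) * stick_mean(pmax(0, b * (Depar - Deperp)))
}
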