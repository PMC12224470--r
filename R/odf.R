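#' ODF spherical-harmonic coefficients
#'
#' Even-order SH coefficients of a fiber orientation distribution function.
#' Coefficients follow the package's signal convention (see [sh_basis()]):
#' the l = 0 coefficient is fixed by the ODF normalization (`p00 =
#' sqrt(4*pi)`) and is not stored; a fully aligned (delta) ODF has invariant
#' `p_l = 1` for every even l.
#'
#' ODF positivity is not enforced; a warning is emitted when a zonal ODF dips
#' below zero on a check grid (invariants-based estimation is unaffected).
#'
#' @param plm named numeric vector of coefficients for even l >= 2, names as
#'   produced by [sh_basis()] (e.g. `"l2m0"`); missing coefficients are 0.
#' @param lmax maximum even order.
#' @return A list of class `odf_coefficients`.
#' @export
odf_coefficients <- function(plm, lmax = 4) {
  if (lmax %% 2 != 0) stop("lmax must be even")
  idx <- sh_index(lmax)
  idx <- idx[idx$l > 0, ]
  full <- stats::setNames(numeric(nrow(idx)), paste0("l", idx$l, "m", idx$m))
  if (length(plm)) {
    if (is.null(names(plm))) stop("plm must be a named vector (e.g. 'l2m0')")
    unknown <- setdiff(names(plm), names(full))
    if (length(unknown)) stop("unknown coefficient name(s): ",
                              paste(unknown, collapse = ", "))
    full[names(plm)] <- plm
  }
  structure(list(plm = full, lmax = lmax, idx = idx),
            class = "odf_coefficients")
}

#' Zonal (axially symmetric) ODF with prescribed invariants
#'
#' Builds the axially symmetric ODF whose rotational invariants equal the
#' requested `p_l` exactly, aligned with `axis`. In the aligned frame only
#' m = 0 coefficients are nonzero: `p_l0 = sqrt(4*pi*(2l+1)) * p_l`. Because
#' evaluation of signals only involves `P_l(g . axis)`, no explicit Wigner
#' rotation is needed; the axis is stored alongside the zonal coefficients.
#'
#' @param p2,p4 target invariants in \[0,1\] (`p4` defaults to 0.8 * `p2`,
#'   the midpoint of the histology-motivated `p4/p2` range 0.75-0.85).
#' @param axis unit 3-vector, fascicle bundle orientation.
#' @param lmax maximum even order (>= 4 to carry `p4`).
#' @param check_positivity warn if the truncated ODF is negative somewhere.
#' @return An `odf_coefficients` with attributes `axis` and `pl`.
#' @examples
#' odf <- zonal_odf(p2 = 1, p4 = 1, axis = c(0, 0, 1))  # delta-like
#' odf_invariants(odf)
#' @export
zonal_odf <- function(p2, p4 = 0.8 * p2, axis = c(0, 0, 1), lmax = 4,
                      check_positivity = FALSE) {
  pl <- c(p2 = p2, p4 = p4)
  if (any(pl < 0 | pl > 1)) stop("p2 and p4 must lie in [0,1]")
  axis <- axis / sqrt(sum(axis^2))
  plm <- c(l2m0 = sqrt(4 * pi * 5) * p2)
  if (lmax >= 4) plm <- c(plm, l4m0 = sqrt(4 * pi * 9) * p4)
  odf <- odf_coefficients(plm, lmax = lmax)
  attr(odf, "axis") <- axis
  attr(odf, "pl") <- pl
  if (check_positivity) {
    xi <- seq(-1, 1, length.out = 201)
    dens <- 1 + 5 * p2 * legendre_poly(2, xi) + 9 * p4 * legendre_poly(4, xi)
    if (min(dens) < -1e-8)
      warning("truncated zonal ODF dips below zero (min ",
              signif(min(dens), 3), " on the check grid)")
  }
  odf
}

#' Rotational invariants of an ODF
#'
#' `p_l = sqrt( sum_m p_lm^2 / (4*pi*(2l+1)) )` for even l >= 2, with
#' `p_0 = 1` fixed by normalization. A fully aligned ODF gives `p_l = 1`,
#' an isotropic one 0.
#'
#' @param odf an `odf_coefficients`.
#' @return Named vector `p0, p2, ...`.
#' @export
odf_invariants <- function(odf) {
  ls <- seq(2, odf$lmax, by = 2)
  pl <- vapply(ls, function(l) {
    rows <- odf$idx$l == l
    sqrt(sum(odf$plm[rows]^2) / (4 * pi * (2 * l + 1)))
  }, numeric(1))
  stats::setNames(c(1, pl), paste0("p", c(0, ls)))
}

#' Rotational invariants of a Watson orientation distribution
#'
#' For the axially symmetric Watson distribution with concentration `kappa`
#' (density proportional to `exp(kappa * (n.mu)^2)`), the invariants are
#' Legendre moments
#' `p_l(kappa) = E[P_l(cos psi)] =
#'   int_0^1 exp(kappa xi^2) P_l(xi) dxi / int_0^1 exp(kappa xi^2) dxi`,
#' computed by adaptive quadrature on the scaled integrand (stable up to
#' kappa ~ 1e6). `p_l` is monotone increasing in kappa, 0 at kappa = 0
#' (isotropic) and -> 1 as kappa -> Inf (delta).
#'
#' @param kappa concentration parameter(s), >= 0.
#' @param lmax maximum even order.
#' @return For scalar `kappa`, a named vector `p2, p4, ...`; for vector
#'   `kappa`, a matrix (length(kappa) x orders).
#' @examples
#' watson_invariants(0)       # isotropic: all zero
#' watson_invariants(1e4)[1]  # near delta: p2 > 0.99
#' @export
watson_invariants <- function(kappa, lmax = 4) {
  if (any(kappa < 0)) stop("kappa must be nonnegative")
  ls <- seq(2, lmax, by = 2)
  one <- function(k) {
    if (k == 0) return(stats::setNames(numeric(length(ls)), paste0("p", ls)))
    # integrate exp(k*(xi^2 - 1)) * P_l(xi); for large kappa restrict to the
    # boundary layer near xi = 1 where all the mass lives
    lo <- if (k > 100) max(0, 1 - 10 / sqrt(k)) else 0
    dens <- function(xi) exp(k * (xi^2 - 1))
    Z <- stats::integrate(dens, lo, 1, rel.tol = 1e-12)$value
    vapply(ls, function(l) {
      stats::integrate(function(xi) dens(xi) * legendre_poly(l, xi),
                       lo, 1, rel.tol = 1e-12)$value / Z
    }, numeric(1)) |> stats::setNames(paste0("p", ls))
  }
  if (length(kappa) == 1) one(kappa)
  else t(vapply(kappa, one, numeric(length(ls))))
}

# Zonal SH coefficients of a Watson ODF with the given axis (used by the
# Watson-constrained estimators).
watson_odf <- function(kappa, axis = c(0, 0, 1), lmax = 4) {
  pl <- watson_invariants(kappa, lmax)
  odf <- zonal_odf(p2 = pl[["p2"]],
                   p4 = if (lmax >= 4) pl[["p4"]] else 0,
                   axis = axis, lmax = lmax)
  attr(odf, "kappa") <- kappa
  odf
}
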