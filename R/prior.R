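#' Gaussian training prior over Standard Model parameters
#'
#' The "soft" prior used to synthesize training data for the learned
#' estimator: independent Gaussians over `(f, Da, Depar, Deperp, p2)`
#' truncated to the physical box (fractions and ODF invariants in \[0,1\],
#' diffusivities in \[0,3\] um^2/ms) with `Deperp <= Depar` enforced by
#' rejection. `p4` is tied to `p2` through a ratio drawn uniformly from
#' `p4_ratio_range` (histology-motivated default 0.75-0.85). The `variance`
#' vector is interpreted literally as variance (not standard deviation).
#'
#' @param mean length-5 prior means for `(f, Da, Depar, Deperp, p2)`.
#' @param variance length-5 prior variances (> 0).
#' @param p4_ratio_range interval for the ratio `p4 / p2`.
#' @return A list of class `sm_prior`.
#' @examples
#' sm_prior()  # the reference prior used throughout
#' @export
sm_prior <- function(mean = c(f = 0.5, Da = 2, Depar = 2, Deperp = 0.7, p2 = 0.45),
                     variance = c(f = 0.06, Da = 1, Depar = 1, Deperp = 0.1, p2 = 0.06),
                     p4_ratio_range = c(0.75, 0.85)) {
  mean <- stats::setNames(as.numeric(mean), SM_PARAMS[1:5])
  variance <- stats::setNames(as.numeric(variance), SM_PARAMS[1:5])
  if (any(variance <= 0)) stop("prior variances must be positive")
  for (p in SM_PARAMS[1:5]) {
    bd <- sm_param_bounds(p)
    if (mean[p] < bd[1] || mean[p] > bd[2])
      stop("prior mean for ", p, " lies outside its physical bounds")
  }
  if (p4_ratio_range[1] > p4_ratio_range[2] || any(p4_ratio_range < 0) ||
      any(p4_ratio_range > 1))
    stop("p4_ratio_range must be an increasing interval within [0,1]")
  structure(list(mean = mean, variance = variance,
                 p4_ratio_range = p4_ratio_range),
            class = "sm_prior")
}

#' @export
print.sm_prior <- function(x, ...) {
  cat("SM training prior (truncated Gaussian):\n")
  print(rbind(mean = x$mean, variance = x$variance))
  cat(sprintf("p4/p2 ~ U(%.2f, %.2f); Deperp <= Depar by rejection\n",
              x$p4_ratio_range[1], x$p4_ratio_range[2]))
  invisible(x)
}

#' Sample ground-truth parameters from the prior
#'
#' Draws `n` parameter sets by rejection: Gaussian draws are kept only when
#' inside the physical box and satisfying `Deperp <= Depar`; `p4 = rho * p2`
#' with `rho ~ U(p4_ratio_range)`; a uniformly random fascicle axis is
#' attached to each draw.
#'
#' @param prior an [sm_prior()].
#' @param n number of draws.
#' @param seed integer seed (RNG state is restored afterwards).
#' @return A list with `theta` (data.frame `f, Da, Depar, Deperp, p2, p4`)
#'   and `axes` (n x 3 unit vectors).
#' @export
sample_prior <- function(prior, n, seed = 1) {
  stopifnot(n >= 1)
  with_seed(seed, {
    sd <- sqrt(prior$variance)
    lo <- vapply(SM_PARAMS[1:5], function(p) sm_param_bounds(p)[1], numeric(1))
    hi <- vapply(SM_PARAMS[1:5], function(p) sm_param_bounds(p)[2], numeric(1))
    got <- 0L
    theta <- matrix(0, n, 5, dimnames = list(NULL, SM_PARAMS[1:5]))
    while (got < n) {
      m <- max(1000L, ceiling((n - got) * 1.6))
      cand <- sapply(1:5, function(j) stats::rnorm(m, prior$mean[j], sd[j]))
      ok <- rep(TRUE, m)
      for (j in 1:5) ok <- ok & cand[, j] >= lo[j] & cand[, j] <= hi[j]
      ok <- ok & cand[, 4] <= cand[, 3]  # Deperp <= Depar
      keep <- which(ok)
      if (!length(keep)) next
      take <- keep[seq_len(min(length(keep), n - got))]
      theta[(got + 1):(got + length(take)), ] <- cand[take, , drop = FALSE]
      got <- got + length(take)
    }
    theta <- as.data.frame(theta)
    theta$p4 <- theta$p2 * stats::runif(n, prior$p4_ratio_range[1],
                                        prior$p4_ratio_range[2])
    list(theta = theta, axes = random_unit_vectors(n))
  })
}
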