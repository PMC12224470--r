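# ROI-level utilities: the outlier-exclusion rule applied before ROI
# averaging, and the exponential trend fit used for developmental
# trajectories.

#' Two-pass ROI outlier exclusion
#'
#' Stage 1 drops voxels whose value is outside the parameter's physical
#' bounds (fractions and ODF invariants: \[0,1\]; diffusivities:
#' \[0,3\] um^2/ms). Stage 2 computes the mean and standard deviation of the
#' survivors and drops values more than `n_sigma` standard deviations from
#' that mean — a single, non-iterated pass. The output is always a subset of
#' the input and stage 1's output contains no out-of-bounds value; the rule
#' is not guaranteed to be idempotent under re-application (the standard
#' deviation is recomputed).
#'
#' @param values numeric vector of voxelwise values for one ROI (>= 5).
#' @param param parameter name determining the physical bounds
#'   (`f`, `Da`, `Depar`, `Deperp`, `p2`, `p4`).
#' @param n_sigma the sigma multiple (default 2).
#' @return List: `values` (survivors), `n_unphysical`, `n_outlier`,
#'   `mean`, `sd` (of the survivors).
#' @examples
#' exclude_outliers(c(0.4, 0.5, 0.6, 0.45, 1.4), "f")$n_unphysical  # 1
#' @export
exclude_outliers <- function(values, param, n_sigma = 2) {
  if (length(values) < 5) stop("need at least 5 values")
  bd <- sm_param_bounds(param)
  phys <- values[is.finite(values) & values >= bd[1] & values <= bd[2]]
  n_unphys <- length(values) - length(phys)
  if (!length(phys)) stop("all values are unphysical for parameter ", param)
  m <- mean(phys); s <- stats::sd(phys)
  keep <- abs(phys - m) <= n_sigma * s
  out <- phys[keep]
  list(values = out, n_unphysical = n_unphys,
       n_outlier = sum(!keep), mean = mean(out), sd = stats::sd(out))
}

#' Exponential trend fit
#'
#' Fits `y = A * exp(-t / tau) + B` by Levenberg-Marquardt nonlinear least
#' squares with a multi-start over `tau` in {0.1, 0.5, 1, 2, 5} (years) and
#' both signs of the initial amplitude; the best converged fit is kept. The
#' reported time constant is `|tau|`, so growing and decaying trends of the
#' same pace yield the same value. 95 percent confidence intervals come from
#' the Jacobian-based covariance (t quantile with n - 3 degrees of freedom).
#'
#' @param t time points (years).
#' @param y observed values.
#' @return List of class `exp_fit`: `A`, `tau` (= |tau|), `B`, `ci` (3 x 2
#'   matrix of 95 percent CIs on A, tau, B), `converged`, `fit` (the
#'   underlying nls object or NULL).
#' @examples
#' t <- seq(0, 3, length.out = 20)
#' fit_exponential(t, 0.3 * exp(-t / 0.8) + 0.5)
#' @export
fit_exponential <- function(t, y) {
  if (length(t) < 4) stop("need at least 4 points")
  if (diff(range(t)) <= 0) stop("time points must have positive spread")
  fail <- structure(list(A = NA_real_, tau = NA_real_, B = NA_real_,
                         ci = matrix(NA_real_, 3, 2,
                                     dimnames = list(c("A", "tau", "B"),
                                                     c("lo", "hi"))),
                         converged = FALSE, fit = NULL), class = "exp_fit")
  rng <- diff(range(y))
  best <- NULL
  for (tau0 in c(0.1, 0.5, 1, 2, 5)) for (sgn in c(1, -1)) {
    A0 <- sgn * max(rng, 1e-8)
    fit <- try(minpack.lm::nlsLM(
      y ~ A * exp(-t / tau) + B,
      start = list(A = A0, tau = tau0, B = mean(y)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(fail)
  fit <- best$fit
  co <- stats::coef(fit)
  se <- try(sqrt(diag(stats::vcov(fit))), silent = TRUE)
  if (inherits(se, "try-error") || any(!is.finite(se))) return(fail)
  tq <- stats::qt(0.975, df = length(t) - 3)
  ci <- cbind(lo = co - tq * se, hi = co + tq * se)
  # report |tau|; mirror its CI if tau came out negative
  tau_ci <- sort(abs(ci["tau", ]))
  ci["tau", ] <- tau_ci
  structure(list(A = unname(co["A"]), tau = unname(abs(co["tau"])),
                 B = unname(co["B"]),
                 ci = ci[c("A", "tau", "B"), , drop = FALSE],
                 converged = TRUE, fit = fit),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (!x$converged) { cat("exponential fit: did not converge\n"); return(invisible(x)) }
  cat(sprintf("y = A exp(-t/tau) + B: A = %.4g, |tau| = %.4g, B = %.4g\n",
              x$A, x$tau, x$B))
  cat(sprintf("95%% CI tau: [%.4g, %.4g]\n", x$ci["tau", 1], x$ci["tau", 2]))
  invisible(x)
}
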