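#' Generate the benchmark test set
#'
#' Ground-truth Standard Model parameters `(f, Da, Depar, Deperp, p2)` are
#' drawn uniformly from the box `[lo, hi]` (defaults focus on the most
#' probable white-matter range), `p4 = rho * p2` with `rho ~ U(0.75, 0.85)`,
#' and each voxel receives a zonal ODF with exactly those invariants at a
#' uniformly random orientation. Signals are synthesized on the protocol
#' (SH orders 0-4) and Gaussian noise at the stated SNR is added once; all
#' estimators then see the same noisy realization, so SSM differences across
#' estimators are not noise-realization artifacts. With the default box
#' `Depar >= 1.5 > 1 >= Deperp`, so the `Depar >= Deperp` constraint never
#' rejects.
#'
#' @param n number of voxels (benchmark default 10000).
#' @param lo,hi named bounds for `(f, Da, Depar, Deperp, p2)`.
#' @param snr Gaussian noise level relative to b = 0 (Inf for noise-free).
#' @param protocol an [sm_protocol()]; default the canonical two-shell
#'   protocol.
#' @param seed integer seed (controls draws, orientations and noise).
#' @return A list of class `sm_test_set`: `theta` (truth data.frame incl.
#'   `p4`), `axes`, `signals` (noisy, volumes x voxels), `clean` (noise-free),
#'   `protocol`, `snr`, `seed`.
#' @export
make_test_set <- function(n = 10000,
                          lo = c(f = 0.3, Da = 1.5, Depar = 1.5,
                                 Deperp = 0.4, p2 = 0.3),
                          hi = c(f = 0.8, Da = 2.5, Depar = 2.5,
                                 Deperp = 1, p2 = 0.8),
                          snr = 25, protocol = NULL, seed = 1) {
  if (any(lo >= hi)) stop("need lo < hi elementwise")
  if (is.null(protocol)) protocol <- default_protocol(seed = 1)
  with_seed(seed, {
    theta <- as.data.frame(sapply(SM_PARAMS[1:5], function(p)
      stats::runif(n, lo[[p]], hi[[p]])))
    bad <- theta$Deperp > theta$Depar
    while (any(bad)) {  # cannot trigger for the default box
      k <- sum(bad)
      theta$Depar[bad] <- stats::runif(k, lo[["Depar"]], hi[["Depar"]])
      theta$Deperp[bad] <- stats::runif(k, lo[["Deperp"]], hi[["Deperp"]])
      bad <- theta$Deperp > theta$Depar
    }
    theta$p4 <- theta$p2 * stats::runif(n, 0.75, 0.85)
    axes <- random_unit_vectors(n)
    clean <- synthesize_zonal_many(theta, cbind(p2 = theta$p2, p4 = theta$p4),
                                   axes, protocol)
    signals <- if (is.finite(snr)) add_noise(clean, snr = snr) else clean
    structure(list(theta = theta, axes = axes, signals = signals,
                   clean = clean, protocol = protocol, snr = snr,
                   seed = seed, lo = lo, hi = hi),
              class = "sm_test_set")
  })
}

#' @export
print.sm_test_set <- function(x, ...) {
  cat("SM benchmark test set:", nrow(x$theta), "voxels, SNR", x$snr,
      "\nparameter box:\n")
  print(rbind(lo = x$lo, hi = x$hi))
  invisible(x)
}

#' Pack a test set into a synthetic 4D phantom
#'
#' Arranges the test-set signals into a 4D volume so that the voxelwise
#' command-line pipeline can be exercised end to end. Unused voxels hold zero
#' signal (background). The voxel-to-truth-row lookup is returned and can be
#' written as a sidecar table.
#'
#' @param test_set an [make_test_set()] result.
#' @param shape length-3 grid dimensions; must hold at least `n` voxels.
#'   Default: the smallest near-cubic grid that fits.
#' @return A list with `stack` (a `volume_stack`), `lookup` (data.frame
#'   voxel linear index -> truth row) and the test set's protocol.
#' @export
synthesize_phantom <- function(test_set, shape = NULL) {
  n <- nrow(test_set$theta)
  if (is.null(shape)) {
    s <- ceiling(n^(1 / 3))
    shape <- c(s, s, ceiling(n / s^2))
  }
  if (prod(shape) < n)
    stop("shape holds ", prod(shape), " voxels but the test set has ", n)
  nvol <- nrow(test_set$signals)
  arr <- array(0, c(shape, nvol))
  flat <- matrix(0, prod(shape), nvol)
  flat[seq_len(n), ] <- t(test_set$signals)
  arr <- array(flat, c(shape, nvol))
  list(stack = volume_stack(arr),
       lookup = data.frame(voxel = seq_len(n), row = seq_len(n)),
       protocol = test_set$protocol)
}
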