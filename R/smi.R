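# SMI: the learned Standard Model estimator. A third-order polynomial
# regression maps the six normalized rotational invariants {S0,S2,S4} x
# {two shells} to each SM parameter; it is trained on signals synthesized
# from prior-sampled parameter sets with the benchmark noise model.

# All monomials of total degree <= degree over the columns of X (including
# the constant). For 6 features at degree 3 this gives choose(9,3) = 84 terms.
poly_features <- function(X, degree = 3) {
  X <- as.matrix(X)
  p <- ncol(X)
  combos <- list(integer(0))                       # constant term
  for (d in seq_len(degree))
    combos <- c(combos, utils::combn(p + d - 1, d, simplify = FALSE) |>
                  lapply(function(cc) cc - seq_len(d) + 1L))
  # each combo is a multiset of column indices (non-decreasing)
  out <- matrix(1, nrow(X), length(combos))
  for (j in seq_along(combos)) {
    for (col in combos[[j]]) out[, j] <- out[, j] * X[, col]
  }
  colnames(out) <- vapply(combos, function(cc)
    if (!length(cc)) "1" else paste(colnames(X)[cc], collapse = "*"),
    character(1))
  out
}

#' Synthesize a training set for the learned estimator
#'
#' For each prior draw: synthesize noise-free zonal-ODF signals on the
#' protocol, add Gaussian noise at the stated SNR, fit spherical harmonics
#' per shell and compute the rotational invariants normalized by the noisy
#' b = 0 mean. Features are the six values `{S0,S2,S4} x {nonzero shells}`.
#'
#' @param prior an [sm_prior()].
#' @param protocol an [sm_protocol()] with two nonzero shells.
#' @param snr training SNR (Gaussian noise relative to b = 0); use a very
#'   large value (e.g. 1e12) for effectively noise-free features.
#' @param n number of training voxels.
#' @param seed integer seed.
#' @return List with `features` (n x 6), `targets` (n x 6 data.frame) and
#'   the generating metadata.
#' @export
build_training_set <- function(prior, protocol, snr = 25, n = 1e5, seed = 1) {
  nz <- protocol_nonzero_shells(protocol)
  if (length(nz$b) < 2)
    stop("training requires a protocol with at least two nonzero shells")
  draw <- sample_prior(prior, n, seed = seed)
  th <- draw$theta
  clean <- synthesize_zonal_many(th, cbind(p2 = th$p2, p4 = th$p4),
                                 draw$axes, protocol)
  noisy <- with_seed(seed + 104729L,
                     add_noise(clean, snr = snr, model = "gaussian"))
  features <- signal_features(noisy, protocol)
  list(features = features, targets = th, prior = prior, snr = snr,
       n = n, seed = seed, protocol_sig = protocol_signature(protocol))
}

#' Train the SMI polynomial-regression estimator
#'
#' Fits one ordinary-least-squares regression per SM parameter, mapping all
#' monomials of total degree <= 3 of the six normalized invariants to the
#' parameter. A tiny ridge term (1e-8) is used only if the design is
#' numerically singular.
#'
#' @param prior an [sm_prior()] (ignored when `training` is given).
#' @param protocol an [sm_protocol()].
#' @param snr training SNR; the fitted model stores it so mismatched use is
#'   detectable.
#' @param n training-set size (default 1e5; must be at least 10x the number
#'   of polynomial terms).
#' @param degree polynomial order (default 3).
#' @param seed integer seed.
#' @param training optionally a precomputed [build_training_set()] result.
#' @return An object of class `smi`: coefficient matrix (`terms x targets`),
#'   training metadata, and residual summary. Methods: `print`, `summary`,
#'   `coef`, `predict`.
#' @examples
#' \donttest{
#' proto <- default_protocol(seed = 1)
#' model <- smi_train(sm_prior(), proto, snr = 25, n = 2e4, seed = 7)
#' model
#' }
#' @export
smi_train <- function(prior = sm_prior(), protocol, snr = 25, n = 1e5,
                      degree = 3, seed = 1, training = NULL) {
  if (is.null(training))
    training <- build_training_set(prior, protocol, snr = snr, n = n,
                                   seed = seed)
  X <- poly_features(training$features, degree)
  if (nrow(X) < 10 * ncol(X))
    stop("training set too small: need at least ", 10 * ncol(X),
         " draws for ", ncol(X), " polynomial terms")
  Y <- as.matrix(training$targets[SM_PARAMS])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    # ridge fallback for a numerically singular design
    beta <- solve(crossprod(X) + 1e-8 * diag(ncol(X)), crossprod(X, Y))
  } else {
    beta <- qr.coef(qrX, Y)
  }
  resid <- Y - X %*% beta
  structure(list(coefficients = beta, degree = degree,
                 feature_names = colnames(training$features),
                 prior = training$prior, snr = training$snr,
                 n = nrow(X), seed = training$seed,
                 protocol_sig = training$protocol_sig,
                 train_rmse = sqrt(colMeans(resid^2))),
            class = "smi")
}

#' @export
print.smi <- function(x, ...) {
  cat("SMI estimator: degree-", x$degree, " polynomial regression on ",
      length(x$feature_names), " rotational-invariant features\n", sep = "")
  cat("trained on n =", x$n, "prior draws at SNR", x$snr, "\n")
  cat("training RMSE:\n")
  print(signif(x$train_rmse, 3))
  invisible(x)
}

#' @export
coef.smi <- function(object, ...) object$coefficients

#' @export
summary.smi <- function(object, ...) {
  cat("Standard Model Imaging (SMI) estimator\n")
  print(object)
  cat("prior:\n")
  print(object$prior)
  invisible(object)
}

#' Apply a trained SMI model
#'
#' Evaluates the fitted polynomial on invariant features and clips each
#' estimate to its physical bounds (clip events are counted). Accepts either
#' a feature matrix (columns as produced by [signal_features()]) or raw
#' signals plus a protocol; the protocol fingerprint must match the one the
#' model was trained under.
#'
#' @param object a fitted `smi` model.
#' @param features voxels x 6 invariant features.
#' @param signals alternatively, a (volumes x voxels) signal matrix.
#' @param protocol the acquisition protocol for `signals`.
#' @param ... unused.
#' @return An [sm_estimates] object with all six SM parameters.
#' @export
predict.smi <- function(object, features = NULL, signals = NULL,
                        protocol = NULL, ...) {
  if (is.null(features)) {
    if (is.null(signals) || is.null(protocol))
      stop("supply either features or signals + protocol")
    if (protocol_signature(protocol) != object$protocol_sig)
      stop("protocol does not match the one this SMI model was trained on")
    features <- signal_features(signals, protocol)
  }
  X <- poly_features(features, object$degree)
  est <- X %*% object$coefficients
  clipped <- 0L
  for (p in colnames(est)) {
    bd <- sm_param_bounds(p)
    out <- est[, p] < bd[1] | est[, p] > bd[2]
    clipped <- clipped + sum(out)
    est[, p] <- pmin(bd[2], pmax(bd[1], est[, p]))
  }
  sm_estimates(as.data.frame(est), estimator = "smi",
               diagnostics = list(n_clipped = clipped))
}

#' Fit voxels with a trained SMI model
#'
#' Convenience wrapper equivalent to
#' `predict(model, signals = signals, protocol = protocol)`.
#'
#' @param signals (volumes x voxels) matrix or vector.
#' @param protocol an [sm_protocol()].
#' @param model a fitted `smi`.
#' @return An [sm_estimates] object.
#' @export
fit_smi <- function(signals, protocol, model) {
  predict(model, signals = signals, protocol = protocol)
}

#' Estimator output container
#'
#' Holds per-voxel estimates for the subset of SM parameters an estimator
#' actually estimates; constrained parameters are left out. Voxels where the
#' fit failed are flagged and excluded from downstream benchmarking.
#'
#' @param estimates data.frame of per-voxel estimates (columns a subset of
#'   `f, Da, Depar, Deperp, p2, p4`).
#' @param estimator estimator name.
#' @param flags logical vector marking failed voxels.
#' @param diagnostics free-form list (residuals, convergence, clip counts).
#' @return A list of class `sm_estimates`.
#' @export
sm_estimates <- function(estimates, estimator, flags = NULL,
                         diagnostics = list()) {
  estimates <- as.data.frame(estimates)
  unknown <- setdiff(names(estimates), SM_PARAMS)
  if (length(unknown)) stop("unknown parameter column(s): ",
                            paste(unknown, collapse = ", "))
  if (is.null(flags)) flags <- rep(FALSE, nrow(estimates))
  structure(list(estimates = estimates, estimator = estimator,
                 flags = flags, diagnostics = diagnostics),
            class = "sm_estimates")
}

#' @export
print.sm_estimates <- function(x, ...) {
  cat(sprintf("%s estimates: %d voxel(s), parameters {%s}, %d flagged\n",
              x$estimator, nrow(x$estimates),
              paste(names(x$estimates), collapse = ", "), sum(x$flags)))
  print(utils::head(x$estimates, 4))
  if (nrow(x$estimates) > 4) cat("...\n")
  invisible(x)
}
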