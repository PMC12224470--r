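#' Sensitivity-Specificity Matrix
#'
#' Quantifies how an estimator's output `theta_hat_j` responds to changes in
#' every ground-truth parameter `theta_i` over a test set:
#' `S_ij = <theta_i>/<theta_hat_j> * d theta_hat_j / d theta_i`, evaluated as
#' the slope of an ordinary least-squares regression (with intercept) of each
#' estimated parameter on all ground-truth parameters. Rows are normalized by
#' the ground-truth means, columns by the mean of the estimates over the same
#' voxels, which makes off-diagonal entries dimensionless and insensitive to
#' a multiplicative bias of the estimator. An ideal estimator gives the
#' identity (the two normalizations coincide there); nonzero
#' off-diagonals are spurious cross-parameter correlations. Rows are the five
#' ground truths `(f, Da, Depar, Deperp, p2)`; columns are only the
#' parameters the estimator reports, so the matrix is generally not square.
#' `p4` is excluded from the rows (it is nearly collinear with `p2` by
#' construction, ratio in \[0.75, 0.85\]); an estimated `p4` column is still
#' reported.
#'
#' Flagged voxels and rows with non-finite estimates are dropped listwise
#' before the regression (counts kept in the result).
#'
#' @param truth data.frame of ground-truth parameters (needs
#'   `f, Da, Depar, Deperp, p2`), e.g. `test_set$theta`.
#' @param estimates an [sm_estimates] (or plain data.frame of estimates).
#' @return An object of class `ssm`: `S` (5 x n_estimated matrix),
#'   `estimator`, `n_used`, `n_dropped`.
#' @examples
#' ts <- make_test_set(n = 500, snr = Inf, seed = 2)
#' oracle <- sm_estimates(ts$theta[c("f", "Da", "Depar", "Deperp", "p2")],
#'                        estimator = "oracle")
#' compute_ssm(ts$theta, oracle)  # identity
#' @export
compute_ssm <- function(truth, estimates) {
  est_name <- "estimates"
  flags <- NULL
  if (inherits(estimates, "sm_estimates")) {
    est_name <- estimates$estimator
    flags <- estimates$flags
    estimates <- estimates$estimates
  }
  estimates <- as.data.frame(estimates)
  rows_truth <- SM_PARAMS[1:5]
  truth <- as.data.frame(truth)[rows_truth]
  if (nrow(truth) != nrow(estimates))
    stop("truth and estimates differ in voxel count")
  keep <- stats::complete.cases(estimates) &
    apply(as.matrix(estimates), 1, function(r) all(is.finite(r)))
  if (!is.null(flags)) keep <- keep & !flags
  if (sum(keep) < 100)
    stop("fewer than 100 valid voxels after dropping flagged ones")
  X <- cbind(1, as.matrix(truth[keep, ]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("collinear ground-truth parameters; cannot evaluate the SSM")
  B <- qr.coef(qrX, as.matrix(estimates[keep, , drop = FALSE]))
  mi <- colMeans(truth[keep, ])
  S <- B[-1, , drop = FALSE] * mi
  cols <- colnames(estimates)
  mj <- colMeans(estimates[keep, , drop = FALSE])
  mj[abs(mj) < 1e-12] <- 1  # constant-zero column: slopes are 0 anyway
  S <- sweep(S, 2, mj, "/")
  dimnames(S) <- list(rows_truth, cols)
  structure(list(S = S, estimator = est_name, n_used = sum(keep),
                 n_dropped = sum(!keep), truth_means = mi),
            class = "ssm")
}

#' @export
print.ssm <- function(x, digits = 2, ...) {
  cat("Sensitivity-Specificity Matrix -", x$estimator, "\n")
  cat("(rows: ground truth; columns: estimated;",
      x$n_used, "voxels used,", x$n_dropped, "dropped)\n")
  print(round(x$S, digits))
  invisible(x)
}

#' Heatmap of a Sensitivity-Specificity Matrix
#'
#' Base-graphics color map of the SSM with the values printed in each cell;
#' diagonal-style entries (matching row/column parameter) are outlined.
#'
#' @param x an `ssm`.
#' @param ... passed to [graphics::image()].
#' @export
plot.ssm <- function(x, ...) {
  S <- x$S
  nr <- nrow(S); nc <- ncol(S)
  pal <- grDevices::colorRampPalette(c("#2166ac", "white", "#b2182b"))(101)
  zlim <- max(1, max(abs(S)))
  graphics::image(seq_len(nc), seq_len(nr), t(S[nr:1, , drop = FALSE]),
                  col = pal, zlim = c(-zlim, zlim), axes = FALSE,
                  xlab = "estimated", ylab = "ground truth",
                  main = paste("SSM -", x$estimator), ...)
  graphics::axis(1, seq_len(nc), colnames(S))
  graphics::axis(2, seq_len(nr), rev(rownames(S)), las = 1)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    graphics::text(j, nr - i + 1, sprintf("%.2f", S[i, j]),
                   font = if (rownames(S)[i] == colnames(S)[j]) 2 else 1)
  }
  invisible(x)
}

#' Prior-impact matrix for the learned estimator
#'
#' Quantifies how the learned estimator's outputs move when the training
#' prior's mean is perturbed:
#' `P_ij = <theta_i>/<theta_j> * d <theta_hat_j> / d mu_i`, where `mu_i` is
#' the prior mean of parameter i. For each swept parameter the estimator is
#' retrained at each grid point (only `mu_i` perturbed, variances fixed),
#' applied to the same fixed test set, and the mean estimate regressed on
#' `mu_i`. The canonical sweep is 90 to 110 percent of the reference mean in
#' 2.5 percent steps (9 points).
#'
#' @param reference an [sm_prior()].
#' @param protocol an [sm_protocol()].
#' @param test_set an [make_test_set()] result (fixed across the sweep).
#' @param snr training SNR.
#' @param n_train training-set size per retraining.
#' @param seed integer seed (each retraining derives its own sub-seed).
#' @param sweep_params parameters to sweep (default all five).
#' @param grid relative grid for the prior mean.
#' @param estimator_factory optional function `(prior, protocol, snr, n,
#'   seed)` returning a fitted model usable with
#'   `predict(model, features = ...)`; defaults to [smi_train()]. Exposed so
#'   reference estimators (e.g. one that ignores the prior) can be swept.
#' @return An object of class `prior_impact`: `P` (swept x estimated matrix),
#'   `sweeps` (per swept parameter: grid of `mu_i` and mean estimates), and
#'   `r2` (per swept parameter, R^2 of the own-parameter mean-estimate vs
#'   `mu_i` linear fit).
#' @export
prior_impact_sweep <- function(reference = sm_prior(), protocol, test_set,
                               snr = 25, n_train = 5e4, seed = 1,
                               sweep_params = SM_PARAMS[1:5],
                               grid = seq(0.90, 1.10, by = 0.025),
                               estimator_factory = NULL) {
  if (is.null(estimator_factory))
    estimator_factory <- function(prior, protocol, snr, n, seed)
      smi_train(prior, protocol, snr = snr, n = n, seed = seed)
  features <- signal_features(test_set$signals, test_set$protocol)
  mi <- colMeans(test_set$theta[SM_PARAMS[1:5]])
  P <- matrix(NA_real_, length(sweep_params), 6,
              dimnames = list(sweep_params, SM_PARAMS))
  sweeps <- list(); r2 <- stats::setNames(numeric(length(sweep_params)),
                                          sweep_params)
  for (ip in seq_along(sweep_params)) {
    p <- sweep_params[ip]
    mus <- reference$mean[[p]] * grid
    means <- matrix(NA_real_, length(grid), 6,
                    dimnames = list(NULL, SM_PARAMS))
    for (g in seq_along(grid)) {
      m <- reference$mean
      m[p] <- mus[g]
      prior_g <- sm_prior(mean = m, variance = reference$variance,
                          p4_ratio_range = reference$p4_ratio_range)
      model <- estimator_factory(prior_g, protocol, snr, n_train,
                                 seed + 1000L * ip + g)
      est <- predict(model, features = features)
      means[g, ] <- colMeans(est$estimates[SM_PARAMS])
    }
    slopes <- apply(means, 2, function(y) {
      fit <- stats::lm.fit(cbind(1, mus), y)
      fit$coefficients[2]
    })
    # column normalization by the sweep-averaged mean estimate, matching the
    # estimate-mean convention of compute_ssm
    P[p, ] <- slopes * mi[[p]] / colMeans(means)
    own <- means[, p]
    r2[p] <- if (stats::sd(own) < 1e-14) NA_real_ else stats::cor(mus, own)^2
    sweeps[[p]] <- list(mu = mus, means = means)
  }
  structure(list(P = P, sweeps = sweeps, r2 = r2, grid = grid,
                 reference = reference, n_train = n_train, snr = snr),
            class = "prior_impact")
}

#' @export
print.prior_impact <- function(x, digits = 2, ...) {
  cat("Prior-impact matrix (rows: swept prior mean; columns: estimated)\n")
  print(round(x$P, digits))
  cat("R^2 of own-parameter mean estimate vs prior mean:\n")
  print(round(x$r2, 3))
  invisible(x)
}
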