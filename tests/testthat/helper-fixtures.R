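# Shared fixtures, built once per test run.

the <- new.env(parent = emptyenv())

test_protocol <- function() {
  if (is.null(the$protocol)) the$protocol <- default_protocol(seed = 1)
  the$protocol
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# The scaled-down benchmark shared by the acceptance tests: one noisy test
# set, all baseline estimators run on the same signals. Built lazily so only
# the files that need it pay for it.
acceptance_benchmark <- function() {
  if (is.null(the$bench)) {
    proto <- test_protocol()
    ts <- make_test_set(n = 2000, snr = 25, protocol = proto, seed = 11)
    est <- list(
      noddi = fit_noddi(ts$signals, proto),
      smt = fit_smt(ts$signals, proto),
      wmti = suppressWarnings(fit_wmti(ts$signals, proto)))
    the$bench <- list(
      test_set = ts,
      estimates = est,
      ssm = lapply(est, function(e) compute_ssm(ts$theta, e)))
  }
  the$bench
}

# Trained SMI model at reduced (but still prior-limited) training size.
acceptance_smi <- function() {
  if (is.null(the$smi))
    the$smi <- smi_train(sm_prior(), test_protocol(), snr = 25, n = 5e4,
                         seed = 7)
  the$smi
}
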