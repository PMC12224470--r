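# Sensitivity-Specificity Matrix and the prior-impact sweep.

test_that("the oracle estimator yields the identity SSM to 1e-12", {
  ts <- make_test_set(n = 600, snr = Inf, seed = 2)
  oracle <- sm_estimates(ts$theta[c("f", "Da", "Depar", "Deperp", "p2")],
                         estimator = "oracle")
  s <- compute_ssm(ts$theta, oracle)
  expect_equal(unname(s$S), diag(5), tolerance = 1e-12)
})

test_that("constant and constructed-linear estimators match closed-form SSM", {
  ts <- make_test_set(n = 800, snr = Inf, seed = 5)
  th <- ts$theta
  # constant column: all sensitivities vanish
  s0 <- compute_ssm(th, data.frame(f = rep(0.4, 800)))
  expect_equal(max(abs(s0$S)), 0, tolerance = 1e-12)
  # f-hat = 0.5 f + 0.1 Da: slopes known exactly, normalization
  # <theta_i>/<theta_hat_j>
  fhat <- 0.5 * th$f + 0.1 * th$Da
  s1 <- compute_ssm(th, data.frame(f = fhat))
  expect_equal(s1$S["f", "f"], 0.5 * mean(th$f) / mean(fhat),
               tolerance = 1e-10)
  expect_equal(s1$S["Da", "f"], 0.1 * mean(th$Da) / mean(fhat),
               tolerance = 1e-10)
  expect_equal(s1$S["p2", "f"], 0, tolerance = 1e-10)
})

test_that("SSM entries are invariant to row shuffling and drop flagged voxels", {
  ts <- make_test_set(n = 500, snr = Inf, seed = 7)
  th <- ts$theta
  est <- data.frame(f = 0.8 * th$f + 0.05 * th$p2)
  s1 <- compute_ssm(th, est)
  perm <- sample(500)
  s2 <- compute_ssm(th[perm, ], est[perm, , drop = FALSE])
  expect_equal(s1$S, s2$S, tolerance = 1e-12)
  # flagged voxels are excluded listwise: the result equals a manual subset
  flags <- rep(FALSE, 500); flags[1:50] <- TRUE
  wrecked <- est; wrecked$f[1:50] <- 99
  s3 <- compute_ssm(th, sm_estimates(wrecked, "x", flags = flags))
  s_ref <- compute_ssm(th[-(1:50), ], est[-(1:50), , drop = FALSE])
  expect_equal(s3$S, s_ref$S, tolerance = 1e-12)
  expect_equal(s3$n_dropped, 50)
})

test_that("test-set marginals are uniform and constraints never bind", {
  ts <- make_test_set(n = 4000, seed = 13)
  th <- ts$theta
  for (p in c("f", "Da", "Depar", "Deperp", "p2")) {
    ks <- suppressWarnings(
      ks.test(th[[p]], "punif", ts$lo[[p]], ts$hi[[p]]))
    expect_gt(ks$p.value, 0.01)
  }
  # interval arithmetic: Depar >= 1.5 > 1 >= Deperp, so the ordering
  # constraint cannot reject
  expect_true(all(th$Depar >= th$Deperp))
  expect_gte(min(th$Depar), 1.5)
  expect_lte(max(th$Deperp), 1)
  # fixed seed reproduces signals bit for bit
  ts2 <- make_test_set(n = 100, seed = 99)
  ts3 <- make_test_set(n = 100, seed = 99)
  expect_identical(ts2$signals, ts3$signals)
})

test_that("prior-impact sweep responds to reference stub estimators", {
  proto <- test_protocol()
  ts <- make_test_set(n = 300, snr = 25, protocol = proto, seed = 3)
  # an estimator that ignores the prior entirely: P = 0
  ignore_factory <- function(prior, protocol, snr, n, seed) {
    structure(list(), class = "stub_ignore")
  }
  assign("predict.stub_ignore",
         function(object, features, ...) {
           n <- nrow(features)
           sm_estimates(data.frame(f = rep(0.4, n), Da = 1.8, Depar = 1.9,
                                   Deperp = 0.6, p2 = 0.5, p4 = 0.4), "stub")
         }, envir = globalenv())
  withr::defer(rm("predict.stub_ignore", envir = globalenv()))
  sw0 <- prior_impact_sweep(sm_prior(), proto, ts, n_train = 100, seed = 1,
                            sweep_params = c("f", "Da"),
                            grid = c(0.9, 1, 1.1),
                            estimator_factory = ignore_factory)
  expect_equal(max(abs(sw0$P)), 0, tolerance = 1e-10)
  # an estimator that returns the prior mean verbatim: on-diagonal ~ 1
  mean_factory <- function(prior, protocol, snr, n, seed) {
    structure(list(prior = prior), class = "stub_mean")
  }
  assign("predict.stub_mean",
         function(object, features, ...) {
           n <- nrow(features)
           m <- object$prior$mean
           sm_estimates(data.frame(f = rep(m[["f"]], n), Da = m[["Da"]],
                                   Depar = m[["Depar"]], Deperp = m[["Deperp"]],
                                   p2 = m[["p2"]], p4 = 0.8 * m[["p2"]]),
                        "stub")
         }, envir = globalenv())
  withr::defer(rm("predict.stub_mean", envir = globalenv()))
  sw1 <- prior_impact_sweep(sm_prior(), proto, ts, n_train = 100, seed = 1,
                            sweep_params = c("f", "Da"),
                            grid = c(0.9, 1, 1.1),
                            estimator_factory = mean_factory)
  # diagonal: slope 1 times <theta_i>/<theta_hat_i>; with the test-set truth
  # means close to the prior means these land near 1
  expect_equal(sw1$P["f", "f"], mean(ts$theta$f) / mean(sm_prior()$mean[["f"]] *
                                                          c(0.9, 1, 1.1)),
               tolerance = 1e-10)
  expect_equal(sw1$P["f", "Da"], 0, tolerance = 1e-10)
})

test_that("benchmark orchestration reports the oracle as an identity", {
  ts <- make_test_set(n = 400, snr = Inf, seed = 21)
  outdir <- withr::local_tempdir()
  bm <- run_benchmark(list(estimators = "oracle"), outdir = outdir,
                      test_set = ts)
  expect_equal(unname(bm$ssm$oracle$S), diag(5), tolerance = 1e-12)
  expect_true(file.exists(file.path(outdir, "ssm_oracle.csv")))
  expect_true(file.exists(file.path(outdir, "report.json")))
  # same seeds -> byte-identical CSV
  outdir2 <- withr::local_tempdir()
  run_benchmark(list(estimators = "oracle"), outdir = outdir2, test_set = ts)
  expect_identical(readLines(file.path(outdir, "ssm_oracle.csv")),
                   readLines(file.path(outdir2, "ssm_oracle.csv")))
})
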