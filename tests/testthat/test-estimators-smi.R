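# Prior sampling, training-set construction and the SMI polynomial estimator.

test_that("prior sampling respects bounds, constraint and moments", {
  pr <- sm_prior()
  draw <- sample_prior(pr, 2e4, seed = 3)
  th <- draw$theta
  expect_true(all(th$f >= 0 & th$f <= 1))
  expect_true(all(th$p2 >= 0 & th$p2 <= 1))
  expect_true(all(th$Da >= 0 & th$Da <= 3))
  expect_true(all(th$Deperp <= th$Depar))
  expect_true(all(th$p4 / th$p2 >= 0.75 & th$p4 / th$p2 <= 0.85))
  # f is symmetric about 0.5 within [0,1]: truncation does not shift its mean
  expect_equal(mean(th$f), 0.5, tolerance = 0.01)
  # truncated-normal moment oracle for Da (one-dimensional truncation; the
  # Deperp <= Depar rejection involves neither f nor Da)
  a <- (0 - 2) / 1; b <- (3 - 2) / 1
  m_oracle <- 2 + (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_equal(mean(th$Da), m_oracle, tolerance = 0.02)
  # degenerate-variance limit collapses onto the mean
  tiny <- sm_prior(variance = rep(1e-12, 5))
  d2 <- sample_prior(tiny, 50, seed = 1)
  expect_equal(unname(colMeans(d2$theta[, 1:5])), unname(pr$mean),
               tolerance = 1e-5)
  expect_error(sm_prior(mean = c(1.5, 2, 2, 0.7, 0.45)), "bounds")
})

test_that("noise-free training features equal the factorized invariants", {
  proto <- test_protocol()
  tr <- build_training_set(sm_prior(), proto, snr = 1e12, n = 50, seed = 4)
  th <- tr$targets
  for (i in c(1, 25, 50)) {
    kp <- kernel_params(f = th$f[i], Da = th$Da[i], Depar = th$Depar[i],
                        Deperp = th$Deperp[i])
    pl <- c(1, th$p2[i], th$p4[i])
    k <- 0
    for (b in c(1, 2)) for (l in c(0, 2, 4)) {
      k <- k + 1
      expect_equal(tr$features[i, paste0("S", l, "_b", b)],
                   abs(pl[l / 2 + 1] * kernel_projection(kp, b, l)),
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("training is reproducible and features carry the expected signal", {
  proto <- test_protocol()
  tr1 <- build_training_set(sm_prior(), proto, snr = 25, n = 2000, seed = 12)
  tr2 <- build_training_set(sm_prior(), proto, snr = 25, n = 2000, seed = 12)
  expect_identical(tr1$features, tr2$features)
  # S4 at b = 2 is proportional to p4 through Eq-level factorization, so the
  # two must be positively correlated even under noise
  expect_gt(cor(tr1$features[, "S4_b2"], tr1$targets$p4), 0.2)
})

test_that("polynomial regression recovers nested polynomial targets exactly", {
  set.seed(6)
  X <- matrix(runif(6 * 2000), ncol = 6,
              dimnames = list(NULL, paste0("x", 1:6)))
  # an exact degree-2 polynomial of the features must be fit with ~0 residual
  y <- 0.3 + 0.5 * X[, 1] - 1.2 * X[, 2] * X[, 3] + 0.7 * X[, 4]^2
  targets <- data.frame(f = y, Da = y, Depar = y, Deperp = y,
                        p2 = y, p4 = y)
  tr <- list(features = X, targets = targets, prior = sm_prior(), snr = Inf,
             seed = 1, protocol_sig = "test")
  model <- smi_train(training = tr, protocol = NULL)
  expect_lt(max(model$train_rmse), 1e-8)
  # OLS is invariant under row permutation
  perm <- sample(nrow(X))
  tr2 <- tr
  tr2$features <- X[perm, ]; tr2$targets <- targets[perm, ]
  model2 <- smi_train(training = tr2, protocol = NULL)
  expect_equal(model$coefficients, model2$coefficients, tolerance = 1e-8)
})

test_that("SMI prediction is deterministic, bounded and protocol-checked", {
  proto <- test_protocol()
  model <- acceptance_smi()
  ts <- make_test_set(n = 300, snr = 25, protocol = proto, seed = 23)
  feat <- signal_features(ts$signals, proto)
  est1 <- predict(model, features = feat)
  est2 <- predict(model, features = feat[c(1:300, 1:300), ])
  # duplicated rows give identical outputs
  expect_equal(est2$estimates[1:300, ], est2$estimates[301:600, ],
               ignore_attr = TRUE)
  expect_equal(est1$estimates, est2$estimates[1:300, ], ignore_attr = TRUE)
  # outputs respect physical bounds
  expect_true(all(est1$estimates$f >= 0 & est1$estimates$f <= 1))
  expect_true(all(est1$estimates$Da >= 0 & est1$estimates$Da <= 3))
  # mismatched protocol is refused
  other <- default_protocol(seed = 99)
  expect_error(predict(model, signals = ts$signals, protocol = other),
               "protocol")
})

test_that("near the prior mode SMI reproduces the generating parameters", {
  proto <- test_protocol()
  model <- acceptance_smi()
  pm <- sm_prior()$mean
  kp <- kernel_params(f = pm[["f"]], Da = pm[["Da"]], Depar = pm[["Depar"]],
                      Deperp = pm[["Deperp"]])
  odf <- zonal_odf(pm[["p2"]], 0.8 * pm[["p2"]], axis = c(0, 0, 1))
  sig <- synthesize_signals(kp, odf, proto)
  est <- predict(model, signals = matrix(sig, ncol = 1), protocol = proto)
  expect_lt(abs(est$estimates$f - pm[["f"]]), 0.05)
  expect_lt(abs(est$estimates$p2 - pm[["p2"]]), 0.05)
  for (p in c("Da", "Depar", "Deperp"))
    expect_lt(abs(est$estimates[[p]] - pm[[p]]), 0.2)
})
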