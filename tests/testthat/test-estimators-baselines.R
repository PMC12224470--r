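# Constrained baseline estimators: self-consistency on data generated under
# each estimator's own constraints, plus their known limiting behaviors.

test_that("NODDI recovers its own generating parameters noise-free", {
  proto <- test_protocol()
  set.seed(14)
  for (i in 1:3) {
    f <- runif(1, 0.35, 0.75); kappa <- runif(1, 1, 8)
    axis <- smikit:::random_unit_vectors(1)[1, ]
    kp <- kernel_params(f = f, Da = 1.7, Depar = 1.7, Deperp = 1.7 * (1 - f))
    odf <- smikit:::watson_odf(kappa, axis = axis, lmax = 8)
    sig <- synthesize_signals(kp, odf, proto)
    est <- fit_noddi(sig, proto)
    expect_equal(est$estimates$f, f, tolerance = 1e-3)
    expect_equal(est$estimates$p2, unname(watson_invariants(kappa)["p2"]),
                 tolerance = 1e-3)
  }
})

test_that("NODDI reports ~zero anisotropy for isotropic signals", {
  proto <- test_protocol()
  kp <- kernel_params(f = 0.5, Da = 1.7, Depar = 1.7, Deperp = 0.85)
  sig <- synthesize_signals(kp, zonal_odf(0, 0), proto)  # kappa = 0 generator
  est <- fit_noddi(sig, proto)
  expect_lt(est$estimates$p2, 0.02)
})

test_that("SMT is exactly self-consistent and handles the Delta -> 0 branch", {
  proto <- test_protocol()
  # noise-free means generated under SMT's own constraints
  kp <- kernel_params(f = 0.5, Da = 2, Depar = 2, Deperp = 1)
  odf <- zonal_odf(0.6, 0.48, axis = c(0.3, 0.4, sqrt(0.75)))
  est <- fit_smt(synthesize_signals(kp, odf, proto), proto)
  expect_equal(est$estimates$f, 0.5, tolerance = 1e-6)
  expect_equal(est$estimates$Da, 2, tolerance = 1e-6)
  expect_equal(est$estimates$Deperp, 1, tolerance = 1e-6)
  # series branch agrees with the closed form at Delta = 1e-6
  h <- smikit:::zeppelin_mean(1, 1 + 1e-6, 1)
  closed <- exp(-1) * sqrt(pi / (4 * 1e-6)) * pracma::erf(sqrt(1e-6))
  expect_equal(h, closed, tolerance = 1e-9)
  # f = 0 generator: D-hat matches the generator diffusivity, f-hat ~ 0
  iso <- kernel_params(f = 0, Da = 1.4, Depar = 1.4, Deperp = 1.4)
  est0 <- fit_smt(synthesize_signals(iso, zonal_odf(0.3, 0.24), proto), proto)
  expect_equal(est0$estimates$Da, 1.4, tolerance = 1e-3)
  expect_lt(est0$estimates$f, 1e-3)
  expect_true(est0$flags)  # f pinned at its bound is flagged
})

test_that("DKI fit nulls the kurtosis of Gaussian signals and matches FA", {
  proto <- test_protocol()
  dt <- c(0.7, 0.7, 2, 0, 0, 0)    # axially symmetric tensor along z
  sig <- exp(-proto$bvals * (smikit:::design_d2(proto$dirs) %*% dt))
  fit <- dki_fit(matrix(sig, ncol = 1), proto)
  expect_lt(max(abs(fit$vt)), 1e-6)
  expect_equal(as.vector(fit$dt), dt, tolerance = 1e-8)
  # FA closed form for eigenvalues (2, 0.7, 0.7):
  # sqrt(3/2 * sum((l - lbar)^2) / sum(l^2)) = 0.582544
  lam <- c(2, 0.7, 0.7)
  fa_closed <- sqrt(1.5 * sum((lam - mean(lam))^2) / sum(lam^2))
  expect_equal(fa_from_tensor(fit), fa_closed, tolerance = 1e-8)
  expect_equal(fa_closed, 0.5825439, tolerance = 1e-6)
})

test_that("isotropic two-compartment mixture has kurtosis 3 Var/Mean^2", {
  # use a low-b protocol so the quadratic signal representation is accurate
  proto <- default_protocol(b1 = 0.15, b2 = 0.3, seed = 1)
  sig <- 0.5 * exp(-proto$bvals * 1) + 0.5 * exp(-proto$bvals * 2)
  fit <- dki_fit(matrix(sig, ncol = 1), proto)
  # closed form: 3 * Var(D) / Mean(D)^2 = 3 * 0.25 / 1.5^2 = 1/3
  expect_equal(mean_kurtosis(fit), 1 / 3, tolerance = 0.01)
})

test_that("WMTI recovers aligned fibers and vanishes as f -> 0", {
  proto <- test_protocol()
  kp <- kernel_params(f = 0.5, Da = 2.0, Depar = 2.2, Deperp = 0.6)
  u <- c(0, 0, 1)
  sig <- kernel_signal(kp, proto$bvals, abs(as.vector(proto$dirs %*% u)))
  est <- fit_wmti(matrix(sig, ncol = 1), proto)
  # WMTI's own validity regime: perfectly aligned fibers, noise-free
  expect_equal(est$estimates$f, 0.5, tolerance = 0.05)
  expect_equal(est$estimates$Da, 2.0, tolerance = 0.25)
  expect_equal(est$estimates$Depar, 2.2, tolerance = 0.25)
  expect_equal(est$estimates$Deperp, 0.6, tolerance = 0.1)
  # f -> 0: directional kurtosis -> 0 and f-hat -> 0
  kp0 <- kernel_params(f = 1e-4, Da = 2, Depar = 2.2, Deperp = 0.6)
  sig0 <- kernel_signal(kp0, proto$bvals, abs(as.vector(proto$dirs %*% u)))
  fit0 <- dki_fit(matrix(sig0, ncol = 1), proto)
  expect_lt(max(smikit:::directional_kurtosis(fit0, smikit:::wmti_grid())),
            0.01)
  est0 <- fit_wmti(fit0)
  expect_lt(est0$estimates$f, 0.02)
})

test_that("W-WMTI keeps its branch ordering and matches WMTI's f when aligned", {
  proto <- test_protocol()
  kp <- kernel_params(f = 0.5, Da = 2.4, Depar = 1.8, Deperp = 0.8)
  u <- c(0.3, -0.2, sqrt(1 - 0.09 - 0.04))
  sig <- kernel_signal(kp, proto$bvals, abs(as.vector(proto$dirs %*% u)))
  eww <- fit_wwmti(matrix(sig, ncol = 1), proto)
  ew <- fit_wmti(matrix(sig, ncol = 1), proto)
  expect_gte(eww$estimates$Da, eww$estimates$Depar)   # opposite branch
  expect_equal(eww$estimates$f, ew$estimates$f, tolerance = 1e-10)
})

test_that("estimators only report the parameters they estimate", {
  proto <- test_protocol()
  ts <- make_test_set(n = 5, snr = Inf, protocol = proto, seed = 2)
  expect_named(fit_smt(ts$signals, proto)$estimates,
               c("f", "Da", "Deperp"))
  expect_named(suppressWarnings(fit_wmti(ts$signals, proto))$estimates,
               c("f", "Da", "Depar", "Deperp"))
  est_n <- fit_noddi(ts$signals[, 1:2], proto)
  expect_named(est_n$estimates, c("f", "p2"))
})
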