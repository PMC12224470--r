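# Fascicle kernel, Legendre projections, signal synthesis and noise.

test_that("kernel signal matches closed-form special cases", {
  kp <- kernel_params(f = 0.5, Da = 2, Depar = 2, Deperp = 0.7, s0 = 1.3)
  # b = 0: all exponentials are 1
  expect_equal(kernel_signal(kp, 0, 0.37), 1.3)
  # isotropic collapse: f = 0, Depar = Deperp = D -> s0 exp(-bD), xi-free
  iso <- kernel_params(f = 0, Da = 1, Depar = 1.4, Deperp = 1.4)
  expect_equal(kernel_signal(iso, 1.5, c(0, 0.3, 1)),
               rep(exp(-1.5 * 1.4), 3))
  # direct scalar evaluation
  expect_equal(kernel_signal(kernel_params(0.5, 2, 2, 0.7), 1, 1), exp(-2))
  # parameter validation
  expect_error(kernel_params(f = 1.2, Da = 2, Depar = 2, Deperp = 0.7), "f must")
  expect_error(kernel_params(f = 0.5, Da = 2, Depar = 1, Deperp = 2), "Deperp")
  expect_error(kernel_params(f = 0.5, Da = 4, Depar = 2, Deperp = 1),
               "diffusivities")
})

test_that("Legendre projections match quadrature-independent references", {
  kp <- kernel_params(f = 0.5, Da = 2, Depar = 2, Deperp = 0.7)
  expect_equal(kernel_projection(kp, 0, 0), 1)          # K0(0) = s0
  expect_equal(kernel_projection(kp, 0, 2), 0, tolerance = 1e-12)
  expect_error(kernel_projection(kp, 1, 3), "even")
  # pure stick closed form: K0(b) = sqrt(pi/(4 b Da)) erf(sqrt(b Da))
  stick <- kernel_params(f = 1, Da = 2, Depar = 2, Deperp = 0)
  expect_equal(kernel_projection(stick, 1, 0),
               sqrt(pi / 8) * pracma::erf(sqrt(2)), tolerance = 1e-12)
  # adaptive-quadrature oracle for l = 2 on a generic kernel
  oracle <- stats::integrate(function(xi)
    kernel_signal(kp, 2, xi) * (3 * xi^2 - 1) / 2, 0, 1, rel.tol = 1e-12)$value
  expect_equal(kernel_projection(kp, 2, 2), oracle, tolerance = 1e-10)
  # quadrature convergence: doubling the order changes nothing material
  expect_equal(kernel_projection(kp, 2, 4, order = 64),
               kernel_projection(kp, 2, 4, order = 128), tolerance = 1e-10)
  # monotonicity: the spherical-mean kernel strictly decreases in b
  k0 <- kernel_projection(kp, seq(0, 3, by = 0.25), 0)
  expect_true(all(diff(k0) < 0))
})

test_that("synthesized signals match a brute-force spherical convolution", {
  proto <- test_protocol()
  kp <- kernel_params(f = 0.55, Da = 2.2, Depar = 1.9, Deperp = 0.6)
  odf <- zonal_odf(0.6, 0.45, axis = c(0, 0, 1))
  syn <- synthesize_signals(kp, odf, proto)
  expect_equal(syn[smikit:::protocol_b0_idx(proto)], rep(1, 4))
  # direct numerical convolution on a dense equal-area sphere grid
  grid <- smikit:::fibonacci_directions(20000, rotate = FALSE)
  dens <- 1 + 5 * 0.6 * (3 * grid[, 3]^2 - 1) / 2 +
    9 * 0.45 * ((35 * grid[, 3]^2 - 30) * grid[, 3]^2 + 3) / 8
  for (v in c(10, 30, 60)) {
    direct <- mean(dens * kernel_signal(kp, proto$bvals[v],
                                        abs(grid %*% proto$dirs[v, ])))
    expect_equal(syn[v], direct, tolerance = 1e-4)
  }
})

test_that("jointly rotating ODF and gradients leaves signals unchanged", {
  proto <- test_protocol()
  kp <- kernel_params(f = 0.4, Da = 2.1, Depar = 2.3, Deperp = 0.9)
  axis <- c(0.6, -0.48, sqrt(1 - 0.36 - 0.2304))
  set.seed(8)
  R <- random_rotation()
  s1 <- synthesize_signals(kp, zonal_odf(0.5, 0.4, axis = axis), proto)
  proto_rot <- sm_protocol(proto$bvals, proto$dirs %*% t(R))
  s2 <- synthesize_signals(kp, zonal_odf(0.5, 0.4, axis = as.vector(R %*% axis)),
                           proto_rot)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("isotropic-ODF signals reduce to the exponential spherical mean", {
  proto <- test_protocol()
  iso <- kernel_params(f = 0, Da = 1, Depar = 1.1, Deperp = 1.1)
  sig <- synthesize_signals(iso, zonal_odf(0, 0), proto)
  for (b in c(1, 2)) {
    idx <- which(abs(proto$bvals - b) < 0.05)
    expect_equal(sig[idx], rep(exp(-b * 1.1), length(idx)), tolerance = 1e-12)
  }
})

test_that("noise injection has the stated scale and bias", {
  set.seed(21)
  x <- rep(1, 1e6)
  g <- add_noise(x, snr = 25)
  expect_equal(sd(g - x), 0.04, tolerance = 5e-3)       # sigma = s0/snr
  expect_equal(mean(g - x), 0, tolerance = 2e-4)
  # effectively infinite SNR leaves signals unchanged
  expect_equal(add_noise(x[1:100], snr = 1e12), x[1:100], tolerance = 1e-9)
  # Rician high-SNR mean bias ~ sigma^2 / (2 s)
  s <- rep(0.5, 1e6)
  r <- add_noise(s, snr = 25, model = "rician")
  # leading-order series bias sigma^2/(2s); slack covers the next series
  # term and the Monte-Carlo error of the mean
  expect_lt(abs(mean(r - s) - 0.04^2 / (2 * 0.5)), 1.5e-4)
  expect_error(add_noise(x, snr = 0), "positive")
})
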