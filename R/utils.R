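# Internal helpers shared across modules.

# Canonical parameter order used throughout: kernel parameters first, then ODF
# anisotropy invariants.
SM_PARAMS <- c("f", "Da", "Depar", "Deperp", "p2", "p4")

# Free-water diffusivity ceiling (um^2/ms); also the physical upper bound for
# all compartment diffusivities.
D0_FREE_WATER <- 3

# Physical bounds for a named SM parameter (fractions and ODF invariants live
# in [0,1], diffusivities in [0, D0]).
sm_param_bounds <- function(param) {
  if (param %in% c("f", "fiso", "p2", "p4")) c(0, 1)
  else if (param %in% c("Da", "Depar", "Deperp")) c(0, D0_FREE_WATER)
  else stop("unknown SM parameter: ", param)
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Legendre polynomial P_l(x), hard-coded for the even orders used here.
legendre_poly <- function(l, x) {
  x2 <- x * x
  switch(as.character(l),
    "0" = rep(1, length(x)) * (if (is.matrix(x)) 0 * x + 1 else 1),
    "2" = (3 * x2 - 1) / 2,
    "4" = ((35 * x2 - 30) * x2 + 3) / 8,
    "6" = (((231 * x2 - 315) * x2 + 105) * x2 - 5) / 16,
    "8" = ((((6435 * x2 - 12012) * x2 + 6930) * x2 - 1260) * x2 + 35) / 128,
    stop("legendre_poly implemented for even l <= 8, got l = ", l)
  )
}

# Cached Gauss-Legendre nodes/weights on [0,1] (order 64 is the package
# default; doubling the order changes kernel projections by < 1e-10).
.smikit_cache <- new.env(parent = emptyenv())

gauss_legendre_01 <- function(order = 64) {
  key <- paste0("gl", order)
  if (is.null(.smikit_cache[[key]])) {
    gl <- pracma::gaussLegendre(order, 0, 1)
    # pre-tabulate P_l at the nodes for the even orders we project onto
    pl <- sapply(c(0, 2, 4, 6, 8), function(l) legendre_poly(l, gl$x))
    colnames(pl) <- paste0("l", c(0, 2, 4, 6, 8))
    .smikit_cache[[key]] <- list(x = gl$x, w = gl$w, pl = pl)
  }
  .smikit_cache[[key]]
}

# Uniform random unit vectors (n x 3).
random_unit_vectors <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# Short deterministic fingerprint of a protocol, used to detect mismatched
# training/inference acquisitions without a hashing dependency.
protocol_signature <- function(protocol) {
  v <- c(round(protocol$bvals, 6), round(as.vector(protocol$dirs), 6))
  paste0("p", length(protocol$bvals), "-",
         format(sum(v * seq_along(v)) %% 1e9, scientific = FALSE, trim = TRUE))
}
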