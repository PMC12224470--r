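#' Acquisition protocol for multi-shell diffusion MRI
#'
#' A protocol pairs per-volume b-values (in ms/um^2) with unit gradient
#' directions and groups volumes into shells of nominally equal b. Internally
#' all b-values are in ms/um^2 and diffusivities in um^2/ms; conversion from
#' the s/mm^2 convention of FSL gradient tables happens only at the file
#' boundary (division by 1000). Directions are treated as axially symmetric
#' (g and -g equivalent) since only even-order spherical harmonics are used.
#'
#' @param bvals numeric vector of per-volume b-values (ms/um^2).
#' @param dirs numeric matrix (n x 3) of gradient directions; rows for b = 0
#'   volumes may be zero vectors, all others must have unit norm.
#' @param shell_tol b-value tolerance (ms/um^2) when grouping shells.
#' @return An object of class `sm_protocol` with fields `bvals`, `dirs`,
#'   `shells` (list mapping nominal b to volume indices), `shell_b`
#'   (nominal b per shell) and `shell_tol`.
#' @examples
#' p <- sm_protocol(c(0, 1, 2), rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' p$shells
#' @export
sm_protocol <- function(bvals, dirs, shell_tol = 0.1) {
  bvals <- as.numeric(bvals)
  dirs <- as.matrix(dirs)
  if (ncol(dirs) != 3) stop("dirs must be an n x 3 matrix")
  if (length(bvals) != nrow(dirs))
    stop("length mismatch: ", length(bvals), " b-values vs ",
         nrow(dirs), " directions")
  if (any(bvals < 0)) stop("negative b-values are not allowed")
  nrm <- sqrt(rowSums(dirs^2))
  b0 <- bvals <= shell_tol
  if (!any(b0)) stop("protocol has no b = 0 volume")
  bad <- !b0 & abs(nrm - 1) > 1e-6
  if (any(bad)) {
    if (any(nrm[bad] < 1e-12))
      stop("zero gradient vector on a diffusion-weighted volume")
    dirs[bad, ] <- dirs[bad, , drop = FALSE] / nrm[bad]
  }
  dirs[b0 & nrm < 1e-12, ] <- 0

  # group shells by nominal b within tolerance
  ub <- sort(unique(round(bvals / shell_tol) * shell_tol))
  shell_b <- c()
  shells <- list()
  assigned <- rep(FALSE, length(bvals))
  for (b in ub) {
    idx <- which(!assigned & abs(bvals - b) <= shell_tol)
    if (!length(idx)) next
    key <- mean(bvals[idx])
    shell_b <- c(shell_b, key)
    shells[[length(shells) + 1L]] <- idx
    assigned[idx] <- TRUE
  }
  names(shells) <- format(shell_b, trim = TRUE)
  if (sum(shell_b > 0) < 1) stop("protocol has no nonzero shell")
  structure(list(bvals = bvals, dirs = dirs, shells = shells,
                 shell_b = shell_b, shell_tol = shell_tol),
            class = "sm_protocol")
}

#' @export
print.sm_protocol <- function(x, ...) {
  cat("dMRI protocol:", length(x$bvals), "volumes,",
      sum(x$shell_b > 0), "nonzero shell(s)\n")
  for (i in seq_along(x$shell_b))
    cat(sprintf("  b = %-5.3g ms/um^2 : %d volume(s)\n",
                x$shell_b[i], length(x$shells[[i]])))
  invisible(x)
}

# indices of b=0 volumes / of volumes in each nonzero shell
protocol_b0_idx <- function(protocol) {
  unlist(protocol$shells[protocol$shell_b <= protocol$shell_tol], use.names = FALSE)
}

protocol_nonzero_shells <- function(protocol) {
  keep <- protocol$shell_b > protocol$shell_tol
  list(b = protocol$shell_b[keep], idx = protocol$shells[keep])
}

#' Read an FSL-style gradient table
#'
#' Reads `bval` (one row of scalars, s/mm^2) and `bvec` (three rows) text
#' files, converts b-values to ms/um^2 (division by 1000), normalizes
#' directions and groups shells.
#'
#' @param bval_path,bvec_path paths to the FSL bval/bvec text files.
#' @param shell_tol shell grouping tolerance in ms/um^2.
#' @return An [sm_protocol()] object.
#' @export
read_bvalbvec <- function(bval_path, bvec_path, shell_tol = 0.1) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) != 3)
    stop("bvec file must have 3 rows, found ", nrow(bv))
  if (ncol(bv) != length(bvals))
    stop("bval/bvec length mismatch: ", length(bvals), " vs ", ncol(bv))
  if (any(bvals < 0)) stop("negative b-value in ", bval_path)
  sm_protocol(bvals / 1000, t(bv), shell_tol = shell_tol)
}

#' Write an FSL-style gradient table
#'
#' Inverse of [read_bvalbvec()]: writes b-values in s/mm^2 and directions as
#' three rows.
#'
#' @param protocol an [sm_protocol()].
#' @param bval_path,bvec_path output paths.
#' @export
write_bvalbvec <- function(protocol, bval_path, bvec_path) {
  cat(paste(format(protocol$bvals * 1000, trim = TRUE), collapse = " "), "\n",
      sep = "", file = bval_path)
  utils::write.table(t(protocol$dirs), bvec_path, row.names = FALSE,
                     col.names = FALSE)
  invisible(protocol)
}

# Spherical-Fibonacci layout of n quasi-uniform points on the sphere,
# randomly rotated as a whole (deterministic given the RNG state).
fibonacci_directions <- function(n, rotate = TRUE) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  s <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(s * cos(phi), s * sin(phi), z)
  if (rotate) {
    # random rotation via QR of a Gaussian matrix
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    pts <- pts %*% q
  }
  pts
}

#' Canonical two-shell simulation protocol
#'
#' Builds the two-shell acquisition used throughout the package's simulations:
#' b = 0 volumes plus b = 1 ms/um^2 and b = 2 ms/um^2 shells with
#' quasi-uniform directions (spherical-Fibonacci layout, randomly rotated;
#' deterministic given `seed`). Defaults mirror a ~6 minute clinical protocol:
#' 4 b0, 20 directions at b = 1 and 60 at b = 2.
#'
#' @param n_b0,n_b1,n_b2 volume counts for the b = 0, 1 and 2 shells.
#' @param b1,b2 shell b-values in ms/um^2.
#' @param seed integer seed controlling the direction layout.
#' @return An [sm_protocol()].
#' @examples
#' p <- default_protocol(seed = 1)
#' length(p$bvals)  # 84
#' @export
default_protocol <- function(n_b0 = 4, n_b1 = 20, n_b2 = 60,
                             b1 = 1, b2 = 2, seed = 1) {
  if (n_b1 < 6 || n_b2 < 6)
    stop("each nonzero shell needs at least 6 directions")
  with_seed(seed, {
    d1 <- fibonacci_directions(n_b1)
    d2 <- fibonacci_directions(n_b2)
    bvals <- c(rep(0, n_b0), rep(b1, n_b1), rep(b2, n_b2))
    dirs <- rbind(matrix(0, n_b0, 3), d1, d2)
    sm_protocol(bvals, dirs)
  })
}

#' Serialize / deserialize a protocol as JSON
#'
#' Round-trips b-values and directions exactly (full double precision).
#'
#' @param protocol an [sm_protocol()].
#' @param path output (input) JSON path.
#' @return `protocol_from_json` returns an [sm_protocol()].
#' @export
protocol_to_json <- function(protocol, path) {
  # doubles as 17-significant-digit strings: guarantees bit-exact round-trips
  obj <- list(bvals = format(protocol$bvals, digits = 17, trim = TRUE),
              dirs = format(as.vector(protocol$dirs), digits = 17,
                            trim = TRUE),
              n_volumes = length(protocol$bvals),
              shell_tol = protocol$shell_tol,
              units = "ms/um^2",
              layout = "spherical-Fibonacci or as-read; axially symmetric")
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(protocol)
}

#' @rdname protocol_to_json
#' @export
protocol_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sm_protocol(as.numeric(obj$bvals),
              matrix(as.numeric(obj$dirs), ncol = 3),
              shell_tol = obj$shell_tol)
}
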