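# Internal helpers shared across modules.

#' Trapezoidal quadrature weights for an increasing wavelength grid
#'
#' Weights w such that sum(w * f) approximates the integral of f over the
#' grid span. Used for all spectral inner products so that results are
#' (approximately) invariant to grid resampling density.
#'
#' @param values strictly increasing numeric vector (nm)
#' @return numeric vector of weights (nm)
#' @keywords internal
#' @noRd
trapezoidWeights <- function(values) {
  n <- length(values)
  if (n < 2L) stop("wavelength grid needs at least 2 points")
  d <- diff(values)
  w <- numeric(n)
  w[1L] <- d[1L] / 2
  w[n] <- d[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (d[-(n - 1L)] + d[-1L]) / 2
  w
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All seeded operations in the package go
# through this so library code never clobbers user RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("seed must be coercible to integer")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a per-stage / per-item child seed from a root seed, kept within
# the 32-bit signed integer range R requires.
deriveSeed <- function(root, index) {
  root <- as.double(root)
  (as.integer(root) %% 1000000L) * 2000L + (as.integer(index) %% 2000L) + 1L
}

# Cubic-spline resampling of a set of spectra (rows) from wavelengths `from`
# onto wavelengths `to`; wavelengths outside the source range contribute 0.
resampleSpectra <- function(mat, from, to) {
  mat <- rbind(mat)
  out <- matrix(0, nrow(mat), length(to))
  inside <- to >= min(from) & to <= max(from)
  if (any(inside)) {
    for (i in seq_len(nrow(mat))) {
      out[i, inside] <- stats::spline(from, mat[i, ], xout = to[inside],
                                      method = "natural")$y
    }
  }
  out
}

# Gaussian blur of a matrix with a separable kernel (replicate padding).
gaussianBlur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(m) {
    nr <- nrow(m)
    idx <- outer(seq_len(nr), -r:r, "+")
    idx[idx < 1L] <- 1L
    idx[idx > nr] <- nr
    out <- matrix(0, nr, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(blur1(t(blur1(x))))
}

# Linear interpolation matrix W (length(dst) x length(src)) mapping values on
# the 1D source lattice `src` to positions `dst`, replicating beyond the ends.
# Exactly reproduces source values at source positions (rows are unit vectors).
interp1Matrix <- function(src, dst) {
  ns <- length(src)
  W <- matrix(0, length(dst), ns)
  if (ns == 1L) {
    W[, 1L] <- 1
    return(W)
  }
  for (i in seq_along(dst)) {
    x <- dst[i]
    if (x <= src[1L]) {
      W[i, 1L] <- 1
    } else if (x >= src[ns]) {
      W[i, ns] <- 1
    } else {
      j <- findInterval(x, src)
      t <- (x - src[j]) / (src[j + 1L] - src[j])
      W[i, j] <- 1 - t
      W[i, j + 1L] <- t
    }
  }
  W
}

# round-half-up quantisation to integers in [0, 2^bits - 1] from [0,1];
# pmin/pmax keep the first argument's shape, so x comes first
quantizeBits <- function(x, bits) {
  peak <- 2^bits - 1
  pmax(pmin(floor(x * peak + 0.5), peak), 0)
}
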