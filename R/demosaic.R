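# Baseline reconstruction: band splitting, offset-aware bilinear
# interpolation back to X x Y x ns, and per-pixel spectral correction.

#' Group snapshot pixels by sampled band
#'
#' Splits the snapshot into per-band sparse sample sets: for each band, the
#' (x, y, value) triplets at the lattice positions where the mosaic samples
#' that band. The sets are disjoint and their union covers every pixel.
#'
#' @param snapshot a \linkS4class{SnapshotMosaic}
#' @return a list with one data.frame (columns x, y, value) per band, in
#'   band-index order
#' @export
splitBands <- function(snapshot) {
  img <- snapshotImage(snapshot)
  pat <- snapshotPattern(snapshot)
  X <- nrow(img); Y <- ncol(img)
  bm <- patternBandMap(pat, X, Y)
  bands <- sort(unique(as.vector(pat@assignment)))
  xs <- rep(seq_len(X), times = Y)
  ys <- rep(seq_len(Y), each = X)
  lapply(bands, function(b) {
    sel <- as.vector(bm) == b
    data.frame(x = xs[sel], y = ys[sel], value = as.vector(img)[sel])
  })
}

# Positions (1-based) of block cell `phase` along an axis of length `len`
# for block edge n: phase, phase+n, phase+2n, ... (empty when the frame is
# too small to contain the phase at all)
latticePositions <- function(phase, n, len) {
  if (phase > len) return(integer(0))
  seq.int(phase, len, by = n)
}

#' Bilinear demosaicking
#'
#' Reconstructs the full X x Y x ns cube from a snapshot by interpolating
#' each band's sparse sample lattice. Samples sit at their true sensor
#' coordinates (block phase preserved), interpolation is separable linear
#' along X then Y, and positions beyond a band's outermost samples replicate
#' the nearest lattice row/column. At a band's own sample sites the
#' reconstruction equals the snapshot value exactly; constants are
#' reproduced exactly and affine ramps exactly in the lattice interior.
#'
#' Bands that occupy several cells of the mosaic block are reconstructed per
#' cell and averaged; for the usual one-cell-per-band layouts the single
#' lattice is used directly.
#'
#' @param snapshot a \linkS4class{SnapshotMosaic}
#' @param bandCenters optional band centres for the output cube
#' @return an ns-band \linkS4class{Hypercube} (role "intermediate")
#' @export
bilinearDemosaick <- function(snapshot, bandCenters = NULL) {
  img <- snapshotImage(snapshot)
  pat <- snapshotPattern(snapshot)
  n <- pat@n
  a <- pat@assignment
  X <- nrow(img); Y <- ncol(img)
  bands <- sort(unique(as.vector(a)))
  ns <- length(bands)
  out <- array(0, c(X, Y, ns))
  for (k in seq_len(ns)) {
    b <- bands[k]
    cells <- which(a == b, arr.ind = TRUE)
    acc <- matrix(0, X, Y)
    used <- 0L
    for (ci in seq_len(nrow(cells))) {
      rx <- latticePositions(cells[ci, 1L], n, X)
      cy <- latticePositions(cells[ci, 2L], n, Y)
      if (length(rx) == 0L || length(cy) == 0L) next  # band unobserved here
      V <- img[rx, cy, drop = FALSE]
      Wx <- interp1Matrix(rx, seq_len(X))
      Wy <- interp1Matrix(cy, seq_len(Y))
      acc <- acc + Wx %*% V %*% t(Wy)
      used <- used + 1L
    }
    if (used > 0L) out[, , k] <- acc / used
  }
  if (is.null(bandCenters)) bandCenters <- as.numeric(bands)
  hypercube(out, bandCenters, "intermediate")
}

#' Apply the spectral-correction matrix C per pixel
#'
#' Maps each pixel's ns measured band values to ni ideal band values:
#' \code{out[x,y,] = C \%*\% cube[x,y,]} (exact linear map, no clipping).
#'
#' @param cube an ns-band \linkS4class{Hypercube}
#' @param C a \linkS4class{CalibrationMatrix} (ni x ns) or plain matrix
#' @param bandCenters optional ideal band centres for the output
#' @return an ni-band \linkS4class{Hypercube} with role "ideal"
#' @export
applySpectralCorrection <- function(cube, C, bandCenters = NULL) {
  Cm <- if (is(C, "CalibrationMatrix")) calMatrix(C) else rbind(C)
  d <- cubeData(cube)
  X <- dim(d)[1L]; Y <- dim(d)[2L]; B <- dim(d)[3L]
  if (ncol(Cm) != B)
    stop(sprintf("calibration matrix has %d columns but cube has %d bands",
                 ncol(Cm), B))
  out <- matrix(d, X * Y, B) %*% t(Cm)
  if (is.null(bandCenters)) bandCenters <- seq_len(nrow(Cm))
  hypercube(array(out, c(X, Y, nrow(Cm))), bandCenters, "ideal")
}

#' Linear demosaicking pipeline
#'
#' The baseline reconstruction: bilinear demosaicking followed by spectral
#' correction with the sensor's matrix C, yielding an ni-band ideal-space
#' cube directly comparable to the ground truth of
#' \code{\link{makeIdealHypercube}}.
#'
#' @param snapshot a \linkS4class{SnapshotMosaic}
#' @param sensor a \linkS4class{SensorModel}
#' @return an ni-band \linkS4class{Hypercube} (role "ideal")
#' @export
linearPipeline <- function(snapshot, sensor) {
  inter <- bilinearDemosaick(snapshot)
  applySpectralCorrection(inter, calibration(sensor),
                          bandCenters = sensor@idealSpecs$lambda0)
}
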