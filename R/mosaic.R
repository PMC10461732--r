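# Forward model: HR cube -> intermediate cube -> snapshot mosaic, plus the
# ideal target cube.

#' White balance (flat-field correction)
#'
#' Converts raw counts to reflectance using white and dark reference
#' captures: \code{(raw - dark) / (white - dark)}, clipped below at 0.
#' References may be full cubes, per-band vectors, or scalars.
#'
#' @param raw a \linkS4class{Hypercube} of raw counts
#' @param white white reference (Hypercube, per-band vector, or scalar)
#' @param dark dark reference (same forms; default 0)
#' @return a reflectance \linkS4class{Hypercube} with the same role
#' @export
whiteBalance <- function(raw, white, dark = 0) {
  d <- cubeData(raw)
  expand <- function(ref) {
    if (is(ref, "Hypercube")) return(cubeData(ref))
    if (length(ref) == 1L) return(array(ref, dim(d)))
    if (length(ref) == dim(d)[3L])
      return(aperm(array(ref, dim(d)[c(3L, 1L, 2L)]), c(2L, 3L, 1L)))
    stop("reference must be a cube, a per-band vector, or a scalar")
  }
  w <- expand(white)
  k <- expand(dark)
  if (any(w <= k)) stop("degenerate reference: white must exceed dark everywhere")
  out <- pmax((d - k) / (w - k), 0)
  hypercube(out, bandCenters(raw), cubeRole(raw))
}

#' Apply sensor spectral responses to an HR cube
#'
#' Computes at each pixel the quadrature-weighted inner products of the
#' band responses with the high-resolution spectrum:
#' \code{out[x,y,b] = sum_l R[b,l] * hr[x,y,l] * w[l]}, with trapezoidal
#' weights \code{w} from the grid, so results are stable under grid
#' resampling. If the cube's band centres differ from the response grid the
#' spectra are cubic-spline resampled onto it (wavelengths outside the cube's
#' range contribute zero).
#'
#' @param hr an HR \linkS4class{Hypercube} (nd bands)
#' @param resp a \linkS4class{SpectralResponseMatrix} (ns or ni rows)
#' @param role role tag for the output cube
#' @return a \linkS4class{Hypercube} with one band per response row, band
#'   centres at each response row's peak wavelength
#' @export
applySpectralResponse <- function(hr, resp, role = "intermediate") {
  grid <- resp@grid
  lam <- gridValues(grid)
  d <- cubeData(hr)
  X <- dim(d)[1L]; Y <- dim(d)[2L]; nd <- dim(d)[3L]
  M <- matrix(d, X * Y, nd)
  if (!(length(bandCenters(hr)) == length(lam) &&
        isTRUE(all.equal(bandCenters(hr), lam)))) {
    M <- resampleSpectra(M, bandCenters(hr), lam)
  }
  R <- responses(resp)
  Rw <- sweep(R, 2L, gridWeights(grid), "*")
  out <- M %*% t(Rw)
  out[out < 0] <- 0
  centers <- lam[apply(R, 1L, which.max)]
  hypercube(array(out, c(X, Y, nrow(R))), centers, role)
}

# full-frame band index map for a pattern: bandMap[x, y] = sampled band
patternBandMap <- function(pattern, X, Y) {
  n <- pattern@n
  a <- pattern@assignment
  r <- ((seq_len(X) - 1L) %% n) + 1L
  c <- ((seq_len(Y) - 1L) %% n) + 1L
  matrix(a[cbind(rep(r, times = Y), rep(c, each = X))], X, Y)
}

#' Spatially subsample an intermediate cube into a snapshot mosaic
#'
#' Keeps, at every pixel, only the band the mosaic filter array samples
#' there: \code{image[x,y] = cube[x, y, assignment[((x-1) mod n)+1,
#' ((y-1) mod n)+1]]}. Frames whose dimensions are not multiples of n keep
#' their partial edge blocks.
#'
#' @param intermediate an ns-band \linkS4class{Hypercube}
#' @param pattern a \linkS4class{MosaicPattern}
#' @return a \linkS4class{SnapshotMosaic}
#' @export
mosaicSubsample <- function(intermediate, pattern) {
  d <- cubeData(intermediate)
  X <- dim(d)[1L]; Y <- dim(d)[2L]; B <- dim(d)[3L]
  if (max(pattern@assignment) > B)
    stop("pattern band index exceeds cube band count")
  bm <- patternBandMap(pattern, X, Y)
  idx <- cbind(rep(seq_len(X), times = Y), rep(seq_len(Y), each = X),
               as.vector(bm))
  snapshotMosaic(matrix(d[idx], X, Y), pattern)
}

#' Scatter a snapshot back into a sparse cube
#'
#' Inverse placement of \code{\link{mosaicSubsample}}: each snapshot value is
#' written into an all-zero ns-band cube at its (pixel, sampled band) slot.
#' Re-subsampling the result recovers the snapshot exactly.
#'
#' @param snapshot a \linkS4class{SnapshotMosaic}
#' @param nsBands number of bands of the target cube (default: n^2)
#' @param bandCenters optional band centres for the cube
#' @return an ns-band \linkS4class{Hypercube} (role "intermediate")
#' @export
scatterSnapshot <- function(snapshot, nsBands = NULL, bandCenters = NULL) {
  img <- snapshotImage(snapshot)
  pat <- snapshotPattern(snapshot)
  X <- nrow(img); Y <- ncol(img)
  if (is.null(nsBands)) nsBands <- pat@n^2
  if (is.null(bandCenters)) bandCenters <- seq_len(nsBands)
  d <- array(0, c(X, Y, nsBands))
  bm <- patternBandMap(pat, X, Y)
  idx <- cbind(rep(seq_len(X), times = Y), rep(seq_len(Y), each = X),
               as.vector(bm))
  d[idx] <- as.vector(img)
  hypercube(d, bandCenters, "intermediate")
}

#' Ideal target hypercube from an HR cube
#'
#' Applies the ni ideal Lorentzian band responses to the HR cube; this is the
#' ground-truth cube the demosaicking pipeline is evaluated against.
#'
#' @param hr an HR \linkS4class{Hypercube}
#' @param idealResp ni-band ideal \linkS4class{SpectralResponseMatrix}
#' @return an ni-band \linkS4class{Hypercube} with role "ideal"
#' @export
makeIdealHypercube <- function(hr, idealResp) {
  applySpectralResponse(hr, idealResp, role = "ideal")
}

#' Simulate a paired training sample from an HR cube
#'
#' Runs the full forward model: measured responses give the intermediate
#' X x Y x ns cube, mosaic subsampling gives the 2D snapshot, and the ideal
#' responses give the X x Y x ni target cube.
#'
#' @param hr an HR \linkS4class{Hypercube}
#' @param sensor a \linkS4class{SensorModel}
#' @return a \linkS4class{PairedSample}
#' @examples
#' sp <- phantomSpec(dim = c(32, 32), seed = 7)
#' pair <- simulatePair(makePhantomHypercube(sp), defaultSensor())
#' @export
simulatePair <- function(hr, sensor) {
  intermediate <- applySpectralResponse(hr, measuredResponses(sensor),
                                        role = "intermediate")
  snapshot <- mosaicSubsample(intermediate, sensorPattern(sensor))
  ideal <- makeIdealHypercube(hr, idealResponses(sensor))
  pairedSample(snapshot, intermediate, ideal)
}
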