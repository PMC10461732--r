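# Full-reference reconstruction quality metrics: L1, PSNR, SSIM, and a
# pluggable perceptual (feature-space) score.

asArray <- function(x) if (is(x, "Hypercube")) cubeData(x) else x

#' Mean absolute (L1) error
#'
#' @param ref,test arrays (or Hypercubes) of identical shape
#' @return mean absolute difference
#' @export
l1Error <- function(ref, test) {
  a <- asArray(ref); b <- asArray(test)
  stopifnot(all(dim(a) == dim(b)))
  mean(abs(a - b))
}

#' Peak signal-to-noise ratio
#'
#' \code{10 * log10(peak^2 / MSE)} in dB. Identical inputs (MSE = 0) return
#' \code{Inf}.
#'
#' @param ref,test arrays (or Hypercubes) of identical shape
#' @param peak dynamic range of the data (default 1 for unit-normalised data)
#' @return PSNR in dB
#' @export
psnr <- function(ref, test, peak = 1) {
  a <- asArray(ref); b <- asArray(test)
  stopifnot(all(dim(a) == dim(b)))
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# 1D Gaussian window, normalised to sum 1
gaussianWindow <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1L) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g / sum(g)
}

# valid-mode separable filtering of a matrix with a 1D kernel g
validFilter <- function(x, g) {
  k <- length(g)
  H <- nrow(x); W <- ncol(x)
  if (H < k || W < k) stop("image smaller than the SSIM window")
  B1 <- matrix(0, H - k + 1L, H)
  for (i in seq_len(H - k + 1L)) B1[i, i:(i + k - 1L)] <- g
  B2 <- matrix(0, W - k + 1L, W)
  for (i in seq_len(W - k + 1L)) B2[i, i:(i + k - 1L)] <- g
  B1 %*% x %*% t(B2)
}

ssim2d <- function(a, b, window, K1, K2, dynamicRange) {
  C1 <- (K1 * dynamicRange)^2
  C2 <- (K2 * dynamicRange)^2
  mu1 <- validFilter(a, window)
  mu2 <- validFilter(b, window)
  s11 <- validFilter(a * a, window) - mu1^2
  s22 <- validFilter(b * b, window) - mu2^2
  s12 <- validFilter(a * b, window) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Structural similarity index
#'
#' Sliding-window SSIM with a Gaussian 11x11 window (sigma 1.5), stabilisers
#' K1 = 0.01 and K2 = 0.03, valid-mode windows (no border padding). For
#' rank-3 arrays the per-band 2D SSIM values are averaged.
#'
#' @param ref,test matrices or rank-3 arrays (or Hypercubes) of equal shape
#' @param dynamicRange data range L (default 1 for unit-normalised data)
#' @param windowSize,sigma Gaussian window parameters
#' @param K1,K2 stabiliser constants
#' @return scalar in [-1, 1]
#' @export
ssim <- function(ref, test, dynamicRange = 1, windowSize = 11L, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03) {
  a <- asArray(ref); b <- asArray(test)
  stopifnot(all(dim(a) == dim(b)))
  g <- gaussianWindow(windowSize, sigma)
  if (length(dim(a)) == 2L || is.null(dim(a))) {
    return(ssim2d(as.matrix(a), as.matrix(b), g, K1, K2, dynamicRange))
  }
  vals <- vapply(seq_len(dim(a)[3L]), function(k) {
    ssim2d(a[, , k], b[, , k], g, K1, K2, dynamicRange)
  }, numeric(1L))
  mean(vals)
}

#' Perceptual (feature-space) similarity score
#'
#' Mean squared distance between the feature maps of two RGB images under a
#' fixed, frozen feature extractor: 0 for identical images, symmetric in its
#' arguments. The extractor is injectable; the packaged default
#' (\code{\link{defaultFeatureExtractor}}) is a synthetic fixed-seed random
#' convolutional stack, so scores are comparable within one extractor but
#' not across published perceptual-metric weights.
#'
#' @param refRgb,testRgb X x Y x 3 arrays
#' @param extractor function mapping an image array to a numeric feature
#'   array
#' @return non-negative scalar
#' @export
perceptualScore <- function(refRgb, testRgb,
                            extractor = defaultFeatureExtractor()) {
  fa <- extractor(refRgb)
  fb <- extractor(testRgb)
  mean((as.numeric(fa) - as.numeric(fb))^2)
}

#' Evaluate a set of reconstructions against references
#'
#' For each (reference, reconstruction) cube pair: normalises both by the
#' reference cube's maximum (band-space inner-product values are not on a
#' unit scale), computes L1 / SSIM / PSNR on the cubes, renders the
#' normalised cubes to sRGB and computes the same metrics there. Returns a
#' per-image data.frame with a \code{"summary"} attribute (mean and sd per
#' metric).
#'
#' @param pairs list of lists with elements \code{reference} and
#'   \code{reconstruction} (Hypercubes), optionally \code{name}
#' @param cspec a \code{ColourimetrySpec} for the sRGB metrics
#' @return data.frame (one row per image) with attribute \code{"summary"}
#' @seealso \code{\link{writeEvaluation}}
#' @export
evaluateSuite <- function(pairs, cspec = colourimetrySpec()) {
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    ref <- cubeData(p$reference)
    rec <- cubeData(p$reconstruction)
    m <- max(ref)
    if (m <= 0) m <- 1
    refN <- ref / m
    recN <- rec / m
    bc <- bandCenters(p$reference)
    rgbRef <- hypercubeToSRGB(hypercube(refN, bc, "ideal"), cspec = cspec)
    rgbRec <- hypercubeToSRGB(hypercube(recN, bc, "ideal"), cspec = cspec)
    data.frame(
      name = p$name %||% sprintf("image%02d", i),
      l1 = l1Error(refN, recN),
      ssim = ssim(refN, recN),
      psnr = psnr(refN, recN),
      rgb_l1 = l1Error(rgbRef, rgbRec),
      rgb_ssim = ssim(rgbRef, rgbRec),
      rgb_psnr = psnr(rgbRef, rgbRec))
  })
  out <- do.call(rbind, rows)
  metricCols <- setdiff(names(out), "name")
  attr(out, "summary") <- data.frame(
    metric = metricCols,
    mean = vapply(metricCols, function(cn) mean(out[[cn]]), numeric(1L)),
    sd = vapply(metricCols, function(cn) stats::sd(out[[cn]]), numeric(1L)),
    row.names = NULL)
  out
}

#' Write an evaluation report as CSV plus a JSON sidecar
#'
#' @param report output of \code{\link{evaluateSuite}}
#' @param csvPath destination CSV path; the JSON summary goes to the same
#'   path with extension \code{.json}
#' @return invisibly, the two paths written
#' @export
writeEvaluation <- function(report, csvPath) {
  utils::write.csv(report, csvPath, row.names = FALSE)
  jsonPath <- sub("\\.[^.]*$", ".json", csvPath)
  jsonlite::write_json(list(summary = attr(report, "summary"),
                            perImage = report),
                       jsonPath, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE)
  invisible(c(csv = csvPath, json = jsonPath))
}
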