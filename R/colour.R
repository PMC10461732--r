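# Spectral -> CIE XYZ -> sRGB conversion under a D65 illuminant.

# CIE 1931 2-degree standard observer colour-matching functions, 10 nm
# tabulation, 380-780 nm (classic CIE table), and the CIE D65 relative
# spectral power distribution on the same 10 nm grid. Finer grids are
# obtained by natural-spline resampling in colourimetrySpec().
cie1931Table <- function() {
  lam <- seq(380, 780, by = 10)
  xbar <- c(0.0014, 0.0042, 0.0143, 0.0435, 0.1344, 0.2839, 0.3483, 0.3362,
            0.2908, 0.1954, 0.0956, 0.0320, 0.0049, 0.0093, 0.0633, 0.1655,
            0.2904, 0.4334, 0.5945, 0.7621, 0.9163, 1.0263, 1.0622, 1.0026,
            0.8544, 0.6424, 0.4479, 0.2835, 0.1649, 0.0874, 0.0468, 0.0227,
            0.0114, 0.0058, 0.0029, 0.0014, 0.0007, 0.0003, 0.0002, 0.0001,
            0.0000)
  ybar <- c(0.0000, 0.0001, 0.0004, 0.0012, 0.0040, 0.0116, 0.0230, 0.0380,
            0.0600, 0.0910, 0.1390, 0.2080, 0.3230, 0.5030, 0.7100, 0.8620,
            0.9540, 0.9950, 0.9950, 0.9520, 0.8700, 0.7570, 0.6310, 0.5030,
            0.3810, 0.2650, 0.1750, 0.1070, 0.0610, 0.0320, 0.0170, 0.0082,
            0.0041, 0.0021, 0.0010, 0.0005, 0.0002, 0.0001, 0.0001, 0.0000,
            0.0000)
  zbar <- c(0.0065, 0.0201, 0.0679, 0.2074, 0.6456, 1.3856, 1.7471, 1.7721,
            1.6692, 1.2876, 0.8130, 0.4652, 0.2720, 0.1582, 0.0782, 0.0422,
            0.0203, 0.0087, 0.0039, 0.0021, 0.0017, 0.0011, 0.0008, 0.0003,
            0.0002, 0.0000, 0.0000, 0.0000, 0.0000, 0.0000, 0.0000, 0.0000,
            0.0000, 0.0000, 0.0000, 0.0000, 0.0000, 0.0000, 0.0000, 0.0000,
            0.0000)
  d65 <- c(49.98, 54.65, 82.75, 91.49, 93.43, 86.68, 104.86, 117.01,
           117.81, 114.86, 115.92, 108.81, 109.35, 107.80, 104.79, 107.69,
           104.41, 104.05, 100.00, 96.33, 95.79, 88.69, 90.01, 89.60,
           87.70, 83.29, 83.70, 80.03, 80.21, 82.28, 78.28, 69.72,
           71.61, 74.35, 61.60, 69.89, 75.09, 63.59, 46.42, 66.81,
           63.38)
  list(lambda = lam, cmf = cbind(x = xbar, y = ybar, z = zbar), d65 = d65)
}

# sRGB (IEC 61966-2-1) XYZ -> linear RGB matrix, D65 white.
srgbMatrix <- function() {
  matrix(c(3.2404542, -1.5371385, -0.4985314,
           -0.9692660, 1.8760108, 0.0415560,
           0.0556434, -0.2040259, 1.0572252), 3, 3, byrow = TRUE)
}

#' Colourimetry specification
#'
#' Bundles the CIE 1931 2-degree colour-matching functions, the D65
#' illuminant, the XYZ-to-linear-sRGB matrix and the sRGB transfer-function
#' parameters, all resampled onto one wavelength grid. The normalisation
#' constant k (Y of a perfect reflector equals 1) is computed per band set in
#' \code{\link{spectraToXYZ}}, not per image, so brightness errors between
#' reconstructions stay visible.
#'
#' @param wavelengths grid to tabulate on (nm; default 380-780 at 1 nm)
#' @return an object of class \code{ColourimetrySpec} (list with elements
#'   \code{lambda}, \code{cmf}, \code{illuminant}, \code{rgbMatrix},
#'   \code{gammaThreshold}, \code{gammaExponent})
#' @export
colourimetrySpec <- function(wavelengths = seq(380, 780, by = 1)) {
  tab <- cie1931Table()
  cmf <- pmax(resampleSpectra(t(tab$cmf), tab$lambda, wavelengths), 0)
  ill <- pmax(resampleSpectra(tab$d65, tab$lambda, wavelengths)[1L, ], 0)
  structure(list(lambda = wavelengths, cmf = t(cmf), illuminant = ill,
                 rgbMatrix = srgbMatrix(),
                 gammaThreshold = 0.0031308, gammaExponent = 2.4),
            class = "ColourimetrySpec")
}

#' @export
print.ColourimetrySpec <- function(x, ...) {
  cat(sprintf("ColourimetrySpec: CIE 1931 2-deg + D65, %d wavelengths %.0f-%.0f nm\n",
              length(x$lambda), min(x$lambda), max(x$lambda)))
  invisible(x)
}

#' Integrate a reflectance cube to CIE XYZ under D65
#'
#' \code{XYZ[p] = k * sum_b cube[p,b] * E(lambda_b) * cmf(lambda_b) *
#' dlambda_b}, with CMFs and illuminant resampled at the cube's band centres,
#' trapezoidal band weights, and k normalising the Y of a unit reflector
#' (over the same band set) to 1. Linear in the cube values.
#'
#' @param cube a \linkS4class{Hypercube} whose band centres overlap the CMF
#'   support
#' @param cspec a \code{ColourimetrySpec} (default: \code{colourimetrySpec()})
#' @return X x Y x 3 numeric array of XYZ values
#' @export
spectraToXYZ <- function(cube, cspec = colourimetrySpec()) {
  lam <- bandCenters(cube)
  if (max(lam) < min(cspec$lambda) || min(lam) > max(cspec$lambda))
    stop("no cube band overlaps the colour-matching function support")
  cmf <- t(resampleSpectra(t(cspec$cmf), cspec$lambda, lam))
  cmf[cmf < 0] <- 0
  E <- pmax(resampleSpectra(cspec$illuminant, cspec$lambda, lam)[1L, ], 0)
  w <- if (length(lam) > 1L) trapezoidWeights(lam) else 1
  denom <- sum(E * cmf[, 2L] * w)
  if (denom <= 0) stop("no cube band overlaps the colour-matching function support")
  k <- 1 / denom
  d <- cubeData(cube)
  X <- dim(d)[1L]; Y <- dim(d)[2L]
  M <- matrix(d, X * Y, dim(d)[3L])
  xyz <- k * (M %*% (cmf * (E * w)))
  array(xyz, c(X, Y, 3L))
}

# sRGB piecewise transfer function and its inverse (on [0,1])
srgbEncode <- function(u, threshold = 0.0031308, exponent = 2.4) {
  ifelse(u <= threshold, 12.92 * u, 1.055 * u^(1 / exponent) - 0.055)
}

srgbDecode <- function(v, threshold = 0.0031308, exponent = 2.4) {
  ifelse(v <= 12.92 * threshold, v / 12.92, ((v + 0.055) / 1.055)^exponent)
}

#' Convert XYZ to sRGB
#'
#' Applies the standard XYZ-to-linear-RGB matrix, clips linear RGB to [0,1],
#' applies the piecewise sRGB gamma, and optionally quantises to 8 bits
#' (round-half-up).
#'
#' @param xyz X x Y x 3 array of XYZ values
#' @param cspec a \code{ColourimetrySpec}
#' @param bits NULL for unit-interval floats (default) or 8 for integers in
#'   0..255
#' @return X x Y x 3 sRGB array
#' @export
xyzToSRGB <- function(xyz, cspec = colourimetrySpec(), bits = NULL) {
  d <- dim(xyz)
  lin <- matrix(xyz, d[1L] * d[2L], 3L) %*% t(cspec$rgbMatrix)
  lin <- pmin(pmax(lin, 0), 1)
  srgb <- srgbEncode(lin, cspec$gammaThreshold, cspec$gammaExponent)
  if (!is.null(bits)) srgb <- quantizeBits(srgb, bits)
  array(srgb, c(d[1L], d[2L], 3L))
}

#' Invert the sRGB transform back to XYZ
#'
#' Exact inverse of \code{\link{xyzToSRGB}} for unquantised, in-gamut values.
#'
#' @param srgb X x Y x 3 unit-interval sRGB array
#' @param cspec a \code{ColourimetrySpec}
#' @return X x Y x 3 XYZ array
#' @export
srgbToXYZ <- function(srgb, cspec = colourimetrySpec()) {
  d <- dim(srgb)
  lin <- srgbDecode(matrix(srgb, d[1L] * d[2L], 3L),
                    cspec$gammaThreshold, cspec$gammaExponent)
  array(lin %*% t(solve(cspec$rgbMatrix)), c(d[1L], d[2L], 3L))
}

#' Render a hypercube as an sRGB image
#'
#' Applies the sensor's correction matrix C first when given an ns-band
#' intermediate cube alongside a sensor, then integrates to XYZ and encodes
#' to sRGB. Band-limited sensors (e.g. 470-620 nm) integrate only over the
#' available bands: a unit reflector then maps to a fixed, slightly
#' non-white chromaticity (returned as the \code{"whitepoint"} attribute);
#' setting \code{rescaleWhite = TRUE} rescales channelwise so that a unit
#' reflector renders white.
#'
#' @param cube an ni-band (or, with \code{sensor}, ns-band) Hypercube
#' @param sensor optional \linkS4class{SensorModel}; its C is applied when
#'   the cube band count equals ns
#' @param cspec a \code{ColourimetrySpec}
#' @param rescaleWhite compensate the band-truncated integral for display
#' @param scale divisor bringing cube values to a reflectance-like scale
#'   before integration; band-space cubes produced by the forward model
#'   carry raw response inner products, for which
#'   \code{\link{bandIntegralScale}} is the natural choice (default 1:
#'   values already reflectance-like)
#' @param bits NULL for floats, 8 for 0..255 integers
#' @return X x Y x 3 sRGB array with attribute \code{"whitepoint"} (the XYZ
#'   of a unit reflector under this band set)
#' @export
hypercubeToSRGB <- function(cube, sensor = NULL, cspec = colourimetrySpec(),
                            rescaleWhite = FALSE, scale = 1, bits = NULL) {
  if (!is.null(sensor) &&
      dim(cubeData(cube))[3L] == nrow(responses(measuredResponses(sensor)))) {
    cube <- applySpectralCorrection(cube, calibration(sensor),
                                    bandCenters = sensor@idealSpecs$lambda0)
  }
  if (!identical(scale, 1)) {
    cube <- hypercube(cubeData(cube) / scale, bandCenters(cube),
                      cubeRole(cube))
  }
  xyz <- spectraToXYZ(cube, cspec)
  ones <- hypercube(array(1, c(1L, 1L, length(bandCenters(cube)))),
                    bandCenters(cube), "ideal")
  wp <- as.numeric(spectraToXYZ(ones, cspec))
  if (rescaleWhite) {
    d65 <- c(0.95047, 1, 1.08883)
    for (ch in 1:3) xyz[, , ch] <- xyz[, , ch] * d65[ch] / wp[ch]
  }
  out <- xyzToSRGB(xyz, cspec, bits = bits)
  attr(out, "whitepoint") <- wp
  out
}

#' Unit-reflector band value of a sensor's ideal bands
#'
#' The mean quadrature integral of the ideal band responses: the value a
#' perfect (unit) reflector takes in ideal band space under the forward
#' model. Dividing band-space cubes by this brings them to a
#' reflectance-like scale for display.
#'
#' @param sensor a \linkS4class{SensorModel}
#' @return positive scalar (nm-weighted response integral)
#' @export
bandIntegralScale <- function(sensor) {
  R <- responses(idealResponses(sensor))
  mean(R %*% gridWeights(sensorGrid(sensor)))
}
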