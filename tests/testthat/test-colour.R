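# Colorimetry: XYZ integration under D65 and the sRGB transfer.

test_that("a unit reflector over dense 400-700 nm bands renders white", {
  lam <- seq(400, 700, by = 2)
  cube <- hypercube(array(1, c(2, 2, length(lam))), lam, "ideal")
  xyz <- spectraToXYZ(cube)
  expect_equal(xyz[1, 1, 2], 1, tolerance = 1e-12)   # Y normalised to 1
  srgb <- hypercubeToSRGB(cube)
  expect_true(all(abs(srgb - 1) <= 0.01))
  # the whitepoint attribute is the D65 white point to 1%
  wp <- attr(srgb, "whitepoint")
  expect_equal(wp, c(0.95047, 1, 1.08883), tolerance = 0.01)
})

test_that("spectraToXYZ is linear and monotone in reflectance", {
  lam <- seq(420, 680, length.out = 40)
  cube <- randomCube(3, 3, 40, lam, seed = 1, role = "ideal")
  zero <- hypercube(array(0, c(3, 3, 40)), lam, "ideal")
  expect_equal(spectraToXYZ(zero), array(0, c(3, 3, 3)))
  x1 <- spectraToXYZ(cube)
  x2 <- spectraToXYZ(hypercube(2 * cubeData(cube), lam, "ideal"))
  expect_equal(x2, 2 * x1, tolerance = 1e-12)
  # raising one band's reflectance never decreases Y
  d <- cubeData(cube)
  d[2, 2, 17] <- d[2, 2, 17] + 0.3
  x3 <- spectraToXYZ(hypercube(d, lam, "ideal"))
  expect_gte(x3[2, 2, 2], x1[2, 2, 2] - 1e-14)
  expect_error(spectraToXYZ(hypercube(array(1, c(1, 1, 2)), c(900, 950), "ideal")))
})

test_that("xyzToSRGB implements the standard matrix, clip, gamma and quantisation", {
  expect_equal(xyzToSRGB(array(0, c(1, 1, 3))), array(0, c(1, 1, 3)))
  wp <- array(c(0.95047, 1, 1.08883), c(1, 1, 3))
  expect_equal(as.numeric(xyzToSRGB(wp, bits = 8)), c(255, 255, 255))
  # closed-form transfer: linear 0.5 -> ~0.7354 -> 188/255
  enc <- mosaicHSI:::srgbEncode(0.5)
  expect_equal(enc, 1.055 * 0.5^(1 / 2.4) - 0.055, tolerance = 1e-12)
  expect_equal(enc, 0.7354, tolerance = 1e-4)
  expect_equal(floor(enc * 255 + 0.5), 188)
  # round trip on unclipped in-gamut values
  set.seed(2)
  xyz <- array(runif(5 * 4 * 3, 0.05, 0.4), c(5, 4, 3))
  srgb <- xyzToSRGB(xyz)
  lin <- mosaicHSI:::srgbDecode(srgb)
  inGamut <- TRUE
  back <- srgbToXYZ(srgb)
  keep <- apply(matrix(matrix(xyz, 20, 3) %*% t(mosaicHSI:::srgbMatrix()), 20, 3),
                1L, function(v) all(v >= 0 & v <= 1))
  expect_equal(matrix(back, 20, 3)[keep, ], matrix(xyz, 20, 3)[keep, ],
               tolerance = 1e-6)
})

test_that("flat spectra render near-neutral and repeated calls are stable", {
  lam <- seq(400, 700, by = 3)
  set.seed(3)
  levels <- matrix(runif(16, 0.1, 0.9), 4, 4)
  d <- array(rep(levels, times = length(lam)), c(4, 4, length(lam)))
  cube <- hypercube(d, lam, "ideal")
  rgb <- hypercubeToSRGB(cube, bits = 8)
  expect_true(all(abs(rgb[, , 1] - rgb[, , 2]) <= 2))
  expect_true(all(abs(rgb[, , 2] - rgb[, , 3]) <= 2))
  expect_identical(hypercubeToSRGB(cube, bits = 8), rgb)
})

test_that("band-limited sensors yield a fixed non-white unit-reflector chromaticity", {
  lam <- seq(470, 620, length.out = 16)
  cube <- hypercube(array(1, c(2, 2, 16)), lam, "ideal")
  rgb <- hypercubeToSRGB(cube)
  wp <- attr(rgb, "whitepoint")
  expect_equal(wp[2], 1, tolerance = 1e-12)   # Y still normalised over bands
  # truncated-integral oracle: X and Z lose their out-of-band lobes
  tab <- mosaicHSI:::cie1931Table()
  g <- seq(380, 780, by = 1)
  cmf <- t(mosaicHSI:::resampleSpectra(t(tab$cmf), tab$lambda, g))
  ill <- mosaicHSI:::resampleSpectra(tab$d65, tab$lambda, g)[1L, ]
  sel <- g >= min(lam) & g <= max(lam)
  oracle <- colSums(cmf[sel, ] * ill[sel]) / sum(cmf[sel, 2] * ill[sel])
  expect_equal(wp, oracle, tolerance = 0.02)
  expect_gt(max(abs(wp - c(0.95047, 1, 1.08883))), 0.05)  # clearly non-white
  # the rescale toggle brings the unit reflector back to white
  rgb2 <- hypercubeToSRGB(cube, rescaleWhite = TRUE)
  expect_true(all(abs(rgb2 - 1) <= 0.01))
})
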