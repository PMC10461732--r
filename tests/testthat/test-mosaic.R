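# Forward model: white balance, spectral response, mosaic subsampling.

test_that("whiteBalance maps the references to 0, 1 and the midpoint to 0.5", {
  lam <- seq(450, 650, length.out = 5)
  white <- hypercube(array(2, c(3, 3, 5)), lam)
  dark <- hypercube(array(0.5, c(3, 3, 5)), lam)
  expect_equal(cubeData(whiteBalance(white, white, dark)),
               array(1, c(3, 3, 5)))
  expect_equal(cubeData(whiteBalance(dark, white, dark)),
               array(0, c(3, 3, 5)))
  mid <- hypercube((cubeData(white) + cubeData(dark)) / 2, lam)
  expect_equal(cubeData(whiteBalance(mid, white, dark)),
               array(0.5, c(3, 3, 5)))
  # per-band vector references and clipping below dark
  raw <- hypercube(array(0.1, c(3, 3, 5)), lam)
  wb <- whiteBalance(raw, rep(2, 5), rep(0.5, 5))
  expect_equal(cubeData(wb), array(0, c(3, 3, 5)))
  expect_error(whiteBalance(raw, dark, white), "degenerate")
})

test_that("a weight-normalised delta response selects a single HR band", {
  grid <- wavelengthGrid(seq(450, 650, by = 2))
  k <- 37L
  r <- matrix(0, 1, length(gridValues(grid)))
  r[1, k] <- 1 / gridWeights(grid)[k]
  resp <- spectralResponseMatrix(r, grid)
  hr <- randomCube(4, 5, length(gridValues(grid)), gridValues(grid), seed = 2)
  out <- applySpectralResponse(hr, resp)
  expect_equal(cubeData(out)[, , 1L], cubeData(hr)[, , k], tolerance = 1e-12)
})

test_that("applySpectralResponse is linear and matches the summation oracle", {
  s <- tinySensor()
  grid <- sensorGrid(s)
  nd <- length(gridValues(grid))
  h1 <- randomCube(4, 4, nd, gridValues(grid), seed = 3)
  h2 <- randomCube(4, 4, nd, gridValues(grid), seed = 4)
  a <- 0.3; b <- 1.7
  mix <- hypercube(a * cubeData(h1) + b * cubeData(h2), gridValues(grid))
  resp <- measuredResponses(s)
  lhs <- cubeData(applySpectralResponse(mix, resp))
  rhs <- a * cubeData(applySpectralResponse(h1, resp)) +
    b * cubeData(applySpectralResponse(h2, resp))
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # flat spectrum pixel -> band value is the weighted row sum
  flat <- hypercube(array(1, c(1, 1, nd)), gridValues(grid))
  out <- as.numeric(cubeData(applySpectralResponse(flat, resp)))
  oracle <- as.numeric(responses(resp) %*% gridWeights(grid))
  expect_equal(out, oracle, tolerance = 1e-12)
})

test_that("spectral inner products are stable under grid density doubling", {
  # smooth closed-form spectra evaluated on both grids (wide bands keep the
  # trapezoid error tiny)
  specs <- data.frame(lambda0 = c(500, 550, 600), qe = 0.8, fwhm = 30)
  spectrum <- function(l) 0.4 + 0.3 * sin(l / 60) + 0.2 * exp(-(l - 560)^2 / 8000)
  mk <- function(step) {
    g <- wavelengthGrid(seq(400, 700, by = step))
    resp <- buildResponseMatrix(g, specs)
    hr <- hypercube(array(rep(spectrum(gridValues(g)),
                              each = 4), c(2, 2, length(gridValues(g)))),
                    gridValues(g))
    cubeData(applySpectralResponse(hr, resp))
  }
  coarse <- mk(0.1)
  fine <- mk(0.05)
  expect_equal(coarse, fine, tolerance = 1e-6)
})

test_that("mosaicSubsample implements the block index arithmetic", {
  # band b constant at value b: the snapshot tiles the assignment grid
  pat <- mosaicPattern(4L)
  d <- array(0, c(8, 8, 16))
  for (b in 1:16) d[, , b] <- b
  cube <- hypercube(d, 1:16, "intermediate")
  snap <- mosaicSubsample(cube, pat)
  img <- snapshotImage(snap)
  expect_equal(img[1:4, 1:4], matrix(1:16, 4, 4, byrow = TRUE) + 0)
  expect_equal(img[5:8, 5:8], img[1:4, 1:4])
  # 0-based index oracle: snapshot[x,y] = cube[x,y, a[x mod 4, y mod 4]]
  cube2 <- randomCube(8, 8, 16, 1:16, seed = 5, role = "intermediate")
  snap2 <- mosaicSubsample(cube2, pat)
  for (x0 in c(0L, 3L, 5L)) for (y0 in c(0L, 2L, 6L)) {
    b0 <- (x0 %% 4L) * 4L + (y0 %% 4L)   # row-major 0-based band
    expect_identical(snapshotImage(snap2)[x0 + 1L, y0 + 1L],
                     cubeData(cube2)[x0 + 1L, y0 + 1L, b0 + 1L])
  }
  expect_error(mosaicSubsample(randomCube(8, 8, 4, 1:4), pat))
})

test_that("subsample -> scatter -> subsample is the identity", {
  pat <- mosaicPattern(4L)
  cube <- randomCube(9, 11, 16, 1:16, seed = 6, role = "intermediate")
  snap <- mosaicSubsample(cube, pat)
  back <- scatterSnapshot(snap, nsBands = 16L)
  snap2 <- mosaicSubsample(back, pat)
  expect_identical(snapshotImage(snap2), snapshotImage(snap))
})

test_that("sampled positions of each band form the expected lattice", {
  pat <- mosaicPattern(4L)
  cube <- randomCube(10, 14, 16, 1:16, seed = 7, role = "intermediate")
  snap <- mosaicSubsample(cube, pat)
  sets <- splitBands(snap)
  a <- patternAssignment(pat)
  for (b in seq_along(sets)) {
    cells <- which(a == b, arr.ind = TRUE)
    for (i in seq_len(nrow(sets[[b]]))) {
      x <- sets[[b]]$x[i]; y <- sets[[b]]$y[i]
      expect_true(any(cells[, 1L] == ((x - 1L) %% 4L) + 1L &
                        cells[, 2L] == ((y - 1L) %% 4L) + 1L))
    }
  }
})

test_that("simulatePair is deterministic with consistent shapes", {
  s <- tinySensor()
  hr <- randomCube(12, 10, length(gridValues(sensorGrid(s))),
                   gridValues(sensorGrid(s)), seed = 8)
  p1 <- simulatePair(hr, s)
  p2 <- simulatePair(hr, s)
  expect_identical(cubeData(p1@intermediate), cubeData(p2@intermediate))
  expect_identical(snapshotImage(p1@snapshot), snapshotImage(p2@snapshot))
  expect_equal(dim(snapshotImage(p1@snapshot)), c(12L, 10L))
  expect_equal(dim(cubeData(p1@intermediate)), c(12L, 10L, 4L))
  expect_equal(dim(cubeData(p1@ideal)), c(12L, 10L, 3L))
  # snapshot pixels equal the intermediate cube at the assigned bands
  bm <- mosaicHSI:::patternBandMap(sensorPattern(s), 12L, 10L)
  for (x in c(1L, 5L, 12L)) for (y in c(1L, 7L, 10L)) {
    expect_identical(snapshotImage(p1@snapshot)[x, y],
                     cubeData(p1@intermediate)[x, y, bm[x, y]])
  }
})
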