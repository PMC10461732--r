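# Bilinear demosaicking and spectral correction.

test_that("splitBands partitions every pixel by sampled band", {
  pat <- mosaicPattern(4L)
  cube <- randomCube(8, 8, 16, 1:16, seed = 1, role = "intermediate")
  snap <- mosaicSubsample(cube, pat)
  sets <- splitBands(snap)
  expect_length(sets, 16L)
  expect_true(all(vapply(sets, nrow, integer(1L)) == 4L))
  keys <- unlist(lapply(sets, function(s) paste(s$x, s$y)))
  expect_equal(sort(keys), sort(paste(rep(1:8, times = 8), rep(1:8, each = 8))))
  # partial blocks: 6x6 frame, per-band counts from the index arithmetic
  cube6 <- randomCube(6, 6, 16, 1:16, seed = 2, role = "intermediate")
  sets6 <- splitBands(mosaicSubsample(cube6, pat))
  counts <- vapply(sets6, nrow, integer(1L))
  expect_equal(sum(counts), 36L)
  a <- patternAssignment(pat)
  oracle <- vapply(1:16, function(b) {
    cell <- which(a == b, arr.ind = TRUE)
    length(seq(cell[1L], 6L, by = 4L)) * length(seq(cell[2L], 6L, by = 4L))
  }, integer(1L))
  expect_equal(counts, oracle)
})

test_that("bilinear demosaicking reproduces constants exactly and samples bit-exactly", {
  pat <- mosaicPattern(4L)
  d <- array(rep(seq(0.2, 1.7, length.out = 16), each = 64), c(8, 8, 16))
  cube <- hypercube(d, 1:16, "intermediate")
  snap <- mosaicSubsample(cube, pat)
  rec <- bilinearDemosaick(snap)
  expect_equal(cubeData(rec), d, tolerance = 1e-14)
  # sample sites recovered bit-exactly on a random frame
  cubeR <- randomCube(11, 13, 16, 1:16, seed = 3, role = "intermediate")
  snapR <- mosaicSubsample(cubeR, pat)
  recR <- bilinearDemosaick(snapR)
  bm <- mosaicHSI:::patternBandMap(pat, 11L, 13L)
  for (x in seq_len(11L)) for (y in seq_len(13L)) {
    expect_identical(cubeData(recR)[x, y, bm[x, y]],
                     snapshotImage(snapR)[x, y])
  }
})

test_that("bilinear demosaicking recovers affine ramps in the lattice interior", {
  pat <- mosaicPattern(4L)
  X <- 16L; Y <- 16L
  ramp <- outer(seq_len(X), seq_len(Y),
                function(x, y) 0.5 + 0.03 * x + 0.011 * y)
  d <- array(ramp, c(X, Y, 16))
  snap <- mosaicSubsample(hypercube(d, 1:16, "intermediate"), pat)
  rec <- cubeData(bilinearDemosaick(snap))
  # interior: inside every band's outermost sample rows/cols
  interior <- 5:12
  for (b in 1:16) {
    expect_lt(max(abs(rec[interior, interior, b] - ramp[interior, interior])),
              1e-9)
  }
})

test_that("a single non-zero sample produces a tent of support 2n-1", {
  pat <- mosaicPattern(4L)
  img <- matrix(0, 16, 16)
  img[5, 9] <- 1   # a lattice point of the band at block cell (1, 1)
  snap <- snapshotMosaic(img, pat)
  rec <- cubeData(bilinearDemosaick(snap))
  b <- patternAssignment(pat)[1L, 1L]
  plane <- rec[, , b]
  nz <- which(plane > 1e-12, arr.ind = TRUE)
  expect_true(all(abs(nz[, 1L] - 5L) <= 3L))   # support 2n-1 = 7 wide
  expect_true(all(abs(nz[, 2L] - 9L) <= 3L))
  # direct interpolation oracle at an interior point between samples
  expect_equal(plane[6, 9], 0.75, tolerance = 1e-12)
  expect_equal(plane[7, 10], 0.5 * 0.75, tolerance = 1e-12)
})

test_that("reconstructed bands stay inside their sample range (convexity)", {
  pat <- mosaicPattern(4L)
  cube <- randomCube(12, 12, 16, 1:16, seed = 4, role = "intermediate")
  snap <- mosaicSubsample(cube, pat)
  rec <- cubeData(bilinearDemosaick(snap))
  sets <- splitBands(snap)
  for (b in 1:16) {
    expect_gte(min(rec[, , b]), min(sets[[b]]$value) - 1e-12)
    expect_lte(max(rec[, , b]), max(sets[[b]]$value) + 1e-12)
  }
})

test_that("degenerate frames smaller than the block still reconstruct", {
  pat <- mosaicPattern(4L)
  cube <- randomCube(3, 3, 16, 1:16, seed = 5, role = "intermediate")
  snap <- mosaicSubsample(cube, pat)
  rec <- bilinearDemosaick(snap)
  expect_equal(dim(cubeData(rec)), c(3L, 3L, 16L))
  expect_true(all(is.finite(cubeData(rec))))
})

test_that("applySpectralCorrection equals the per-pixel matrix product", {
  set.seed(6)
  cube <- randomCube(2, 2, 5, 1:5, seed = 6, role = "intermediate")
  C <- matrix(rnorm(15), 3, 5)
  out <- cubeData(applySpectralCorrection(cube, C))
  for (x in 1:2) for (y in 1:2) {
    expect_equal(out[x, y, ], as.numeric(C %*% cubeData(cube)[x, y, ]),
                 tolerance = 1e-12)
  }
  # identity and zero-row behaviour
  id <- applySpectralCorrection(cube, diag(5))
  expect_equal(cubeData(id), cubeData(cube), tolerance = 1e-14)
  Cz <- C; Cz[2L, ] <- 0
  outz <- cubeData(applySpectralCorrection(cube, Cz))
  expect_true(all(outz[, , 2L] == 0))
  expect_error(applySpectralCorrection(cube, matrix(0, 3, 4)))
})

test_that("linearPipeline composes interpolation and correction", {
  s <- tinySensor()
  # constant scene: output equals C applied to the per-band constants
  consts <- c(0.4, 0.9, 1.3, 0.7)
  d <- array(rep(consts, each = 36), c(6, 6, 4))
  snap <- mosaicSubsample(hypercube(d, 1:4, "intermediate"), sensorPattern(s))
  out <- linearPipeline(snap, s)
  expect_equal(dim(cubeData(out))[3L], 3L)
  expected <- as.numeric(calMatrix(calibration(s)) %*% consts)
  for (b in 1:3) {
    expect_equal(cubeData(out)[, , b], matrix(expected[b], 6, 6),
                 tolerance = 1e-12)
  }
  # random frame: matches the composed oracle
  cube <- randomCube(8, 8, 4, 1:4, seed = 7, role = "intermediate")
  snapR <- mosaicSubsample(cube, sensorPattern(s))
  lhs <- cubeData(linearPipeline(snapR, s))
  rhs <- cubeData(applySpectralCorrection(bilinearDemosaick(snapR),
                                          calibration(s)))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})
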