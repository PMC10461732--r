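# Sensor spectral model: Lorentzian bands and the correction matrix C.

# Independent oracle: locate the two half-maximum crossings of a band
# response by bracketed root finding on a dense grid.
halfMaxSeparation <- function(lambda0, qe, fwhm) {
  f <- function(l) {
    a <- lorentzianAlpha(lambda0, fwhm)
    qe * a * l^2 / ((l - lambda0)^2 + a * l^2)
  }
  g <- function(l) f(l) - qe / 2
  lo <- max(lambda0 - 10 * fwhm, 1e-3)
  hi <- lambda0 + 10 * fwhm
  left <- stats::uniroot(g, c(lo, lambda0), tol = 1e-12)$root
  right <- stats::uniroot(g, c(lambda0, hi), tol = 1e-12)$root
  right - left
}

test_that("lorentzianAlpha matches its closed form and the FWHM definition", {
  expect_equal(lorentzianAlpha(550, 15), 1.858813e-4, tolerance = 1e-5)
  # zero-width limit
  expect_lt(lorentzianAlpha(550, 1e-6), 1e-12)
  expect_error(lorentzianAlpha(-1, 10))
  expect_error(lorentzianAlpha(550, 0))
  set.seed(42)
  for (i in 1:10) {
    l0 <- runif(1, 450, 650)
    fw <- runif(1, 5, 30)
    qe <- runif(1, 0.2, 1)
    expect_equal(halfMaxSeparation(l0, qe, fw), fw, tolerance = 1e-6)
  }
})

test_that("lorentzianResponse peaks at lambda0 with value QE and stays in (0, QE]", {
  grid <- wavelengthGrid(seq(400, 1000, by = 1))
  f <- lorentzianResponse(grid, 550, 0.8, 15)
  expect_identical(f[gridValues(grid) == 550], 0.8)
  expect_true(all(f > 0))
  expect_true(all(f <= 0.8))
  expect_equal(sum(f == 0.8), 1L)  # attained only at lambda0
  expect_equal(gridValues(grid)[which.max(f)], 550)
  # off-grid centre: maximum at the nearest grid point
  g2 <- wavelengthGrid(seq(400, 700, by = 5))
  f2 <- lorentzianResponse(g2, 552, 0.9, 20)
  expect_equal(gridValues(g2)[which.max(f2)], 550)
})

test_that("the response is symmetric in the scaled variable (lambda-lambda0)/lambda", {
  l0 <- 550
  for (t in c(0.01, 0.05, 0.1)) {
    g <- wavelengthGrid(c(l0 / (1 + t), l0 / (1 - t)))
    f <- lorentzianResponse(g, l0, 0.7, 12)
    expect_equal(f[1L], f[2L], tolerance = 1e-12)
  }
})

test_that("buildResponseMatrix stacks Lorentzian rows in order", {
  grid <- wavelengthGrid(seq(400, 1000, by = 1))
  one <- buildResponseMatrix(grid, data.frame(lambda0 = 550, qe = 0.8, fwhm = 15))
  expect_equal(dim(responses(one)), c(1L, 601L))
  expect_equal(responses(one)[1L, ], lorentzianResponse(grid, 550, 0.8, 15))
  specs <- data.frame(lambda0 = seq(470, 620, length.out = 16),
                      qe = 0.8, fwhm = 12)
  m <- buildResponseMatrix(grid, specs)
  expect_equal(dim(responses(m)), c(16L, 601L))
  peaks <- gridValues(grid)[apply(responses(m), 1L, which.max)]
  nearest <- vapply(specs$lambda0, function(l)
    gridValues(grid)[which.min(abs(gridValues(grid) - l))], numeric(1L))
  expect_equal(peaks, nearest)
  dup <- buildResponseMatrix(grid, specs[c(1, 1), ])
  expect_identical(responses(dup)[1L, ], responses(dup)[2L, ])
  expect_error(buildResponseMatrix(grid, data.frame()))
})

test_that("synthesizeMeasuredResponses is identity at zero parasitics and seeded", {
  grid <- wavelengthGrid(seq(450, 650, by = 2))
  ideal <- buildResponseMatrix(grid, data.frame(lambda0 = c(500, 550, 600),
                                                qe = 0.8, fwhm = 12))
  same <- synthesizeMeasuredResponses(ideal, 0, 0, 0, seed = 1L)
  expect_identical(responses(same), responses(ideal))
  leaky <- synthesizeMeasuredResponses(ideal, leakage = 0.01, seed = 1L)
  r <- responses(leaky)
  for (b in seq_len(nrow(r))) expect_true(all(r[b, ] >= 0.01 * max(r[b, ])))
  a <- synthesizeMeasuredResponses(ideal, 0.05, 0.03, 0.01, seed = 7L)
  b <- synthesizeMeasuredResponses(ideal, 0.05, 0.03, 0.01, seed = 7L)
  expect_identical(responses(a), responses(b))
  expect_error(synthesizeMeasuredResponses(ideal, crosstalk = -0.1))
})

test_that("computeCalibrationMatrix solves the regularised least squares", {
  s <- tinySensor()
  ideal <- idealResponses(s)
  # measured = ideal, ridge 0 -> identity
  C0 <- calMatrix(computeCalibrationMatrix(ideal, ideal, ridge = 0))
  expect_equal(C0, diag(3), tolerance = 1e-8)
  # measured = 2 * ideal -> 0.5 * identity
  twice <- spectralResponseMatrix(2 * responses(ideal), ideal@grid)
  C2 <- calMatrix(computeCalibrationMatrix(twice, ideal, ridge = 0))
  expect_equal(C2, 0.5 * diag(3), tolerance = 1e-8)
  # ni x ns shape on the default sensor
  expect_equal(dim(calMatrix(calibration(defaultSensor()))), c(13L, 16L))
  # residual non-increasing as ridge -> 0
  M <- responses(measuredResponses(s))
  I <- responses(ideal)
  res <- vapply(c(1e-2, 1e-4, 0), function(r) {
    C <- calMatrix(computeCalibrationMatrix(measuredResponses(s), ideal, r))
    norm(C %*% M - I, "F")
  }, numeric(1L))
  expect_true(all(diff(res) <= 1e-10))
  expect_error(computeCalibrationMatrix(
    measuredResponses(s),
    spectralResponseMatrix(I[, 1:50], wavelengthGrid(seq(450, 548, by = 2)))))
})
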