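# Shared fixtures: a small fast sensor and cubes built in code.

# 2x2 mosaic (ns = 4), ni = 3, coarse grid: cheap enough for every test.
tinySensor <- function(seed = 11L, crosstalk = 0.05, harmonic = 0.02,
                       leakage = 0.01) {
  grid <- wavelengthGrid(seq(450, 650, by = 2))
  measuredSpecs <- data.frame(lambda0 = c(480, 520, 560, 600),
                              qe = c(0.8, 0.75, 0.85, 0.8),
                              fwhm = c(14, 12, 13, 15))
  idealSpecs <- data.frame(lambda0 = c(490, 540, 590),
                           qe = c(1, 1, 1), fwhm = c(10, 10, 10))
  makeSensorModel(grid, measuredSpecs, idealSpecs, mosaicPattern(2L),
                  parasitics = list(crosstalk = crosstalk,
                                    harmonic = harmonic,
                                    leakage = leakage, seed = seed),
                  name = "tiny-2x2")
}

randomCube <- function(X, Y, B, centers = seq(450, 650, length.out = B),
                       seed = 1L, role = "hr") {
  set.seed(seed)
  hypercube(array(runif(X * Y * B), c(X, Y, B)), centers, role)
}

# brute-force SSIM oracle: explicit loop over every valid 11x11 window
ssimBruteForce <- function(a, b, dynamicRange = 1) {
  g1 <- mosaicHSI:::gaussianWindow(11L, 1.5)
  Wg <- outer(g1, g1)
  C1 <- (0.01 * dynamicRange)^2
  C2 <- (0.03 * dynamicRange)^2
  vals <- c()
  for (i in seq_len(nrow(a) - 10L)) {
    for (j in seq_len(ncol(a) - 10L)) {
      wa <- a[i:(i + 10L), j:(j + 10L)]
      wb <- b[i:(i + 10L), j:(j + 10L)]
      mu1 <- sum(Wg * wa); mu2 <- sum(Wg * wb)
      s11 <- sum(Wg * wa^2) - mu1^2
      s22 <- sum(Wg * wb^2) - mu2^2
      s12 <- sum(Wg * wa * wb) - mu1 * mu2
      vals <- c(vals, ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
                  ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)))
    }
  }
  mean(vals)
}

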