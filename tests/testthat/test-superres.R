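# Residual U-Net: construction, loss algebra, gradients, training descent.

test_that("the network maps shapes correctly and builds deterministically", {
  cfg <- networkConfig(channels = 4, depth = 2, blocks = 1, width = 4,
                       seed = 9)
  n1 <- buildNetwork(cfg)
  n2 <- buildNetwork(cfg)
  expect_identical(n1$params, n2$params)
  x <- array(runif(16 * 16 * 4), c(16, 16, 4))
  y <- mosaicHSI:::netForwardArray(n1, x)
  expect_equal(dim(y), dim(x))
  # head is zero-initialised: the untrained network is the identity
  expect_identical(y, x)
  # depth-d bottleneck is 2^d smaller: non-multiple inputs are padded and
  # cropped transparently
  x2 <- array(runif(13 * 10 * 4), c(13, 10, 4))
  expect_equal(dim(mosaicHSI:::netForwardArray(n1, x2)), c(13L, 10L, 4L))
})

test_that("totalLoss follows the corrected-main plus weighted-auxiliary form", {
  # 1x1x2 toy: yi = 1, C = [0.5 0.5], yhat = (0,0), ys = yhat -> loss 1
  batch <- list(yhat = array(0, c(1, 1, 2)), ys = array(0, c(1, 1, 2)),
                yi = array(1, c(1, 1, 1)), C = matrix(c(0.5, 0.5), 1, 2))
  expect_equal(as.numeric(totalLoss(batch, lossConfig("l1", gamma = 0.001))), 1)
  # zero loss when yhat = ys and C yhat = yi
  ys <- array(runif(8), c(2, 2, 2))
  C <- matrix(c(0.3, 0.7, 0.5, 0.5), 2, 2, byrow = TRUE)
  yi <- array(t(apply(matrix(ys, 4, 2), 1L, function(v) C %*% v)), c(2, 2, 2))
  yi <- array(matrix(ys, 4, 2) %*% t(C), c(2, 2, 2))
  b2 <- list(yhat = ys, ys = ys, yi = yi, C = C)
  expect_equal(as.numeric(totalLoss(b2, lossConfig("l1"))), 0, tolerance = 1e-14)
  # gamma = 0 reduces to the main term
  b3 <- list(yhat = ys * 0.9, ys = ys, yi = yi, C = C)
  l0 <- totalLoss(b3, lossConfig("l1", gamma = 0))
  expect_equal(as.numeric(l0), attr(l0, "main"))
  # perceptual decomposition: total(gamma) - total(0) = gamma * aux, exactly
  lc <- lossConfig("perceptual", gamma = 0.25)
  lp <- totalLoss(b3, lc)
  lz <- totalLoss(b3, lossConfig("perceptual", gamma = 0,
                                 extractor = lc$extractor))
  expect_equal(as.numeric(lp) - as.numeric(lz), 0.25 * attr(lp, "aux"),
               tolerance = 1e-12)
  expect_error(lossConfig("l1", gamma = -1))
})

test_that("backpropagation matches finite differences in both loss modes", {
  set.seed(14)
  cfg <- networkConfig(channels = 2, depth = 1, blocks = 1, width = 3,
                       seed = 5)
  net <- buildNetwork(cfg)
  x <- array(runif(8 * 8 * 2), c(8, 8, 2))
  ys <- array(runif(8 * 8 * 2), c(8, 8, 2))
  C <- matrix(runif(4), 2, 2)
  yi <- array(runif(8 * 8 * 2), c(8, 8, 2))
  for (mode in c("l1", "perceptual")) {
    lcfg <- lossConfig(mode, gamma = 0.05)
    lossOf <- function(p) {
      fw <- mosaicHSI:::nnForward(p, x, 1, 1)
      mosaicHSI:::lossAndGrad(fw$y, ys, yi, C, lcfg, wantGrad = FALSE)$loss
    }
    fw <- mosaicHSI:::nnForward(net$params, x, 1, 1)
    lg <- mosaicHSI:::lossAndGrad(fw$y, ys, yi, C, lcfg, wantGrad = TRUE)
    grads <- mosaicHSI:::nnBackward(net$params, fw$cache, lg$grad, 1, 1,
                                    mosaicHSI:::nnZeroGrads(net$params))
    eps <- 1e-6
    for (nm in c("stem", "enc1_down", "dec1_merge", "head")) {
      i <- sample(length(net$params[[nm]]$W), 1L)
      p2 <- net$params; p2[[nm]]$W[i] <- p2[[nm]]$W[i] + eps
      p3 <- net$params; p3[[nm]]$W[i] <- p3[[nm]]$W[i] - eps
      fd <- (lossOf(p2) - lossOf(p3)) / (2 * eps)
      expect_equal(grads[[nm]]$W[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("training descends on a single sample and is seed-reproducible", {
  s <- tinySensor()
  sp <- phantomSpec(dim = c(16L, 16L), nd = 40L, range = c(460, 640),
                    nMaterials = 3L, nVessels = 2L, noise = 0, seed = 21L)
  pair <- simulatePair(makePhantomHypercube(sp), s)
  netCfg <- networkConfig(channels = 4, depth = 1, blocks = 1, width = 6,
                          seed = 2)
  tcfg <- trainConfig(patchSize = 16L, batchSize = 2L, iterations = 200L,
                      learningRate = 2e-3, augment = FALSE, evalEvery = 200L,
                      seed = 3L)
  tr <- trainDemosaicker(list(pair), list(pair), s, netCfg = netCfg,
                         tcfg = tcfg)
  init <- as.numeric(totalLoss(list(
    yhat = cubeData(bilinearDemosaick(pair@snapshot)),
    ys = cubeData(pair@intermediate), yi = cubeData(pair@ideal),
    C = calibration(s)), lossConfig("l1")))
  expect_lt(tr$history$trainLoss[nrow(tr$history)], init)
  expect_lt(tr$bestValLoss, init)
  # reproducibility: identical runs give identical histories
  tr2 <- trainDemosaicker(list(pair), list(pair), s, netCfg = netCfg,
                          tcfg = tcfg)
  expect_identical(tr$history, tr2$history)
})

test_that("inference applies C, preserves shape and is deterministic", {
  s <- tinySensor()
  cfg <- networkConfig(channels = 4, depth = 1, blocks = 1, width = 4,
                       seed = 1)
  net <- buildNetwork(cfg)
  cube <- randomCube(10, 12, 4, 1:4, seed = 9, role = "intermediate")
  out1 <- inferRefined(net, cube, s)
  out2 <- inferRefined(net, cube, s)
  expect_identical(cubeData(out1), cubeData(out2))
  expect_equal(dim(cubeData(out1)), c(10L, 12L, 3L))
  # zero-initialised head: inference equals C applied to the input
  expect_equal(cubeData(out1),
               cubeData(applySpectralCorrection(cube, calibration(s),
                                                bandCenters = s@idealSpecs$lambda0)),
               tolerance = 1e-12)
  expect_error(inferRefined(net, randomCube(10, 12, 5, 1:5), s))
})

test_that("augmentation produces valid samples with unchanged band histograms", {
  x <- array(runif(12 * 12 * 3), c(12, 12, 3))
  r <- mosaicHSI:::rot90a(x, 1L)
  expect_equal(dim(r), c(12L, 12L, 3L))
  for (b in 1:3) expect_equal(sort(as.numeric(r[, , b])),
                              sort(as.numeric(x[, , b])))
  expect_identical(mosaicHSI:::rot90a(x, 4L), x)
})
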