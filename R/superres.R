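# Learned refinement: a residual U-Net maps the bilinearly demosaicked
# X x Y x ns cube to a sharper X x Y x ns cube; spectral correction with C
# is embedded after the network and inside the training loss.

#' Residual U-Net configuration
#'
#' The network takes and returns ns-channel images. It has a contracting
#' path of \code{depth} downsampling layers with \code{blocks} residual
#' blocks at each resolution, a symmetric expanding path with skip
#' connections, and a global residual connection (the network learns the
#' correction to its bilinear input, so an untrained network reproduces the
#' baseline). Channel width doubles per level from \code{width}, capped at
#' 8x.
#'
#' @param channels ns, the number of input/output bands
#' @param depth number of downsampling layers (>= 1; 4 at full scale, 2 in
#'   the desk-scale profile)
#' @param blocks residual blocks per resolution (default 2)
#' @param width base feature width
#' @param seed initialisation seed
#' @return a \code{NetworkConfig} list
#' @export
networkConfig <- function(channels = 16L, depth = 4L, blocks = 2L,
                          width = 32L, seed = 1L) {
  stopifnot(depth >= 1L, blocks >= 1L, width >= 1L, channels >= 1L)
  structure(list(channels = as.integer(channels), depth = as.integer(depth),
                 blocks = as.integer(blocks), width = as.integer(width),
                 seed = as.integer(seed)),
            class = "NetworkConfig")
}

#' Loss configuration
#'
#' The training loss is \code{mean|yi - C yhat| + gamma * aux}. In
#' \code{"l1"} mode the auxiliary term is \code{mean|ys - yhat|}; in
#' \code{"perceptual"} mode it is the mean squared distance between frozen
#' feature-extractor activations of \code{ys} and \code{yhat}, computed on
#' each band replicated to 3 channels and averaged over bands.
#'
#' @param mode "l1" or "perceptual"
#' @param gamma auxiliary weight (default 0.001)
#' @param extractor frozen feature extractor (see
#'   \code{\link{buildFeatureExtractor}}); only used in perceptual mode
#' @return a \code{LossConfig} list
#' @export
lossConfig <- function(mode = c("l1", "perceptual"), gamma = 0.001,
                       extractor = NULL) {
  mode <- match.arg(mode)
  if (gamma < 0) stop("gamma must be non-negative")
  if (mode == "perceptual" && is.null(extractor))
    extractor <- buildFeatureExtractor()
  structure(list(mode = mode, gamma = gamma, extractor = extractor),
            class = "LossConfig")
}

#' Training configuration
#'
#' @param patchSize square patch edge; aligned to the mosaic block and
#'   divisible by 2^depth (default 64, the desk-scale profile; 224 at full
#'   scale)
#' @param batchSize patches per iteration (default 3)
#' @param iterations optimisation steps (default 500, desk-scale)
#' @param learningRate Adam step size (default 1e-3, desk-scale; 1e-4 at
#'   full scale)
#' @param augment random flips and multiples-of-90-degree rotations
#' @param evalEvery validation-loss cadence in iterations
#' @param seed seed for patch sampling and augmentation
#' @return a \code{TrainConfig} list
#' @export
trainConfig <- function(patchSize = 64L, batchSize = 3L, iterations = 500L,
                        learningRate = 1e-3, augment = TRUE,
                        evalEvery = 50L, seed = 1L) {
  stopifnot(patchSize >= 1L, batchSize >= 1L, iterations >= 1L,
            learningRate > 0)
  structure(list(patchSize = as.integer(patchSize),
                 batchSize = as.integer(batchSize),
                 iterations = as.integer(iterations),
                 learningRate = learningRate, augment = isTRUE(augment),
                 evalEvery = as.integer(evalEvery),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Build a residual U-Net
#'
#' @param cfg a \code{NetworkConfig}
#' @return a \code{DemosaicNet}: the callable model handle holding the
#'   parameter list and its configuration
#' @examples
#' net <- buildNetwork(networkConfig(channels = 4, depth = 1, width = 4))
#' @export
buildNetwork <- function(cfg) {
  params <- nnBuildParams(cfg$channels, cfg$depth, cfg$blocks, cfg$width,
                          cfg$seed)
  structure(list(params = params, config = cfg), class = "DemosaicNet")
}

#' @export
print.DemosaicNet <- function(x, ...) {
  np <- sum(vapply(x$params, function(l) length(l$W) + length(l$b),
                   numeric(1L)))
  cat(sprintf("DemosaicNet: %d channels, depth %d, %d res blocks/level, width %d, %d parameters\n",
              x$config$channels, x$config$depth, x$config$blocks,
              x$config$width, np))
  invisible(x)
}

# Raw network forward on an [H,W,ns] array (handles padding to 2^depth).
netForwardArray <- function(model, x, wantCache = FALSE) {
  m <- 2^model$config$depth
  pp <- nnPadToMultiple(x, m)
  fw <- nnForward(model$params, pp$x, model$config$depth, model$config$blocks)
  y <- fw$y[seq_len(pp$dims[1L]), seq_len(pp$dims[2L]), , drop = FALSE]
  if (wantCache) list(y = fw$y, yCropped = y, cache = fw$cache, pad = pp)
  else y
}

#' Fixed random convolutional feature extractor
#'
#' A frozen two-layer conv/ReLU stack with fixed-seed random weights, used
#' as the feature map for the perceptual auxiliary loss and as the default
#' extractor of \code{\link{perceptualScore}}. It is a synthetic stand-in
#' interface-compatible with pre-trained feature networks: random
#' convolutional features still expose local structure differences, but
#' scores are not comparable with published perceptual metrics.
#'
#' @param channels input channels (3; inputs are band-replicated grayscale)
#' @param width feature channels per layer
#' @param seed weight seed
#' @return a \code{FeatureExtractor} (callable on [H,W,3] arrays)
#' @export
buildFeatureExtractor <- function(channels = 3L, width = 8L, seed = 909L) {
  withSeed(seed, {
    layers <- list(nnInitConv(channels, width), nnInitConv(width, width))
  })
  structure(list(layers = layers, channels = channels), class = "FeatureExtractor")
}

#' @export
print.FeatureExtractor <- function(x, ...) {
  cat(sprintf("FeatureExtractor: frozen random conv stack, %d layers\n",
              length(x$layers)))
  invisible(x)
}

#' Default feature extractor for perceptual scoring
#'
#' @return a function mapping an [H,W,3] image array to its feature array
#' @export
defaultFeatureExtractor <- function() {
  fe <- buildFeatureExtractor()
  function(img) feForward(fe, img)$y
}

feForward <- function(fe, x) {
  c1 <- nnConvForward(x, fe$layers[[1L]]$W, fe$layers[[1L]]$b)
  a1 <- nnRelu(c1$y)
  c2 <- nnConvForward(a1, fe$layers[[2L]]$W, fe$layers[[2L]]$b)
  list(y = nnRelu(c2$y), c1 = c1, c2 = c2)
}

# Gradient of sum(dY * features) wrt the extractor input.
feBackward <- function(fe, fw, dY) {
  d2 <- nnReluBackward(fw$c2$y, dY)
  b2 <- nnConvBackward(fw$c2, d2, fe$layers[[2L]]$W)
  d1 <- nnReluBackward(fw$c1$y, b2$dx)
  nnConvBackward(fw$c1, d1, fe$layers[[1L]]$W)$dx
}

replicate3 <- function(band2d) {
  array(band2d, c(nrow(band2d), ncol(band2d), 3L))
}

# Loss and its gradient wrt yhat. yhat/ys: [H,W,ns]; yi: [H,W,ni]; C ni x ns.
lossAndGrad <- function(yhat, ys, yi, C, lcfg, wantGrad = TRUE) {
  d <- dim(yhat)
  HW <- d[1L] * d[2L]
  corr <- matrix(yhat, HW, d[3L]) %*% t(C)
  r <- matrix(yi, HW, ncol(corr)) - corr
  main <- mean(abs(r))
  gradMain <- NULL
  if (wantGrad) {
    gradMain <- array(-(sign(r) %*% C) / length(r), d)
  }
  aux <- 0
  gradAux <- NULL
  if (lcfg$gamma > 0 || !wantGrad) {
    if (lcfg$mode == "l1") {
      aux <- mean(abs(ys - yhat))
      if (wantGrad) gradAux <- -sign(ys - yhat) / length(ys)
    } else {
      fe <- lcfg$extractor
      gradAux <- if (wantGrad) array(0, d) else NULL
      for (b in seq_len(d[3L])) {
        fwS <- feForward(fe, replicate3(ys[, , b]))
        fwH <- feForward(fe, replicate3(yhat[, , b]))
        g <- fwH$y - fwS$y
        aux <- aux + mean(g^2)
        if (wantGrad) {
          dIn <- feBackward(fe, fwH, 2 * g / (length(g) * d[3L]))
          gradAux[, , b] <- gradAux[, , b] + dIn[, , 1L] + dIn[, , 2L] +
            dIn[, , 3L]
        }
      }
      aux <- aux / d[3L]
    }
  }
  total <- main + lcfg$gamma * aux
  grad <- NULL
  if (wantGrad) {
    grad <- gradMain
    if (lcfg$gamma > 0 && !is.null(gradAux)) grad <- grad + lcfg$gamma * gradAux
  }
  list(loss = total, main = main, aux = aux, grad = grad)
}

#' Combined demosaicking training loss
#'
#' \code{mean|yi - C yhat| + gamma * aux}: the main term penalises the
#' spectrally corrected network output against the ideal hypercube; the
#' auxiliary term supervises the raw output against the intermediate
#' hypercube (L1, or frozen-feature mean squared distance in perceptual
#' mode). Zero exactly when both terms vanish.
#'
#' @param batch list with elements \code{yhat} (network output, [H,W,ns]
#'   array or ns-band Hypercube), \code{ys} (intermediate target),
#'   \code{yi} (ideal target, ni bands), \code{C} (ni x ns matrix or
#'   \linkS4class{CalibrationMatrix})
#' @param lcfg a \code{LossConfig}
#' @return non-negative scalar with attributes \code{"main"} and
#'   \code{"aux"} (the two unweighted terms)
#' @export
totalLoss <- function(batch, lcfg = lossConfig()) {
  yhat <- asArray(batch$yhat)
  ys <- asArray(batch$ys)
  yi <- asArray(batch$yi)
  C <- if (is(batch$C, "CalibrationMatrix")) calMatrix(batch$C) else rbind(batch$C)
  stopifnot(all(dim(yhat) == dim(ys)),
            all(dim(yi)[1:2] == dim(yhat)[1:2]),
            ncol(C) == dim(yhat)[3L], nrow(C) == dim(yi)[3L])
  res <- lossAndGrad(yhat, ys, yi, C, lcfg, wantGrad = FALSE)
  structure(res$loss, main = res$main, aux = res$aux)
}

rot90a <- function(x, k) {
  k <- k %% 4L
  if (k == 0L) return(x)
  for (i in seq_len(k)) {
    x <- aperm(x, c(2L, 1L, 3L))
    x <- x[rev(seq_len(dim(x)[1L])), , , drop = FALSE]
  }
  x
}

augmentTriplet <- function(inp, ys, yi) {
  if (stats::runif(1L) < 0.5) {
    inp <- inp[rev(seq_len(dim(inp)[1L])), , , drop = FALSE]
    ys <- ys[rev(seq_len(dim(ys)[1L])), , , drop = FALSE]
    yi <- yi[rev(seq_len(dim(yi)[1L])), , , drop = FALSE]
  }
  if (stats::runif(1L) < 0.5) {
    inp <- inp[, rev(seq_len(dim(inp)[2L])), , drop = FALSE]
    ys <- ys[, rev(seq_len(dim(ys)[2L])), , drop = FALSE]
    yi <- yi[, rev(seq_len(dim(yi)[2L])), , drop = FALSE]
  }
  k <- sample(0:3, 1L)
  list(inp = rot90a(inp, k), ys = rot90a(ys, k), yi = rot90a(yi, k))
}

# Precompute (bilinear input, ys, yi) arrays for a list of PairedSamples.
prepareSamples <- function(samples, sensor) {
  C <- calMatrix(calibration(sensor))
  lapply(samples, function(s) {
    list(inp = cubeData(bilinearDemosaick(s@snapshot)),
         ys = cubeData(s@intermediate),
         yi = cubeData(s@ideal))
  })
}

#' Train the residual U-Net demosaicker
#'
#' Minimises \code{\link{totalLoss}} with Adam over random mosaic-aligned
#' patches of the training samples' bilinear reconstructions, with optional
#' flip/rotation augmentation. The validation loss is evaluated on full
#' frames every \code{evalEvery} iterations and the parameters with the
#' lowest validation loss are returned. Aborts with a diagnostic if the
#' loss becomes non-finite.
#'
#' @param train,validation lists of \linkS4class{PairedSample}
#' @param sensor the \linkS4class{SensorModel} (provides C and the mosaic n)
#' @param netCfg a \code{NetworkConfig} (channels must equal ns)
#' @param lcfg a \code{LossConfig}
#' @param tcfg a \code{TrainConfig}
#' @param verbose print progress every evaluation
#' @return a \code{TrainedDemosaicker}: list with the best \code{model},
#'   \code{history} data.frame (iter, trainLoss, valLoss) and
#'   \code{bestValLoss}
#' @export
trainDemosaicker <- function(train, validation, sensor,
                             netCfg = NULL, lcfg = lossConfig(),
                             tcfg = trainConfig(), verbose = FALSE) {
  if (length(train) < 1L || length(validation) < 1L)
    stop("need at least one training and one validation sample")
  ns <- nrow(responses(measuredResponses(sensor)))
  if (is.null(netCfg)) netCfg <- networkConfig(channels = ns, depth = 2L,
                                               blocks = 1L, width = 16L)
  if (netCfg$channels != ns) stop("network channels must equal ns")
  n <- sensorPattern(sensor)@n
  ps <- tcfg$patchSize
  if (ps %% n != 0L || ps %% 2L^netCfg$depth != 0L)
    stop("patchSize must be a multiple of the mosaic n and of 2^depth")
  C <- calMatrix(calibration(sensor))
  trainPrep <- prepareSamples(train, sensor)
  valPrep <- prepareSamples(validation, sensor)
  model <- buildNetwork(netCfg)
  state <- nnAdamInit(model$params)
  valLoss <- function(p) {
    model2 <- model; model2$params <- p
    mean(vapply(valPrep, function(s) {
      yhat <- netForwardArray(model2, s$inp)
      lossAndGrad(yhat, s$ys, s$yi, C, lcfg, wantGrad = FALSE)$loss
    }, numeric(1L)))
  }
  history <- data.frame(iter = integer(), trainLoss = numeric(),
                        valLoss = numeric())
  best <- list(params = model$params, val = valLoss(model$params))
  withSeed(tcfg$seed, {
    runningLoss <- NA_real_
    for (it in seq_len(tcfg$iterations)) {
      grads <- nnZeroGrads(model$params)
      batchLoss <- 0
      for (bi in seq_len(tcfg$batchSize)) {
        s <- trainPrep[[sample.int(length(trainPrep), 1L)]]
        d <- dim(s$inp)
        maxX <- d[1L] - ps
        maxY <- d[2L] - ps
        # top-left corners aligned to the mosaic block so patch phase
        # statistics match full frames
        x0 <- if (maxX > 0L) sample.int(maxX %/% n + 1L, 1L) * n - n else 0L
        y0 <- if (maxY > 0L) sample.int(maxY %/% n + 1L, 1L) * n - n else 0L
        xr <- (x0 + 1L):(x0 + ps)
        yr <- (y0 + 1L):(y0 + ps)
        inp <- s$inp[xr, yr, , drop = FALSE]
        ysP <- s$ys[xr, yr, , drop = FALSE]
        yiP <- s$yi[xr, yr, , drop = FALSE]
        if (tcfg$augment) {
          aug <- augmentTriplet(inp, ysP, yiP)
          inp <- aug$inp; ysP <- aug$ys; yiP <- aug$yi
        }
        fw <- nnForward(model$params, inp, netCfg$depth, netCfg$blocks)
        lg <- lossAndGrad(fw$y, ysP, yiP, C, lcfg, wantGrad = TRUE)
        if (!is.finite(lg$loss))
          stop(sprintf("non-finite loss at iteration %d; try a lower learning rate", it))
        batchLoss <- batchLoss + lg$loss
        grads <- nnBackward(model$params, fw$cache, lg$grad / tcfg$batchSize,
                            netCfg$depth, netCfg$blocks, grads)
      }
      batchLoss <- batchLoss / tcfg$batchSize
      runningLoss <- if (is.na(runningLoss)) batchLoss
                     else 0.9 * runningLoss + 0.1 * batchLoss
      upd <- nnAdamStep(model$params, grads, state, tcfg$learningRate)
      model$params <- upd$p
      state <- upd$state
      if (it %% tcfg$evalEvery == 0L || it == tcfg$iterations) {
        vl <- valLoss(model$params)
        history <- rbind(history, data.frame(iter = it,
                                             trainLoss = runningLoss,
                                             valLoss = vl))
        if (vl < best$val) best <- list(params = model$params, val = vl)
        if (verbose)
          message(sprintf("iter %d: train %.5f, val %.5f", it, runningLoss, vl))
      }
    }
  })
  model$params <- best$params
  structure(list(model = model, history = history, bestValLoss = best$val,
                 lossConfig = lcfg, trainConfig = tcfg,
                 sensorName = sensor@name),
            class = "TrainedDemosaicker")
}

#' @export
print.TrainedDemosaicker <- function(x, ...) {
  cat(sprintf("TrainedDemosaicker (%s loss): best val loss %.5f after %d iterations\n",
              x$lossConfig$mode, x$bestValLoss, x$trainConfig$iterations))
  invisible(x)
}

#' Learned demosaicking inference
#'
#' Runs the trained residual U-Net on a bilinearly demosaicked ns-band cube
#' (padding to the network's stride hidden from the caller) and applies the
#' sensor's spectral correction, returning the ni-band ideal-space cube.
#' Deterministic: repeated calls give identical output.
#'
#' @param trained a \code{TrainedDemosaicker} (or bare \code{DemosaicNet})
#' @param cube ns-band \linkS4class{Hypercube} (the bilinear reconstruction)
#' @param sensor the \linkS4class{SensorModel}
#' @return an ni-band \linkS4class{Hypercube} (role "ideal")
#' @export
inferRefined <- function(trained, cube, sensor) {
  model <- if (inherits(trained, "TrainedDemosaicker")) trained$model else trained
  d <- cubeData(cube)
  if (dim(d)[3L] != model$config$channels)
    stop("cube band count does not match network channels")
  y <- netForwardArray(model, d)
  refined <- hypercube(y, bandCenters(cube), "intermediate")
  applySpectralCorrection(refined, calibration(sensor),
                          bandCenters = sensor@idealSpecs$lambda0)
}

#' Full learned pipeline: snapshot to ideal-space cube
#'
#' Bilinear demosaicking followed by the trained refinement network and
#' spectral correction; the learned counterpart of
#' \code{\link{linearPipeline}}.
#'
#' @param snapshot a \linkS4class{SnapshotMosaic}
#' @param trained a \code{TrainedDemosaicker}
#' @param sensor the \linkS4class{SensorModel}
#' @return an ni-band \linkS4class{Hypercube}
#' @export
learnedPipeline <- function(snapshot, trained, sensor) {
  inferRefined(trained, bilinearDemosaick(snapshot), sensor)
}
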