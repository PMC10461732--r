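# Minimal convolutional-network engine used by the residual U-Net
# super-resolver: 3x3 same-padding convolutions via cached im2col indexing
# and BLAS matrix products, 2x average pooling, nearest-neighbour
# upsampling, ReLU, hand-derived backpropagation and an Adam optimiser.
# Tensors are arrays [H, W, C]; a convolution's weights are a
# (9*Cin) x Cout matrix with row order (di, dj, c), di fastest.

.nnIndexCache <- new.env(parent = emptyenv())

# im2col gather indices into the zero-padded (H+2)x(W+2)xC array for a 3x3
# kernel; cached per shape because building them dominates small-conv cost.
nnIm2colIndex <- function(H, W, C) {
  key <- paste(H, W, C, sep = "x")
  idx <- .nnIndexCache[[key]]
  if (!is.null(idx)) return(idx)
  Hp <- H + 2L
  Wp <- W + 2L
  iv <- rep(seq_len(H), times = W)
  jv <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L * C)
  for (c in seq_len(C)) {
    base <- (c - 1L) * Hp * Wp
    for (dj in 1:3) {
      for (di in 1:3) {
        col <- di + 3L * (dj - 1L) + 9L * (c - 1L)
        idx[, col] <- (iv + di - 1L) + (jv + dj - 2L) * Hp + base
      }
    }
  }
  .nnIndexCache[[key]] <- idx
  idx
}

nnPad1 <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1L] + 2L, d[2L] + 2L, d[3L]))
  xp[2:(d[1L] + 1L), 2:(d[2L] + 1L), ] <- x
  xp
}

nnConvForward <- function(x, W, b) {
  d <- dim(x)
  idx <- nnIm2colIndex(d[1L], d[2L], d[3L])
  M <- nnPad1(x)[idx]
  dim(M) <- c(d[1L] * d[2L], 9L * d[3L])
  y <- M %*% W + rep(b, each = d[1L] * d[2L])
  dim(y) <- c(d[1L], d[2L], ncol(W))
  list(y = y, M = M, dims = d)
}

nnConvBackward <- function(cache, dY, W) {
  d <- cache$dims
  HW <- d[1L] * d[2L]
  cout <- ncol(W)
  dYm <- dY
  dim(dYm) <- c(HW, cout)
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  # input gradient of a same-padded 3x3 conv = same-padded 3x3 conv of dY
  # with the 180-degree-rotated kernel, in/out channels swapped
  Wa <- W
  dim(Wa) <- c(3L, 3L, d[3L], cout)
  Wrot <- aperm(Wa[3:1, 3:1, , , drop = FALSE], c(1L, 2L, 4L, 3L))
  dim(Wrot) <- c(9L * cout, d[3L])
  idx2 <- nnIm2colIndex(d[1L], d[2L], cout)
  dYa <- dY
  dim(dYa) <- c(d[1L], d[2L], cout)
  Mb <- nnPad1(dYa)[idx2]
  dim(Mb) <- c(HW, 9L * cout)
  dx <- Mb %*% Wrot
  dim(dx) <- c(d[1L], d[2L], d[3L])
  list(dx = dx, dW = dW, db = db)
}

nnRelu <- function(x) x * (x > 0)
nnReluBackward <- function(pre, d) d * (pre > 0)

nnAvgPool2 <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[1L], by = 2L)
  o2 <- seq(1L, d[2L], by = 2L)
  (x[o1, o2, , drop = FALSE] + x[o1 + 1L, o2, , drop = FALSE] +
     x[o1, o2 + 1L, , drop = FALSE] + x[o1 + 1L, o2 + 1L, , drop = FALSE]) / 4
}

nnAvgPool2Backward <- function(dy, dims) {
  dx <- array(0, dims)
  o1 <- seq(1L, dims[1L], by = 2L)
  o2 <- seq(1L, dims[2L], by = 2L)
  q <- dy / 4
  dx[o1, o2, ] <- q
  dx[o1 + 1L, o2, ] <- q
  dx[o1, o2 + 1L, ] <- q
  dx[o1 + 1L, o2 + 1L, ] <- q
  dx
}

nnUp2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), ,
    drop = FALSE]
}

nnUp2Backward <- function(dy) {
  d <- dim(dy)
  o1 <- seq(1L, d[1L], by = 2L)
  o2 <- seq(1L, d[2L], by = 2L)
  dy[o1, o2, , drop = FALSE] + dy[o1 + 1L, o2, , drop = FALSE] +
    dy[o1, o2 + 1L, , drop = FALSE] + dy[o1 + 1L, o2 + 1L, , drop = FALSE]
}

nnInitConv <- function(cin, cout, zero = FALSE) {
  if (zero) {
    W <- matrix(0, 9L * cin, cout)
  } else {
    W <- matrix(stats::rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))),
                9L * cin, cout)
  }
  list(W = W, b = numeric(cout))
}

# channel width at pyramid level l (0-based); doubling capped at 8x base
nnLevelWidth <- function(base, l) base * 2^min(l, 3L)

# Parameter layout of the residual U-Net (named flat list of conv layers).
nnBuildParams <- function(channels, depth, blocks, width, seed) {
  withSeed(seed, {
    p <- list()
    p[["stem"]] <- nnInitConv(channels, width)
    for (r in seq_len(blocks)) {
      p[[sprintf("enc0_res%d_c1", r)]] <- nnInitConv(width, width)
      p[[sprintf("enc0_res%d_c2", r)]] <- nnInitConv(width, width)
    }
    for (l in seq_len(depth)) {
      wIn <- nnLevelWidth(width, l - 1L)
      wOut <- nnLevelWidth(width, l)
      p[[sprintf("enc%d_down", l)]] <- nnInitConv(wIn, wOut)
      for (r in seq_len(blocks)) {
        p[[sprintf("enc%d_res%d_c1", l, r)]] <- nnInitConv(wOut, wOut)
        p[[sprintf("enc%d_res%d_c2", l, r)]] <- nnInitConv(wOut, wOut)
      }
    }
    for (l in rev(seq_len(depth))) {
      wHi <- nnLevelWidth(width, l)
      wLo <- nnLevelWidth(width, l - 1L)
      p[[sprintf("dec%d_up", l)]] <- nnInitConv(wHi, wLo)
      p[[sprintf("dec%d_merge", l)]] <- nnInitConv(2L * wLo, wLo)
      for (r in seq_len(blocks)) {
        p[[sprintf("dec%d_res%d_c1", l, r)]] <- nnInitConv(wLo, wLo)
        p[[sprintf("dec%d_res%d_c2", l, r)]] <- nnInitConv(wLo, wLo)
      }
    }
    p[["head"]] <- nnInitConv(width, channels, zero = TRUE)
    p
  })
}

nnResForward <- function(p, prefix, r, h) {
  c1 <- p[[sprintf("%s_res%d_c1", prefix, r)]]
  c2 <- p[[sprintf("%s_res%d_c2", prefix, r)]]
  f1 <- nnConvForward(h, c1$W, c1$b)
  a1 <- nnRelu(f1$y)
  f2 <- nnConvForward(a1, c2$W, c2$b)
  s <- h + f2$y
  list(y = nnRelu(s), cache = list(f1 = f1, pre1 = f1$y, f2 = f2, s = s))
}

nnResBackward <- function(p, prefix, r, cache, dy, grads) {
  c1n <- sprintf("%s_res%d_c1", prefix, r)
  c2n <- sprintf("%s_res%d_c2", prefix, r)
  ds <- nnReluBackward(cache$s, dy)
  b2 <- nnConvBackward(cache$f2, ds, p[[c2n]]$W)
  grads[[c2n]]$W <- grads[[c2n]]$W + b2$dW
  grads[[c2n]]$b <- grads[[c2n]]$b + b2$db
  da1 <- nnReluBackward(cache$pre1, b2$dx)
  b1 <- nnConvBackward(cache$f1, da1, p[[c1n]]$W)
  grads[[c1n]]$W <- grads[[c1n]]$W + b1$dW
  grads[[c1n]]$b <- grads[[c1n]]$b + b1$db
  list(dx = ds + b1$dx, grads = grads)
}

# Forward pass; returns network output (with the global residual added) and
# the cache needed for backprop.
nnForward <- function(p, x, depth, blocks) {
  cache <- list()
  st <- nnConvForward(x, p$stem$W, p$stem$b)
  h <- nnRelu(st$y)
  cache$stem <- st
  cache$enc0res <- vector("list", blocks)
  for (r in seq_len(blocks)) {
    rr <- nnResForward(p, "enc0", r, h)
    cache$enc0res[[r]] <- rr$cache
    h <- rr$y
  }
  skips <- vector("list", depth)   # skips[[l]] feeds decoder level l
  cache$enc <- vector("list", depth)
  for (l in seq_len(depth)) {
    skips[[l]] <- h
    pooled <- nnAvgPool2(h)
    dn <- nnConvForward(pooled, p[[sprintf("enc%d_down", l)]]$W,
                        p[[sprintf("enc%d_down", l)]]$b)
    h <- nnRelu(dn$y)
    enc <- list(prePoolDims = dim(skips[[l]]), down = dn, res = vector("list", blocks))
    for (r in seq_len(blocks)) {
      rr <- nnResForward(p, sprintf("enc%d", l), r, h)
      enc$res[[r]] <- rr$cache
      h <- rr$y
    }
    cache$enc[[l]] <- enc
  }
  cache$dec <- vector("list", depth)
  for (l in rev(seq_len(depth))) {
    up <- nnUp2(h)
    uc <- nnConvForward(up, p[[sprintf("dec%d_up", l)]]$W,
                        p[[sprintf("dec%d_up", l)]]$b)
    ua <- nnRelu(uc$y)
    skip <- skips[[l]]
    cat3 <- array(c(ua, skip), c(dim(ua)[1L], dim(ua)[2L],
                                 dim(ua)[3L] + dim(skip)[3L]))
    mc <- nnConvForward(cat3, p[[sprintf("dec%d_merge", l)]]$W,
                        p[[sprintf("dec%d_merge", l)]]$b)
    h <- nnRelu(mc$y)
    dec <- list(upConv = uc, preUp = uc$y, merge = mc, preMerge = mc$y,
                upChannels = dim(ua)[3L], res = vector("list", blocks))
    for (r in seq_len(blocks)) {
      rr <- nnResForward(p, sprintf("dec%d", l), r, h)
      dec$res[[r]] <- rr$cache
      h <- rr$y
    }
    cache$dec[[l]] <- dec
  }
  hd <- nnConvForward(h, p$head$W, p$head$b)
  cache$head <- hd
  list(y = x + hd$y, cache = cache)
}

nnZeroGrads <- function(p) {
  lapply(p, function(layer) list(W = layer$W * 0, b = layer$b * 0))
}

# Backward pass: dLoss/dOutput -> parameter gradients (accumulated into
# `grads`). The input gradient is not needed (only parameters are trained).
nnBackward <- function(p, cache, dout, depth, blocks, grads) {
  hb <- nnConvBackward(cache$head, dout, p$head$W)
  grads$head$W <- grads$head$W + hb$dW
  grads$head$b <- grads$head$b + hb$db
  d <- hb$dx
  dskips <- vector("list", depth)
  for (l in seq_len(depth)) {
    dec <- cache$dec[[l]]
    for (r in rev(seq_len(blocks))) {
      rb <- nnResBackward(p, sprintf("dec%d", l), r, dec$res[[r]], d, grads)
      grads <- rb$grads
      d <- rb$dx
    }
    dm <- nnReluBackward(dec$preMerge, d)
    mb <- nnConvBackward(dec$merge, dm, p[[sprintf("dec%d_merge", l)]]$W)
    mn <- sprintf("dec%d_merge", l)
    grads[[mn]]$W <- grads[[mn]]$W + mb$dW
    grads[[mn]]$b <- grads[[mn]]$b + mb$db
    k <- dec$upChannels
    dua <- mb$dx[, , seq_len(k), drop = FALSE]
    dskips[[l]] <- mb$dx[, , (k + 1L):dim(mb$dx)[3L], drop = FALSE]
    du <- nnReluBackward(dec$preUp, dua)
    ub <- nnConvBackward(dec$upConv, du, p[[sprintf("dec%d_up", l)]]$W)
    un <- sprintf("dec%d_up", l)
    grads[[un]]$W <- grads[[un]]$W + ub$dW
    grads[[un]]$b <- grads[[un]]$b + ub$db
    d <- nnUp2Backward(ub$dx)
  }
  for (l in rev(seq_len(depth))) {
    enc <- cache$enc[[l]]
    for (r in rev(seq_len(blocks))) {
      rb <- nnResBackward(p, sprintf("enc%d", l), r, enc$res[[r]], d, grads)
      grads <- rb$grads
      d <- rb$dx
    }
    dd <- nnReluBackward(enc$down$y, d)
    db <- nnConvBackward(enc$down, dd, p[[sprintf("enc%d_down", l)]]$W)
    dn <- sprintf("enc%d_down", l)
    grads[[dn]]$W <- grads[[dn]]$W + db$dW
    grads[[dn]]$b <- grads[[dn]]$b + db$db
    d <- nnAvgPool2Backward(db$dx, enc$prePoolDims) + dskips[[l]]
  }
  for (r in rev(seq_len(blocks))) {
    rb <- nnResBackward(p, "enc0", r, cache$enc0res[[r]], d, grads)
    grads <- rb$grads
    d <- rb$dx
  }
  ds <- nnReluBackward(cache$stem$y, d)
  sb <- nnConvBackward(cache$stem, ds, p$stem$W)
  grads$stem$W <- grads$stem$W + sb$dW
  grads$stem$b <- grads$stem$b + sb$db
  grads
}

# Adam optimiser state + update (in place on the parameter list).
nnAdamInit <- function(p) {
  list(m = nnZeroGrads(p), v = nnZeroGrads(p), t = 0L)
}

nnAdamStep <- function(p, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(p)) {
    for (s in c("W", "b")) {
      g <- grads[[nm]][[s]]
      state$m[[nm]][[s]] <- beta1 * state$m[[nm]][[s]] + (1 - beta1) * g
      state$v[[nm]][[s]] <- beta2 * state$v[[nm]][[s]] + (1 - beta2) * g^2
      mh <- state$m[[nm]][[s]] / bc1
      vh <- state$v[[nm]][[s]] / bc2
      p[[nm]][[s]] <- p[[nm]][[s]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(p = p, state = state)
}

# Replicate-pad an [H,W,C] tensor on the bottom/right to multiples of m,
# returning the padded tensor and the original dims for cropping back.
nnPadToMultiple <- function(x, m) {
  d <- dim(x)
  H2 <- as.integer(ceiling(d[1L] / m) * m)
  W2 <- as.integer(ceiling(d[2L] / m) * m)
  if (H2 == d[1L] && W2 == d[2L]) return(list(x = x, dims = d))
  ri <- c(seq_len(d[1L]), rep(d[1L], H2 - d[1L]))
  ci <- c(seq_len(d[2L]), rep(d[2L], W2 - d[2L]))
  list(x = x[ri, ci, , drop = FALSE], dims = d)
}
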