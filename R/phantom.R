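# Synthetic tissue-like phantom hypercubes: smooth per-material reflectance
# spectra mixed by smooth spatial abundance maps, darkened by curvilinear
# vessel-like strokes, so the full simulate/demosaick/learn pipeline is
# testable without any external dataset.

#' Phantom specification
#'
#' Describes one family of white-balanced reflectance phantoms. Defaults
#' are the desk-scale study conditions: 64 x 64 pixels, 121 bands over
#' 420-680 nm (covering a visible-range 470-620 nm sensor with margin),
#' 4 materials with sum-of-Gaussians spectra, smoothed Voronoi regions,
#' 3 vessel strokes, and mild additive noise.
#'
#' @param dim spatial size c(X, Y)
#' @param nd number of spectral bands
#' @param range wavelength range c(min, max) in nm
#' @param nMaterials number of materials (>= 1)
#' @param nVessels number of vessel strokes (0 disables vessels)
#' @param vesselWidth stroke Gaussian half-width in pixels
#' @param vesselDepth peak fractional absorption of a stroke (in [0, 1))
#' @param mixSmooth Gaussian smoothing sigma (pixels) of the abundance maps
#' @param noise additive Gaussian noise sd (reflectance units; clipped at 0)
#' @param seed RNG seed; phantoms are bit-reproducible from (spec, seed)
#' @return a \code{PhantomSpec} list
#' @export
phantomSpec <- function(dim = c(64L, 64L), nd = 121L, range = c(420, 680),
                        nMaterials = 4L, nVessels = 3L, vesselWidth = 1.5,
                        vesselDepth = 0.6, mixSmooth = 4, noise = 0.002,
                        seed = 1L) {
  stopifnot(length(dim) == 2L, all(dim >= 1L), nd >= 2L,
            range[2L] > range[1L], nMaterials >= 1L, nVessels >= 0L,
            vesselWidth > 0, vesselDepth >= 0, vesselDepth < 1, noise >= 0)
  structure(list(dim = as.integer(dim), nd = as.integer(nd),
                 range = as.numeric(range), nMaterials = as.integer(nMaterials),
                 nVessels = as.integer(nVessels), vesselWidth = vesselWidth,
                 vesselDepth = vesselDepth, mixSmooth = mixSmooth,
                 noise = noise, seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' @export
print.PhantomSpec <- function(x, ...) {
  cat(sprintf("PhantomSpec: %dx%d px, %d bands %.0f-%.0f nm, %d materials, %d vessels, seed %d\n",
              x$dim[1L], x$dim[2L], x$nd, x$range[1L], x$range[2L],
              x$nMaterials, x$nVessels, x$seed))
  invisible(x)
}

phantomWavelengths <- function(spec) {
  seq(spec$range[1L], spec$range[2L], length.out = spec$nd)
}

# One smooth spectrum in [0.05, 0.95]: quadratic baseline plus 2-4 wide
# Gaussian bumps; widths >= 25 nm keep the discrete second difference small.
randomSpectrum <- function(lam) {
  t <- (lam - min(lam)) / diff(range(lam))
  s <- stats::runif(1L, 0.25, 0.55) + stats::runif(1L, -0.15, 0.15) * t +
    stats::runif(1L, -0.1, 0.1) * t^2
  for (g in seq_len(sample(2:4, 1L))) {
    amp <- stats::runif(1L, -0.2, 0.25)
    mu <- stats::runif(1L, min(lam), max(lam))
    sg <- stats::runif(1L, 25, 60)
    s <- s + amp * exp(-(lam - mu)^2 / (2 * sg^2))
  }
  pmin(pmax(s, 0.05), 0.95)
}

#' Sample per-material reflectance spectra
#'
#' Draws \code{nMaterials} smooth spectra in [0, 1] whose pairwise RMS
#' separation is at least 0.03 (redrawing deterministically until
#' distinct). Deterministic given the spec seed.
#'
#' @param spec a \code{PhantomSpec}
#' @return nMaterials x nd matrix of reflectances
#' @export
sampleMaterialSpectra <- function(spec) {
  lam <- phantomWavelengths(spec)
  withSeed(spec$seed, {
    S <- matrix(0, spec$nMaterials, spec$nd)
    for (m in seq_len(spec$nMaterials)) {
      for (try in seq_len(100L)) {
        cand <- randomSpectrum(lam)
        ok <- m == 1L || all(vapply(seq_len(m - 1L), function(j) {
          sqrt(mean((S[j, ] - cand)^2)) >= 0.03
        }, logical(1L)))
        if (ok) break
      }
      S[m, ] <- cand
    }
    S
  })
}

# Smooth per-material abundance maps summing to 1 at every pixel:
# Voronoi labels of random seed points, one-hot, Gaussian-smoothed,
# renormalised.
abundanceMaps <- function(spec) {
  X <- spec$dim[1L]; Y <- spec$dim[2L]; m <- spec$nMaterials
  if (m == 1L) return(array(1, c(X, Y, 1L)))
  npts <- m * 3L
  px <- stats::runif(npts, 1, X)
  py <- stats::runif(npts, 1, Y)
  lab <- c(seq_len(m), sample.int(m, npts - m, replace = TRUE))
  gx <- matrix(rep(seq_len(X), times = Y), X, Y)
  gy <- matrix(rep(seq_len(Y), each = X), X, Y)
  d2 <- array(Inf, c(X, Y))
  nearest <- array(1L, c(X, Y))
  for (p in seq_len(npts)) {
    dd <- (gx - px[p])^2 + (gy - py[p])^2
    upd <- dd < d2
    d2[upd] <- dd[upd]
    nearest[upd] <- lab[p]
  }
  A <- array(0, c(X, Y, m))
  for (k in seq_len(m)) {
    A[, , k] <- gaussianBlur((nearest == k) * 1, spec$mixSmooth)
  }
  tot <- apply(A, c(1L, 2L), sum)
  for (k in seq_len(m)) A[, , k] <- A[, , k] / tot
  A
}

# Binary-ish vessel stroke mask in [0,1]: random smooth curves rasterised
# with a Gaussian cross-section of width vesselWidth.
vesselMask <- function(spec) {
  X <- spec$dim[1L]; Y <- spec$dim[2L]
  mask <- matrix(0, X, Y)
  if (spec$nVessels == 0L) return(mask)
  gx <- matrix(rep(seq_len(X), times = Y), X, Y)
  gy <- matrix(rep(seq_len(Y), each = X), X, Y)
  for (v in seq_len(spec$nVessels)) {
    x <- stats::runif(1L, 1, X)
    y <- stats::runif(1L, 1, Y)
    ang <- stats::runif(1L, 0, 2 * pi)
    nsteps <- ceiling(1.5 * max(X, Y))
    for (s in seq_len(nsteps)) {
      ang <- ang + stats::rnorm(1L, 0, 0.15)
      x <- x + cos(ang)
      y <- y + sin(ang)
      if (x < -5 || x > X + 5 || y < -5 || y > Y + 5) break
      d2 <- (gx - x)^2 + (gy - y)^2
      near <- d2 < (4 * spec$vesselWidth)^2
      prof <- exp(-d2[near] / (2 * spec$vesselWidth^2))
      mask[near] <- pmax(mask[near], prof)
    }
  }
  mask
}

# Smooth absorption spectrum for the vessel strokes: broad band around
# 540 nm over a flat base (haemoglobin-like, not radiometrically calibrated).
vesselAbsorption <- function(lam) {
  0.25 + 0.75 * exp(-(lam - 540)^2 / (2 * 40^2))
}

#' Generate a phantom HR hypercube
#'
#' Per-pixel convex mixture of the material spectra weighted by smooth
#' abundance maps; vessel strokes darken the cube multiplicatively through
#' a smooth absorption profile; optional additive Gaussian noise, clipped
#' at 0. Bit-reproducible from the spec (all randomness flows from
#' \code{spec$seed}).
#'
#' @param spec a \code{PhantomSpec}
#' @return an HR \linkS4class{Hypercube}
#' @examples
#' hr <- makePhantomHypercube(phantomSpec(dim = c(32, 32), seed = 3))
#' @export
makePhantomHypercube <- function(spec) {
  if (spec$nMaterials < 1L) stop("at least one material is required")
  lam <- phantomWavelengths(spec)
  S <- sampleMaterialSpectra(spec)
  withSeed(spec$seed + 1L, {
    A <- abundanceMaps(spec)
    X <- spec$dim[1L]; Y <- spec$dim[2L]
    cube <- matrix(A, X * Y, spec$nMaterials) %*% S
    if (spec$nVessels > 0L) {
      vm <- as.vector(vesselMask(spec))
      att <- 1 - spec$vesselDepth * outer(vm, vesselAbsorption(lam))
      cube <- cube * att
    }
    if (spec$noise > 0) {
      cube <- cube + stats::rnorm(length(cube), 0, spec$noise)
    }
    cube <- pmax(cube, 0)
    hypercube(array(cube, c(X, Y, spec$nd)), lam, "hr")
  })
}

#' Generate a split phantom dataset of paired samples
#'
#' Draws \code{count} phantoms with per-image seeds derived from the spec
#' seed, runs each through \code{\link{simulatePair}}, and splits them
#' into disjoint train/validation/test sets. The returned manifest (also
#' written to \code{dir} when given) records the spec, per-image seeds and
#' split, so the dataset can be regenerated bit-identically.
#'
#' @param spec a \code{PhantomSpec} (its seed is the dataset root seed)
#' @param count number of phantoms
#' @param split fractions c(train, val, test), summing to 1
#' @param sensor a \linkS4class{SensorModel}
#' @param dir optional output directory for manifest.json (and ENVI cubes
#'   when \code{writeCubes} is TRUE)
#' @param writeCubes also write each HR phantom as an ENVI cube
#' @return list with elements \code{train}, \code{val}, \code{test} (lists
#'   of \linkS4class{PairedSample}) and \code{manifest}
#' @export
makeDataset <- function(spec, count, split = c(0.6, 0.2, 0.2),
                        sensor = defaultSensor(), dir = NULL,
                        writeCubes = FALSE) {
  stopifnot(count >= 1L, length(split) == 3L, all(split >= 0),
            abs(sum(split) - 1) < 1e-8)
  nTrain <- round(split[1L] * count)
  nVal <- round(split[2L] * count)
  nTest <- count - nTrain - nVal
  seeds <- vapply(seq_len(count), function(i) deriveSeed(spec$seed, i),
                  integer(1L))
  pairs <- vector("list", count)
  for (i in seq_len(count)) {
    si <- spec
    si$seed <- seeds[i]
    hr <- makePhantomHypercube(si)
    pairs[[i]] <- simulatePair(hr, sensor)
    if (isTRUE(writeCubes) && !is.null(dir)) {
      writeENVI(hr, file.path(dir, sprintf("phantom%03d.hdr", i)))
    }
  }
  assignSplit <- c(rep("train", nTrain), rep("val", nVal), rep("test", nTest))
  manifest <- list(schema = "phantom-dataset-1",
                   rootSeed = spec$seed, count = count,
                   seeds = seeds, split = assignSplit,
                   spec = unclass(spec), sensor = sensor@name)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(train = pairs[assignSplit == "train"],
       val = pairs[assignSplit == "val"],
       test = pairs[assignSplit == "test"],
       manifest = manifest)
}
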