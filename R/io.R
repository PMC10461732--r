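# Interchange formats: ENVI hypercubes (BSQ write; BSQ/BIL/BIP read),
# 16-bit TIFF snapshots with JSON sidecars, YAML sensor descriptions, and
# the end-to-end pipeline runner.

enviPaths <- function(path) {
  base <- sub("\\.hdr$", "", path)
  list(hdr = paste0(base, ".hdr"), raw = paste0(base, ".raw"))
}

#' Write a hypercube as an ENVI file pair
#'
#' Writes \code{<base>.hdr} (text header with the wavelength list) and
#' \code{<base>.raw} (float32 little-endian, BSQ interleave). Lossless up
#' to float32 precision.
#'
#' @param cube a \linkS4class{Hypercube}
#' @param path destination path (with or without \code{.hdr})
#' @return invisibly, the header path
#' @export
writeENVI <- function(cube, path) {
  p <- enviPaths(path)
  d <- cubeData(cube)
  X <- dim(d)[1L]; Y <- dim(d)[2L]; B <- dim(d)[3L]
  wl <- paste(sprintf("%.17g", bandCenters(cube)), collapse = ", ")
  hdr <- c("ENVI",
           "description = {mosaicHSI hypercube}",
           sprintf("samples = %d", Y),
           sprintf("lines = %d", X),
           sprintf("bands = %d", B),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           "interleave = bsq",
           "byte order = 0",
           sprintf("cube role = %s", cubeRole(cube)),
           sprintf("wavelength units = nm"),
           sprintf("wavelength = {%s}", wl))
  writeLines(hdr, p$hdr)
  con <- file(p$raw, "wb")
  on.exit(close(con))
  # BSQ: band by band, each band line-major (rows of the image)
  for (b in seq_len(B)) {
    writeBin(as.numeric(t(d[, , b])), con, size = 4L, endian = "little")
  }
  invisible(p$hdr)
}

parseEnviHeader <- function(hdrPath) {
  txt <- paste(readLines(hdrPath, warn = FALSE), collapse = "\n")
  fields <- list()
  lines <- strsplit(txt, "\n")[[1L]]
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (grepl("\\{", val) && !grepl("\\}", val)) {
        while (i < length(lines) && !grepl("\\}", val)) {
          i <- i + 1L
          val <- paste(val, trimws(lines[i]))
        }
      }
      fields[[tolower(key)]] <- val
    }
    i <- i + 1L
  }
  fields
}

#' Read an ENVI hypercube
#'
#' Supports BSQ, BIL and BIP interleaves, float32/float64 sample types,
#' little/big endian, and the \code{wavelength} header list.
#'
#' @param path the \code{.hdr} path (or base path)
#' @return a \linkS4class{Hypercube}
#' @export
readENVI <- function(path) {
  p <- enviPaths(path)
  if (!file.exists(p$hdr)) stop("ENVI header not found: ", p$hdr)
  h <- parseEnviHeader(p$hdr)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("ENVI header missing fields: ",
                         paste(miss, collapse = ", "))
  Y <- as.integer(h$samples)
  X <- as.integer(h$lines)
  B <- as.integer(h$bands)
  dtype <- as.integer(h[["data type"]])
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type: ", dtype))
  endian <- if (!is.null(h[["byte order"]]) && as.integer(h[["byte order"]]) == 1L)
    "big" else "little"
  rawFile <- p$raw
  if (!file.exists(rawFile)) {
    alt <- sub("\\.raw$", ".dat", rawFile)
    if (file.exists(alt)) rawFile <- alt else stop("ENVI data file not found: ", rawFile)
  }
  con <- file(rawFile, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = X * Y * B, size = size, endian = endian)
  if (length(v) != X * Y * B) stop("ENVI data file truncated")
  interleave <- tolower(trimws(h$interleave))
  cube <- switch(interleave,
    # bsq storage order (fastest first): samples, lines, bands
    bsq = aperm(array(v, c(Y, X, B)), c(2L, 1L, 3L)),
    # bil: samples, bands, lines
    bil = aperm(array(v, c(Y, B, X)), c(3L, 1L, 2L)),
    # bip: bands, samples, lines
    bip = aperm(array(v, c(B, Y, X)), c(3L, 2L, 1L)),
    stop("unsupported interleave: ", interleave))
  wl <- if (!is.null(h$wavelength)) {
    as.numeric(strsplit(gsub("[{}]", "", h$wavelength), ",")[[1L]])
  } else seq_len(B)
  role <- trimws(h[["cube role"]] %||% "hr")
  if (!role %in% c("hr", "intermediate", "ideal")) role <- "hr"
  hypercube(cube, wl, role)
}

#' Write a snapshot as 16-bit TIFF plus JSON sidecar
#'
#' Values are scaled by \code{scale} (default: the frame maximum) and
#' quantised to uint16; the sidecar \code{<path>.json} records the scale
#' factor, the mosaic pattern and the sensor id so the frame can be
#' restored and demosaicked.
#'
#' @param snapshot a \linkS4class{SnapshotMosaic}
#' @param path destination \code{.tif} path
#' @param sensorId sensor name recorded in the sidecar
#' @param scale full-scale value mapped to 65535 (default \code{max(image)})
#' @return invisibly, c(tiff, json) paths
#' @export
writeSnapshot <- function(snapshot, path, sensorId = "unknown", scale = NULL) {
  img <- snapshotImage(snapshot)
  pat <- snapshotPattern(snapshot)
  if (is.null(scale)) scale <- max(img)
  if (scale <= 0) scale <- 1
  q <- quantizeBits(pmin(img / scale, 1), 16L)
  tiff::writeTIFF(q / 65535, path, bits.per.sample = 16L)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(schema = "snapshot-1", sensor = sensorId,
                            scale = scale,
                            pattern = list(n = pat@n,
                                           assignment = as.vector(t(pat@assignment)))),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff = path, json = sidecar))
}

#' Read a snapshot written by \code{\link{writeSnapshot}}
#'
#' @param path the \code{.tif} path; the \code{<path>.json} sidecar must
#'   exist (its absence is an explicit error, since the mosaic pattern and
#'   scale are not recoverable from pixels alone)
#' @return a \linkS4class{SnapshotMosaic} with attribute \code{"sensor"}
#' @export
readSnapshot <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("snapshot sidecar not found: ", sidecar,
         " (the mosaic pattern and scale live in the sidecar)")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  n <- as.integer(meta$pattern$n)
  pat <- mosaicPattern(n, matrix(as.integer(meta$pattern$assignment), n, n,
                                 byrow = TRUE))
  snap <- snapshotMosaic(round(img * 65535) / 65535 * meta$scale, pat)
  attr(snap, "sensor") <- meta$sensor
  snap
}

#' Load a sensor description from YAML
#'
#' Schema (version 1): \code{name}; \code{grid} (either
#' \code{start/stop/step} or \code{values}); \code{mosaic} with \code{n}
#' and row-major \code{assignment} (0-based band indices); \code{measured}
#' with \code{specs} (lambda0/qe/fwhm rows) and optional \code{parasitics}
#' (crosstalk/harmonic/leakage/seed) or explicit \code{curves};
#' \code{ideal} with \code{specs}; optional explicit \code{calibration}
#' matrix (list of rows) — when absent, C is synthesized by regularised
#' least squares and the sensor records \code{calibrationSource =
#' "synthesized"}.
#'
#' @param path YAML file path
#' @return a \linkS4class{SensorModel}
#' @examples
#' s <- loadSensor(system.file("extdata", "default_sensor.yaml",
#'                             package = "mosaicHSI"))
#' @export
loadSensor <- function(path) {
  if (!file.exists(path)) stop("sensor file not found: ", path)
  y <- yaml::read_yaml(path)
  fail <- function(field) stop(sprintf("sensor schema error in %s: missing or invalid '%s'",
                                       path, field))
  if (is.null(y$schema) || y$schema != "sensor-1") fail("schema")
  if (is.null(y$grid)) fail("grid")
  gridVals <- if (!is.null(y$grid$values)) as.numeric(y$grid$values)
  else if (!is.null(y$grid$start)) seq(y$grid$start, y$grid$stop, by = y$grid$step)
  else fail("grid")
  grid <- wavelengthGrid(gridVals)
  if (is.null(y$mosaic)) fail("mosaic")
  # YAML 1.1 parses a bare `n:` key as the boolean FALSE; accept both forms
  names(y$mosaic)[names(y$mosaic) %in% c("FALSE", "no")] <- "n"
  if (is.null(y$mosaic$n)) fail("mosaic")
  n <- as.integer(y$mosaic$n)
  pat <- if (!is.null(y$mosaic$assignment)) {
    a <- matrix(as.integer(unlist(y$mosaic$assignment)), n, n, byrow = TRUE)
    mosaicPattern(n, a + 1L)   # file uses 0-based indices
  } else mosaicPattern(n)
  specsFrom <- function(node, field) {
    if (is.null(node$specs)) fail(field)
    df <- do.call(rbind, lapply(node$specs, function(s) {
      if (is.null(s$lambda0) || is.null(s$qe) || is.null(s$fwhm)) fail(field)
      data.frame(lambda0 = s$lambda0, qe = s$qe, fwhm = s$fwhm)
    }))
    df
  }
  if (is.null(y$measured)) fail("measured")
  if (is.null(y$ideal)) fail("ideal")
  idealSpecs <- specsFrom(y$ideal, "ideal.specs")
  ideal <- buildResponseMatrix(grid, idealSpecs)
  if (!is.null(y$measured$curves)) {
    mr <- do.call(rbind, lapply(y$measured$curves, as.numeric))
    if (ncol(mr) != length(gridVals)) fail("measured.curves")
    measured <- spectralResponseMatrix(mr, grid)
  } else {
    mSpecs <- specsFrom(y$measured, "measured.specs")
    par <- y$measured$parasitics %||% list()
    measured <- synthesizeMeasuredResponses(
      buildResponseMatrix(grid, mSpecs),
      crosstalk = par$crosstalk %||% 0, harmonic = par$harmonic %||% 0,
      leakage = par$leakage %||% 0, seed = par$seed %||% 1L)
  }
  calib <- NULL
  source <- "synthesized"
  if (!is.null(y$calibration)) {
    Cm <- do.call(rbind, lapply(y$calibration, as.numeric))
    calib <- calibrationMatrix(Cm)
    source <- "loaded"
  } else {
    calib <- computeCalibrationMatrix(measured, ideal,
                                      ridge = y$ridge %||% 1e-6)
  }
  new("SensorModel", name = y$name %||% "unnamed",
      grid = grid, measured = measured, ideal = ideal,
      idealSpecs = idealSpecs, calibration = calib, pattern = pat,
      calibrationSource = source)
}

#' Write a sensor description to YAML
#'
#' Writes the spec-based form (band specs + parasitics, no explicit C) used
#' by \code{\link{loadSensor}}.
#'
#' @param grid a \linkS4class{WavelengthGrid} as start/stop/step
#' @param measuredSpecs,idealSpecs data.frames (lambda0, qe, fwhm)
#' @param pattern a \linkS4class{MosaicPattern}
#' @param parasitics list(crosstalk, harmonic, leakage, seed)
#' @param name sensor name
#' @param path destination YAML path
#' @return invisibly, the path
#' @export
writeSensorYAML <- function(grid, measuredSpecs, idealSpecs, pattern,
                            parasitics, name, path) {
  v <- gridValues(grid)
  step <- unique(round(diff(v), 10))
  y <- list(schema = "sensor-1", name = name,
            grid = if (length(step) == 1L)
              list(start = v[1L], stop = v[length(v)], step = step)
            else list(values = v),
            mosaic = list(n = pattern@n,
                          assignment = as.vector(t(pattern@assignment)) - 1L),
            measured = list(
              specs = lapply(seq_len(nrow(measuredSpecs)), function(i)
                as.list(measuredSpecs[i, c("lambda0", "qe", "fwhm")])),
              parasitics = parasitics),
            ideal = list(
              specs = lapply(seq_len(nrow(idealSpecs)), function(i)
                as.list(idealSpecs[i, c("lambda0", "qe", "fwhm")]))))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the end-to-end pipeline on synthetic phantoms
#'
#' simulate -> demosaick (linear and optionally learned) -> spectral
#' correction -> sRGB -> evaluate, writing per-stage artifacts, a metric
#' CSV/JSON report, and a provenance JSON (config, seeds, timings, package
#' version) into \code{outDir}. All randomness derives from
#' \code{config$seed}.
#'
#' @param config list (or path to a YAML file) with elements \code{seed},
#'   \code{outDir}, optional \code{phantom} (arguments to
#'   \code{\link{phantomSpec}}), \code{count}, \code{split},
#'   \code{sensor} (path to a YAML sensor or NULL for
#'   \code{\link{defaultSensor}}), \code{train} (FALSE, or a list of
#'   \code{\link{trainConfig}} arguments), \code{writePng}
#' @return invisibly, a list with the report, paths and the trained model
#'   (if any)
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  outDir <- config$outDir %||% stop("config$outDir is required")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  sensor <- if (!is.null(config$sensor)) loadSensor(config$sensor)
  else defaultSensor()
  t0 <- tic()
  spArgs <- config$phantom %||% list()
  spArgs$seed <- deriveSeed(seed, 1L)
  spec <- do.call(phantomSpec, spArgs)
  ds <- makeDataset(spec, count = config$count %||% 10L,
                    split = unlist(config$split %||% c(0.6, 0.2, 0.2)),
                    sensor = sensor, dir = outDir)
  timings$simulate <- tic() - t0
  trained <- NULL
  if (!is.null(config$train) && !identical(config$train, FALSE)) {
    t0 <- tic()
    targs <- if (is.list(config$train)) config$train else list()
    targs$seed <- deriveSeed(seed, 2L)
    tcfg <- do.call(trainConfig, targs)
    trained <- trainDemosaicker(ds$train, ds$val, sensor, tcfg = tcfg)
    timings$train <- tic() - t0
  }
  t0 <- tic()
  cspec <- colourimetrySpec()
  pairs <- list()
  for (i in seq_along(ds$test)) {
    s <- ds$test[[i]]
    lin <- linearPipeline(s@snapshot, sensor)
    pairs[[length(pairs) + 1L]] <- list(reference = s@ideal,
                                        reconstruction = lin,
                                        name = sprintf("test%02d_linear", i))
    if (!is.null(trained)) {
      lrn <- learnedPipeline(s@snapshot, trained, sensor)
      pairs[[length(pairs) + 1L]] <- list(reference = s@ideal,
                                          reconstruction = lrn,
                                          name = sprintf("test%02d_learned", i))
    }
    if (isTRUE(config$writePng %||% TRUE)) {
      sc <- bandIntegralScale(sensor)
      rgb <- hypercubeToSRGB(s@ideal, cspec = cspec, rescaleWhite = TRUE,
                             scale = sc)
      png::writePNG(rgb, file.path(outDir, sprintf("test%02d_ideal.png", i)))
      rgbL <- hypercubeToSRGB(lin, cspec = cspec, rescaleWhite = TRUE,
                              scale = sc)
      png::writePNG(rgbL, file.path(outDir, sprintf("test%02d_linear.png", i)))
    }
  }
  report <- evaluateSuite(pairs, cspec)
  paths <- writeEvaluation(report, file.path(outDir, "metrics.csv"))
  timings$evaluate <- tic() - t0
  provenance <- list(schema = "pipeline-run-1",
                     seed = seed,
                     config = config[setdiff(names(config), "outDir")],
                     timings = timings,
                     version = as.character(utils::packageVersion("mosaicHSI")))
  jsonlite::write_json(provenance, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(report = report, paths = paths, trained = trained,
                 sensor = sensor, dataset = ds))
}
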