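#' @import methods
NULL

#' Wavelength grid with quadrature weights
#'
#' A strictly increasing vector of wavelengths (nm) together with trapezoidal
#' quadrature weights, the common spectral axis for sensor responses and
#' high-resolution spectra.
#'
#' @slot values strictly increasing wavelengths in nm
#' @slot weights trapezoidal step weights in nm (same length)
#' @exportClass WavelengthGrid
setClass("WavelengthGrid",
  representation(values = "numeric", weights = "numeric"),
  validity = function(object) {
    v <- object@values
    if (length(v) < 2L) return("grid needs at least 2 wavelengths")
    if (any(!is.finite(v))) return("wavelengths must be finite")
    if (any(v <= 0)) return("wavelengths must be positive")
    if (any(diff(v) <= 0)) return("wavelengths must be strictly increasing")
    if (length(object@weights) != length(v)) return("weights length mismatch")
    TRUE
  }
)

#' Construct a WavelengthGrid
#'
#' @param values strictly increasing wavelengths (nm)
#' @return a \linkS4class{WavelengthGrid}
#' @examples
#' g <- wavelengthGrid(seq(400, 700, by = 5))
#' @export
wavelengthGrid <- function(values) {
  new("WavelengthGrid", values = as.numeric(values),
      weights = trapezoidWeights(as.numeric(values)))
}

#' @describeIn wavelengthGrid wavelengths (nm)
#' @param grid a WavelengthGrid
#' @export
gridValues <- function(grid) grid@values

#' @describeIn wavelengthGrid quadrature weights (nm)
#' @export
gridWeights <- function(grid) grid@weights

#' Spectral response matrix
#'
#' Non-negative band responsivities sampled on a \linkS4class{WavelengthGrid}:
#' one row per band (ns measured bands, or ni ideal Lorentzian target bands),
#' one column per grid wavelength.
#'
#' @slot responses numeric matrix (bands x wavelengths), entries >= 0
#' @slot grid the wavelength grid the columns are sampled on
#' @slot labels band labels
#' @exportClass SpectralResponseMatrix
setClass("SpectralResponseMatrix",
  representation(responses = "matrix", grid = "WavelengthGrid",
                 labels = "character"),
  validity = function(object) {
    r <- object@responses
    if (!is.numeric(r)) return("responses must be numeric")
    if (any(!is.finite(r))) return("responses must be finite")
    if (any(r < 0)) return("responses must be non-negative")
    if (ncol(r) != length(object@grid@values))
      return("response columns must match grid length")
    if (length(object@labels) != nrow(r)) return("one label per band required")
    TRUE
  }
)

#' Construct a SpectralResponseMatrix
#' @param responses bands x wavelengths matrix of responsivities (>= 0)
#' @param grid \linkS4class{WavelengthGrid} of the columns
#' @param labels optional band labels
#' @return a \linkS4class{SpectralResponseMatrix}
#' @export
spectralResponseMatrix <- function(responses, grid, labels = NULL) {
  responses <- rbind(responses)
  if (is.null(labels)) labels <- paste0("band", seq_len(nrow(responses)))
  new("SpectralResponseMatrix", responses = responses, grid = grid,
      labels = as.character(labels))
}

#' @describeIn spectralResponseMatrix the response matrix (bands x wavelengths)
#' @param x a SpectralResponseMatrix
#' @export
responses <- function(x) x@responses

#' Spectral-correction calibration matrix
#'
#' The ni x ns linear map taking the sensor's ns measured band values at one
#' pixel to ni idealised (Lorentzian) band values, compensating cross-talk,
#' harmonics and leakage.
#'
#' @slot mat numeric ni x ns matrix
#' @exportClass CalibrationMatrix
setClass("CalibrationMatrix",
  representation(mat = "matrix"),
  validity = function(object) {
    if (!is.numeric(object@mat)) return("calibration matrix must be numeric")
    if (any(!is.finite(object@mat))) return("calibration entries must be finite")
    TRUE
  }
)

#' Construct a CalibrationMatrix
#' @param mat numeric ni x ns matrix
#' @return a \linkS4class{CalibrationMatrix}
#' @export
calibrationMatrix <- function(mat) new("CalibrationMatrix", mat = rbind(mat))

#' @describeIn calibrationMatrix the underlying ni x ns matrix
#' @param x a CalibrationMatrix
#' @export
calMatrix <- function(x) x@mat

#' Mosaic filter-array pattern
#'
#' The n x n block of band indices tiled over the sensor: pixel (x, y) of the
#' full frame samples band \code{assignment[((x-1) mod n)+1, ((y-1) mod n)+1]}
#' (1-based; block phase anchored at pixel (1,1)).
#'
#' @slot n block edge length in pixels
#' @slot assignment integer n x n matrix of band indices in 1..n^2
#' @exportClass MosaicPattern
setClass("MosaicPattern",
  representation(n = "integer", assignment = "matrix"),
  validity = function(object) {
    n <- object@n
    a <- object@assignment
    if (length(n) != 1L || n < 1L) return("n must be a positive scalar")
    if (!all(dim(a) == c(n, n))) return("assignment must be n x n")
    if (any(a != round(a))) return("assignment must be integer band indices")
    if (any(a < 1L) || any(a > n * n))
      return("band indices must lie in 1..n^2")
    TRUE
  }
)

#' Construct a MosaicPattern
#'
#' @param n block edge length; default assignment is row-major
#'   (band \code{(r-1)*n + c} at block cell (r, c))
#' @param assignment optional n x n integer matrix of 1-based band indices
#' @return a \linkS4class{MosaicPattern}
#' @examples
#' mosaicPattern(4)   # the 4x4 row-major 16-band layout
#' @export
mosaicPattern <- function(n, assignment = NULL) {
  n <- as.integer(n)
  if (is.null(assignment)) {
    assignment <- matrix(seq_len(n * n), n, n, byrow = TRUE)
  }
  storage.mode(assignment) <- "integer"
  new("MosaicPattern", n = n, assignment = assignment)
}

#' @describeIn mosaicPattern number of distinct bands sampled by the pattern
#' @param pattern a MosaicPattern
#' @export
nBands <- function(pattern) length(unique(as.vector(pattern@assignment)))

#' @describeIn mosaicPattern the n x n assignment matrix (1-based indices)
#' @export
patternAssignment <- function(pattern) pattern@assignment

#' Hyperspectral cube
#'
#' A rank-3 non-negative array (X rows x Y cols x B bands) with band-centre
#' wavelengths and a role tag: \code{"hr"} for high-spectral-resolution input,
#' \code{"intermediate"} for the ns measured-response bands, \code{"ideal"}
#' for the ni Lorentzian target bands.
#'
#' @slot data numeric X x Y x B array, finite (reflectance cubes are clipped
#'   at 0 where they are produced, e.g. by \code{whiteBalance})
#' @slot bandCenters numeric vector of band-centre wavelengths (nm), length B
#' @slot role one of "hr", "intermediate", "ideal"
#' @exportClass Hypercube
setClass("Hypercube",
  representation(data = "array", bandCenters = "numeric", role = "character"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L) return("data must be a rank-3 array")
    if (any(!is.finite(d))) return("cube values must be finite")
    if (length(object@bandCenters) != dim(d)[3L])
      return("bandCenters length must equal band count")
    if (!object@role %in% c("hr", "intermediate", "ideal"))
      return("role must be hr, intermediate or ideal")
    TRUE
  }
)

#' Construct a Hypercube
#' @param data X x Y x B non-negative array
#' @param bandCenters band-centre wavelengths (nm), length B
#' @param role "hr", "intermediate" or "ideal"
#' @return a \linkS4class{Hypercube}
#' @export
hypercube <- function(data, bandCenters, role = "hr") {
  new("Hypercube", data = data, bandCenters = as.numeric(bandCenters),
      role = role)
}

#' @describeIn hypercube the underlying X x Y x B array
#' @param cube a Hypercube
#' @export
cubeData <- function(cube) cube@data

#' @describeIn hypercube band-centre wavelengths (nm)
#' @export
bandCenters <- function(cube) cube@bandCenters

#' @describeIn hypercube the role tag
#' @export
cubeRole <- function(cube) cube@role

#' Snapshot mosaic image
#'
#' The scalar-valued X x Y frame captured in a single exposure through the
#' mosaic filter array: each pixel holds one band's measurement, which band
#' being determined by the \linkS4class{MosaicPattern}.
#'
#' @slot image numeric X x Y matrix, finite and >= 0
#' @slot pattern the mosaic pattern the frame was sampled with
#' @exportClass SnapshotMosaic
setClass("SnapshotMosaic",
  representation(image = "matrix", pattern = "MosaicPattern"),
  validity = function(object) {
    if (any(!is.finite(object@image))) return("snapshot must be finite")
    if (any(object@image < 0)) return("snapshot must be non-negative")
    TRUE
  }
)

#' Construct a SnapshotMosaic
#' @param image X x Y matrix of single-band-per-pixel measurements
#' @param pattern a \linkS4class{MosaicPattern}
#' @return a \linkS4class{SnapshotMosaic}
#' @export
snapshotMosaic <- function(image, pattern) {
  new("SnapshotMosaic", image = image, pattern = pattern)
}

#' @describeIn snapshotMosaic the X x Y pixel matrix
#' @param snapshot a SnapshotMosaic
#' @export
snapshotImage <- function(snapshot) snapshot@image

#' @describeIn snapshotMosaic the mosaic pattern
#' @export
snapshotPattern <- function(snapshot) snapshot@pattern

#' Snapshot sensor model
#'
#' Everything needed to simulate and correct one snapshot mosaic camera:
#' the wavelength grid, the ns measured band responses (with parasitics), the
#' ni ideal Lorentzian band responses and their specs, the ni x ns spectral
#' correction matrix C, and the mosaic layout.
#'
#' @slot name sensor identifier
#' @slot grid common \linkS4class{WavelengthGrid}
#' @slot measured ns-band measured \linkS4class{SpectralResponseMatrix}
#' @slot ideal ni-band ideal \linkS4class{SpectralResponseMatrix}
#' @slot idealSpecs data.frame with columns lambda0, qe, fwhm (one row per
#'   ideal band)
#' @slot calibration \linkS4class{CalibrationMatrix} (ni x ns)
#' @slot pattern \linkS4class{MosaicPattern}
#' @slot calibrationSource "loaded" or "synthesized"
#' @exportClass SensorModel
setClass("SensorModel",
  representation(name = "character", grid = "WavelengthGrid",
                 measured = "SpectralResponseMatrix",
                 ideal = "SpectralResponseMatrix",
                 idealSpecs = "data.frame",
                 calibration = "CalibrationMatrix",
                 pattern = "MosaicPattern",
                 calibrationSource = "character"),
  validity = function(object) {
    ns <- nrow(object@measured@responses)
    ni <- nrow(object@ideal@responses)
    if (ni > ns) return("ideal band count ni must not exceed ns")
    if (!all(dim(object@calibration@mat) == c(ni, ns)))
      return("calibration matrix must be ni x ns")
    if (nBands(object@pattern) != ns)
      return("pattern must sample exactly ns distinct bands")
    if (nrow(object@idealSpecs) != ni)
      return("idealSpecs must have one row per ideal band")
    TRUE
  }
)

#' @describeIn makeSensorModel the sensor's wavelength grid
#' @export
sensorGrid <- function(sensor) sensor@grid

#' @describeIn makeSensorModel measured (parasitic-affected) band responses
#' @export
measuredResponses <- function(sensor) sensor@measured

#' @describeIn makeSensorModel ideal Lorentzian band responses
#' @export
idealResponses <- function(sensor) sensor@ideal

#' @describeIn makeSensorModel the spectral-correction matrix C
#' @export
calibration <- function(sensor) sensor@calibration

#' @describeIn makeSensorModel the mosaic pattern
#' @export
sensorPattern <- function(sensor) sensor@pattern

#' Paired training sample
#'
#' The supervised-learning triplet produced by the forward model from one HR
#' cube: the 2D snapshot, the X x Y x ns intermediate hypercube (the
#' demosaicking network's regression target) and the X x Y x ni ideal
#' hypercube (the spectrally corrected target).
#'
#' @slot snapshot \linkS4class{SnapshotMosaic}
#' @slot intermediate ns-band \linkS4class{Hypercube}
#' @slot ideal ni-band \linkS4class{Hypercube}
#' @exportClass PairedSample
setClass("PairedSample",
  representation(snapshot = "SnapshotMosaic", intermediate = "Hypercube",
                 ideal = "Hypercube"),
  validity = function(object) {
    ds <- dim(object@snapshot@image)
    di <- dim(object@intermediate@data)[1:2]
    de <- dim(object@ideal@data)[1:2]
    if (!all(ds == di) || !all(ds == de))
      return("snapshot, intermediate and ideal must share spatial dims")
    TRUE
  }
)

#' Construct a PairedSample
#' @param snapshot a \linkS4class{SnapshotMosaic}
#' @param intermediate the ns-band \linkS4class{Hypercube}
#' @param ideal the ni-band \linkS4class{Hypercube}
#' @return a \linkS4class{PairedSample}
#' @export
pairedSample <- function(snapshot, intermediate, ideal) {
  new("PairedSample", snapshot = snapshot, intermediate = intermediate,
      ideal = ideal)
}

setMethod("show", "WavelengthGrid", function(object) {
  v <- object@values
  cat(sprintf("WavelengthGrid: %d points, %.1f-%.1f nm\n",
              length(v), min(v), max(v)))
})

setMethod("show", "SpectralResponseMatrix", function(object) {
  cat(sprintf("SpectralResponseMatrix: %d bands x %d wavelengths (%.0f-%.0f nm)\n",
              nrow(object@responses), ncol(object@responses),
              min(object@grid@values), max(object@grid@values)))
})

setMethod("show", "CalibrationMatrix", function(object) {
  cat(sprintf("CalibrationMatrix: %d x %d (ni x ns)\n",
              nrow(object@mat), ncol(object@mat)))
})

setMethod("show", "MosaicPattern", function(object) {
  cat(sprintf("MosaicPattern: %dx%d block, %d distinct bands\n",
              object@n, object@n, nBands(object)))
})

setMethod("show", "Hypercube", function(object) {
  d <- dim(object@data)
  cat(sprintf("Hypercube [%s]: %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              object@role, d[1L], d[2L], d[3L],
              min(object@bandCenters), max(object@bandCenters)))
})

setMethod("show", "SnapshotMosaic", function(object) {
  d <- dim(object@image)
  cat(sprintf("SnapshotMosaic: %d x %d pixels, %dx%d pattern\n",
              d[1L], d[2L], object@pattern@n, object@pattern@n))
})

setMethod("show", "SensorModel", function(object) {
  cat(sprintf("SensorModel '%s': ns=%d, ni=%d, %dx%d mosaic, C %s\n",
              object@name, nrow(object@measured@responses),
              nrow(object@ideal@responses), object@pattern@n,
              object@pattern@n, object@calibrationSource))
})

setMethod("show", "PairedSample", function(object) {
  d <- dim(object@snapshot@image)
  cat(sprintf("PairedSample: %d x %d, ns=%d, ni=%d\n", d[1L], d[2L],
              dim(object@intermediate@data)[3L], dim(object@ideal@data)[3L]))
})
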