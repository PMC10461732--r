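# Sensor spectral model: Lorentzian Fabry-Perot band responses, synthetic
# parasitic measured responses, and the spectral-correction matrix C.

#' Lorentzian width parameter alpha
#'
#' The ideal Fabry-Perot band-pass response expressed in wavelength is
#' \deqn{f(\lambda) = QE \frac{\alpha \lambda^2}{(\lambda-\lambda_0)^2 +
#' \alpha\lambda^2}}
#' \code{lorentzianAlpha} returns the unique \eqn{\alpha} for which the two
#' half-maximum crossings of \eqn{f} are separated by exactly \code{fwhm}:
#' \eqn{\alpha = (\sqrt{\lambda_0^2 + FWHM^2} - \lambda_0)^2 / FWHM^2}.
#'
#' @param lambda0 central wavelength (nm), > 0
#' @param fwhm full-width at half-maximum (nm), > 0
#' @return dimensionless scalar alpha
#' @examples
#' lorentzianAlpha(550, 15)   # ~1.86e-4
#' @export
lorentzianAlpha <- function(lambda0, fwhm) {
  if (any(lambda0 <= 0) || any(fwhm <= 0))
    stop("lambda0 and fwhm must be positive")
  ((sqrt(lambda0^2 + fwhm^2) - lambda0) / fwhm)^2
}

#' Ideal Lorentzian band response on a wavelength grid
#'
#' Evaluates the Fabry-Perot band response (see \code{\link{lorentzianAlpha}})
#' for one band spec at every grid wavelength. The response is strictly
#' positive, bounded by \code{qe}, and attains \code{qe} exactly at
#' \code{lambda0}.
#'
#' @param grid a \linkS4class{WavelengthGrid}
#' @param lambda0 central wavelength (nm)
#' @param qe quantum efficiency in (0, 1]
#' @param fwhm full-width at half-maximum (nm)
#' @return numeric response vector, one value per grid wavelength
#' @export
lorentzianResponse <- function(grid, lambda0, qe, fwhm) {
  if (qe <= 0 || qe > 1) stop("qe must lie in (0, 1]")
  a <- lorentzianAlpha(lambda0, fwhm)
  lam <- gridValues(grid)
  # grouped so that f(lambda0) == qe exactly (the inner ratio is x/x = 1)
  qe * (a * lam^2 / ((lam - lambda0)^2 + a * lam^2))
}

#' Build a response matrix from ideal band specs
#'
#' @param grid a \linkS4class{WavelengthGrid}
#' @param specs data.frame with columns \code{lambda0}, \code{qe},
#'   \code{fwhm}; one row per band
#' @return a \linkS4class{SpectralResponseMatrix} with one Lorentzian row per
#'   spec, in the order given
#' @export
buildResponseMatrix <- function(grid, specs) {
  specs <- as.data.frame(specs)
  if (nrow(specs) < 1L) stop("at least one band spec is required")
  stopifnot(all(c("lambda0", "qe", "fwhm") %in% names(specs)))
  r <- t(vapply(seq_len(nrow(specs)), function(i) {
    lorentzianResponse(grid, specs$lambda0[i], specs$qe[i], specs$fwhm[i])
  }, numeric(length(gridValues(grid)))))
  spectralResponseMatrix(r, grid,
                         labels = sprintf("%.0fnm", specs$lambda0))
}

#' Synthesize parasitic-affected measured responses
#'
#' Perturbs a set of ideal band responses into plausible factory-measured
#' curves exhibiting the parasitic effects real mosaic sensors show:
#' convex cross-talk mixing between adjacent bands, one secondary harmonic
#' peak per band (placed at the second-order position 2*lambda0 or lambda0/2,
#' whichever falls inside the grid, else mirrored about the grid midpoint),
#' and a constant leakage floor (each value clamped up to
#' \code{leakage * row maximum}). With all perturbations zero the input is
#' returned unchanged. Deterministic given \code{seed}.
#'
#' @param ideal a \linkS4class{SpectralResponseMatrix} of clean band responses
#' @param crosstalk mixing fraction into each adjacent band, >= 0
#' @param harmonic secondary-peak amplitude as a fraction of the band peak,
#'   >= 0 (jittered per band by a factor in [0.5, 1.5])
#' @param leakage baseline floor as a fraction of each row's maximum, >= 0
#' @param seed integer seed for the per-band jitter
#' @return a \linkS4class{SpectralResponseMatrix} of the same shape
#' @export
synthesizeMeasuredResponses <- function(ideal, crosstalk = 0, harmonic = 0,
                                        leakage = 0, seed = 1L) {
  if (crosstalk < 0 || harmonic < 0 || leakage < 0)
    stop("perturbation parameters must be non-negative")
  r <- responses(ideal)
  grid <- ideal@grid
  lam <- gridValues(grid)
  ns <- nrow(r)
  withSeed(seed, {
    out <- r
    if (crosstalk > 0 && ns > 1L) {
      out <- matrix(0, ns, ncol(r))
      for (b in seq_len(ns)) {
        lo <- max(1L, b - 1L)
        hi <- min(ns, b + 1L)
        nb <- setdiff(lo:hi, b)
        w <- crosstalk * length(nb)
        out[b, ] <- (1 - w) * r[b, ]
        for (j in nb) out[b, ] <- out[b, ] + crosstalk * r[j, ]
      }
    }
    if (harmonic > 0) {
      for (b in seq_len(ns)) {
        peakIdx <- which.max(r[b, ])
        l0 <- lam[peakIdx]
        qe <- r[b, peakIdx]
        cand <- c(2 * l0, l0 / 2)
        inR <- cand[cand >= min(lam) & cand <= max(lam)]
        lh <- if (length(inR)) inR[1L] else min(lam) + max(lam) - l0
        amp <- harmonic * qe * stats::runif(1L, 0.5, 1.5)
        a <- lorentzianAlpha(lh, max(lam[2L] - lam[1L], 5))
        out[b, ] <- out[b, ] + amp * a * lam^2 / ((lam - lh)^2 + a * lam^2)
      }
    }
    if (leakage > 0) {
      for (b in seq_len(nrow(out))) {
        floorv <- leakage * max(out[b, ])
        out[b, ] <- pmax(out[b, ], floorv)
      }
    }
    spectralResponseMatrix(out, grid, labels = ideal@labels)
  })
}

#' Compute the spectral-correction matrix C
#'
#' Ridge-regularised least squares fit of the linear map from the ns measured
#' band responses to the ni ideal band responses:
#' \deqn{C = \arg\min_C \|C M - I\|_F^2 + \rho \|C\|_F^2}
#' solved in closed form as \eqn{C = I M^T (M M^T + \rho' \mathbb{1})^{-1}}
#' with \eqn{\rho' = \rho \cdot tr(M M^T)/ns} (trace scaling makes the
#' regularisation weight dimensionless). With \code{ridge = 0} and
#' \code{measured == ideal} this recovers the identity.
#'
#' @param measured ns-band \linkS4class{SpectralResponseMatrix}
#' @param ideal ni-band \linkS4class{SpectralResponseMatrix} on the same grid
#' @param ridge regularisation weight, >= 0 (default 1e-6)
#' @return a \linkS4class{CalibrationMatrix} of shape ni x ns
#' @export
computeCalibrationMatrix <- function(measured, ideal, ridge = 1e-6) {
  if (ridge < 0) stop("ridge must be non-negative")
  if (!isTRUE(all.equal(gridValues(measured@grid), gridValues(ideal@grid))))
    stop("measured and ideal responses must share the same wavelength grid")
  M <- responses(measured)
  I <- responses(ideal)
  G <- tcrossprod(M)                      # ns x ns
  lam <- ridge * sum(diag(G)) / nrow(M)
  C <- t(solve(G + diag(lam, nrow(G)), M %*% t(I)))
  calibrationMatrix(C)
}

#' Assemble a full snapshot sensor model
#'
#' Builds measured responses from ns band specs (Lorentzians perturbed by the
#' given parasitics), ideal responses from ni band specs, and synthesizes the
#' correction matrix C by regularised least squares unless an explicit C is
#' supplied.
#'
#' @param grid a \linkS4class{WavelengthGrid}
#' @param measuredSpecs data.frame (lambda0, qe, fwhm) for the ns sensor bands
#' @param idealSpecs data.frame (lambda0, qe, fwhm) for the ni target bands
#' @param pattern a \linkS4class{MosaicPattern} sampling ns distinct bands
#' @param parasitics list with elements \code{crosstalk}, \code{harmonic},
#'   \code{leakage}, \code{seed}
#' @param calibration optional explicit \linkS4class{CalibrationMatrix}
#' @param ridge regularisation weight for C synthesis
#' @param name sensor identifier
#' @return a \linkS4class{SensorModel}
#' @seealso \code{\link{defaultSensor}}
#' @export
makeSensorModel <- function(grid, measuredSpecs, idealSpecs, pattern,
                            parasitics = list(crosstalk = 0.04,
                                              harmonic = 0.03,
                                              leakage = 0.005, seed = 42L),
                            calibration = NULL, ridge = 1e-6,
                            name = "custom") {
  clean <- buildResponseMatrix(grid, measuredSpecs)
  measured <- synthesizeMeasuredResponses(
    clean,
    crosstalk = parasitics$crosstalk %||% 0,
    harmonic = parasitics$harmonic %||% 0,
    leakage = parasitics$leakage %||% 0,
    seed = parasitics$seed %||% 1L)
  ideal <- buildResponseMatrix(grid, idealSpecs)
  source <- "loaded"
  if (is.null(calibration)) {
    calibration <- computeCalibrationMatrix(measured, ideal, ridge = ridge)
    source <- "synthesized"
  }
  new("SensorModel", name = name, grid = grid, measured = measured,
      ideal = ideal, idealSpecs = as.data.frame(idealSpecs),
      calibration = calibration, pattern = pattern,
      calibrationSource = source)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default visible-range 4x4 snapshot sensor
#'
#' A 16-band 4x4 mosaic sensor modelled after visible-range snapshot mosaic
#' cameras: measured bands centred evenly over 470-620 nm (FWHM 12 nm,
#' QE 0.8) perturbed by mild cross-talk, harmonics and leakage, and ni = 13
#' ideal Lorentzian target bands over 480-612 nm (FWHM 10 nm, QE 1). The
#' correction matrix is synthesized by regularised least squares.
#'
#' @param n mosaic block edge (default 4, i.e. ns = 16)
#' @param seed seed for the parasitic perturbations
#' @return a \linkS4class{SensorModel}
#' @examples
#' s <- defaultSensor()
#' dim(calMatrix(calibration(s)))   # 13 x 16
#' @export
defaultSensor <- function(n = 4L, seed = 2021L) {
  n <- as.integer(n)
  ns <- n * n
  grid <- wavelengthGrid(seq(400, 1000, by = 1))
  measuredSpecs <- data.frame(
    lambda0 = seq(470, 620, length.out = ns),
    qe = rep(0.8, ns),
    fwhm = rep(12, ns))
  ni <- max(1L, ns - 3L)
  idealSpecs <- data.frame(
    lambda0 = seq(480, 612, length.out = ni),
    qe = rep(1, ni),
    fwhm = rep(10, ni))
  makeSensorModel(grid, measuredSpecs, idealSpecs, mosaicPattern(n),
                  parasitics = list(crosstalk = 0.04, harmonic = 0.03,
                                    leakage = 0.005, seed = seed),
                  name = sprintf("visible-%dx%d", n, n))
}
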