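---
title: "Snapshot mosaic simulation and learned demosaicking: methods"
author: "mosaicHSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Snapshot mosaic simulation and learned demosaicking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicHSI)
```

## The problem

Snapshot mosaic hyperspectral cameras tile an n×n spectral filter array over
the pixel grid, so one exposure captures a scalar X×Y frame in which each
pixel holds a single band out of ns = n² (e.g. 16 bands for a 4×4 layout).
Recovering a full X×Y×ns hypercube from that frame is an ill-posed
*demosaicking* problem; on top of it, real Fabry–Pérot filter mosaics show
parasitic spectral behaviour (cross-talk between neighbouring filters,
harmonic secondary peaks, broadband leakage), so the measured band values
must also be *spectrally corrected* before they approximate clean band-pass
measurements. This package implements the full loop: a physical forward
model that turns high-spectral-resolution (HR) reflectance cubes into
realistic snapshot frames and training targets, a bilinear demosaicking
baseline, a learned residual U-Net refinement with embedded spectral
correction, colorimetric sRGB rendering, and an evaluation harness —
together with a synthetic phantom generator so that every stage runs and is
tested without any external dataset.

## Sensor model

Each ideal band is a Lorentzian band-pass in wavelength,

$$f(\lambda;\lambda_0,QE,FWHM) = QE\,\frac{\alpha\lambda^2}
{(\lambda-\lambda_0)^2+\alpha\lambda^2},\qquad
\alpha=\frac{\left(\sqrt{\lambda_0^2+FWHM^2}-\lambda_0\right)^2}{FWHM^2}.$$

This α is the unique choice for which the two half-maximum crossings of
$f$ are separated by exactly $FWHM$: substituting
$\lambda = \lambda_0/(1\mp\sqrt\alpha)$ gives $f = QE/2$, and solving the
resulting quadratic for $\sqrt\alpha$ yields the expression above. The unit
tests verify this with an independent root-finding oracle rather than
trusting the algebra. `lorentzianResponse()` evaluates $f$ on a
`WavelengthGrid`; the peak value $QE$ is attained exactly at $\lambda_0$.

Measured (parasitic) responses are synthesized from the clean Lorentzians by
`synthesizeMeasuredResponses()`: convex cross-talk mixing between adjacent
bands, one harmonic secondary Lorentzian per band (at $2\lambda_0$ or
$\lambda_0/2$ when inside the grid, else mirrored about the grid midpoint),
and a leakage floor implemented as clamping each response up to a fraction
of its row maximum — enough structure to make the correction matrix
non-trivial. Real deployments would instead load factory response curves
(the YAML schema accepts explicit `curves`).

The spectral-correction matrix C (ni×ns, ni ≤ ns) maps measured band values
to ideal band values at each pixel. When not supplied explicitly it is
synthesized by ridge-regularised least squares,
$C = \arg\min \|CM - I\|_F^2 + \rho\|C\|_F^2$, solved in closed form. The
ridge weight (default `1e-6`, trace-scaled to be dimensionless) exists
because parasitic responses of neighbouring bands are near-collinear and a
raw pseudo-inverse is numerically fragile; with `ridge = 0` and clean
responses the solver recovers the identity to 1e-8, which the tests assert.
Whether manufacturers constrain C (e.g. non-negativity) is not public;
unconstrained least squares is assumed.

All spectral inner products use trapezoidal quadrature weights from the
wavelength grid, so results are stable under resampling of the grid (the
tests verify invariance to grid-density doubling at 1e-6 relative).

## Forward model

`simulatePair()` composes three steps. (1) `applySpectralResponse()`
computes at each pixel the quadrature-weighted inner products of the ns
measured responses with the HR spectrum, giving the X×Y×ns *intermediate*
cube — the super-resolution target. HR cubes whose band centres differ from
the sensor grid are cubic-spline resampled (out-of-range wavelengths
contribute zero response). (2) `mosaicSubsample()` keeps one band per pixel:
`image[x,y] = cube[x,y, assignment[(x-1) mod n + 1, (y-1) mod n + 1]]`,
0-based row-major band order by default (band $rn+c$ at block cell $(r,c)$;
the actual camera layouts are not published, so the assignment is
configurable in the sensor YAML). Block phase is anchored at pixel (1,1) of
the full frame and frames whose dimensions are not multiples of n keep
their partial edge blocks, as real sensors do. (3) `makeIdealHypercube()`
applies the ni ideal Lorentzian responses to the HR cube, producing the
ground-truth *ideal* cube the pipeline is evaluated against.

Sensor noise, optics PSF and motion blur are deliberately outside the
forward model.

## Bilinear baseline

`bilinearDemosaick()` groups pixels by sampled band and interpolates each
band's sparse lattice back to full resolution. Two choices matter and are
not forced by the problem statement:

- **Offset-aware lattices.** Each band's samples sit at their true sensor
  coordinates (their phase inside the block). Collapsing them to a
  decimated grid and resizing would misregister bands by up to n/2 pixels
  against each other.
- **Border handling.** Beyond a band's outermost samples the nearest
  lattice row/column value is replicated (clamped), preserving monotonicity
  at frame borders. Frames smaller than the block degenerate to
  nearest-sample interpolation — defined, not an error.

Separable linear interpolation on a uniform lattice reproduces constants
everywhere and affine ramps exactly in the lattice interior, and equals the
snapshot values bit-exactly at sample sites; all three are asserted in the
tests. `linearPipeline()` appends the per-pixel correction `C`.

## Residual U-Net refinement

The learned demosaicker maps the bilinear X×Y×ns reconstruction to a
sharper X×Y×ns cube. The architecture is a U-Net with residual blocks: a
contracting path of `depth` downsampling stages (2× average pooling +
widening convolution) with `blocks` residual blocks per resolution, a
symmetric expanding path (nearest-neighbour upsampling, skip concatenation,
merge convolution, residual blocks), and a 3×3 convolution head that is
**zero-initialised** with a global residual connection — an untrained
network therefore reproduces the bilinear baseline exactly, and training
can only move away from it. At full scale the natural configuration is
`depth = 4, blocks = 2`; the packaged desk-scale profile uses
`depth = 2, blocks = 1, width = 16` on 64×64 patches so the whole study
runs in minutes on one CPU core.

The engine (convolutions via cached im2col indexing and BLAS products,
hand-derived backpropagation, Adam) is part of the package; its gradients
are checked against central finite differences in the test suite, in both
loss modes.

### Loss

$$\ell(\hat y_s; y_s, y_i) = \big\|y_i - C\hat y_s\big\|_1
 + \gamma\,\mathrm{aux}(\hat y_s, y_s),\qquad \gamma = 0.001,$$

with mean reductions so that γ is comparable across patch sizes. The main
term supervises the *corrected* output against the ideal cube — the network
never predicts the ideal cube directly; the known C is embedded after it.
The auxiliary term supervises the raw output against the intermediate cube:
either L1 (`mode = "l1"`; both terms L1) or a feature-reconstruction term
(`mode = "perceptual"`): mean squared distance between frozen
feature-extractor activations, with the main term printed as a norm and the
auxiliary as a squared norm. γ defaults to 0.001 in both modes; only the
perceptual configuration has a canonical published value, so the L1 mode
reuses the same slot (configurable).

Feature extractors for perceptual losses are image-domain networks
expecting 3 channels. Hyperspectral cubes are fed band-by-band as grayscale
replicated to 3 channels and the feature term is averaged over bands; this
avoids choosing an arbitrary band triplet. The packaged extractor is a
frozen two-layer random-weight convolutional stack (fixed seed): pretrained
classification weights are not shipped, so perceptual scores are
comparable only within one extractor. Any callable extractor can be
injected.

### Training protocol

Adam on random patches with top-left corners aligned to the n×n mosaic
grid (so patch phase statistics match full frames), random flips and
multiples-of-90° rotations as augmentation, batch size 3, and selection of
the checkpoint with the lowest validation loss. At full scale the reference
protocol is 224×224 patches and learning rate 1e-4 over many epochs; the
desk-scale profile uses 64×64 patches (full phantom frames), ≤ 500
iterations and learning rate 1e-3 — a scaled-down run needs a larger step
to traverse a comparable distance in parameter space. A non-finite loss
aborts with a diagnostic. Runs are bit-reproducible given the config seed.

## Colorimetry

`spectraToXYZ()` integrates reflectance-scaled band values against the CIE
1931 2° colour-matching functions under D65:
$XYZ_p = k\sum_b c_{p,b}\,E(\lambda_b)\,\bar{xyz}(\lambda_b)\,\Delta\lambda_b$.
The CMFs and D65 are embedded as the standard 10 nm tables and
spline-resampled to band centres; the tables reproduce the D65 white point
(0.95047, 1, 1.08883) to 0.1%. The normalisation k sets the Y of a unit
reflector **over the cube's band set** to 1 and is fixed per band set, not
per image — per-image normalisation would hide brightness errors when
comparing reconstructions. For band-limited sensors (e.g. 470–620 nm) the
integral is truncated, a unit reflector maps to a fixed non-white
chromaticity (returned as the `"whitepoint"` attribute), and an optional
`rescaleWhite` toggle (off by default) compensates channelwise for display.
`xyzToSRGB()` applies the standard XYZ→linear-sRGB matrix, clips to [0,1],
the piecewise sRGB transfer (linear below 0.0031308, exponent 2.4 above)
and round-half-up 8-bit quantisation. Chromatic adaptation, tone mapping
and ICC embedding are out of scope.

Note on scales: forward-model cubes carry raw response inner products
(units reflectance×nm), not reflectance. `bandIntegralScale()` returns the
unit-reflector band value for display scaling, and `evaluateSuite()`
normalises each pair by the reference maximum before computing metrics —
PSNR is range-dependent, so the convention is explicit.

## Metrics

L1 is the plain mean absolute difference; PSNR is $10\log_{10}(1/MSE)$ on
unit-normalised data with an `Inf` sentinel for identical inputs; SSIM uses
the standard Gaussian 11×11 window (σ = 1.5), K1 = 0.01, K2 = 0.03,
dynamic range 1, valid-mode windows, applied per band and averaged (the
multiband reduction is a convention; it is stated here because it is not
canonical). The SSIM implementation is verified against an explicit
per-window brute-force oracle to 1e-8. The perceptual score is an
LPIPS-style feature distance behind an injectable extractor; scores from
published weights are deliberately not claimed.

## Phantoms: what they emulate, and what they do not

`makePhantomHypercube()` emulates the statistical structure of
white-balanced tissue reflectance cubes: 2–4-Gaussian-plus-baseline
material spectra (smooth, in [0,1], pairwise RMS separation ≥ 0.03),
smoothed-Voronoi abundance maps forming a partition of unity, curvilinear
vessel-like strokes darkening the cube through a smooth absorption band
around 540 nm, and mild additive noise (sd 0.002, clipped at 0). Defaults
are 64×64 pixels and 121 bands over 420–680 nm — enough margin around a
470–620 nm sensor that band responses are fully sampled, while keeping the
desk-scale study fast. Vessel strokes provide the high-frequency structure
on which a learned demosaicker visibly beats bilinear interpolation.

Phantoms are *not* radiometrically calibrated tissue: no specific
chromophores, no specularities, no camera noise model, no real-scene
texture spectrum. Passing the desk-scale study therefore shows that the
pipeline is implemented correctly and that learning extracts real signal
from mosaic-sampled data under controlled conditions; it does not certify
reconstruction quality on clinical data.

## Study sizes and numerical choices

The packaged study (also what `scripts/acceptance.R` reruns) uses 20
phantoms split 12/4/4, the 16-band 4×4 visible-range default sensor with
ni = 13 ideal bands, and ≤ 500 training iterations — sizes chosen so the
whole suite runs in minutes on a single core while leaving a clear gap
between the baseline and the learned method. Other fixed choices:
float32 as the ENVI on-disk dtype; 16-bit TIFF snapshots with the scale
factor recorded in a JSON sidecar; all randomness derived from a single
root seed via a stable per-item derivation; duplicated mosaic cells for
one band are reconstructed per cell and averaged (exactness at sample
sites is then guaranteed only for one-cell-per-band layouts, which is what
real sensors use).

## Known limitations

- The measured-response synthesis is a plausible parasitic model, not a
  calibrated one; C quality against a real factory calibration is untested.
- The perceptual loss/score use random frozen features, not pretrained
  weights; absolute perceptual numbers are not comparable to published
  values.
- Angular dependence of Fabry–Pérot filters, sensor noise and optics are
  not modelled.
- The pure-R network engine is adequate for desk-scale studies; full-scale
  training (224×224 patches, depth 4) calls for a GPU framework outside
  this package's scope.
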