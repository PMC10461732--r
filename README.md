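# mosaicHSI

Simulation and learned demosaicking of snapshot mosaic hyperspectral
images, in R.

Snapshot mosaic cameras tile an n×n spectral filter array over the pixel
grid and capture a whole hyperspectral frame in one exposure — at the cost
of recording only **one band per pixel**. They are the leading route to
real-time hyperspectral imaging in image-guided surgery, where line-scan
cameras are too slow. Exploiting the data requires solving an ill-posed
*demosaicking* problem (recovering the full X×Y×ns cube from the scalar
X×Y mosaic frame) and correcting the *parasitic spectral behaviour* of
real Fabry–Pérot filter mosaics (cross-talk, harmonics, leakage).

mosaicHSI is for researchers building or evaluating such pipelines. It
provides, end to end:

- **Sensor model** — ideal band responses as Lorentzian band-passes

  f(λ; λ₀, QE, FWHM) = QE · αλ² / ((λ − λ₀)² + αλ²),
  α = (√(λ₀² + FWHM²) − λ₀)² / FWHM²,

  the unique α giving half-maximum crossings separated by exactly FWHM;
  synthetic parasitic "measured" responses; and the ni×ns spectral
  correction matrix **C** (ridge-regularised least squares when not
  supplied by a calibration file).
- **Forward model** — white balance, per-pixel inner products of sensor
  responses with HR spectra (intermediate X×Y×ns cube), mosaic
  subsampling to the 2D snapshot, and the ideal X×Y×ni target cube.
- **Demosaicking** — an offset-aware bilinear baseline, and a residual
  U-Net super-resolver (built-in conv-net engine with verified
  backpropagation and Adam; no external deep-learning framework) trained
  with the combined loss ‖yᵢ − Cŷₛ‖₁ + γ·aux (γ = 0.001; L1 or
  frozen-feature perceptual auxiliary), with C embedded after the network.
- **Colorimetry** — CIE 1931 XYZ under D65 and sRGB rendering.
- **Metrics** — L1, PSNR, SSIM (verified against a brute-force per-window
  oracle) and a pluggable LPIPS-style perceptual score.
- **Phantoms** — a synthetic generator of tissue-like reflectance cubes
  (smooth material spectra, Voronoi regions, vessel-like strokes), so the
  whole pipeline runs and is tested with no external data.
- **I/O** — ENVI cubes (BSQ write, BSQ/BIL/BIP read), 16-bit TIFF
  snapshots with JSON sidecars, YAML sensor descriptions, and a CLI
  (`inst/scripts/hsdemosaic.R`).

## Worked example

Simulate a 16-band 4×4 snapshot from a synthetic phantom, reconstruct it
with the bilinear baseline and with a trained residual U-Net, and compare:

```r
library(mosaicHSI)

sensor <- defaultSensor()                  # 4x4, ns = 16, ni = 13, 470-620 nm
ds <- makeDataset(phantomSpec(seed = 101), count = 20,
                  split = c(0.6, 0.2, 0.2), sensor = sensor)

# default network: residual U-Net, depth 2, width 16 (desk-scale profile)
trained <- trainDemosaicker(
  ds$train, ds$val, sensor,
  tcfg = trainConfig(iterations = 500, learningRate = 1e-3,
                     evalEvery = 100, seed = 5))

score <- function(recon, ref) {
  m <- max(cubeData(ref))
  c(psnr = psnr(cubeData(ref) / m, cubeData(recon) / m),
    ssim = ssim(cubeData(ref) / m, cubeData(recon) / m))
}
rowMeans(sapply(ds$test, function(s)
  score(linearPipeline(s@snapshot, sensor), s@ideal)))
#>       psnr       ssim
#> 30.3626218  0.9271098
rowMeans(sapply(ds$test, function(s)
  score(learnedPipeline(s@snapshot, trained, sensor), s@ideal)))
#>       psnr       ssim
#> 33.3408398  0.9720750
```

On the four held-out phantoms the learned demosaicker improves mean PSNR
by about 3 dB over bilinear interpolation (30.4 → 33.3 dB) and SSIM from
0.927 to 0.972: the network recovers the vessel-scale detail that
bilinear upsampling blurs, while the embedded matrix C corrects the
sensor's parasitic spectral mixing in both pipelines. (Training takes a
few minutes on one CPU core; runs are bit-reproducible from the seeds.)

Render any reconstruction for visual inspection:

```r
rgb <- hypercubeToSRGB(linearPipeline(ds$test[[1]]@snapshot, sensor),
                       rescaleWhite = TRUE,
                       scale = bandIntegralScale(sensor))
png::writePNG(rgb, "reconstruction.png")
```

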