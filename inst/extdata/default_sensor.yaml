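schema: sensor-1
name: visible-4x4
grid:
  start: 400.0
  stop: 1000.0
  step: 1.0
mosaic:
  'n': 4
  assignment:
  - 0
  - 1
  - 2
  - 3
  - 4
  - 5
  - 6
  - 7
  - 8
  - 9
  - 10
  - 11
  - 12
  - 13
  - 14
  - 15
measured:
  specs:
  - lambda0: 470.0
    qe: 0.8
    fwhm: 12.0
  - lambda0: 480.0
    qe: 0.8
    fwhm: 12.0
  - lambda0: 490.0
    qe: 0.8
    fwhm: 12.0
  - lambda0: 500.0
    qe: 0.8
    fwhm: 12.0
  - lambda0: 510.0
    qe: 0.8
    fwhm: 12.0
  - lambda0: 520.0
    qe: 0.8
    fwhm: 12.0
  - lambda0: 530.0
    qe: 0.8
    fwhm: 12.0
  - lambda0: 540.0
    qe: 0.8
    fwhm: 12.0
  - lambda0: 550.0
    qe: 0.8
    fwhm: 12.0
  - lambda0: 560.0
    qe: 0.8
    fwhm: 12.0
  - lambda0: 570.0
    qe: 0.8
    fwhm: 12.0
  - lambda0: 580.0
    qe: 0.8
    fwhm: 12.0
  - lambda0: 590.0
    qe: 0.8
    fwhm: 12.0
  - lambda0: 600.0
    qe: 0.8
    fwhm: 12.0
  - lambda0: 610.0
    qe: 0.8
    fwhm: 12.0
  - lambda0: 620.0
    qe: 0.8
    fwhm: 12.0
  parasitics:
    crosstalk: 0.04
    harmonic: 0.03
    leakage: 0.005
    seed: 2021
ideal:
  specs:
  - lambda0: 480.0
    qe: 1.0
    fwhm: 10.0
  - lambda0: 491.0
    qe: 1.0
    fwhm: 10.0
  - lambda0: 502.0
    qe: 1.0
    fwhm: 10.0
  - lambda0: 513.0
    qe: 1.0
    fwhm: 10.0
  - lambda0: 524.0
    qe: 1.0
    fwhm: 10.0
  - lambda0: 535.0
    qe: 1.0
    fwhm: 10.0
  - lambda0: 546.0
    qe: 1.0
    fwhm: 10.0
  - lambda0: 557.0
    qe: 1.0
    fwhm: 10.0
  - lambda0: 568.0
    qe: 1.0
    fwhm: 10.0
  - lambda0: 579.0
    qe: 1.0
    fwhm: 10.0
  - lambda0: 590.0
    qe: 1.0
    fwhm: 10.0
  - lambda0: 601.0
    qe: 1.0
    fwhm: 10.0
  - lambda0: 612.0
    qe: 1.0
    fwhm: 10.0
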