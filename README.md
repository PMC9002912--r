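# purkinjelca

Objective measurement of the eye's longitudinal chromatic aberration (LCA)
from fourth Purkinje image (PIV) spot patterns — the dim, inverted
reflections of a square LED array off the posterior surface of the
crystalline lens — recorded under a blue (440–480 nm) and a red
(580–640 nm) pulse band. It is written for vision scientists and
instrument builders who want the full analysis chain of such a two-band
Hartmann-type measurement, together with a synthetic eye-image simulator
that makes every stage testable without clinical data.

## Method

A spot's displacement from its reference position measures the local
wavefront slope (Hartmann test). The wavefront over the pupil is expanded
in the low-order Cartesian Zernike basis on pupil-normalized coordinates,

    W(x, y) = Σ_{i=0..5} C_i Z_i(x, y),
    Z0 = 1, Z1 = x, Z2 = y, Z3 = 2xy, Z4 = −1 + 2x² + 2y², Z5 = y² − x²,

and the four-point slope field is inverted for C1–C5 by a closed-form
least squares (the design's gradient columns are orthogonal), verified
against a generic QR solver to 1e-10. Comparing the blue PIV pattern
directly with the red one isolates the chromatic wavefront, whose defocus
coefficient converts to diopters by

    D = D_b − D_r = 4√3 (C_b4 − C_r4) / R²,

with the coefficients in µm and the pupil radius R in mm. Detection uses a
circle Hough transform for the iris, intensity banding (PIV lives in low
grey levels, the bright PI reflection in 200–255), connected-component
noise removal, a small-radius Hough pass for the four spots, and pixel-sum
centroids. The Atchison chromatic-difference-of-refraction polynomial
Rx(λ) provides a literature reference value for any wavelength pair in
365–950 nm.

## Worked example

```r
library(purkinjelca)

cfg <- lca_config()                          # 0.05 mm/px, R = 2.5 mm, ρ = 0.6
sim <- simulate_subject(0.5, cfg, seed = 11) # inject 0.5 D of LCA
m   <- measure_lca(sim$blue, sim$red, cfg)
m
#> Objective LCA measurement (blue vs red pulse band)
#>   C4 blue: 0.7535 um,  C4 red: 0.2993 um,  pupil R: 2.5 mm
#>   LCA: 0.5035 D
#>   dispersion-model reference (460-610 nm): 1.0108 D
```

The per-band defocus coefficients (µm) are fitted against the ideal LED
grid; their difference, 0.4542 µm, converts to 0.5035 D — within 0.7% of
the injected 0.5 D, the residual being centroid discretization error of
the 8-bit rendering. The dispersion-model line is the Atchison reference
between the band-centre wavelengths, printed for comparison.

Reference values from the dispersion model alone:

```r
chromatic_refraction(750) - chromatic_refraction(365)  # 3.2268 D
lca_reference(400, 700)                                # 2.2057 D
```

A thin command-line front end over the same functions ships in
`inst/cli/purkinje-lca` with `simulate`, `detect`, `measure` and `report`
subcommands.

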