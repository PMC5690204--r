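---
title: "Film read-out methods: scanner corrections, calibration and merging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Film read-out methods: scanner corrections, calibration and merging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(ebt3dose)
```

This vignette documents the measurement model behind `ebt3dose`, the
reasoning for the package's default parameters, and the limits of the
bundled synthetic scanner/film simulator. It works at a reduced bed size
(160 x 200 px instead of the full 576 x 720 px bed) so every chunk runs in
seconds; nothing about the methods depends on the bed size.

## The measurement model

Radiochromic film read in transmission on a flatbed scanner yields, per
colour channel, a 16-bit pixel value `PV`. The dose-carrying signal is the
*net optical density* formed against a background scan of the **same**
film piece taken before irradiation:

$$\mathrm{netOD} = \log_{10}\!\frac{PV_\mathrm{unexposed}}{PV_\mathrm{exposed}}.$$

Because both readings come from the same piece, multiplicative film
nonuniformity (emulsion bands, piece-to-piece background variation)
cancels in the ratio. What does *not* cancel is the scanner's own
position-dependent sensitivity, which differs between the two scans'
content and is additive in PV. The package therefore corrects pixel
values before forming the OD:

$$PV_\mathrm{corr}(x, y) = PV(x, y) + M(x, y) + M_D(x, D),$$

a two-phase additive correction:

* **Matrix correction `M`** — derived from a stack of unexposed film
  scans. The stack mean is flattened to its mean over the *normalization
  area*, a 3 cm x 4 cm region at the plate centre where the scanner is
  defined to be correct. `M` captures everything dose-independent: the
  transversal (lateral) sensitivity falloff, the smaller longitudinal
  one, and any fixed-pattern structure.
* **Dose-dependent transversal correction `M_D`** — flatbed lateral
  response grows with the darkness of the film, so `M` alone
  undercorrects exposed film away from the centre. `M_D(x, D)` is
  measured by exposing one film stripe to a single known dose, scanning
  it at several transversal placements, and recording what the matrix
  correction failed to remove at each bed column. The table is anchored
  by an implicit all-zero row at dose 0 (an unexposed film is fully
  corrected by `M`), is forced to zero over the normalization columns,
  and is interpolated linearly in dose.

`M_D` depends on the dose one is trying to measure, so
`apply_corrections_iterative()` runs a fixed-point iteration: convert
with `M` only, estimate the dose, re-correct with `M + M_D(x, D)`,
re-estimate, and stop when the largest pixel dose change falls below a
tolerance (default 0.1% of the median first estimate, floored at
0.002 Gy). The correction is a small perturbation of the dose scale, so
the iteration contracts fast; two to three iterations are typical.

```{r corrections}
scanner <- scanner_model(width_px = 160, height_px = 200)
film <- film_model()

stack <- generate_unexposed_stack(6, film, scanner, seed = 11)
mat <- build_matrix_correction(stack$scans, norm_roi = scanner$norm_roi)
mat

stripes <- generate_stripe_series(2, positions = c(71, 89), film, scanner,
                                  seed = 31)
md <- build_dose_transversal_correction(stripes, mat)
md
```

## Calibration

Net OD is converted to absorbed dose to water through a rational
response

$$D(x) = \frac{a + c\,x}{1 + b\,x},$$

fitted per channel to calibration points from traceably exposed film
pieces. After clearing the denominator the model is linear in
`(a, c, b)`, which gives exact starting values; a Levenberg–Marquardt
pass then minimizes the untransformed dose residuals. Fits are refused
when the curve has a pole or is non-monotone inside the data range.

Two functional forms circulate in film dosimetry for this response: the
fully rational form above and an additive variant
`D(x) = a + c x / (1 + b x)`. They are not reparameterizations of each
other, so `fit_calibration(form = "additive")` exposes the second form
as an explicit configuration switch rather than silently choosing one.
The default is the fully rational form.

Doses are determined as the **mean of the red- and green-channel doses,
averaged in dose space** — never by averaging PVs or ODs, which would
mix channels with different sensitivities. The blue channel's response
is kept for quality control only. Negative net OD (noise around zero
dose) clamps to 0 Gy, defining the dose zero level; conversions beyond
the calibrated range are flagged (or refused), because extrapolation
above the top calibration point is not certified. Curves are per film
lot and expire after three months.

```{r calibration}
calset <- generate_calibration_set(c(0.25, 0.5, 1, 2, 4, 8), film, scanner,
                                   seed = 21)
points <- measure_calibration_points(calset, matrix = mat)
curve <- fit_calibration_curves(points, lot_id = "SIMLOT", q = "Co-60")
curve
```

## Four-orientation read-out and merging

A film is scanned four times: normal, rotated 180°, flipped, and flipped
plus rotated. After correction and dose conversion, each map is restored
to the film frame by the exact inverse index permutation (all four
transforms are involutions; no interpolation ever happens). Dust on the
scanner glass contaminates a fixed *bed* position, which maps to four
*different* film positions — so per pixel, any orientation deviating
from the median of the four by more than
`max(2% of the median, 0.04 Gy)` is discarded and the survivors are
averaged. At least two orientations always contribute; pixels where
fewer survive fall back to the two values nearest the median and are
flagged unreliable. Averaging four maps also halves the read noise.

```{r readout}
piece <- film_piece(film, "SHEET1", scanner$width_px, seed = 41)
field <- flat_top_dose_field(2, field_cm = 3, penumbra_cm = 0.3,
                             scanner = scanner)
t0 <- as.POSIXct("2024-03-01 12:00:00", tz = "UTC")
tags <- c("normal", "rot180", "flipped", "flipped_rot180")
entries <- lapply(seq_along(tags), function(i) {
  bg <- simulate_scan(uniform_dose_field(0, scanner), piece, scanner,
                      orientation = tags[i], seed = 100 + i,
                      exposure_time = t0, scan_time = t0 - 86400)$scan
  ex <- simulate_scan(field, piece, scanner, orientation = tags[i],
                      seed = 200 + i, dust_count = 2L,
                      exposure_time = t0, scan_time = t0 + 4 * 86400)$scan
  list(exposed = ex, background = bg, tag = tags[i])
})
res <- run_readout(readout_config(entries, list(matrix = mat, md = md), curve))
res
```

## Quality control

Three rule families are enforced, all logged with their rule name and
measured values:

* **Background homogeneity** (`background_qc()`): a film piece whose
  unexposed reading deviates from the lot mean by more than 0.5% in red
  or green, or 1% in blue, is rejected. The thresholds are strict
  (`>`): a deviation of exactly 0.5% still passes.
* **Blue-band homogeneity** (`homogeneity_qc_blue()`): emulsion
  spreading shows as longitudinal sensitivity bands, most visible in the
  blue channel of unexposed film; a sheet whose per-column blue profile
  deviates from the sheet mean by more than 1% anywhere is rejected. On
  a full bed the scanner's own lateral falloff (up to ~1800 PV, several
  percent) dwarfs film bands, so pass the matrix correction to flatten
  the scanner first.
* **Timing** (`timing_check()`): film darkens after exposure, so
  read-out happens on a fixed schedule — four days after irradiation
  with a ±12 h tolerance by default, or a 48 h window with a tight
  ±0.5–1 h tolerance.

## Uncertainty budgeting

`uncertainty_budget()` combines relative standard uncertainties (% at
1 SD) in quadrature, step by step, and expands the final combined value
by a coverage factor:

```{r budget}
uncertainty_budget(c(
  "calibration of the film system"  = 1.40,
  "scanner corrections"             = 0.71,
  "film dose measurement"           = 1.00), k = 2)
```

## The simulator: parameters and their rationale

The package ships a forward model (`scanner_model()`, `film_model()`,
`simulate_scan()` and the `generate_*()` helpers) that produces scans
paired with exact ground truth, so every stage of the pipeline is
testable without scanner hardware. Its defaults are frozen to magnitudes
representative of a consumer flatbed used for film dosimetry:

* **Transversal deficit 300 PV (left) / 1800 PV (right), longitudinal
  340 PV**, quadratic ramps that are exactly zero over the normalization
  area. These set the size of the artifact `M` must remove.
* **Pixel noise 9 PV (1 SD).** Chosen so that the maximum pixel
  difference between two matrix corrections each derived from a 10-scan
  stack is about 20 PV — the repeatability a well-behaved flatbed
  achieves. (The maximum of |N(0, 9·√(2/10))| over 576 x 720 pixels has
  expectation ≈ 19.5 PV.)
* **Dose-dependent lateral deficit 600 PV (red/green) at the right edge
  per 2 Gy**, scaling linearly with dose: large enough that a
  matrix-only pipeline fails a 0.5% profile-flatness check by an order
  of magnitude, as the real effect does.
* **+0.03% reading drift per successive scan of exposed film**, the
  reason `average_repeated_scans()` fits a per-pixel trend for bursts
  longer than five scans instead of a plain mean.
* **Stripe dose ripple 0.1% (1 SD).** The stripe used to derive `M_D` is
  exposed on a rotating reel whose dose uniformity is well under 0.2%;
  the simulator puts a smooth 0.1% pattern on the stripe that travels
  with the film across placements. This ripple is the dominant error
  source of `M_D` and budgets the end-to-end flatness at roughly 0.2%,
  comfortably inside the 0.5% acceptance bound.
* **Dust factor 0.92** (an 8% darkening inside a speck), roughly a +20%
  local dose error at 2 Gy — far outside the merge thresholds, which is
  what makes single-orientation specks reliably removable.
* **2 Gy anchor:** a 40000 PV red background with the default response
  places a 2 Gy exposure at about 26 250 PV, inside the 26000–26500 PV
  window where the film's relative dose resolution is best.

All sensitivity terms are additive in PV and vanish over the
normalization area, so the additive two-phase correction is exactly the
right correction class for the simulator. That is deliberate — the
generator is a testbed for the pipeline, not an optics simulation.

### Limitations

The simulator does not model optical scatter or Callier-type effects
(which make real lateral response multiplicative to some degree),
film-curl Newton rings, scanner warm-up drift within a scan, JPEG-like
compression artifacts (scans are always lossless), or the energy
dependence of the film response; the beam quality `q` is carried as
metadata only. Corrections derived on the simulator therefore validate
the *pipeline logic*, not any particular physical scanner. For a real
instrument, `M` and `M_D` must be measured on that instrument with the
same protocol.
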