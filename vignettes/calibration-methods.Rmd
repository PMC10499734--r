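---
title: "Calibrating scanner and staining variation for automated HER2 assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating scanner and staining variation for automated HER2 assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihccal)
```

## The problem

Automated HER2 scoring of breast-cancer immunohistochemistry reduces
each cell to one number — the mean DAB optical density of its membrane —
and compares it against three intensity thresholds. Both the whole-slide
scanner (channel crosstalk, display-gamma encoding, incident-light
colour) and the staining batch (day-to-day DAB intensity) move that
number before any algorithm sees it, so thresholds tuned on a reference
laboratory silently misclassify elsewhere. `ihccal` implements a
two-stage calibration built on two physical calibrator slides — a colour
chart slide for the device, a DAB microbead calibrator for the stain —
and an automated scoring chain, validated end to end against synthetic
renderings with exact ground truth.

## Stage 1: device model and chart-based correction

The device model assumed throughout is

1. linear colour mixing: a 3×3 matrix applied to the linear-light RGB
   entering the sensor, with unit row sums so clear glass stays white;
2. per-channel incident light `I0`, measured on clear glass;
3. additive sensor noise in device space;
4. a global display-gamma encoding `value^(1/gamma)`.

Correction inverts these in reverse order: Hadamard division by `I0`
(so glass maps to (1,1,1)), the power law `value^gamma`, and a
polynomial colour map. Three choices deserve comment.

**Gamma from grayscale luminance.** The exponent is fitted by bounded
1-D least squares (`stats::optimize` on [0.2, 5], tolerance 1e-10) on
the luminance of the neutral patches A1, B1, C1 and the background,
where luminance is the Y row of the sRGB matrix. Because the background
normalizes to exactly 1 — a fixed point of every power law — the
saturation guard (only patches with Y strictly inside (0, 1) enter the
fit) removes it automatically; the three gray steps carry all the
information. A chart whose grays are saturated raises an
insufficient-data error rather than returning a meaningless exponent.

**White-point-preserving polynomial correction.** The map uses exactly
the five-term basis (R, G, B, R·G·B, 1) per output channel. The
white-preservation constraint `M{(1,1,1)} = (1,1,1)` is imposed through
the KKT (Lagrange multiplier) system of the constrained least-squares
problem, not by penalty weighting, so it holds to machine precision for
every fitted map regardless of noise — a property the test suite
asserts at 1e-9. With 13 chart colours and 5 basis terms the normal
matrix is well conditioned; a chart of identical colours is rejected as
a degenerate fit.

**Colorimetry tables.** Reference chart colours come from spectral
transmittance on the 340–830 nm / 5 nm grid. The CIE 1931 2° observer
is embedded as a published analytic multi-lobe piecewise-Gaussian
approximation (clamped at zero), and the D65 illuminant as the
Planckian radiator at 6504 K — both smooth analytic stand-ins for the
tabulated standards. To make the pipeline exactly self-consistent
despite the approximation, the spectral integration is normalized per
channel so that full transmittance maps onto the white point implied by
the sRGB matrix (for Y this is the usual `k = 1/sum(S*ybar)` up to the
1e-7 rounding of the published matrix). The practical consequences:
clear glass is exactly (1,1,1) in linear RGB, matching the
white-preservation constraint and the incident normalization; and all
ground truth used in validation is generated and inverted under the
same tables, so no conclusion depends on their absolute accuracy. What
this does *not* provide is NIST-traceable absolute colorimetry of a
physical chart; users with a real chart substitute its calibration CSV
via `load_spectral_table()`.

Out-of-gamut values are never clipped inside the pipeline — fitting
needs signed residuals — only at image export. dE\* is the plain CIE76
Euclidean distance in CIELAB (not CIEDE2000), with the conventional
reading of < 1 as imperceptible and 1–2 as expert-perceptible;
`compute_de_map()` reports pixelwise maps with mean/SD over an optional
mask and a 64-bin histogram.

## Stage 2: staining model and intensity transfer

Optical density is `OD = -log10(value / incident)` per channel, floored
at one 16-bit code value (1/65536) so dark pixels stay finite. Colour
unmixing solves the 3×3 system spanned by the DAB vector, the
hematoxylin vector and their normalized cross product (the residual
channel); stain concentrations are clipped at zero, the residual stays
signed.

The DAB direction is estimated from the calibrator beads as the
unit-normalized mean direction of the *lightly stained* levels — OD
norm in (0.02, 0.6) by default — because strongly stained DAB scatters
and departs from Beer–Lambert linearity, making dark beads unreliable
direction estimates. The calibrator carries no hematoxylin, so that
vector defaults to the widely used Ruifrok–Johnston direction and is
overridable.

Bead measurement is layout-driven when the slide geometry is known
(the shipped renderer records it): within each level rectangle, bead
pixels are those with summed OD above 0.05, eroded by one pixel to
avoid rim effects. A level too light to clear the pixelwise threshold
falls back to the central half of its rectangle — geometrically inside
the bead — provided its mean summed OD exceeds 0.005, comfortably above
glass noise; a truly blank level is a missing-level error. Without a
layout, beads are auto-detected by connected components and assigned to
levels by grid position.

The intensity transfer pairs level *k*'s DAB OD on the target batch
with level *k*'s on the reference batch, prepends the anchor (0, 0),
and interpolates piecewise-linearly, continuing the last segment's
slope beyond the last knot (the dark regime is unreliable anyway, and
the classification thresholds live far below it). Noisy, non-monotone
ladders are first repaired by isotonic regression; duplicate abscissae
are collapsed by averaging. Method 1 maps the reference thresholds
through the *inverse* transfer onto the target scale; a threshold
landing on a flat segment inverts to the segment midpoint with a
warning. Method 2 unmixes with the target stain model, maps the DAB
channel forward, and recomposes with the reference vectors, leaving
hematoxylin and the residual untouched. For any strictly monotone
transfer the two methods classify identically except for cells lying
numerically on a threshold, a cross-method property the suite checks on
rendered phantoms.

## Scoring

Immunoscore intervals are half-open with the boundary belonging to the
higher score (an OD exactly at t2 scores 2). The H-score is
`sum(Pm * m)` over score percentages, 0–300. The status rule is a
percentage reduction of the ASCO/CAP guideline — 3+ if P3 > 10, else 2+
if P2+P3 > 10, else 1+ if P1+P2+P3 > 10, else 0, with strict
comparisons — and is configurable, because membrane-completeness
criteria are not computable from mean OD alone. Cells without detected
nuclei are retained for scoring.

**Automatic threshold derivation.** Reference thresholds are found by
exhaustive search over ordered triples on a 0.01–0.60 OD grid (0.01
steps, ≈34k triples), maximizing the count of score-known reference
cases whose automated status matches. Among equally concordant triples
the package picks the *max-margin* one — the triple whose thresholds
keep the greatest minimal distance to any observed reference cell OD —
with remaining ties broken lexicographically toward small thresholds.
The margin criterion matters: the smallest concordant triple always
abuts an empirical quantile of some reference case (typically the
90th percentile of the 2+ case), and a threshold that touches a cell's
OD does not survive the ±0.002–0.005 OD re-measurement jitter between
serially sectioned datasets; centering it in the concordant region
makes the derived thresholds generalize. The search is exact and
deterministic.

## What the synthetic data emulates — and what it does not

The generator renders all three slide types under the stage-1 device
model plus a per-batch multiplicative DAB scale:

* charts: reference colours painted into a 3×4 patch grid with a glass
  background, canvas 160×208 px;
* calibrators: ten bead disks (radius 10 px, two rows of five) at
  nominal ODs on a geometric ladder from 0.02 to 1.2 — the real
  calibrator's level ODs are not public, so the ladder spans the range
  from barely-stained to beyond the Beer–Lambert-reliable regime;
* tissue phantoms: 35 non-overlapping cells per 180×180 px image
  (dart-throwing placement), each a hematoxylin nucleus disk
  (radius 4–6 px, OD 0.6) with a 3 px DAB membrane annulus whose
  nominal OD is drawn from per-status uniform mixtures chosen to sit
  clearly between thresholds near (0.05, 0.15, 0.29) — the working
  range of DAB thresholds in practice.

Scanner noise defaults to additive Gaussian sd 0.003 in device space;
random device matrices are identity plus half-normal nonnegative
crosstalk (scale 0.05), rows renormalized, condition number capped at
10 — crosstalk is nonnegative because negative mixing coefficients
would drive dark saturated colours below zero where clipping destroys
information no calibration can recover, which is not how sensor
response behaves. Two fixed personalities (A: mild crosstalk, B:
stronger) make multi-scanner designs reproducible by name. The
experiment design mirrors a two-scanner study: ten target datasets over
scanners {A, B} and display gammas {1.0, 1.8, 2.2}, batch scales drawn
uniformly from [0.7, 1.3], with per-case cell geometry held fixed
across datasets (serial sections) while scanner noise varies.

The phantoms deliberately omit several properties of real slides:
optical blur and focus variation, spatial illumination gradients,
cytoplasmic staining between nucleus and membrane, touching/overlapping
cells, nuclear pleomorphism, and the dark-DAB scattering nonlinearity.
Passing the suite therefore demonstrates that the *inverse problems are
solved correctly under the forward model* — gamma and colour maps are
recovered exactly, batch scales are transferred, statuses are restored —
not that the simplified blob detector or the thresholds would transfer
unchanged to clinical images. Real per-cell measurements enter through
the CSV table path and reuse the entire scoring and calibration chain.

## Numerical choices and validation sizes

Tolerances and conventions collected in one place: gamma search
interval [0.2, 5], objective tolerance 1e-10; white-preservation
asserted at 1e-9; unmixing closure at 1e-10; OD floor 1/65536; bead
pixel threshold 0.05 summed OD (fallback floor 0.005); light-level
window (0.02, 0.6) OD norm; central patch fraction 50% per side;
stain-matrix condition limit 1e6; dE\* histograms with 64 bins; nucleus
detection at hematoxylin OD 0.15, membrane read-out on the annulus
(r+0.5, r+2.5] around the estimated nucleus radius.

The validation suite uses problem sizes chosen to exercise every
component while keeping a full run in tens of seconds: 50 random
devices × 3 gammas for calibration recovery, 100 noisy charts for the
gamma estimator, 20 phantoms for method equivalence, the 10-dataset ×
4-case design (plus both full selectors and the uncalibrated baseline)
for concordance and H-score variability, and 8 score-known cases for
threshold recovery. `scripts/acceptance.R` recomputes all of it from a
single seed.

## Known limitations

Registration between scanners is out of scope — dE\* maps require
pre-aligned images. Only illuminant D65 is supported; there is no
chromatic adaptation or ICC profile generation. The hematoxylin channel
is never rescaled by the staining calibration, so without the chart
stage a gamma-encoded image keeps a miscalibrated counterstain (visible
as reduced nucleus detection). The transfer map is only as good as the
calibrator in its light-to-mid range; behaviour beyond the last bead is
a linear guess. And the status rule operates purely on percentages of
mean-OD scores, a deliberate reduction of the clinical guideline.
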