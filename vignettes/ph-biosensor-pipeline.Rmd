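---
title: "Ratiometric pH-biosensor imaging and screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric pH-biosensor imaging and screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phscreen)
```

## The measurement problem

Dual-excitation ratiometric pH sensors such as the mCherryEA variant of
mCherry report cytoplasmic pH through the protonation state of their
chromophore: excitation at the shorter wavelength grows with pH while
excitation at the longer wavelength shrinks, and the ratio of the two
emission intensities cancels expression level, cell density and optical
path. This makes the ratio usable both in kinetic plate-reader assays
(excitation 454/580 nm, emission 630 nm) and — the step this package
automates — on whole colonies arrayed on agar plates and photographed in a
gel-documentation imager (excitation 440/530 nm, emission 595 nm), where
it turns a plate photo into a per-colony internal-pH readout and a
screening statistic.

`phscreen` implements the full chain: a seeded forward simulator of
sensor-bearing colonies and wells (ground truth for every downstream
test), colony-grid quantification of two-channel 16-bit plate images,
Boltzmann calibration and inversion with detection-limit handling, robust
hit calling over arrayed libraries, and kinetic trajectory analysis with
surfactant (CTAB) end-point recalibration.

## The sensor response model

The calibration curve is the four-parameter Boltzmann sigmoid

$$R(\mathrm{pH}) = A_2 + \frac{A_1 - A_2}{1 + e^{(\mathrm{pH} - x_0)/dx}},$$

strictly increasing from the acid asymptote $A_1$ to the alkaline
asymptote $A_2$, with midpoint $x_0$ (the apparent p$K_a$) and width
$dx$. Its analytic inverse,
$\mathrm{pH} = x_0 + dx\,\log\!\big(\tfrac{A_1-A_2}{R-A_2} - 1\big)$,
is applied only inside the sensor's dynamic range (pH 6.5–8.75 for
mCherryEA); outside it the reported pH is clamped to the nearest
detection limit and flagged. Clamping rather than discarding mirrors how
such readings are used in practice: a trajectory pinned at 6.5 *is* the
observation "at or below the lower detection limit".

Two default parameter sets ship with the package, one per instrument
scale (the two are never mixed):

* **In-vitro / plate-reader** (`sensor_params_invitro()`):
  $x_0 = 7.3$ (the sensor's apparent p$K_a$), $A_1 = 0.1$, $A_2 = 3.0$,
  $dx = 0.35$. The asymmetric placement of 7.3 within the 6.5–9.0 span
  gives the characteristic ~8-fold ratio increase from pH 6.5 to 9.0.
* **Colony imager** (`sensor_params_imager()`): the imager reports
  compressed ratios (≈0.5–1.2). Three in-situ anchor readings are
  available to pin the curve — ratio 0.55 at pH 6.5, 0.73 at pH 7.53 and
  1.15 at pH 8.75. Three anchors cannot determine four parameters, so the
  width is fixed at $dx = 0.5$ (a broad in-situ curve whose solved
  midpoint, 8.01, stays inside the detection window; narrower choices
  push the midpoint toward the upper limit, wider ones beyond it) and
  $A_1, A_2, x_0$ are solved exactly through the anchors. The midpoint is
  deliberately left free of the in-vitro value: nothing requires the two
  instruments' ratio scales to share a midpoint.

```{r}
p <- sensor_params_invitro()
boltzmann_ratio(9.0, p) / boltzmann_ratio(6.5, p)   # ~8-fold
sensor_params_imager()
```

## The acquisition model

`channel_intensities()` factorizes the two channels as

$$I_B = b + g\,L\,\gamma(\mathrm{pH}), \qquad
  I_A = b + R(\mathrm{pH}) \cdot (I_B - b),$$

with gain $g$, expression level $L$, additive instrument background $b$,
and $\gamma$ a decreasing sigmoid (sharing $x_0$ and $dx$ with $R$;
asymptotes 1 → 0.7) that encodes the loss of the long-wavelength
excitation peak as the chromophore deprotonates. The factorization
guarantees by construction that the *background-subtracted* channel ratio
equals $R(\mathrm{pH})$ exactly and is invariant to $L$ and $g$, while
the *raw* ratio — which is what instruments print and what all published
plate statistics use — carries a small background-dependent offset. The
package is consistent about this distinction: calibrations are fitted to
raw measured ratios (so the offset is absorbed into the fitted curve),
and ground-truth ratios on synthetic plates are planted on the raw scale
by numerically inverting the full acquisition model
(`ph_for_raw_ratio()`).

The $\gamma$ asymptote 0.7 is chosen so that $\gamma \cdot R$ (channel A)
remains strictly increasing in pH — the condition is
$(g_2-g_1)/g_1 < (A_2-A_1)/A_2$, satisfied by both default parameter
sets — reproducing the qualitative channel directions observed for the
sensor.

Noise is Gaussian per measured value with
$\sigma(x) = \sqrt{\sigma_\mathrm{read}^2 + s^2 x}$: a read-noise floor
plus a shot-noise-like term. Defaults
($\sigma_\mathrm{read} = 30$ FLU, $s = 1$) give per-pixel scatter of a
few hundred FLU on colonies of $2\text{–}3\times10^4$ FLU, comparable to
the replicate standard deviations reported for colony imaging. All
stochastic operations take an explicit seed and are bit-reproducible.

The imager background default (2500 FLU) represents residual colony/agar
autofluorescence on dye-darkened plates; empty-vector-level colonies
(~0.44–0.48 × 10^4 FLU) then sit just under the default low-signal QC
threshold of $2\times$ background while sensor colonies clear it
4–6-fold, matching the published contrast.

## Synthetic plates

`render_plate()` draws each colony as a flat disk convolved with a
Gaussian (σ = 0.15 × radius), so the plateau's peak equals the planted
channel amplitude to within 16-bit quantization (≤ 0.5 FLU at unit
gain). The default raster is 968 × 648 px at 7.5 px/mm — quarter linear
scale of the 3872 × 2592 camera the method was described with — purely to
keep simulations light; full scale is a layout parameter away. The
default screening layout is an 18 × 10 grid at 4.5 mm (384-format)
pitch whose outermost rows and columns are excluded, leaving the 16 × 8
= 128 analyzed colonies of one screening plate. The spotted-grid
dimensions behind that published 16 × 8 count are not themselves
published, so the generator exposes the layout completely rather than
hard-coding one. The default colony radius is 1.5 mm: a 5 mm radius
cannot hold at 4.5 mm pitch without total overlap, so the larger
published figure is treated as belonging to a sparser arrangement.

What the generator deliberately does *not* emulate: optics (vignetting,
PSF calibration), agar autofluorescence spectra, colony growth dynamics,
intra-colony pH gradients (the imaging method cannot resolve them), and
colony-morphology phenotypes. Passing recovery tests on these synthetic
plates therefore demonstrates the correctness of the quantification and
calibration chain, not robustness to every artifact of real plate
photographs.

## Quantification

Grid fitting correlates the summed-channel image, convolved with the
colony-footprint disk, against the layout's nominal centers over integer
translations up to half a pitch (the disk convolution makes the score
strictly peaked; bare point-sampling would be flat across a colony
plateau). Ties resolve toward the nominal grid, a blank image raises an
error rather than returning a degenerate fit, and each center is then
refined by intensity centroid within its window. On noise-free renders
every center lands within 1 px of truth.

Per-colony intensity is the maximum of median-smoothed (3 × 3) pixels in
the colony disk — the robust operationalization of "take the highest
measured fluorescence of the colony", immune to single hot pixels.
Background is *not* subtracted by default, matching how the published
FLU values and ratios were computed; the smoothing kernel is
configurable. Colonies with both channels at background are flagged
`missing`; weak-expression colonies are flagged by `qc_low_signal()`
(both channels < 2 × background) and reported as "n.d." rather than
given a pH, mirroring the treatment of weakly expressing mutants in
screens. Edge-margin colonies never enter statistics or calling.

## Screening statistics and hit calling

`plate_stats()` reports classical mean ± SD alongside median and
SD-consistent MAD; `call_hits()` uses the robust pair,
$z = (r - \mathrm{median})/\mathrm{MAD}$, because a single strong hit
inflates the plate SD but barely moves the MAD. Calling is two-sided at
$|z| \ge 3$ by default, with all colonies returned ranked by $|z|$ —
screens in this field also pursue sub-threshold tail colonies by
judgment, so the ranking, not only the calls, is part of the output. On
a plate distributed as the published screen (0.50 ± 0.04), the published
"drastically increased" colony at 0.78 scores $z = 7$ and is always
called; the "reduced" colony at 0.44 scores $z = -1.5$ — a tail colony,
not a statistical call, consistent with its published selection by
inspection rather than by rule.

## Calibration fitting and CTAB recalibration

`fit_boltzmann()` fits the sigmoid by weighted Levenberg–Marquardt
(weights $1/\mathrm{sd}^2$ when replicate SDs are present), initialized
from the series itself (asymptotes at the ratio range ± 5%, midpoint at
the half-range crossing, width = span/8) with up to three jittered
restarts; non-convergence is an error carrying diagnostics, and
under-determined designs are rejected up front. When only the alkaline
asymptote is free — the anchored per-session refit — the solution is
closed-form. Detection limits attach from the calibration span by
default.

CTAB permeabilization collapses the proton gradient so internal pH equals
external pH, giving every experiment a built-in end-point anchor.
`recalibrate_ctab()` rescales both asymptotes multiplicatively so the
mean post-CTAB ratio inverts exactly to the external pH, leaving $x_0$
and $dx$ (sensor chemistry) untouched. The anchor may lie beyond a
detection limit — assays at external pH 6.0 are recalibrated against the
extrapolated curve, and only *reported* pH values are clamped; end-point
validation in `analyze_trajectory()` accordingly compares the post-CTAB
reading against the external pH clamped into the observable range (a
drop to the 6.5 floor at external pH 6.0 is the expected, valid
outcome).

Uncertainty on inverted pH uses the first-order delta method on the
inversion formula and vanishes with the ratio SD.

## Kinetics

Strain physiology is modeled phenomenologically as first-order
relaxation, $\mathrm{pH}_i(t) = \mathrm{pH}_{set} -
(\mathrm{pH}_{set} - \mathrm{pH}_{init})e^{-kt}$, with the initial value
tied to the external pH (identity by default — initial internal pH
follows the externally set pH — or pinned for homeostasis-locked
mutants). Presets encode the characterized strains: wild-type reaching
~7.7 (120 mM potassium) or ~7.0 (0.1 mM) within 15 min; the
potassium-uptake-deficient triple mutant reaching ~7.3 within 20 min
when potassium-replete but stuck near 6.3 — below the sensor floor —
when starved; and the regulator mutant that pins 7.1–7.2 regardless of
external pH. Rates (0.15–0.3 min⁻¹) were fixed once from those
time-to-plateau statements.

The plateau of a trajectory is the mean of the last three pre-CTAB
points — published plateaus are read off curves without a stated rule,
so the package states one. Ratio series are not smoothed by default.

## Problem sizes and numerical choices

Tests and the acceptance script run everything at the sizes the package
itself defaults to: one 18 × 10 plate at quarter camera scale for the
screening round trip, 2 × 5 mini-plates for calibration paths, 13-point
kinetic series, 200 replicate fits for parameter-recovery statistics and
200 ratio-level plates for hit-detection rates. Quantization error is
bounded at 0.5 FLU per pixel; the inversion identity holds to 1e−9
across the open dynamic range; grid recovery is exact to 1 px noise-free.
Degenerate inputs (blank plates, zero denominators, under-determined
fits, missing sidecars, 8-bit files, unpaired channel readings) raise
typed errors or flags rather than silently proceeding.

## Limitations

The simulator's fidelity bounds what green tests prove about real
images: real plates add uneven illumination, reflections, morphology
variation and focus drift that the generator does not model. The
Boltzmann form is assumed exact (no Hill or spline alternatives), session
scale drift is assumed purely multiplicative, and multi-plate
normalization (B-scores, spatial detrending) is out of scope. The
homeostasis model is a single-exponential phenomenology, not transport
kinetics.
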