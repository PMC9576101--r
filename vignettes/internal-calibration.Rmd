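---
title: "Internal CT density calibration: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal CT density calibration: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qctcal)
```

## The problem and the model

Hounsfield units are anchored so that water reads 0 and air −1000 *at the
scanner's effective energy*, but everything else about the grey scale —
protocol, reconstruction kernel, object position in the bore — perturbs the
mapping between HU and physical density. Internal calibration treats the
scan itself as its own phantom. The forward physics is monoenergetic by
construction: a single effective energy \(E\) stands in for the polychromatic
beam, and each reference material \(m\) with nominal density \(\rho_m\) and
tabulated mass attenuation \((\mu/\rho)_m(E)\) has linear attenuation
\(\mu_m(E) = (\mu/\rho)_m(E)\,\rho_m\) and predicted value

\[\mathrm{HU}_m(E) = 1000\,\frac{\mu_m(E) - \mu_w(E)}{\mu_w(E) - \mu_a(E)}.\]

Fitting proceeds in three steps (`internal_calibration()`):
estimate \(E^*\) from the measured ROI values, fit the affine map
\(\hat\mu = a\,\mathrm{HU} + b\) by OLS of \(\mu_m(E^*)\) on the measured
means, and convert voxels to water-equivalent density
\(\rho_{weq} = \hat\mu / (\mu/\rho)_w(E^*)\). Water-equivalent density is
the natural unit for muscle (which is mostly water): water maps to exactly
1.000 g/cm³ and results are comparable across scanners.

## Choice of the energy criterion

Two criteria for \(E^*\) are implemented (`objective=`):

* **`"r2"`** — maximise the coefficient of determination of the affine fit
  of \(\mu(E)\) on measured HU. Because \(R^2\) is invariant under any
  affine transformation of the predictor, this criterion is *exactly*
  indifferent to a scanner gain and offset applied to all HU values, and on
  noise-free data it recovers the generating energy exactly (the predicted
  HU of ≥ 3 distinct materials are affinely related to their \(\mu\) values
  only at the true energy). It is degenerate with 2 ROIs, where any energy
  fits two points perfectly.
* **`"sse"`** — minimise \(\sum_m (\mathrm{HU}_m - \mathrm{HU}_m(E))^2\),
  after shifting all measured values so that the measured air ROI sits at
  its defining −1000 HU. The air anchor makes this criterion exact under a
  pure HU offset, which is the dominant scanner-condition effect; it is the
  only well-posed choice for 2-ROI sets (air plus one tissue).

The default `"auto"` selects `"r2"` for ≥ 3 ROIs and `"sse"` otherwise.
A plain (un-anchored) SSE was rejected: it is well-posed for every subset
but loses the affine invariance that motivates internal calibration in the
first place — a 5% gain error would drag \(E^*\) by tens of keV and the
output density by ~1–2%.

An intrinsic limit follows from counting: two ROI means carry no
non-trivial invariant of the two-parameter affine group, so *no* 2-ROI
estimator can be exactly invariant to an unknown gain *and* offset. With
air + adipose the method is exact under offsets, and gain errors enter only
through the slow energy dependence of \((\mu/\rho)_{adipose}/(\mu/\rho)_w\);
with three or more ROIs the invariance is exact. Users wanting strict
protocol-independence should include a third ROI (blood is convenient).

## Search and numerical choices

The energy search is a 1-keV grid scan over 30–200 keV (ties broken toward
the lower energy, deterministically) followed by golden-section refinement
(`stats::optimize`, tolerance 10⁻⁶ keV). The refinement is far below the
0.01 keV reporting precision because the round-trip density error scales
with the energy error (≈ 5×10⁻⁴ relative per keV for adipose); at the
chosen tolerance the noise-free round trip is accurate to ~10⁻⁹ relative.
Interpolation of the attenuation tables is log-log linear — standard for
photon attenuation data, exact at the tabulated knots, no extrapolation.
The tables have no absorption edges in 10–200 keV; custom tables with
duplicate energies are rejected rather than edge-handled. Degenerate inputs
fail loudly and specifically: only energy-insensitive ROIs (air/water),
fewer than two distinct materials, or identical mean HUs across ROIs.

Negative output densities (air voxels) are preserved, never clamped:
muscle masks exclude air anyway, and clamping would bias Bland-Altman
statistics computed from region means. ROI aggregation is the arithmetic
mean over mask voxels (the QCT convention), with `"median"` available for
robustness to segmentation spill-over.

## Reference tables

Shipped curves cover dry air, liquid water, ICRU-44 adipose tissue, whole
blood, skeletal muscle and cortical bone on a 10–200 keV grid, with nominal
densities 0.0012, 1.000, 0.95, 1.06, 1.05 and 1.92 g/cm³. Water, air and
cortical bone carry the standard published grid values; the three soft
tissues were compiled from their ICRU-44 elemental compositions with a
photoelectric-plus-scatter mixture rule anchored to the water curve, and
agree with the published tissue tables to about 1–2% (file headers record
this provenance). Because every validation property in the package is a
self-consistency property — synthetic scans are generated and analysed with
the same tables — percent-level table differences do not move any of the
reported checks; they matter only when calibrating real scans, where the
tables can be replaced wholesale via `material_library(path = ...)` and
densities via its `rho_ref` override.

The reference-phantom comparator (`phantom_calibration()`) is a plain OLS
line from vial HU to known density; with a sucrose-water phantom it yields
g/cm³, with an HA bone phantom mgHA/cm³ — same fit, different units, and
the unit tag travels with the density volume. Sucrose vials are modelled
(in the generator and tests) as water attenuation scaled by solution
density, adequate for dilute sucrose at diagnostic energies and
overridable with a true solution curve.

## What the synthetic generator does and does not emulate

`generate_scan()` builds voxel grids of homogeneous boxes/spheres whose
ideal HU comes from the forward model at a chosen true energy; scanner
conditions are emulated as an affine HU distortion (gain, offset) plus
additive white Gaussian noise, and fat-infiltrated muscle as voxel-wise
linear mixing of muscle and adipose attenuation by volume fraction. The
default validation scene holds one ROI region per material, ten muscle
samples spanning fat fractions 0–0.27 (water-equivalent densities ≈
1.04–1.01 g/cm³ — the ICRU-44 muscle value; real bovine samples read
slightly higher), and five sucrose vials at 1.00/1.01/1.04/1.06/1.11 g/cm³,
on a 64×52×4 grid — small enough that the full battery runs in seconds.
The default condition battery crosses two protocol-like gains (0.95, 1.05)
with five position-like offsets (−30…30 HU), a deterministic stand-in for
a two-protocol × five-position repeat design. Offsets of that size are
deliberately harsh: raw-HU CVs come out far larger than any real repeat
study would show, which only sharpens the contrast with the
calibration-invariant densities.

Not emulated: projection/reconstruction, beam hardening, scatter,
partial-volume blurring, anatomy, or registration error (masks are assumed
grid-aligned; no resampling happens inside the package). Passing the
synthetic battery therefore demonstrates the *calibration algebra* —
energy recovery, affine-distortion immunity, agreement machinery — not
image-formation robustness on real scanners.

## Agreement statistics

`bland_altman()` reports bias = mean(x−y) and 95% limits of agreement at
the conventional 1.96·SD (sample SD), plus the slope of difference against
pair mean (proportional-bias check). `cv_across_conditions()` uses
100·SD/mean per sample and refuses non-positive means, where a CV is
meaningless — raw HU series near 0 can trip this, which is itself a point
in favour of calibrated densities. The percent difference between two
methods is computed as 100·mean((reference − comparison)/reference) over
samples. Formal repeated-measures testing (ANOVA with post-hoc correction)
is intentionally out of scope; the reproducible quantities are the CVs and
paired differences themselves.

## Known limitations

* 2-ROI calibrations are exactly offset-invariant but only approximately
  gain-invariant (see above); ≥ 3 ROIs restore exact affine invariance.
* A biased reference density poisons every subset that contains the
  offending material — the sweep exists precisely to expose this (cortical
  bone, inhomogeneous in practice, is the usual culprit, and the bone-free
  subsets are the recommended default).
* The single-effective-energy abstraction ignores beam hardening within
  the object; it is the method's founding approximation, not a bug, but it
  bounds achievable accuracy on real polychromatic scans.
* Shipped soft-tissue curves are percent-level compilations, not verbatim
  reference tables; replace them for absolute work.
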