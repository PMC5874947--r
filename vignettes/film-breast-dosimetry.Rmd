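---
title: "Methods: film-based breast dosimetry in coronary angiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: film-based breast dosimetry in coronary angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filmdose)
```

## The measurement chain

`filmdose` models breast organ dose measured with radiochromic film
inside the breast slabs of a sliced anthropomorphic torso phantom during
C-arm fluoroscopy. The chain has four stages, each a module of the
package:

1. **Calibration** (`fitCalibration`, `mpvToDose`): scanned-film net mean
   pixel value (MPV) to absorbed dose, per acquisition mode.
2. **Dose mapping** (`loadScan`, `scanToDoseMap`, `roiMeanDose`): a film
   TIFF to a 2D dose map and circular-mask regional means.
3. **Organ dose** (`breastDoseSide`, `overallBreastDose`,
   `conversionFactor`): per-slab means to mass-weighted per-breast and
   overall doses, normalized by dose-area product (DAP).
4. **Procedure reconstruction** (`estimateBreastDose`): an acquisition
   log plus a per-angulation factor table to a procedure-level dose
   estimate.

A fifth module (`simulateExposure`, `renderFilm`,
`generateMockProcedure`) fabricates ground-truth exposures so the full
chain can be validated against known answers.

## Calibration model

The film's reflective response darkens monotonically with dose. The
functional form of the response is not prescribed by theory, so the
package fits

$$D(x) = a\,x + b\,x^{c}, \qquad a, b \ge 0,\; c \ge 1,$$

on net MPV $x$: non-negative coefficients and $c \ge 1$ guarantee a
monotone, convex-capable curve through the origin, which matches the
behaviour of reflective radiochromic media over the 0–160 mGy working
range. Numerically, the abscissa is rescaled by its maximum before the
bounded Levenberg–Marquardt fit (`minpack.lm::nlsLM`, starts
$a = b = \tfrac{1}{2}\hat{a}_{\mathrm{lin}}$, $c = 1.5$, $c$ capped at 8)
to keep the Jacobian well-conditioned; a pure linear fit is computed in
closed form and kept whenever it is at least as good, so exactly linear
data reproduce to machine precision. If the parametric RMS exceeds a
threshold (default 2% of the maximum corrected dose) the fit falls back
to a monotone piecewise-cubic interpolant (Hyman-filtered spline through
isotonized sample means, anchored at the origin). Any fitted curve is
verified monotone on a 513-point grid and rejected otherwise.

Key decisions where the measurement protocol leaves latitude:

* **Net, not raw, MPV.** The MPV is the *difference* between an
  unexposed reference patch and the exposed region, which removes
  scanner offset and film-lot baseline. A `raw = TRUE` escape hatch
  exists in `scanToDoseMap` for single-patch workflows.
* **Red channel.** The scan protocol stores 48-bit RGB without naming a
  channel; the red channel carries the highest sensitivity for this film
  class and is the default (green/blue/luminance are selectable).
* **Correction placement.** Solid-state probes under-read scatter
  relative to an ionization chamber in phantom geometry, so reference
  doses are multiplied by 1.4 (manual mode) or 2.0 (automatic brightness
  control) *before* fitting. The correction is part of the curve, never
  applied at evaluation time, and `doseRange` reports the corrected
  range (e.g. 0–320 mGy for ABC).
* **No extrapolation.** Net MPV beyond the calibrated support is clamped
  to the range ceiling and flagged per pixel (`outOfRangeMask`); the
  calibration is only trusted inside its fitted range.
* **Degenerate inputs** — fewer than four samples, near-duplicate
  abscissae, zero dose span, reference doses above 160 mGy — are
  rejected with named diagnostics rather than producing a silent bad
  fit.

## ROI extraction and organ dose

Dose maps carry physical pixel spacing (25.4 mm / dpi). A circular mask
counts a pixel when its *center* falls inside the circle — a simple rule
that an independent per-pixel enumeration can reproduce exactly, which
the test suite does. The regional mean is the unweighted mean over
counted pixels; "weighted" in the organ-dose sense refers to the mass
weighting across slabs, not to pixel-level weights, for which no basis
exists in the protocol.

Per side, slab means combine as $\sum_i l_i m_i / \sum_i m_i$. The
weights always derive from the supplied mass table and are renormalized
to sum to one: the published right-breast weighting in the source
experiment (0.25/0.55, 0.18/0.55, 0.17/0.55) is internally inconsistent
with its own mass table (0.25 + 0.18 + 0.12 = 0.55 kg, not 0.60), and
normalization is treated here as a hard invariant. The verbatim variant
remains reachable through `breastDoseSide(weights =, renormalize =
FALSE)` for comparison. Overall dose is the mass-weighted side
combination, algebraically identical to the direct six-slab mass mean.

Reported uncertainty combines, in quadrature, the per-slab standard
error of the ROI mean and the calibration fit RMS, propagated through
the squared weights under the assumption that slabs are read from
independent films. This is a read-noise figure only — it deliberately
excludes film-to-film sensitivity variation (see the noise model below),
energy dependence and positioning error, so it understates the total
physical uncertainty.

## Procedure reconstruction

Angulation labels (`"LAO31/CAU28"`, `"PA"`, …) parse into signed degrees
with LAO and CRA positive, RAO and CAU negative — an arbitrary but fixed
convention. Factor matching proceeds exact → same angulation at nearest
FOV (flagged fallback; this mirrors the standard handling of a
left-ventricle view at a wider FOV than the factor table covers) →
nearest angulation within a 6° Euclidean tolerance, tie-broken by FOV
proximity. The 6° default covers the usual pairing of procedure
angulations to measured ones (e.g. a CAU39° acquisition against a CAU40°
entry) while refusing distant matches with an error that lists the
nearest candidates. The packaged factor table is synthetic and
demonstration-only: measured per-angulation factors exist only
graphically in the source experiment, so no numeric reconstruction
against them is claimed.

## The synthetic generator

The generator is a deliberately minimal analytic model — enough to
exercise every pipeline stage with exactly known answers, with no claim
of dosimetric realism:

* **Geometry.** Three slabs per side (2.5 cm thick, slab 1 at the
  chest-entry plane), each side centered at
  $\pm(\text{gap}/2 + \text{length}/2)$ from the midline (gap default
  1 cm), footprint the ellipse inscribed in length × width. The square
  field (side = FOV) pivots about the chest-entry plane: on the plane at
  depth $d$ the beam axis is displaced by $d\tan(\text{lateral})$
  laterally and $d\tan(\text{axial})$ vertically from the midline plus a
  configurable heart offset (cm, positive toward the patient's left).
  With the pivot at the chest plane the lateral beam walk within the
  8 cm slab stack is modest, so laterality in the simulator is driven
  mainly by the heart offset and the slight left/right size asymmetry
  of the slabs, not by the angulation itself.
* **Transport.** In-footprint dose is
  $E\,e^{-\mu\,(t + d / (\cos\theta_l \cos\theta_a))}$ per exposure
  (entry dose $E$, torso water-equivalent $t$, effective attenuation
  $\mu$, default 0.2 cm⁻¹ — a soft-tissue-like magnitude, configurable
  and admittedly arbitrary); outside footprints a uniform scatter floor
  (default 5% of the in-beam chest-plane dose) applies.
* **Ground truth.** True slab doses are the means over the slab's
  inscribed *circle* (radius min(length, width)/2) — the same mask the
  measurement pipeline uses, so recovery comparisons are unbiased and
  the mask never leaves the slab (no scatter-only pixels dilute the
  mean). Organ doses are computed from those means with the organ-dose
  module itself, making the ground truth self-consistent by
  construction.
* **Digitization.** Film rendering inverts the calibration curve (dense
  monotone interpolation over 8193 points, exact on the piecewise-
  constant synthetic maps), adds noise, and rounds to 16-bit integers
  around an unexposed reference of 45000, signal on the red channel.
  Scans are rendered on the dose grid's own resolution by default
  (dpi = 25.4 / spacing); a fixed 300 dpi output is available via the
  `dpi` argument but is not the default, to keep routine problem sizes
  small.

### The noise model

Independent per-pixel noise cannot represent the film's practical
accuracy limit: averaged over an ROI of $n$ pixels it shrinks as
$1/\sqrt{n}$ and vanishes for any realistic mask. The dominant error in
reflective radiochromic dosimetry is instead *correlated across a film*
— lot sensitivity variation, post-exposure darkening state, scanner
session drift. The noise model therefore has two components in net-MPV
units: an iid per-pixel term (`sigmaPixel`, default 100, graininess
only) and a per-film offset (`sigmaFilm`) drawn once per scan.
`defaultNoiseModel()` calibrates `sigmaFilm` deterministically
(equal-probability quadrature over the offset distribution, solved by
`uniroot`) so that an ROI read at 10 mGy has 15% relative dose SD — the
film's readability limit. Because the response is convex, the same
absolute MPV offset translates into a *smaller relative* dose error at
higher doses, which is why end-to-end recovery at slab doses ≥ 20 mGy
achieves a median absolute error well under 5% (each organ dose also
averages several independent films). The Monte Carlo confirmation of the
15% target (200 replicate seeds on a 10 mGy ROI) and the 20-seed
recovery check run in the acceptance portion of the test suite.

### The mock-procedure generator

`generateMockProcedure()` emits a nine-acquisition log shaped like the
packaged mock-procedure record — same labels, SIDs, tube factors, FOVs
(eight at 15 cm plus the 23 cm left-ventricle view) — with DAP values
drawn uniformly within ±30% of the recorded ones. Beam entry dose scales
with each acquisition's DAP (default 8 mGy per Gy·cm²) so that
accumulated slab doses land in the film's comfortably readable range;
the default +1.5 cm leftward heart offset reproduces the left-dominant
dose pattern a clinical operator induces through floating-table
positioning. All randomness flows from the single `seed` argument
through a locally scoped RNG (global RNG state is saved and restored),
so identical seeds give byte-identical logs and scans.

Default problem sizes are the package's own choice for routine
validation: simulation grids at 1–2 mm pitch (slab maps of roughly
60 × 60 to 125 × 120 pixels), 200 noise replicates on a 40 × 40 ROI
map and 20 recovery seeds; all statistical checks complete in seconds.

## What passing tests do and do not show

The simulator shares the pipeline's geometric conventions (pixel-center
masks, mm coordinates) but is checked against independent brute-force
enumerations, closed-form attenuation ratios, and exact mirror-symmetry
and linearity identities, so agreement is not circular. Still, it is an
analytic toy: no energy spectrum, no table translation, rigid upright
slabs, a flat scatter floor. Passing the recovery criteria demonstrates
the software chain is unbiased and correctly propagates its own noise
model — it says nothing about spectral energy dependence, film
orientation effects, or how well a rigid phantom represents a supine
patient, all of which remain physical-measurement questions outside this
package's scope.

## Known limitations

* Conversion factors transfer only to procedures whose angulation mix
  resembles the table they came from; the packaged factor table is
  synthetic and for demonstration.
* The uncertainty figure on `OrganDoseResult` is a read-noise figure;
  published error bars from physical experiments include components
  (probe calibration, positioning) that are not derivable here and are
  not hard-coded.
* The calibration holds for one film lot / scanner combination;
  lot-to-lot correction, post-exposure kinetics and scanner color
  management are out of scope.
* DAP-to-effective-dose conversion (`effectiveDoseFromDap`, default
  0.2 mSv per Gy·cm²) is a literature scalar shortcut, not a
  tissue-weighted computation.
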