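---
title: "Methods: phase-resolved dose accumulation and NTCP for liver SBRT"
author: "dose4d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-resolved dose accumulation and NTCP for liver SBRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dose4d)
```

## The question the package answers

Liver tumours move with respiration, typically 1-2 cm superior-inferior.
The common clinical remedy is geometric: contour the gross tumour volume
(GTV) on every phase of a respiration-resolved CT (4DCT), merge the phase
GTVs into an internal target volume (ITV), add a setup margin, and irradiate
the whole envelope (the "3D" plan). The alternative is temporal: plan a
small aperture on each phase separately and track the target through the
cycle (the "4D" plan), accumulating the per-phase doses on one reference
anatomy through deformable image registration (DIR). Both strategies cover
the tumour; they differ in how much surrounding normal tissue rides along.
`dose4d` implements the full comparison pipeline - phantom, registration,
planning surrogate, deformable dose accumulation, DVH metrics,
Lyman-Kutcher-Burman (LKB) NTCP, and paired cohort statistics - so the
dosimetric consequences of the two strategies can be studied reproducibly
without patient data.

Because no clinical imaging is distributed, all experiments run on a
synthetic deforming-liver phantom whose cohort-level geometry (liver volume,
target size, motion amplitudes) follows published liver-SBRT statistics.
The package's claims are therefore structural and directional - coverage
objectives are met, tracking spares every liver metric, effect sizes vanish
without motion - not patient-specific dose values.

## The phantom

### Anatomy

A body (elliptical cylinder, 240 x 190 mm cross-section) contains a liver
ellipsoid with fixed aspect ratio (1.5 : 1.35 : 1) scaled analytically to a
target volume, 1177.52 cm^3 by default (a typical cohort mean). A spherical
GTV (default radius 26 mm) sits in the cranial part of the liver, near the
diaphragm where respiratory excursion is largest. Kidneys, stomach,
duodenum, bowel, esophagus and heart are ellipsoids/cylinders placed in
roughly anatomical positions; organ-at-risk masks are carved against the
liver so structures are disjoint. The default grid is 64^3 voxels at
4 x 4 x 3 mm (3 mm slice thickness, the usual 4DCT reconstruction choice),
giving a 256 x 256 x 192 mm field of view.

The default GTV radius was chosen so that the merged target, expanded by
the 5 mm setup margin, lands near 170 cm^3 and the normal liver (liver
minus PTV) near 1008 cm^3, matching typical cohort means; the per-phase
PTV then falls at about 115-125 cm^3, inside the published per-phase range.
Voxelization at the default spacing shrinks Euclidean margin expansions by
up to half a voxel diagonal, so discrete volumes sit a few percent below
their analytic counterparts; tests assert volumes at tolerances that
reflect this.

### Motion model

Respiration is a single global surrogate. Each phase $p$ of $n$ (default
10, equally weighted, phase-based sorting) displaces the anatomy by

$$\delta(p) = \tfrac{A}{2}\left(\cos\tfrac{2\pi p}{n} - 1\right)$$

per axis, where $A$ is the peak-to-peak amplitude vector (default
3/8/12 mm in L-R/A-P/S-I, i.e. ~15 mm total excursion). The displacement is
spatially tapered by an isotropic Gaussian window centred on the GTV
($\sigma$ = 80 mm by default), so the tumour moves with the full amplitude
while distant organs move less - the qualitative pattern of real abdominal
motion, which is largest at the diaphragm.

The *inverse* map is what is analytic: the anatomy seen at phase point $y$
is the reference anatomy at $y - \delta(p)\,g(y)$. This has two useful
consequences. First, phase masks are exact binary evaluations (no
interpolated, resampled masks). Second, the forward pull field
$u_p$ - defined on the reference grid, pointing to phase coordinates -
solves the fixed-point equation $u = \delta(p)\,g(x+u)$, which a plain
Picard iteration contracts to machine precision because the map's Lipschitz
constant is $\|\delta\| e^{-1/2}/\sigma \approx 0.11$ at default settings.
Amplitudes that would push this bound towards 1 (folding) are rejected at
construction with a diagnostic. Mask/field consistency is tested by warping
the largest-excursion phase GTV back through its true field (Dice >= 0.95
against the reference GTV), and liver volume varies by <= 10% over the
cycle.

Image intensities are smooth organ-contrast levels (logistic edges, 2-6 mm
wide) plus a low-frequency multiplicative-free sinusoidal texture
(amplitude 8, wavelengths ~50-60 mm) inside the body and additive Gaussian
noise (sd 2 by default), drawn per phase from the configured seed. The
texture matters: without it, homogeneous organ interiors give an
intensity-based metric no gradient to work with. The phantom is *not* a CT
simulator: no Hounsfield calibration, no cardiac motion, no breathing
irregularity, no sorting artifacts. Passing tests therefore demonstrate
algorithmic correctness and the geometric mechanism of 4D sparing, not
robustness to clinical image quality.

## Registration

The registration stack mirrors the usual clinical DIR layout: a 6-DOF rigid
initialisation followed by an intensity-based cubic B-spline free-form
deformation (FFD), both minimising the mean squared intensity difference
(SSD) - adequate here because the phases are mono-modal by construction.

The rigid stage runs Nelder-Mead on a translation-only pre-fit, then the
joint 6-DOF problem, on a grid downsampled to <= 32 voxels per axis.
The FFD stage optimises a control lattice (default spacing 32 mm, chosen to
resolve an 80 mm-scale deformation comfortably while keeping the problem
small) by gradient descent with a backtracking line search, coarse-to-fine
over 3 pyramid levels. The accepted-objective sequence is non-increasing by
construction; a level stops at a relative decrease below 1e-4 or its
iteration cap (80/50/30), and hitting the final cap flags the result and
warns rather than failing silently. The objective carries a bending-energy
penalty (squared second differences of the control coefficients, weight
0.05) which keeps the map smooth and, at phantom amplitudes, fold-free;
Jacobian positivity can be checked post hoc with `jacobian_determinant()`.

One numerical detail is worth recording: the SSD metric samples the moving
image with *border-clamped* interpolation. With zero-fill sampling the
objective is discontinuous at the volume edge (an infinitesimal
displacement flips boundary samples to the fill value), which stalls
gradient descent at the identity. Dose warping, by contrast, uses zero-fill
deliberately - dose outside the volume is unknown and must not be invented
- and reports the out-of-domain sample count.

At default settings the FFD recovers the phantom's ground-truth fields with
mean liver error well under 2 mm (typically ~0.2 mm at 64^3), against a
~11 mm mean true displacement. The pipeline can also bypass registration
and use the phantom's exact fields, which separates plan geometry from
registration error; the cohort driver does this by default, and the
registered-vs-true comparison is exercised separately (accumulated liver
mean dose agrees within 3%).

`invert_field()` (fixed-point inversion, used when a plan is made on a
non-reference phase) and `compose_fields()` complete the field algebra;
inversion refuses folding fields.

## The dose surrogate

A treatment planning system's dose engine is deliberately out of scope. The
surrogate keeps the one property that drives the 3D-vs-4D comparison: the
irradiated bath scales with the beam aperture, and the aperture scales with
the target. Five coplanar beams (default gantry angles 0, 72, ..., 288
degrees; the angles are shared between the 3D plan and every phase plan)
each project the target plus a 5 mm beam's-eye-view margin into an
aperture on a 2 mm lattice. The per-beam dose factor is a Gaussian penumbra
(sigma 5 mm) on the signed distance to the aperture edge, times an
exponential depth attenuation (4%/cm, a typical megavoltage effective
value) measured from the body surface along the beam. Each beam carries an
equal share of the prescription. The operator is deterministic, linear in
prescription, and non-negative - properties the tests assert directly.

Plans are then scaled to the clinical coverage objective: the unique factor
that makes exactly 95% of target voxels (up to one-voxel quantization)
receive the prescription, i.e. D95(PTV) = prescription. The 3D plan targets
ITV + 5 mm at 50 Gy (5 Gy x 10 fractions); each 4D phase plan targets that
phase's GTV + 5 mm at 0.5 Gy per fraction per phase, stored as total
physical dose (5 Gy per phase, nominal 50 Gy summed) since every evaluated
metric operates on total dose. Organ constraints (normal-liver mean
<= 23 Gy; V5 < 86%, V10 < 68%, V20 < 49%, V30 < 28%, V40 < 20%;
stomach/duodenum maximum <= 45 Gy) are checked and recorded in a report;
violations are recorded, not fatal, mirroring clinical plan review. The
unoptimized crossfire bath is less conformal than a real optimizer's, so
the default phantom satisfies the mean-dose limit while exceeding some
intermediate Vx limits - a known surrogate limitation, visible in the
report rather than hidden.

## Accumulation, DVH and NTCP conventions

Accumulation is pull (backward) mapping with trilinear interpolation - the
interpolation-based convention of commercial DIR tools - not energy- or
mass-conserving transfer. Out-of-domain samples contribute zero and are
counted per phase in the report. A diagnostic bound,
`accumulation_error_bound()`, surfaces the first-order interaction of
registration error with dose gradients ($|\nabla D| \cdot |\Delta u|$),
which is where accumulation error concentrates.

DVHs are cumulative voxel-counting histograms at 0.1 Gy bins on binary
masks (no partial-volume weighting, matching TPS-style reporting), with the
>= convention: voxels at exactly the query dose count as covered. Dmax and
the structure volume are carried exactly; Dmean is the differential first
moment (within one bin width of the voxel mean, as tested). Every Vx is
validated against a brute-force voxel count on random grids.

The LKB chain is:

$$v_{\text{eff}} = \sum_i \Delta v_i \left(\frac{D_i}{D_{\max}}\right)^{1/n},
\qquad
TD_{50}(v) = TD_{50}(1)\, v^{-n},
\qquad
t = \frac{D_{\max} - TD_{50}(v_{\text{eff}})}{m\, TD_{50}(v_{\text{eff}})},
\qquad
\mathrm{NTCP} = \Phi(t)$$

with liver parameters n = 0.32, m = 0.15, TD50(1) = 40 Gy, and the probit
taken as the standard normal CDF - the only reading under which uniform
whole-organ irradiation at TD50(1) yields exactly 50%. Differential bin
doses are bin centres clipped at the exact maximum, so the uniform case
reduces to $v_\text{eff} = 1$ identically and the 0.1 Gy binning keeps the
discretization error in $v_\text{eff}$ below 1e-3 (both tested). The liver
endpoint is evaluated on the normal liver (liver minus PTV), whose volume
is the reference volume of the power law. Parameters for the other organs
ship in `lkb_param_table()` as editable literature defaults in the
Burman-1991 tradition (e.g. kidney nephritis n = 0.70, m = 0.10,
TD50 = 28 Gy); they are engineering defaults for a configurable slot, not
values asserted by any single study.

## Cohort design and statistics

`run_patient()` chains the full workflow for one phantom;
`run_cohort()` derives per-patient seeds deterministically from a master
seed and jitters anatomy and motion uniformly within typical published
cohort ranges: liver volume 945-1597 cm^3, GTV radius 22.7-26.9 mm
(per-phase PTV 89-137 cm^3), per-axis excursions 1-5 / 5-11 / 8-17 mm, and
a GTV position jitter constrained to keep the tumour inside the liver.
Both arms are evaluated on identical reference-phase structures, so every
comparison is paired.

The significance criterion is the Wilcoxon matched-pairs signed-rank test,
two-sided, alpha 0.05: zeros dropped, average ranks on ties, exact p by
sign-pattern enumeration (dynamic programming over doubled ranks) up to 15
informative pairs, normal approximation with tie correction beyond. A
paired t-test is reported alongside as a supplementary statistic. When a
metric's paired differences are all zero (the zero-motion cohort), its
p-value is NA and it is never flagged significant - the test itself is
undefined there, and the implementation says so rather than guessing.
Percent decreases are reported both as mean-of-ratios and ratio-of-means,
labelled, since the two differ under heterogeneity. No multiple-testing
correction is applied, and the report footer says so.

## Problem sizes and numerical choices, collected

* Default study grid 64^3 (4 x 4 x 3 mm), ten phases; module tests use a
  32^3 grid with the same world extent. These sizes keep a 28-patient
  two-arm cohort comfortably desk-scale while leaving >10 voxels across
  the GTV.
* DVH bin width 0.1 Gy; aperture lattice 2 mm; FFD control spacing 32 mm,
  bending weight 0.05, step 2 mm with backtracking, tolerance 1e-4.
* Fixed-point iterations: 14 (phantom true fields), 30 (field inversion,
  tolerance 1e-3 mm); both contractions with margin at default amplitudes.
* Coverage normalization uses the k = ceil(0.95 N)-th largest target voxel,
  making the covered fraction >= 95% by construction; ties at the
  prescription count as covered (>= convention throughout).
* Degenerate inputs error early and explicitly: empty targets, zero-dose
  DVHs for effective-volume reduction (though `ntcp_from_dose()` returns
  exactly 0 for an unirradiated structure), all-zero difference vectors,
  folding deformations, mismatched lattices.

## Known limitations

The dose surrogate is not a transport calculation; absolute OAR doses and
NTCP magnitudes are phantom-dependent and should not be read clinically.
The motion model is a single smooth surrogate without hysteresis,
baseline drift or irregularity, which flatters DIR relative to clinical
4DCT; registration accuracy results are upper bounds on what the same
algorithm achieves on real data. Masks are binary (no partial volumes), and
the accumulation is interpolation-based rather than energy-conserving.
These are scope decisions, not oversights: each sits behind a module
interface where a heavier implementation could be substituted.
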