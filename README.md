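# dose4d

Phase-resolved dose accumulation and NTCP analysis for liver SBRT in R.

## The problem

Liver tumours move 1–2 cm with respiration. The standard planning answer is
geometric: contour the gross tumour volume (GTV) on every phase of a
respiration-resolved CT (4DCT), merge the phase GTVs into an internal
target volume (ITV), add a 5 mm setup margin, and irradiate the whole
envelope — a **3D ITV-based plan**. The alternative is temporal: plan a
small aperture on each breathing phase and track the target, then sum the
per-phase doses on one reference anatomy through deformable image
registration (DIR) — a **4D phase-tracked plan**. Both cover the tumour;
they differ in how much normal liver, kidney, bowel and heart ride along in
the dose bath.

`dose4d` implements the full comparison pipeline for this question,
exercised on a seedable synthetic deforming-liver phantom so no patient
data is needed:

* **phantom** — ten-phase deforming anatomy with exact binary masks and
  ground-truth displacement fields (diffeomorphic, analytically inverted)
* **registration** — rigid + cubic B-spline free-form deformation (FFD) on
  an SSD metric, multiresolution, bending-energy regularised (Rcpp kernels)
* **planning** — analytic five-beam dose surrogate (aperture projection,
  Gaussian penumbra, exponential depth dose) normalized so 95% of the PTV
  receives the prescription (50 Gy in 10 fractions; 0.5 Gy per phase per
  fraction for the 4D arm)
* **accumulation** — pull-interpolation deformable dose accumulation with
  out-of-domain accounting
* **dvh / ntcp** — V5…V40, Dmean, Dmax, D95; Kutcher–Burman
  effective-volume reduction and the Lyman–Kutcher–Burman probit

  v_eff = Σᵢ Δvᵢ (Dᵢ/Dmax)^(1/n),  TD₅₀(v) = TD₅₀(1)·v⁻ⁿ,
  NTCP = Φ((Dmax − TD₅₀(v_eff)) / (m·TD₅₀(v_eff)))

  with liver parameters n = 0.32, m = 0.15, TD₅₀(1) = 40 Gy (editable
  table for other organ endpoints)
* **study** — paired synthetic cohorts with exact Wilcoxon signed-rank
  statistics and percent-decrease summaries

See `vignettes/dose4d-methods.Rmd` for the model details, parameter
rationale and limitations.

## Worked example

```r
library(dose4d)

cfg <- phantom_config()            # 64^3 grid, 10 phases, 3/8/12 mm motion
ph  <- generate_phantom(cfg)
ph
#> <phase_set> 10 phases, grid 64x64x64, liver 1177.4 cm3, GTV 73.7 cm3, |A| = 14.7 mm

plan3 <- build_3d_plan(ph)         # ITV + 5 mm, 50 Gy, D95 objective
plan3
#> <plan3d> PTV 153.5 cm3 (ITV 101.8 cm3), prescription 50 Gy
#>             constraint limit value  pass
#>  normal_liver_Dmean_Gy    23 20.59  TRUE
#>    normal_liver_V5_pct    86 80.52  TRUE
#>   normal_liver_V10_pct    68 75.23 FALSE
#>   normal_liver_V20_pct    49 57.58 FALSE
#>   normal_liver_V30_pct    28 23.01  TRUE
#>   normal_liver_V40_pct    20  9.94  TRUE
#>        stomach_Dmax_Gy    45 19.47  TRUE
#>       duodenum_Dmax_Gy    45  0.00  TRUE

pr <- run_patient(cfg)             # both arms, ground-truth fields
pr
#> <patient_result> |A| = 13.9 mm realized; ITV 101.8 cm3, 3D PTV 153.5 cm3, mean 4D PTV 114.5 cm3
#>   normal_liver_Dmean     3D   20.588   4D   16.104
#>   liver_V30              3D   33.045   4D   25.695
#>   liver_NTCP             3D    2.071   4D    0.484
```

Reading the output: the merged-target PTV (153.5 cm³) is a third larger
than the mean per-phase PTV (114.5 cm³), and tracking that smaller aperture
through the cycle lowers the normal-liver mean dose from 20.6 to 16.1 Gy
and the liver NTCP from 2.1% to 0.5% — same target coverage, smaller bath.
(The constraint report shows the surrogate's unoptimized crossfire
exceeding two intermediate Vx limits; violations are recorded, not fatal,
mirroring clinical plan review.) A full paired cohort with Wilcoxon
statistics is one call: `run_cohort(28, master_seed = 7)`.

A thin CLI over the same functions lives at `inst/cli/dose4d.R`
(`phantom`, `plan`, `register`, `accumulate`, `ntcp`, `study` subcommands).

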