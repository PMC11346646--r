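# vestibflow

Current-flow modelling for galvanic vestibular stimulation (GVS) electrode
montages, for researchers who need to compare placements, estimate doses,
or sanity-check stimulation plans without a full anatomical FEM pipeline.

GVS delivers weak scalp currents (0.5–4 mA) near the mastoids to modulate
vestibular afferents. Where the injected current actually flows — how much
enters the cranial cavity, how strongly the left and right vestibular
organs are driven, and how this differs between the seven montages used in
practice — is a volume-conduction problem. `vestibflow` solves it on a
synthetic voxelized head phantom and computes the complete metric suite
used in the GVS modelling literature.

## What it computes

The potential satisfies the quasi-static Laplace problem

    div( sigma grad V ) = 0,    E = -grad V,    J = sigma E

with 1 mA (configurable) total current at the anode terminal, the cathode
grounded, and insulating exterior boundaries. On top of the solved field:

* per-ROI **mean / SD / 99th-percentile** |E| (V/m) for the left and right
  vestibular network (vestibule + semicircular canals), and each component
  separately;
* **ROI current** (µA): half the unsigned surface flux through the closed
  ROI boundary;
* **symmetricity**: left/right ratio of mean and p99 field;
* **cranial current fraction**: % of injected current crossing the inner
  skull boundary;
* **inter-electrode separations** (chord, mm), electrode current density;
* **intensity rescaling** (`scale_to_match`): the current a montage needs
  to reproduce a reference montage's mean ROI field (exact by linearity);
* percentile-**bootstrap CIs** and **star-plot normalization** of metric
  tables.

The solver is a matrix-free structured-grid finite-volume scheme
(harmonic-mean face conductances, Jacobi-preconditioned conjugate gradient
in C++), certified against an analytic layered-sphere Legendre-series
solution and a manufactured-solution convergence study (observed order
~1.95). See the methods vignette (`vignettes/gvs-current-flow.Rmd`) for the
model, calibration choices, and known accuracy limits.

## Worked example

```r
library(vestibflow)

vol <- build_phantom(phantom_config(voxel_mm = 2))     # 4-shell sphere + ROIs
sol <- solve_montage(vol, "bilateral_bipolar")          # stamp, assemble, solve

left  <- roi_statistics(sol$efield, roi_labels(vol, "left"),  sol$vol)
right <- roi_statistics(sol$efield, roi_labels(vol, "right"), sol$vol)
left
#> <roi_metrics> mean 0.1327 V/m, sd 0.03419, p99 0.226 (33 voxels)
symmetricity(left, right)
#> <symmetricity> mean ratio 1, max ratio 1
cranial_current_fraction(sol$efield, inner_skull_surface(sol$vol), 1, sol$vol)
#> [1] 69.12933
```

Reading: at 1 mA the bilateral-bipolar montage induces a mean field of
0.133 V/m in each vestibular network of the phantom; the mirror-symmetric
geometry yields a symmetricity of exactly 1 (the solved fields are mirror
images), and 69% of the injected current crosses the inner skull boundary
of this spherical phantom (anatomical heads, with their thicker scalp
shunt paths, pass far less — absolute magnitudes here characterize the
phantom, not a human head).

`run_comparison(run_config())` runs all seven montages and writes
`table1_analogue.csv` … `table3_analogue.csv`, `starplot.csv` and a
provenance block; on the symmetric phantom the lateralized montages
(unilateral-monopolar, mastoid–nape, mastoid–forehead) give left/right
mean-field ratios of 1.7–2.8 while the symmetric ones stay at 1.000.

Published reference ratios that are pure functions of printed inputs are
reproduced exactly from the embedded reference tables:

```r
paper_worked_examples()[c(1, 9, 15), ]
#>                     check  computed printed pass
#>         montage1_sym_mean 0.9333333   0.933 TRUE
#>         montage5_sym_mean 1.0833333   1.083 TRUE
#>  odas_matching_current_mA 2.1538462   2.150 TRUE
```

## Package layout

    R/            phantom, montage, solver, efield/metrics, surfaces,
                  oracle, report, reference values, NIfTI/YAML IO
    src/          matrix-free finite-volume operator + PCG (Rcpp)
    tests/        testthat suite incl. end-to-end acceptance checks
    scripts/      acceptance.R
    vignettes/    methods vignette
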