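---
title: "Modelling GVS current flow on a synthetic head phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling GVS current flow on a synthetic head phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Galvanic vestibular stimulation (GVS) delivers weak currents (0.5–4 mA)
through scalp electrodes near the mastoids to modulate vestibular afferents.
Which electrode placement ("montage") to use, and at what intensity, is a
dosing question that current-flow modelling can inform: the induced electric
field (EF) at the vestibule and semicircular canals (SCC), its left/right
balance, and how much of the injected current even reaches the cranial
cavity all depend strongly on the montage.

`vestibflow` implements the complete current-flow metric suite for the seven
GVS montages discussed in the literature, on a *synthetic* voxelized head
phantom. The phantom deliberately replaces MRI-derived anatomy: absolute
field magnitudes from an anatomical head model are not reproducible on a
layered sphere, but every metric definition, the solver physics, the montage
geometry, and all qualitative orderings are, and they can be verified
against closed-form solutions.

## Model and physics

At GVS frequencies (< 1 kHz) tissue is purely resistive to an excellent
approximation, so the potential obeys the quasi-static volume-conduction
equation

$$\nabla \cdot (\sigma \nabla V) = 0,$$

with boundary conditions: a fixed total current $I$ (default 1 mA) at the
anode terminal, the cathode terminal grounded at 0 V, and zero normal
current (Neumann) on all external surfaces. The induced field is
$E = -\nabla V$ (V/m) and the current density $J = \sigma E$ (A/m²).
Linearity in $I$ is exact: results at other intensities are rescaled, which
is also the basis of the `scale_to_match()` dose calculation.

Conductivities (S/m, `conductivity_table("primary")`): skin 0.465,
skull 0.01, CSF 1.65, gray matter 0.276, white matter 0.126, air 1e-7,
cranial nerves 0.017126, ear cartilage 0.16113, SCC 2, blood 0.7, gel 1.4,
electrode metal 5.8e7. The vestibule is assigned the SCC value (2 S/m), as
both are fluid-filled inner-ear spaces and no separate literature value is
in common use. The `"weighted_mean"` set (skin 0.413, skull 0.016, CSF 1.71,
gray 0.466, white 0.216) supports sensitivity runs with meta-analytic
averages.

## The synthetic phantom

`phantom_config()` defaults to a four-shell sphere — scalp/skull/CSF/gray
outer radii 92/86/80/78 mm around a 55 mm white-matter core — the standard
four-shell head-model convention. Each side carries a vestibular region of
interest: a 3 mm-radius "vestibule" sphere centred 62 mm from the origin
along the mastoid direction (directly medial to the mastoid pad, inside the
gray-matter compartment), plus three mutually orthogonal half-tori (major
radius 4 mm, minor 1 mm) standing in for the anterior, posterior and lateral
canals. The "vestibular network" is vestibule ∪ SCC; the optional cochlea is
excluded from network metrics, matching how the literature tabulates
network, vestibule and SCC values separately.

Grids always have an odd voxel count per axis so the mid-sagittal plane
passes through voxel centers; with `asymmetry_factor = 1` the label volume
is then *exactly* mirror-symmetric (asserted voxel-wise in the tests), and
symmetricity deviations from 1 measure physics, not gridding.
`apply_asymmetry(vol, f)` rescales the right ROI's linear dimensions by `f`
about its centre to emulate anatomical left/right asymmetry.

Voxelization resolution matters for the tiny ROIs: at the default 2 mm the
vestibule occupies 14 voxels and the canal set 19; any ROI under 8 voxels is
rejected as under-resolved (which is why 4 mm grids refuse the default ROI
spec).

## Montages and electrodes

The seven presets follow the standard numbering (1 left mastoid, 2 right
forehead, 3 right mastoid, 4 nape, 5 left temple, 6 right temple, 7 left
forehead): bilateral-bipolar {1+, 3−}, bilateral-monopolar {1+, 3+, 2−},
unilateral-monopolar {1+, 2−}, SDAS {1+, 3+, 5−, 6−}, ODAS {1+, 6+, 3−,
5−}, mastoid–nape {1+, 4−}, mastoid–forehead {1+, 7−}. Pads are 30 mm
discs, 5 mm thick (2.5 mm conductive gel against the scalp capped by
2.5 mm metal), stamped as spherical-cap shells normal to the scalp.

Site directions are a calibration of this package, not published
coordinates: mastoids sit 57.33° azimuth from the posterior axis, 15° below
the horizon — chosen so the mastoid–mastoid chord on the 92 mm scalp equals
149.6 mm, the classic bilateral-bipolar inter-electrode separation;
foreheads 25° lateral of anterior, 35° up; temples lateral; nape posterior,
30° down. Separations are straight-line chords between pad centres: the
published mastoid–mastoid value (149.6 mm) is shorter than any plausible
scalp geodesic between mastoids, so chord is the only consistent reading.
Note that the largest published separation (189 mm) exceeds the 184 mm
diameter of *any* single sphere containing both sites — a reminder that a
spherical scalp cannot reproduce anatomical distances exactly.

Multi-anode terminals are a single equipotential unknown: the current split
between pads *emerges* from the solution (`pad_currents()`) rather than
being imposed, mirroring how paralleled metal pads behave.

## Discretization and solver

The solver is a structured-grid finite-volume scheme: one unknown per
conductive voxel, face conductances $g = (A/h)\,2\sigma_i\sigma_j /
(\sigma_i+\sigma_j)$ (series half-cells, i.e. harmonic mean), exterior faces
omitted (hard Neumann), cathode metal fixed at 0 V, anode metal collapsed
into one unknown carrying the total-current constraint. The operator is
symmetric positive definite; interior rows sum to zero, so discrete current
conservation is exact — delivered current matches the configured current to
solver precision (audited per run).

The system is solved matrix-free in C++ by Jacobi-preconditioned conjugate
gradient with a relative-residual stopping rule (default 1e-6, read as a
relative tolerance). Typical problem sizes: the default 2 mm phantom has
~430k unknowns and solves in ~600 iterations / a few seconds; a 1 mm
benchmark sphere has ~3.4M unknowns. Non-convergence raises an error
carrying the residual history; a floating terminal (no conductive path to
ground) is detected at assembly by a BFS reachability check and reported as
a singular system.

Surface current integrals (ROI inflow, cranial fraction, conservation
audits) evaluate $J\cdot n$ *at voxel faces* from the same face
conductances, $I_f = g\,(V_a - V_b)$. This is the discretely conservative
flux; a voxel-averaged central-difference $J$ is qualitatively wrong across
high-contrast interfaces (across skull/CSF it overestimates crossing
current several-fold) and is not used for integrals.

## Metrics

For each ROI, statistics are unweighted over voxel field magnitudes (voxels
have uniform volume): mean, population SD, and the 99th percentile with
linear interpolation between order statistics — reported as "max", the
convention in the GVS modelling literature to suppress numerical hot spots.
The symmetricity report is left/right for both mean and p99. ROI "current"
is half the unsigned surface flux, $0.5\sum_f |J\cdot n| A_f$, in µA — for
a source-free region inflow equals outflow, so this is the current passing
through the region. How the published per-ROI µA values were defined is not
stated in the literature; comparisons to them should treat the convention
as possibly different. The cranial current fraction divides the same
half-unsigned flux through the skull↔CSF interface by the injected current.
The 95% CI on a ROI mean is a percentile bootstrap (2000 resamples, seeded,
caller's RNG untouched); the published tables do not state their CI method,
so this is a package convention. Star-plot tables divide each metric column
by its maximum across montages.

## Validation

Two independent standards certify the solver:

* **Layered-sphere series.** For concentric spheres with surface
  point-current electrodes, the potential has a Legendre-series solution;
  per harmonic degree the radial coefficients solve a small interface
  system (continuity of $V$ and $\sigma\,\partial_r V$; per-layer radial
  scaling keeps it conditioned to degree 200). The single-layer case is
  cross-checked against the classical homogeneous-sphere closed form to
  1e-9, and interface conditions are verified numerically. Comparisons use
  small pads (≤ 10 mm) and an interior sampling shell (r = 40 mm) far from
  the electrodes, where the disc/point difference is below grid error
  (verified: errors change < 0.2% between 6 and 16 mm pads); both
  potentials are mean-centred over the shell since the numeric gauge is the
  grounded cathode.

* **Manufactured solution.** On a cube with uniform conductivity and
  Dirichlet data from the harmonic polynomial $V = x^2 - z^2$ imposed at
  face centres through half-cell conductances, the scheme converges at
  observed order ≈ 1.95 (4 → 2 → 1 mm), and is exact to solver tolerance
  for affine fields.

**Known accuracy limits.** Against the three-layer sphere
(0.465/0.01/0.276 S/m, radii 92/86/80 mm) the relative L2 potential error
on the interior shell is ~10% at 2 mm and ~4.7% at 1 mm. More than 99% of
this is a single amplitude factor (the shape error after rescaling is
0.7%): the staircase voxelization of the thin resistive skull passes
systematically more current than the smooth shell, an O(h) transport bias
that per-ray conductance corrections do not remove (verified by subcell
face-integration experiments, and arbitrated by an independent 0.25 mm
axisymmetric solve that agrees with the series to 1e-5). Consequences for
interpretation: interior field *patterns* and all ratio metrics
(symmetricity, star plots, montage orderings, current matching) are
reliable at 2 mm; absolute magnitudes carry a resolution-dependent
amplitude uncertainty of order 5–10%, shrinking roughly linearly with voxel
size.

What the phantom does *not* emulate: real head shape, skull thickness
variation, CSF topology, anatomical left/right asymmetry (except the
explicit ROI-scaling knob), or the labyrinthine geometry of the inner ear.
Passing tests therefore certify the method and its implementation, not
anatomical field magnitudes: the published anatomical-model values are
reproduced only where they are pure functions of printed inputs
(`paper_worked_examples()`). On ROI rescaling, note that the mean field
inside a high-conductivity inclusion is nearly independent of its size
(Eshelby-type argument), so `apply_asymmetry()` shifts the *p99* ratio far
more than the *mean* ratio — isolated ROI scaling is a weak proxy for
whole-anatomy asymmetry.

## Numerical choices and degenerate inputs

* CG tolerance 1e-6 (relative residual), matching standard practice;
  validation solves use tighter tolerances where their assertions need it.
* Percentile type 7 (linear interpolation), population SD.
* Exterior air is removed from the unknown set rather than kept at
  1e-7 S/m (conditioning; the difference is below solver tolerance).
  Interior air pockets, if present in a user-supplied volume, keep their
  conductivity and stay in the system.
* Empty ROIs, non-positive star-plot columns, near-zero symmetricity
  denominators, overlapping pads, ROIs outside the brain compartment and
  under-resolved ROIs (< 8 voxels) are errors, not warnings.
* Degenerate all-equal bootstrap samples yield a zero-width interval.
* The default pipeline is fully deterministic; the seed only governs the
  optional ROI-jitter option and bootstrap resampling.

## Problem sizes used in the shipped checks

The shipped tests and the acceptance script run the default phantom at
2 mm (~1.1M voxels, ~430k unknowns; each montage solve a few seconds), the
benchmark spheres at 2 mm and 1 mm, the manufactured cube at 4/2/1 mm, and
small hand-built fixtures (rods, mini-spheres) for operator-level checks.
These sizes were chosen so the full validation remains a desk-scale
computation while keeping every ROI resolved.
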