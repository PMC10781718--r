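---
title: "Joint-space volumetry and its time-course model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-space volumetry and its time-course model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmjvol)
```

## The problem

After a transoral vertical ramus osteotomy (TOVRO) for mandibular
prognathism, the condyle-bearing proximal fragment loses most of its
muscular support and *sags* — it displaces anteriorly, medially and
inferiorly in the days after surgery, then partially recovers over the
following year. This changes the geometry of the temporomandibular joint
(TMJ) space: the gap between the glenoid fossa of the temporal bone and the
mandibular condyle. `tmjvol` implements the full measurement chain for
quantifying that change from serial 3D reconstructions:

1. **Reference frame** — eleven cranial landmarks define the mid-axial plane
   (MAP, through right and left orbitale and the right porion), the
   mid-sagittal plane (MSP, perpendicular to MAP through crista galli and
   basion), the coronal plane (COP, perpendicular to both through basion),
   and per-side planes parallel to these through the articular-eminence
   point (EmP) and the glenoid-fossa apex (GfSP, GfCP).
2. **Superimposition** — each follow-up scan is mapped onto the baseline by
   a least-squares rigid fit of the (N, PoR, Ba) landmark triple, optionally
   refined by iterative closest point (ICP) on the surgically unchanged
   cranial region.
3. **Volumetry** — the fossa capture region (a closed surface mesh) is
   voxelized; voxels above the eminence plane form the glenoid fossa volume
   `Vgf`. Removing voxels inside the (superimposed) mandible leaves the
   joint space `Vjs`, which GfCP splits into anterior/posterior (`Vajs`,
   `Vpjs`) and GfSP into medial/lateral (`Vmjs`, `Vljs`) compartments.
4. **Time course** — per-outcome repeated-measures linear model over the
   four visits (T0 preoperative; T1 day 3; T2 six months; T3 twelve months)
   with an unstructured 4×4 covariance, REML estimation, and
   Bonferroni-adjusted pairwise contrasts.

Patient imaging is not distributable, so the package ships a synthetic
phantom and a longitudinal record simulator; every pipeline stage is tested
against closed forms, an independent analytic oracle, or simulation.

## Geometry and numerical choices

**Planes** are stored as unit normal plus point; all construction residuals
are held to 1e-9 mm (`tmj_tolerances()`). Plane normals carry anatomical
orientation: *superior* is the MAP normal pointed toward crista galli,
*anterior* the COP normal pointed toward nasion, *lateral* the GfSP normal
pointed from the mid-sagittal plane toward the side's fossa apex. These
anchors are unambiguous in any valid skull; the choice matters because every
compartment assignment is a signed-distance test against these normals.

**Mesh volume** uses the divergence theorem (signed tetrahedra against the
origin) and requires a watertight mesh; the error message reports the
open-edge count. Generated primitives are inscribed polyhedra, so their
volume approaches the closed form from below — an icosphere at subdivision
4 (5120 faces) is within about 0.22% of `4/3·π·r³`, inside the 0.5% test
band.

**Voxelization** marks a voxel occupied when its center is inside the mesh,
decided by ray-crossing parity along `+x`. Exactly grazing an edge or vertex
would make parity ambiguous, so the ray origins' `(y, z)` coordinates are
shifted by two fixed, incommensurate sub-micron offsets (1.0e-6 and 2.3e-6
of the mesh extent). This serves the same purpose as casting a slightly
tilted ray, but keeps all rays of a row co-linear, which lets the parity
fill run vectorized in pure R (one `findInterval` per pierced row). The
offsets are deterministic: the same mesh and pitch always give the same
grid. Default pitch is `h = 0.3` mm, matching the slice thickness of the
follow-up CBCT protocol the meshes stand in for; volumes are reported at a
single fixed `h` (recorded in the output) without Richardson extrapolation,
mirroring single-resolution clinical measurement.

**Compartment ties.** A voxel center exactly on GfCP or GfSP goes to the
anterior (respectively medial) bin. The set is measure-zero but the rule
must be deterministic for bitwise-reproducible output. Both partitions are
disjoint covers of the joint-space voxels, so `Vajs + Vpjs = Vjs` and
`Vmjs + Vljs = Vjs` hold at voxel-count level at any resolution (the
floating sums agree to one ulp).

**Superimposition.** The landmark triangles of two scans are never exactly
congruent, so the 3-point alignment is a Kabsch least-squares rigid fit
(rotation + translation, reflection excluded) rather than an exact frame
mapping. The source protocol also rectified "minor discrepancies" manually,
without stating how; `tmjvol` exposes this as an explicit option:
`icp_refine()` runs point-to-point ICP restricted to moving vertices on the
positive (superior) side of a region plane — by default the MAP, i.e. the
cranial vault — with correspondence rejection beyond 2× the median pair
distance, and is guaranteed never to return a transform whose
restricted-region RMS exceeds the initialization's. With noiseless phantom
landmarks the landmark fit alone is exact to machine precision, so `refine`
defaults to off.

## The phantom: what it emulates, what it does not

The phantom fossa capture region is a full ellipsoid (default semi-axes
10 × 8 × 6 mm) centered on the eminence plane, so the captured `Vgf` is a
half-ellipsoid with closed form `2/3·π·abc ≈ 1005.31 mm³` — deliberately in
the range of adult fossa capture volumes. The condylar head is an ellipsoid
(default 7 × 5.5 × 4.5 mm) seated 1 mm above the fossa center. Landmarks are
placed analytically on a canonical skull layout; the cranial shell is a
coarse ellipsoid used only by ICP.

The sag at T1 defaults to 1.5 mm anterior, 1.0 mm medial and 1.5 mm
inferior, with recovery fractions `ρ₂ = ρ₃ = 0.6` at T2/T3 (60% of the
displacement undone, so T2 and T3 plateau — matching the reported 6-month
stabilisation). A rotation about the osteotomy contact point (20 mm below
the condyle center, about the anterior axis) is implemented but defaults to
0°, since the stated default world names only the translation components.
Each visit additionally receives a random rigid "scanner pose" (up to 8°,
6 mm; seeded), so the superimposition chain is genuinely exercised. These
sag magnitudes are free parameters of the phantom, not estimates of any
cohort: the source study reports volume changes, not the displacement
vector.

With these defaults the pipeline reproduces the published qualitative
signature — a large day-3 increase in every compartment, partial recovery
by 6 months, no change from 6 to 12 months, with the posterior and lateral
compartments still elevated at one year while anterior and medial return
near baseline. A green pattern test therefore establishes that the
measurement chain responds to condylar displacement in the anatomically
correct directions and order of magnitude — not that the phantom's volumes match
any patient's. Real fossae are not ellipsoids, real boundaries are drawn
manually, segmentation noise is absent, and landmarks here are exact unless
jitter is enabled.

The **oracle** (`oracle_volumes()`) recomputes all six volumes on a fine
lattice (default 0.1 mm) directly from the analytic ellipsoid inequalities
and exact plane coordinates of the canonical layout — no meshes, no voxel
grids, no ray casting, z-slab traversal instead of row-major — so agreement
within 1% at `h = 0.3` is a genuine two-route check: mesh faceting,
voxelization, superimposition and partitioning all sit on one side of it
and none on the other.

## The time-course model

Let `y_i` be the (up to) 4-vector of one joint's outcome over T0–T3. The
model is marginal: `y_i ~ N(μ, Σ)` with one free mean per visit (cell-means
coding) and `Σ` unstructured (10 free parameters, log-Cholesky
parameterised). Estimation is REML: the means are profiled out by GLS and
the restricted criterion is minimised by BFGS, started at the
pairwise-complete covariance floored to positive definite. With complete
balanced data this reduces exactly to sample means and the `n−1` sample
covariance (the saturated-means identity, tested at 1e-6). If the
unstructured fit fails, the model falls back to a
diagonal-plus-common-correlation (compound-symmetry) structure with a
warning.

**Missing day-3 visits.** In the motivating design only 19 of 35 patients
had the day-3 scan. Joints missing T1 contribute their observed visits
through the multivariate-normal likelihood, so the T1 mean is a model-based
estimate, consistent under missing-at-random: because the unstructured `Σ`
links T1 to the fully observed visits, baseline-dependent missingness is
absorbed. The test suite verifies that under a baseline-dependent deletion
rule the model's T1 mean beats the complete-case average. A
`complete_case = TRUE` flag provides the naive comparison analysis.

**Unit of repetition.** The repeated-measures unit is the joint (two per
patient), matching the most literal reading of a repeated-measures
covariance-pattern model with 70 joints. An optional patient-level random
intercept (`include_patient_effect = TRUE`) adds a shared variance
component across a patient's two joints; it is off by default because the
source analysis does not describe one. The simulator, by contrast, *does*
generate between-side correlation (default 0.5) so the option can be
studied; the null-calibration test generates independent joints, i.e. the
model's own world.

**Tests and p-values.** The overall time effect is a 3-degree-of-freedom
Wald statistic on the contrasts against T0, referred to `F(3, n_joints−3)`.
With complete balanced data this is the classical exact one-sample
repeated-measures test, which is why the null simulation (1000 replicates,
100 joints) rejects at 5% ± 2%; with missing data it is an approximation.
Pairwise contrasts report `mean(later) − mean(earlier)` for the six ordered
visit pairs — so a day-3 peak prints positive in the T0-versus-T1 row and
negative in T1-versus-T2, the published orientation — with normal-theory
p-values by default and a Satterthwaite option (finite-difference delta
method on the REML curvature); the source analysis does not state its
degrees-of-freedom method, so both are exposed. Bonferroni adjustment is
`min(1, 6·p)`; tables display `< .0001` and `> .9999` caps and star the
1e-4 significance threshold, while exact adjusted values remain available
programmatically (the published tables themselves print intermediate values
like 0.0023, so nothing is discarded).

## Simulator defaults

The record simulator's default means are the published per-visit estimated
means of the five outcomes (`tovro_reference_volumes()`). Published SEs are
model-based standard errors of means over 70 joints; per-visit standard
deviations are reconstructed as `SE·√70` — an approximation documented as
such — with an exchangeable between-visit correlation of 0.6, a typical
value for serial skeletal measurements. T1 deletion is
completely-at-random for 16 of 35 patients by default, with the
baseline-dependent rule available for MAR experiments. Everything is
reproducible from the spec seed.

## Known limitations

* The fossa capture region is an explicit closed input mesh; the manual
  drawing of the curved anterior/posterior fossa boundaries in clinical
  software is out of scope, deliberately, so that step is an interface, not
  a heuristic.
* No DICOM input, segmentation, or mesh repair beyond orientation
  normalisation; non-watertight input is an error, not a warning.
* ICP is point-to-point over mesh vertices; with sparse or very coarse
  cranial meshes a point-to-plane metric would converge better.
* The voxel inside-test assumes the mesh bounds a volume; self-intersecting
  meshes produce undefined parity.
* Satterthwaite degrees of freedom use finite differences of the REML
  curvature; for tiny samples (< ~10 joints) the curvature estimate is
  noisy and the normal approximation may be preferable.
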