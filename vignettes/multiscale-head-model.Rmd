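---
title: "Multiscale head models and RF fields around an implanted lead: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale head models and RF fields around an implanted lead: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mshead)
```

## The problem

Patients carrying a deep-brain-stimulation (DBS) lead who undergo MRI are
exposed to the scanner's radio-frequency (RF) transmit field. The conductive
lead picks the field up like an antenna and concentrates electric field — and
therefore specific absorption rate (SAR, the absorbed power per unit tissue
mass) — in a small volume of tissue around the electrode contacts. Whether a
numerical model predicts that concentration correctly depends on its spatial
resolution: the contacts, the insulation gaps between them, and sub-millimetre
anatomy such as the medullary laminae of the pallidum are all smaller than the
1 mm cells used by typical whole-head models, and staircased voxelizations
merge or erase them.

`mshead` implements, end to end, the multiscale modelling strategy for this
problem: build a millimetric whole-head label model; refine the basal-ganglia
region with a micro-resolution (0.2 mm) atlas carried over by non-rigid
registration; embed a four-contact lead; assign 128 MHz dielectric properties;
solve Maxwell's equations with a finite-difference time-domain (FDTD) scheme on
a graded Yee grid; and compare fields and SAR between the coarse and the
multiscale model.

Because no anatomical datasets ship with the package, every stage runs against
an analytic phantom with exact ground truth. That choice is deliberate: each
algorithm can then be scored against closed forms, brute-force oracles, or the
known deformation that generated the data.

## The phantom generator

`head_phantom_spec()` defines nested shell ellipsoids (skin, skull, CSF, white
matter) and a basal-ganglia-like nucleus complex: a GPi-analog ellipsoid, a
0.4 mm internal-lamina shell, a GPe shell, a 0.4 mm external-lamina shell, a
putamen shell and a separate caudate blob, all strictly inside the white
matter. A point takes the label of the innermost primitive containing it. Key
properties the generator is built to emulate:

* **Sub-voxel laminae.** The laminae are thicker than the fine voxel (0.2 mm)
  but thinner than the coarse voxel (1 mm). Pure centre-sampling of a curved
  0.4 mm shell on a 1 mm grid would still catch scattered voxel centres, which
  is not how a segmentation at 1 mm behaves, so the rasterizer combines centre
  sampling with an occupancy rule for laminae: a voxel is a lamina only if the
  lamina fills an absolute majority of it (estimated by 4^3 sub-voxel
  sampling); otherwise the voxel falls back to the innermost non-lamina
  primitive. A 0.4 mm sheet can never fill half of a 1 mm voxel, so the
  laminae vanish at coarse spacing and the pallidal segments merge — the
  resolution effect the package studies.
* **Scale.** The phantom is a scaled head analog (outer semiaxes
  16 x 20 x 16 mm) rather than a full-size head. All algorithms are
  resolution- and scale-agnostic; the small scale keeps the bundled
  experiments tractable on a single CPU (the multiscale solve uses roughly
  half a million cells) while preserving every qualitative feature of the
  problem: shells of contrasting conductivity, sub-voxel detail near the
  target, and a lead whose contact pitch is below the coarse cell size.
  Consequences of the scaling are discussed under *Limitations*.

The micro atlas (`make_micro_atlas()`) resamples a fine-resolution crop of the
phantom through a known deformation — a similarity misalignment (default 5
degrees, scale 1.03, a few mm of translation) followed by a random free-form
deformation whose control displacements are drawn uniformly from ±2 mm on a
10 mm lattice. Both the true transform and the warped landmark triplet are
returned, so registration accuracy is measured against exact ground truth.
Note that a cubic B-spline lattice blends 64 control points with weights that
sum to one, so ±2 mm *control* displacements produce point displacements that
are typically a few tenths of a millimetre — the misalignment budget is
dominated by the similarity part, as intended for an atlas that has already
been roughly positioned.

## Registration

Landmark alignment uses the closed-form orthogonal-Procrustes-with-scale
(Umeyama) solution on the AC/PC/interhemispheric triplet; collinear triplets
are rejected. Isotropic scale was chosen over anisotropic: three landmarks
barely constrain nine affine degrees of freedom, and the non-rigid stage
absorbs whatever the similarity leaves behind.

The non-rigid stage (`icp_nonrigid()`) is an iterative-closest-point loop over
hierarchical free-form deformations. At each level of the control-spacing
schedule (default 20, 10, 5, 3, 1, 0.5 mm) it alternates:

1. correspondence: each deformed source vertex maps to its **closest point on
   the target surface** (point-to-triangle, via a uniform spatial hash);
2. fitting: control displacements solve the scattered-data least-squares
   problem with a ridge penalty, `min mean |A c - d|^2 + lambda |c|^2`
   (`lambda = 1e-6`, applied to the displacements about their mean so
   translations stay unbiased), which relaxes control points that no data
   constrains toward the mean displacement and suppresses the local
   oscillations that plague over-parameterized FFD fits;
3. update, until the RMSE improvement drops below 1 mm/1000 or 50 iterations.

Design choices that were genuinely open, and why they were resolved this way:

* **Correspondence to the surface, not the nearest vertex.** With
  nearest-vertex correspondence the achievable RMSE floor is set by the
  target's vertex sampling density, so refining the lattice keeps "improving"
  RMSE by chasing individual vertices. Point-to-surface distance measures the
  geometry itself and plateaus once the true deformation is captured.
* **Full re-fit per level rather than additive increments.** Every level
  re-solves for the total displacement on its own lattice, initialized by the
  correspondences the coarser level produced. The endpoint is the same as an
  additive hierarchy (a finer cubic B-spline space contains the coarser one),
  but the final transform is a single lattice, which keeps the fixed-point
  inversion used by label propagation simple.
* **A canonical frame.** The lattice axes follow the target mesh's principal
  axes (with a deterministic sign convention), so rigidly moving both meshes
  transforms the recovered deformation covariantly — an axis-aligned lattice
  in world coordinates could not satisfy that equivariance.
* **Per-level monotonicity.** The reported per-level RMSE keeps the best
  iterate of each level and never accepts a regression from the previous
  level, so accuracy is non-increasing across the schedule by construction;
  what is *not* forced is how much each level improves.

On the bundled fixture the registration plateau mirrors the published
behaviour of this method class: almost all of the improvement happens at or
before the 3 mm lattice. The package quantifies "no improvement beyond 3 mm"
as the RMSE gained between the 3 mm level and the final level, *as a fraction
of the total improvement achieved from initialization to the final level*
(below 10 % on the fixture). The fraction is taken against the total
improvement rather than the 3 mm value alone because on a synthetic,
noise-free fixture the registration drives the absolute RMSE to a few
micrometres — ratios of two near-zero floors would measure numerical noise,
not registration behaviour.

Label propagation pulls labels back: each target voxel centre is mapped
through the inverse composite transform (similarity, then the structure's
deformation; the deformation inverse is a fixed-point iteration with 0.05 mm
tolerance) and takes the atlas label at that point by nearest neighbour.
Pull-back was preferred to forward push because it cannot leave holes.
Structures are propagated smallest-last so thin detail overrides bulk
(laminae over pallidal segments over putamen). Outside the deformation's
lattice support the displacement continues as a bounded constant extension:
far voxels belong to no registered structure, and a polynomial B-spline
extrapolation would diverge and break the fixed-point inversion.

Accuracy is reported as the centroid distance (Dc) per structure per schedule
level, percent match `PM = 100 TP / (TP + FN)` and positive predictive value
`P+ = 100 TP / (TP + FP)` against the analytic ground truth.

## Electrical model

The tissue table (`inst/extdata/tissues.yaml`) carries conductivity, relative
permittivity and density at 128 MHz, the proton Larmor frequency at 3 T. Grey
matter (0.58 S/m, eps_r 73.51) and white matter (0.34 S/m, eps_r 52.53) are the
standard modelling values at this frequency; basal-ganglia nuclei map to grey
matter and the laminae to white matter. The implant is a platinum/iridium
conductor (4e6 S/m, treated as a perfect conductor above a 1e5 S/m threshold)
with urethane insulation (1e-10 S/m, eps_r 3). Skin, skull and CSF use standard
128 MHz literature values, and the densities are generic textbook numbers
(brain 1040, skin 1100, bone 1900, CSF 1010 kg/m^3); none of these five are
device- or subject-specific measurements, and all are editable in the YAML.
Properties are linear, nondispersive and isotropic; white-matter anisotropy is
out of scope.

The default lead is a natural cubic spline through configurable control
points, an insulation tube swept along it, and four cylindrical contacts
placed from the distal tip. The bundled experiment keeps the commercial
1.5 mm contact length (the surface-field null that marks a contact develops
along its length) but scales the inter-contact gaps to 0.9 mm — below the
coarse cell — so the contact/gap alternation is resolved at 0.2 mm and
staircased into a continuous conductor at 1 mm; the insulation radius is the
1 mm swept-circle value and the 0.75 mm core radius exceeds the
half-diagonal of a 1 mm cell, so the conducting core stays connected on the
coarse grid (both models must carry the antenna effect for the comparison to
isolate *local* resolution effects).

## The FDTD solver

`run_fdtd()` advances Maxwell's equations with leapfrog Yee updates on a
rectilinear, possibly graded mesh: E-derivatives of H use dual spacings,
H-derivatives of E use primal spacings, and material coefficients at each E
edge average the adjacent cells (an edge touching a perfect-conductor cell is
pinned to zero, so the field inside the implant is exactly null). The
multiscale mesh embeds a uniform 0.2 mm region of interest around the contact
array in the 1 mm head grid with geometric grading (adjacent-cell ratio at
most 1.5) — one solver kernel, one global timestep, unconditionally
consistent. The timestep is the Courant bound of the smallest cell times a
0.99 safety factor, then shortened so that one drive period is an integer
number of steps (and a multiple of 32, so the steady-state extraction below
samples exactly).

Numerical choices:

* **CPML boundaries**, 7 layers, cubic polynomial conductivity grading with
  the standard optimum amplitude, kappa = 1 and no complex-frequency-shift
  term: with the coarse-cell timesteps used here a nonzero alpha was measured
  to degrade normal-incidence absorption from about -80 dB to worse than
  -20 dB, so it is off. Measured pulse reflection with 7 layers is about
  -79 dB.
* **Steady state by single-frequency DFT** over each full period; the run
  stops when the relative change of the in-tissue electric phasor energy
  between consecutive periods drops below -40 dB (or at the period cap, with
  a flagged non-converged result). A raised-cosine ramp (one period in the
  bundled experiments) suppresses the switching transient.
* **Sources.** `cp_planewave` drives two orthogonal uniform current sheets in
  quadrature on a transverse plane; with the periodic side boundaries it
  launches an exact uniform plane wave of either polarization (the package
  uses it for the dispersion, Fresnel and PML experiments). `dipole_ring`, the
  birdcage analog used for the head runs, is a ring of z-directed line
  currents ("rungs") with azimuthal quadrature phasing. Each rung is
  discretized cell by cell with its local dual-cell volume, and each element
  is spread trilinearly onto the surrounding edges, so the injected current
  moment is exact on any grid — point dipoles snapped to cells proved far too
  sensitive to the local mesh to give comparable drives on different grids,
  whereas with rung sources the no-implant whole-phantom SAR agrees within
  about 4 % between the uniform and the multiscale mesh.
* **Single-precision field storage.** The scheme is second-order in space;
  float rounding is orders of magnitude below the discretization error, and
  the halved memory traffic roughly doubles throughput (all reductions
  accumulate in double). Subnormal flushing is enabled inside the kernel: the
  leading edge of the ramped wave otherwise fills the domain with denormals
  and slows the update loops several-fold.

Solved field amplitudes are stored as peak phasors at cell centres.

## SAR analysis

Raw SAR is `sigma |E|^2 / (2 rho)` per tissue cell (peak-phasor convention —
stated explicitly since conventions differ), masked to zero in air and in the
space occupied by the device. Mass-averaged SAR grows, for every tissue cell,
the smallest centred cube (measured by centre-to-centre distance per axis)
whose enclosed tissue mass reaches 1 g or 10 g; air and implant contribute
neither mass nor power, cells whose cube cannot reach the target are flagged
invalid, and the implementation (3D prefix sums, O(1) per query) is tested
against exhaustive search. No partial-cell mass correction is applied at the
cube boundary; the resulting bias is below one cell shell. Whole-head SAR is
total absorbed power over total tissue mass, and one field scale factor
`sqrt(3.2 / SAR_w,no-implant)` is applied to all three runs so the no-implant
reference sits exactly at the 3.2 W/kg head-average limit.

The comparison between the coarse and the multiscale model reports: raw and
mass-averaged peaks (with locations in world mm, so grids of different
resolution are commensurable), the |E| peak shift inside the shared region of
interest, |E| profiles along lines parallel to the lead at a lateral offset
just outside the insulation, counts of profile zero-minima (strict local
minima below 20 % of the profile maximum — the field nulls at the conducting
contacts; the profiles follow the lead surface, sampling the centerline
offset laterally by the insulation radius) and maxima, and |E| differences
at reproducible probe points on the
grey-matter and skin layers. On the bundled experiment the multiscale model
resolves the four contacts as four zero-minima; the coarse model, which
staircases the 0.6 mm gaps away, does not, and its raw SAR peak near the
electrode is several-fold lower while the whole-head SAR of the two models
agrees within a few percent — the local-versus-global resolution effect the
method exists to demonstrate.

## Problem sizes

The bundled full-profile experiment uses: a 56 x 68 x 52 mm domain (about
200,000 cells at 1 mm; about 620,000 on the multiscale mesh whose 0.2 mm
region covers the contact array), three FDTD runs (two coarse, one
multiscale), and registration fixtures of about 15,000 target triangles with
2,500 source points per structure. The quadrature ring source keeps a few
millimetres of clearance from the phantom on every azimuth: a rung grazing
the staircased skin surface puts driven edges in direct contact with tissue
cells and produces a spurious local hot spot. These sizes were chosen so the
entire experiment reproduces in well under an hour on one CPU; every
algorithm is size-agnostic and accepts full-scale inputs.

## What the synthetic fixtures do and do not show

Passing the bundled tests demonstrates that each component does what it
claims on data with exact ground truth: the FFD machinery interpolates and
fits correctly, ICP recovers known smooth warps to micrometres, propagation
reproduces analytic structures, the solver matches closed-form wave physics,
and the two-resolution comparison reproduces the qualitative resolution
effect. It does not demonstrate performance on real anatomy: real
registration contends with inter-subject variability, imaging noise,
segmentation disagreement and deformations that are not B-splines; real
head models are an order of magnitude larger; and a generic ring source is
not a specific transmit coil. Absolute field and SAR magnitudes of the
scaled phantom are not comparable to human-head values — only normalized
comparisons between the two resolutions are meaningful here.

## Known limitations

* Thermal/bioheat analysis is out of scope; SAR is the endpoint.
* Dielectrics are isotropic and nondispersive; no fiber-direction anisotropy.
* The mass-averaging cube ignores partial cells at its boundary.
* The graded mesh shares one global timestep (no subgridding), so the fine
  region sets the step for the whole domain.
* Registration assumes closed, star-shaped-ish structure surfaces with
  reasonable overlap after similarity alignment; it is not an intensity
  registration and inherits ICP's sensitivity to gross initial misalignment.
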