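# mshead

Multiscale head models and RF field analysis around implanted
deep-brain-stimulation (DBS) leads.

## The problem

MRI deposits radio-frequency power in tissue; a conductive DBS lead picks up
the transmit field and concentrates electric field and specific absorption
rate (SAR) in the millimetres of tissue around its electrode contacts.
Numerical safety models of this situation are usually built on uniform ≥1 mm
grids — but the contacts, the insulation gaps between them, and the
sub-millimetre anatomy around the target (the medullary laminae of the
pallidum) are all smaller than that, and a staircased 1 mm voxelization
merges or erases them. `mshead` quantifies what that resolution limit does to
the computed fields, by building the same head model at two resolutions and
comparing the solutions.

The pipeline, end to end:

1. **Anatomy.** An analytic head phantom (nested skin/skull/CSF/white-matter
   ellipsoid shells with basal-ganglia-like nuclei separated by 0.4 mm
   laminae) rasterized at 1 mm (the coarse model) and, for the nuclei region,
   at 0.2 mm with a known misalignment + smooth warp (the "ex-vivo atlas").
2. **Registration.** Landmark similarity alignment (closed-form
   orthogonal-Procrustes with scale), then non-rigid iterative-closest-point
   registration over hierarchical cubic B-spline free-form deformations
   (FFD): the displacement at `x` is
   `T(x) = x + Σ_{l,m,n} B_l(u) B_m(v) B_n(w) Φ_{i+l, j+m, k+n}`
   on control lattices refined 20 → 10 → 5 → 3 → 1 → 0.5 mm, each level
   solving a damped scattered-data least-squares problem on
   closest-surface-point correspondences.
3. **Label propagation** through the inverse transform (fixed-point
   inversion), scored with centroid distance `Dc`, percent match
   `PM = 100·TP/(TP+FN)` and positive predictive value
   `P+ = 100·TP/(TP+FP)` against the exact ground truth.
4. **Electromagnetics.** A four-contact lead (cubic-spline wire, swept
   insulation, contact array) is voxelized into a uniform 1 mm grid and into
   a multiscale graded Yee grid with a 0.2 mm region around the contacts;
   128 MHz dielectric properties are assigned
   (grey matter σ = 0.58 S/m, ε_r = 73.51; white matter σ = 0.34, ε_r = 52.53;
   Pt/Ir conductor σ = 4·10⁶ S/m; urethane insulation σ = 10⁻¹⁰, ε_r = 3);
   and an FDTD solver (leapfrog Yee scheme, 7-layer CPML absorbing
   boundaries, Courant-limited timestep, quadrature-driven ring source as a
   birdcage analog, steady state by single-frequency DFT at −40 dB energy
   convergence) computes the fields for three runs: coarse with implant,
   multiscale with implant, and the coarse no-implant reference.
5. **SAR.** Raw SAR `σ|E|²/(2ρ)` (peak-phasor convention), IEEE-style
   cube-grown 1 g and 10 g averages, whole-head SAR, normalization of all
   runs so the no-implant reference sits at SAR_w = 3.2 W/kg, electrode-line
   |E| profiles, and coarse-vs-multiscale comparison statistics.

Everything is driven by exact synthetic ground truth, so each stage is tested
against closed forms, brute-force oracles, or the known deformation that
generated its input. See the methods vignette
(`vignettes/multiscale-head-model.Rmd`) for the model details, parameter
choices and limitations.

## Worked example

```r
library(mshead)
report <- run_pipeline(default_pipeline_config(seed = 1, profile = "full"),
                       verbose = TRUE)
print(report)
```

prints (about twelve minutes on one CPU):

```
Multiscale head-model experiment report
  seed 1 (full profile); cells: coarse 198,016, multiscale 617,308
  whole-head SAR (W/kg): reference 3.200, coarse 3.182, multiscale 3.139
  raw peak SAR near electrode (W/kg): coarse 1.32, multiscale 6.693 (x5.1)
  |E| peak shift between models: 9.86 mm
  contacts resolved as field nulls (right profile): multiscale 4/4, coarse 1/4
```

Reading the numbers:

* The **whole-head SAR** of the two models agrees within a few percent —
  resolution barely matters for the global average, because the lead's
  antenna effect is local.
* The **raw SAR peak next to the electrode** is several-fold higher on the
  multiscale model: the 0.2 mm region resolves the contact edges and the
  conductive/insulating alternation that the 1 mm grid staircases away. The
  1 g and 10 g mass averages largely smooth the difference back out
  (`report$sar_peaks`: 5.02 vs 4.69 W/kg at 1 g, 3.47 vs 3.42 W/kg at 10 g).
* The **field nulls along the lead surface** mark the conducting contacts:
  the multiscale model resolves all four on both flanks, the coarse model at
  most one.
* `report$registration_dc` tabulates the centroid distance per structure
  from the affine alignment through each non-rigid level, and
  `report$segmentation` the PM / P+ / volume of every propagated structure
  against ground truth.

Individual stages are ordinary functions and can be used alone, e.g.

```r
spec  <- head_phantom_spec()
head  <- make_head_phantom(spec, spacing_mm = 1)
crop  <- make_head_phantom(spec, 0.2, region = list(lo = c(-7, -9, -7),
                                                    hi = c(9, 10, 8)))
atlas <- make_micro_atlas(crop$volume, warp_amplitude_mm = 2,
                          warp_spacing_mm = 10, seed = 7,
                          landmarks = head$landmarks)
sim   <- fit_similarity_landmarks(atlas$landmarks, head$landmarks)
gp_t  <- extract_surface(crop$volume,  c(12L, 13L, 21L))   # GP complex
gp_s  <- extract_surface(atlas$volume, c(12L, 13L, 21L))
gp_s  <- surface_mesh(apply_similarity(sim, gp_s$vertices), gp_s$faces)
reg   <- icp_nonrigid(gp_s, gp_t)
print(reg)
```

A thin command-line wrapper is installed as `exec/mshead`
(`mshead phantom|register|score|run-all`).

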