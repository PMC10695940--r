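---
title: "vaultsim: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vaultsim: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the modelling choices behind `vaultsim`: what is
simulated, which approximations are made, and why.  The package studies
spring-assisted posterior vault expansion (SAPVE): an osteotomy across the
posterior skull vault plus two to four implanted, pre-compressed torsional
springs that push the bone flap outward over weeks, increasing intracranial
volume (ICV) in children with syndromic craniosynostosis.

## Synthetic calvarium

`generate_skull()` builds a simplified infant calvarium as an open triangle
shell:

* A symmetric Fibonacci point set on the unit sphere (mirrored about the
  midsagittal plane so the mesh is exactly left–right symmetric) is
  triangulated by its convex hull.
* The sphere is mapped piecewise onto the skull shape: above the skull base
  an ellipsoidal dome with semi-axes `length_ap/2`, `height_cc`,
  `width_ml/2`; below it a nearly flat base (depth 0.8% of the height),
  so the enclosed volume approaches the half-ellipsoid limit used as a
  generator oracle.
* Faces whose centroid falls within `foramen_radius` of the basal centre
  are removed, opening the foramen magnum; its rim is the mesh's single
  boundary loop and is the fully fixed boundary condition of the FE model.
* Smooth seeded Gaussian bumps along the vertex normals add deterministic
  patient-to-patient variability (`bump_amplitude`, `seed`).

Three landmarks (nasion, left/right auditory meatus) define the anatomical
frame: `align_to_frame()` places the origin at the left meatus and
orients the axes anterior–posterior / cranio–caudal / medio–lateral, and
refuses landmark sets whose chirality is flipped (swapped meati).

The default spec (170 x 140 x 100 mm, 3 mm uniform thickness) encloses
about 1.26 l, inside the 0.9–1.8 l infant range.  `generate_cohort()`
draws per-case log-normal size multipliers, so a cohort is reproducible
from one integer seed.

## Osteotomy and springs

`apply_osteotomy()` realizes the cut as an extruded planar slab of width
`kerf` whose trace in the sagittal plane is parametrized exactly by the
three surgical parameters: bottom-end offsets `L` (anterior–posterior) and
`H` (cranio–caudal height) and the inclination `alpha` (degrees from the
vertical, positive leaning forward at the top).  Faces fully inside the
slab and above the bottom ends are removed; remaining faces are labelled
`anterior` (the fixed segment, which keeps the foramen rim) or
`posterior` (the distracted flap).

Two deliberate design decisions differ from a literal cut-through:

1. **Hinged bottom ends.** Faces straddling the bottom-end height are not
   removed; they keep a graded residual thickness (down to 2% at the slab
   centre line), forming a smooth bony hinge at each bottom end, as in the
   clinical procedure where the osteotomy ends act as greenstick hinges.
   This keeps the shell connected, so the stiffness matrix stays positive
   definite with only the foramen rim fixed — a fully detached flap would
   have rigid-body modes that two rank-one springs cannot constrain.  The
   graded (rather than binary) hinge also removes a mesh-resolution step
   from the ICV response, which matters for the response-surface fits.
2. **Smoothed spring anchors.** A spring notch is represented as a small
   Gaussian-weighted cluster of rim vertices rather than one snapped
   vertex; the spring acts on the weighted barycentre.  Snapped anchors
   quantize the parametric response to the mesh and ruin the surrogate
   fits at coarse resolution.

Top springs (`S_T` from the midline, always a symmetric pair) sit on the
upper cut rims; lateral springs sit at arc distance `S_L` up the rim from
each bottom end.  The spring registry mirrors the prefabricated hardware:
models S10/S12/S14 with stiffness 0.17/0.39/0.68 N/mm, wire diameters
1.0/1.2/1.4 mm, and a common 60 mm natural opening.  A spring inserted at
notch distance `d` pushes the notches apart with force `k (60 - d)` along
the line joining them, disengaging at 60 mm.

## Shell finite elements and the expansion solve

Every remaining triangle becomes a flat shell element: constant-strain
membrane plus discrete-Kirchhoff (DKT) plate bending, with a small
Zienkiewicz drilling stiffness for the in-plane rotation, six DOFs per
node, assembled in C++.  Verification oracles (in the test suite):
simply-supported plate deflection within 3% of the Kirchhoff closed form,
membrane patch test exact to 1e-8, spring–bar truss equilibrium exact to
1e-8.

Bone relaxation over the distraction period is modelled quasi-elastically:
the elastic problem is re-solved with the time-decayed effective modulus
`E(t) = E (g_inf + sum g_i exp(-t/tau_i))`.  The stiffness is assembled
once on the reference geometry and scaled by `E(t)/E`; geometric
nonlinearity enters only through the follower spring forces (direction and
magnitude depend on the current notch positions), solved by Newton
iteration with Woodbury low-rank updates of the cached factorization and
a backtracking line search.  This *total* formulation was chosen over
incremental updated-geometry stepping because it makes the quasi-elastic
relaxation limit exact (the relaxation-curve test passes to 1e-6
regardless of step count) and keeps the elastic limit step-independent;
the application stays in the small-strain regime where the two coincide.
To stay on the physical equilibrium branch as the modulus relaxes by an
order of magnitude, `solve_expansion()` first solves the instantaneous
(insertion-time) response and then walks the modulus down in geometric
sub-steps, warm-starting each Newton solve — without this continuation the
solver can converge to spurious folded configurations at strongly relaxed
moduli.

The default material is E = 1300 MPa, nu = 0.22 (paediatric calvarial
bone), with a single-term Prony relaxation g = 0.9, tau = 7 days.  The
Prony term is the one calibrated constant in the package: it was chosen
once so that the long-term ICV gain of the default procedures lands in the
clinically observed 10–20% range, and then frozen.

ICV is the volume of the 3D convex hull of the deformed model
(`convex_hull_volume()`, an exact quickhull written for this package since
no hull library is available in the target environment), which is also how
the clinical studies approximate ICV from segmented surfaces.

## Study design and statistics

For each synthetic case, `build_parameter_space()` centres the parameter
box on the as-operated baseline: `L` and `H` vary by ±10% of the skull's
anterior–posterior extent and height respectively, `alpha` by ±20% of its
baseline magnitude, and the spring positions `S_T`/`S_L` by ±15 mm
(a 3 cm movement range).  `optimal_space_filling()` draws a seeded Latin
hypercube (25 points for the 4-parameter T2/L2 cases, 27 for 5-parameter
TL4) and improves it by maximin coordinate exchange, which preserves the
LHS marginals; over the default 18-case cohort this books exactly 462
simulations.

Each case's simulated ICVs are fitted with a full quadratic response
surface on `[-1, 1]`-scaled parameters (leave-one-out R² from PRESS
residuals guards against over-fitting); `local_sensitivity()` reports, for
each parameter, the predicted ICV change across its full interval with the
others held at the baseline, as a percentage of the baseline prediction.
`group_average()` pools the per-case charts into per-procedure means and
n−1 standard deviations and compares groups pairwise with two-sided
Wilcoxon rank-sum tests (exact for small untied samples).  `agreement()`
implements Bland–Altman statistics (predicted-minus-observed differences,
1.96-sd limits of agreement) plus Pearson correlation for validating
simulated against observed volumes.

### Frozen study conditions

`study_config()` defaults define the reference study: 6 cases per
procedure group, osteotomy baseline at `L = 0.10 x` AP extent,
`H = 0.25 x` height, `alpha = 55` degrees, S12 springs at `S_T = 25` mm and
`S_L = 30` mm, solved over 150 days in 5 steps.  These are the package's
own choices, fixed after pilot runs at the default mesh resolution: the
lateral position `S_L = 30` mm places the lateral springs far enough from
the hinge to produce smooth, well-conditioned parametric responses (near
the hinge the response saturates and its local derivative is dominated by
mesh noise).  At these conditions the reduced-cohort studies reproduce the
expected qualitative pattern — sensitivity to `L` positive, to `H`
negative, to `alpha` negative in all three procedure groups, lateral
spring position `S_L` positive — with baseline gains of roughly 6–20%
depending on the procedure.

## Scope and limitations

* The calvarium is a smooth single-layer shell; sutures, bone thickness
  maps and the skull base anatomy are not modelled.
* Dura, scalp and intracranial pressure are not modelled; all expansion is
  driven by the springs.
* The quasi-elastic viscoelasticity ignores stress-history effects; it is
  a reasonable surrogate for slow, monotonic distraction.
* ICV via the convex hull slightly overestimates enclosed volume for
  non-convex shapes; identical to the clinical surrogate, it is used
  consistently on both sides of every comparison.
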