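---
title: "Evaluating volume-to-surface registration of deformable organs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating volume-to-surface registration of deformable organs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In laparoscopic liver navigation, a preoperative volumetric organ model
(tetrahedral mesh from CT) must be aligned non-rigidly to the surface the
endoscope actually sees intra-operatively — a partial, often noisy and
non-manifold, stitched reconstruction. `hepareg` implements a three-stage
evaluation pipeline for this *volume-to-surface* registration problem:

1. **Registration** by physics-based shape matching: the deformable volume
   is electrically charged and slides into the oppositely charged rigid
   target surface while linear elasticity regularizes the deformation.
2. **Solid voxelization** of the deformed boundary and the reference
   deformed volume onto one shared uniform grid, so differently meshed
   geometries become comparable.
3. **Metrics** on the voxel grids (Hausdorff distance in voxels, Jaccard,
   adjusted Rand index, mutual information, sensitivity, specificity,
   precision) plus a vertexwise RMSE where index correspondence exists.

Three experiment drivers reproduce the classical questions about such a
pipeline: how does registration quality depend on the *orientation* of the
available partial surface, on its *mesh quality*, and on its *size*? A
synthetic deformable-liver phantom with exact ground truth makes every
stage testable without any external data.

## The registration model

The volume is a first-order tetrahedral FEM continuum with the standard
isotropic constitutive matrix built from Young modulus $y$ and Poisson
ratio $p$ (`elasticity_matrix()`), assembled into a sparse stiffness
operator $K$ whose null space spans exactly the six rigid-body modes
(`assemble_stiffness()`). The published parameterizations ship as presets:
$p = 0.4$, $y = 10^3$, with (`"insilico"`) $dt = 0.5$, 50 iterations,
charge $c = 10$, and (`"phantom"`) $dt = 1$, 200 iterations, $c = 500$.

Every target vertex carries charge $c$ times its barycentric area share of
the target surface; the deformable boundary vertices carry the opposite
charge by their own shares. The force on a deformable vertex $v$ is the
softened Coulomb sum
$$F_v = k \sum_t \frac{q_v\, q_t\, (x_t - x_v)}{(|x_t - x_v|^2 + \varepsilon^2)^{3/2}},$$
and minimization runs as an overdamped, diagonally preconditioned explicit
pseudo-time iteration
$$u \leftarrow u + \frac{dt}{\gamma\, m}\bigl(F_{\mathrm{elec}}(u) - K u\bigr),$$
with $m$ the stiffness-lumped diagonal mass proxy. No node is pinned; the
volume floats freely.

### Numerical choices (and why)

The original method's internal force scaling and integrator are not part
of its published description, so the following are this package's own,
deliberate choices:

* **Mass proxy.** Unit nodal masses would demand $dt \sim 10^{-4}$ at
  $y = 10^3$; lumping the stiffness diagonal (Jacobi preconditioning)
  makes the quoted $dt$ values meaningful.
* **Softening** $\varepsilon$ defaults to 0.15 times the target's mean
  edge length: below the mesh discreteness scale the vertex charges stop
  approximating a charged sheet, and the near field would be dominated by
  individual point charges.
* **Force constant calibration.** $k$ is set once, on the undeformed
  configuration, so that the largest electrostatic step equals
  `step_scale` (default 0.2) times the scene's bounding-box diagonal per
  unit pseudo-time. The experiment drivers calibrate on the *full* target
  and reuse the same constant for every partial target of a data set —
  the parameters are fixed across the target surfaces of one comparison,
  so a small target concentrates the same total charge and pulls
  correspondingly harder, exactly the regime in which small targets
  degrade registrations.
* **Trust region.** Each node moves at most `step_clamp` (0.5%) of the
  scene diagonal per step. Near-contact Coulomb forces are orders of
  magnitude above the far field; with only the dt-halving stability guard
  the halvings would stall all bulk motion.
* **Finite force range.** Charge pairs farther apart than `force_range`
  (15% of the scene diagonal) contribute nothing, mirroring field
  precomputation on a finite grid around the target. Consequently organ
  regions far from any target surface simply do not move — which is also
  why a tiny target leaves the Hausdorff distance at its unregistered
  baseline instead of dragging the whole organ toward itself.
* **Stability guard.** If any step still exceeds 10% of the diagonal the
  run restarts with dt halved (logged in the result).
* **Coarse-to-fine softening annealing** is available (`anneal_from`) for
  scenes with a large pose offset, but is off by default: the reference
  bench data provide both states in one coordinate frame.

With charge zero the iteration is exactly the identity; the elastic energy
$\tfrac12 u^\top K u$ is non-negative throughout; and at small $dt$ the
total energy trace is non-increasing (both properties are tested).

## Voxelization and metrics

`make_common_frame()` centres the joint bounding box of all meshes of one
comparison in an $N^3$ grid (default 1024 to match the published setting;
tests and the bundled scripts use 128) with a two-voxel margin. A voxel is
occupied iff its centre lies inside the closed surface, decided by ray
parity along $+x$; rays that graze an edge or vertex are recast with a
deterministic asymmetric jitter of $10^{-6}$ pitch, so grids are bitwise
reproducible. Only closed surfaces are voxelized — open meshes must go
through repair first. Whether grids are compared as filled solids or as
one-voxel shells is a flag (`fill`), since the upstream convention is not
fixed; the default is solid for the overlap metrics, while the Hausdorff
distance always works on the surface-voxel sets (boundary-distance
reading) via an exact Euclidean distance transform, in voxel units.

Directional metrics (sensitivity, specificity, precision) treat the
reference grid as the positive class. Mutual information is reported in
bits; base-2 is a package convention, exposed rather than hidden, because
the upstream base is unstated. Undefined ratios are reported as `NA`,
never coerced to 0. The vertexwise RMSE refuses meshes without index
correspondence instead of silently resampling.

## Mesh repair

`manifold_report()` counts duplicate and isolated vertices, edges with
more than two incident faces, vertices whose incident-face star is not a
single edge-connected fan, boundary loops, components, and degenerate
faces/edges. Two automatic repair strategies operate on stitched surfaces:

* **Strategy (a)** — quick pass: weld duplicate vertices (exact bitwise
  equality by default; an epsilon in mm is exposed), drop isolated
  vertices, keep the single largest-area component.
* **Strategy (b)** — full manifold repair: weld; delete zero-area faces
  and zero-length edges; (faces are already triangles, hence convex);
  excise non-manifold configurations; fill holes by fan-triangulating
  each closed boundary edge loop around its centroid; remove isolated
  vertices.

Two excision details matter. An edge with more than two faces loses *all*
its incident faces (the subsequent hole filling exists precisely to repair
this). A split-star vertex, however, keeps its largest fan and loses only
the smaller ones: deleting the whole star turns out to cascade — two
excision scars meeting at a vertex create a new split star, and iterating
can eat large parts of the mesh. Excision and filling alternate until a
fixed point because filling a *pinched* pair of holes (two loops sharing a
vertex) can itself recreate a split star; boundary loops are recovered as
edge-disjoint cycles, so pinched holes are filled one cycle at a time.
The hole-size cutoff `max_loop_edges` defaults to unlimited in
`strategy_b()` (the threshold above which filling becomes unreliable is a
user decision); the mesh-quality experiment driver defaults it to 16 so
that defect holes close while the open rim of a partial view is never
capped with a fabricated lid.

## The synthetic phantom

`make_phantom()` builds a liver-scale solid: a superellipsoid (semi-axes
60, 45, 35 mm, exponent 2.5 — slightly boxy, like a lobe) with a smooth
low-frequency radial perturbation (amplitude 0.08, deterministic per
seed), tetrahedralized by mapping a Kuhn-subdivided cube lattice (six
tetrahedra per cell, default 8 cells per axis, about 770 boundary faces)
radially onto the shape. The construction is watertight by construction;
the boundary is re-oriented combinatorially, because the radial map can
tangle a few corner elements whose faces would otherwise flip.

`simulate_indentation()` presses a rigid sphere into the organ along one
axis (default $+Y$, radius 30 mm, depth 18 mm — about a fifth of the organ
extent, large enough that overlap metrics separate good from poor
registrations): footprint boundary nodes receive a prescribed smooth
paraboloid displacement (exactly $-$depth at the apex, zero at the rim),
the far third of the organ is pinned, and the remaining nodes follow from
a static linear-elastic solve. Ground truth therefore comes from a
*prescribed-displacement static* solve while the registration is
*force-driven pseudo-dynamics* — two different numerical paths, so
validating one against the other is not an inverse crime.

`crop_partial_view()` emulates an endoscopic view: faces visible from the
gaze direction, largest connected patch, trimmed by a swept plane to the
requested area fraction (within one percentage point). `corrupt_surface()`
injects, deterministically per seed, the defects of a stitched surface:
Gaussian vertex jitter, duplicate vertex records, fins (extra triangles on
interior edges), holes, *stitch blisters* (a copy of a vertex star with
the apex lifted, rim-stitched through exact-duplicate vertices — welding
re-attaches it non-manifoldly, so only strategy (b) removes it), and
*stitching ghosts* (detached, offset patch copies with every face doubled
— non-manifold throughout, removed by (a) as separate meshes and by (b)
as non-manifold geometry). Vertex jitter, duplicates, fins and holes alone
barely mislead a charged-sheet attraction; the blisters and ghosts model
the misregistered-overlap errors of real stitching and are what makes
repair measurably improve registration. Defect sites are kept mutually
disjoint so each corruption is individually countable by oracle tests.

What the phantom does *not* emulate: patient-specific anatomy, breathing
or insufflation deformation, reconstruction noise correlated along scan
lines, and the very fine meshes of real reconstructions. Passing tests on
the phantom therefore demonstrate the pipeline's correctness and its
qualitative sensitivity patterns, not clinical accuracy.

## The experiments

* `run_orientation()` bisects the full target at its area-weighted
  centroid into XZ, XZ-hemi, YZ, YZ-hemi, XY and XY-hemi partial targets
  (the label names the cutting plane; the hemi second cut passes through
  the retained half's own centroid), registers the volume to each,
  voxelizes everything in one shared frame and reports the metric panel
  plus the unregistered baseline row. Which side of a cut is retained is
  configurable; `keep = "larger"` is the default.
* `run_mesh_quality()` compares registration to the raw corrupted view
  and to its strategy (a) and (b) repairs.
* `run_surface_size()` sweeps stepwise bisections along the indentation
  axis (default: twelve steps of one-twelfth of the target's extent;
  the stepwise increment is interpreted in the mesh's local coordinate
  units) and reports metrics as a function of retained area, plus the
  smallest area whose Hausdorff distance is within a tolerance (default
  2 voxels, a user choice — no published numeric threshold exists) of the
  full-target row.
* `summarize_experiments()` adds the reporting statistics: one-way ANOVA
  of the Hausdorff distance across target groups, a one-sample t test
  against a stated mean, and Pearson correlations between area and each
  metric, with significance at $p < 0.05$. A single report has one row
  per target and hence no residual degrees of freedom; the ANOVA then
  reports `NA` with a note — pool reports over seeds to give it
  replicates.

Every row of a report is one registration plus one voxel comparison under
a single shared grid frame, and the provenance log records every setting
(grid size, pad, fill mode, keep side, weld epsilon, loop cutoff) so any
number can be traced to its configuration. Reports are reproducible bit
for bit from (data set, parameters, seed).

## Worked example

```{r, eval = FALSE}
library(hepareg)

scene <- simulate_indentation(make_phantom(seed = 1))
ds <- as_experiment_dataset(scene)

rep1 <- run_orientation(ds, registration_params("insilico"), grid_n = 128)
rep1$rows[, c("label", "area_percent", "hausdorff_vox", "jaccard")]

summarize_experiments(rep1)
```

At the bundled desk scale (grid $128^3$, ~770-face phantom boundary) a
full run of all three experiments takes a few minutes; the published-scale
grid ($1024^3$) is a flag away but needs correspondingly more memory and
time.

## Known limitations

* Small-strain linear elasticity with first-order tetrahedra; a
  corotational or second-order extension is an open extension point.
* The electrostatic sum is an all-pairs evaluation — adequate at desk
  scale, quadratic in vertex count.
* Hole filling is centroid-fan triangulation: correct topology, flat
  geometry; large holes are filled flatly, which is why the loop-size
  cutoff exists.
* Exact numerical equivalence with the original implementation's
  registration scores is not attainable from its published description
  (its force scaling and integrator are internal); the pipeline
  reproduces the *patterns* — full-target recovery, orientation
  sensitivity, repair benefit, monotone size sensitivity — and the
  geometry-level quantities exactly.
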