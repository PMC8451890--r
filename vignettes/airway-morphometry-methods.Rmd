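---
title: "Automated airway morphometry: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated airway morphometry: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaymorph)
```

## The measurement problem

Aerosol dosimetry models need, for every conducting airway, four numbers:
length, diameter, branch angle and inclination to gravity, organized by the
Raabe binary labeling scheme (trachea = `1`; each daughter appends `1` for
the larger-diameter, "major" daughter or `2` for the minor one, so the
airway generation is simply the number of digits). Micro-CT scans of
in-situ silicone lung casts provide the raw geometry: a segmented binary
volume of the airway lumen at single-digit-micrometer voxels. `airwaymorph`
turns such a volume into a per-branch morphometry table and the comparison
statistics used to validate automated against manual measurements and to
compare mouse strains.

Because real cast scans are large external datasets, the package ships a
first-class phantom generator with analytic ground truth. Every stage of
the pipeline is validated against phantoms whose true lengths, diameters
and angles are known in closed form.

## Pipeline stages and their models

### Volume pre-processing

A grayscale volume is thresholded (`threshold_volume()`, foreground =
values at or above the level), optionally downsampled by an integer factor
(`resample_volume()`), opened morphologically (`open_volume()`) and reduced
to its largest 26-connected component (`largest_component()`).

Choices the underlying workflow leaves open, fixed here:

* **Resampling rule.** Block majority vote, with ties going to foreground.
  Ties-to-foreground preserves thin branches, which matters because any
  detail thinner than the opening bandwidth is lost anyway; we prefer to
  lose it at the opening stage, where the loss is principled, not at
  resampling, where it would be an aliasing accident.
* **Structuring element.** A digital ball. The conventional "2 pixels of
  size" element is read as *radius* 2 on the resampled grid: with a
  resampling factor of 2 this makes the opening bandwidth 4 original
  voxels, which is the only reading under which the stated bandwidth
  arithmetic is self-consistent.
* **Connectivity.** 26-connectivity for foreground everywhere (standard
  for tubular structures; 6-connectivity is used for background in the
  topology tests of thinning, the standard complementary pair).

`accuracy_estimate()` encodes the workflow's resolution limit: twice the
opening bandwidth in micrometers. At the reference settings (6.6 µm
voxels, factor 2, 2 px) this is 52.8 µm ≈ 50 µm: structures thinner than
this are genuinely unmeasurable by the workflow, which is why the phantom
rasterizer warns when any branch diameter falls below 4 voxels.

### Centerline extraction

`skeletonize()` is a topology-preserving 3D thinning: simple points
(deletable without changing local object/background topology, tested by
the two-connected-component characterization in the 3×3×3 neighborhood)
are removed in increasing order of the exact Euclidean distance map, so
the surface is eaten inward and the skeleton stays medially centered;
curve endpoints (voxels with at most one foreground neighbor) are kept.
Two documented clean-ups follow:

* **Twig pruning.** Thinning inside a thick tube can leave short side
  twigs that run from the axis to just inside the surface; any terminal
  chain shorter than the local cast radius plus 1.5 voxels is deleted.
  Genuine anatomy — including artifact nubs that protrude *beyond* the
  surface — is longer and survives.
* **Terminal-tip recovery.** The endpoint lock of sequential thinning is
  order-dependent, so a branch tip can retract a few voxels. Each terminal
  is extended along its end tangent while the distance-map value stays at
  the tip's level; the true end is the furthest point before the local
  radius starts falling toward the surface.

`build_network()` clusters skeleton voxels with ≥ 3 neighbors (within a
2-voxel Chebyshev radius — thinning yields junction clumps, not single
voxels) into bifurcation nodes, makes degree-1 voxels terminals, picks the
root as the terminal with the largest local cast radius (the trachea is
the widest airway; a `root_hint` position overrides this), and orients all
branches proximal→distal. Bifurcation node positions are then re-estimated
as the least-squares intersection of lines fitted to the three incident
centerlines just beyond the junction flare (arclength window one to three
local radii from the node): the raw junction clump sits systematically
~1–2 voxels inside the parent, and this refinement is what brings
node-to-node lengths within the recovery tolerances below.

`smooth_centerlines()` is a moving average with pinned endpoints rather
than a parametric spline: the measured quantities (chord lengths, node
positions, tangents) are what the workflow constrains, not the curve
family, and a windowed mean is contract-equivalent and easier to verify.
The pipeline smooths once after network construction and once more after
QC, because merging branches across a removed degree-2 node can leave a
kink at the old node position that would otherwise tilt cross-section
planes.

### Network quality control

`detect_exceptions()` reports the four exception classes a cast skeleton
exhibits; `qc_network()` resolves them in a fixed, deterministic order:

1. **Closed loops** (graph cycles, from artificial contacts that survived
   opening): the cycle edge with the smallest mean local radius is
   removed — contact bridges are thin, anatomy is thick.
2. **Spurs** (terminal branches shorter than
   `max(4 voxels, 1.5 × local parent radius)` — the annular-ligament
   class) are pruned, and **spurious degree-2 nodes** merged, *before*
   trifurcation handling: a short twig hanging off a bifurcation would
   otherwise masquerade as a trifurcation.
3. **Trifurcations**: the two daughters whose departure directions are
   most similar are grouped onto a new node joined to the original by an
   intermediate airway recorded with length 0.1 mm, branch angle 0°, and
   the parent branch's diameter — the manual-morphometry bookkeeping for
   an apparent three-way split. The grouping-by-proximity rule is this
   package's convention (a near-trifurcation is two close bifurcations, so
   the two daughters that almost share a plane belong together); the
   intermediate airway is flagged and exempt from spur pruning.
4. A final spur/merge pass, since resolutions can expose new degree-2
   nodes.

Post-QC the network is acyclic, strictly bifurcating, with no internal
degree-2 nodes and no spurs — the invariants the measurement stage
assumes.

### Morphometry

* **Length** is the chord between the two nodes, not the centerline arc.
* **Branch angle** is the angle between the parent's and daughter's
  node-to-node vectors; chords (not local tangents) are used for both
  branch and gravity angles, matching how the manual schematic defines
  them. This choice is also why automated and manual *branch angles*
  correlate worse than lengths/diameters in method comparisons: the two
  conventions measure subtly different things on curved branches.
* **Gravity** is anatomy-defined: with `t` the unit trachea vector and
  `b` the normalized mean of the two main-bronchus unit vectors, the
  gravity direction is the component of `b` orthogonal to `t` (sign such
  that it points with the bronchi). The trachea is therefore at exactly
  90° to gravity by construction, and all gravity angles are invariant
  under rigid motion of the scan.
* **Hydraulic diameter** `4·Area/Perimeter` is averaged over
  cross-section planes perpendicular to the local centerline tangent,
  sampled every `cross_section_step` voxels (default 2). On each plane
  the mask is trilinearly interpolated on a grid of 0.75-voxel pitch and
  half-width twice the local radius, Gaussian-blurred (σ = 1 grid px),
  and contoured at the 0.5 level; the contour polygon containing the
  centerline point supplies area and perimeter. The blur is a numerical
  necessity, not cosmetics: the 0.5-isoline of interpolated binary data
  is a staircase whose jaggedness inflates the perimeter by ~5% and
  biases the diameter low; with the blur, a 20-voxel cylinder measures
  within 1%.
* **Plane discharge.** A plane is discharged when another branch's
  centerline passes within the plane's half-width laterally and half a
  step along the normal, when its region touches the plane boundary, or
  when the centerline point itself is not inside the foreground. Planes
  within one local radius of either node are never sampled: bifurcation
  flare there inflates the section. (One radius, not half: at half a
  radius the flare still contributes and daughter diameters read up to
  +6% high on phantoms.) If no plane survives — branch shorter than its
  diameter, or highly bent — the diameter is 0 with the validity flag
  unset, and the branch contributes its parent's diameter to generation
  averages, mirroring the zero-flag bookkeeping of the reference
  workflow. "Highly bent" is deliberately emergent from the discharge
  rules rather than a curvature threshold.
* **Labeling** uses the measured hydraulic diameters (with the parent
  fallback for invalid ones). Ties break by larger subtree branch count,
  then by a fixed lexicographic rule on the chord direction, so labeling
  is deterministic.
* The **root branch** (tracheal stub — real scans start at the trachea
  base, so the stub is short) is measured but flagged `root-stub`.

### Comparison statistics

`match_branches()` inner-joins two tables on the Raabe label.
`regression_through_origin()` fits `y = βx` (slope `Σxy/Σx²`) and reports
the *mean-centered* Pearson r — the coefficient named by convention in
method-comparison work — alongside the uncentered R² of the no-intercept
fit, since the two are easily conflated. `anova_by_strain()` runs one-way
fixed-effects ANOVA per generation and measure; the replicates are
*casts* (each cast contributes its generation mean), because generation
data are averaged within a cast before strains are compared — a
`replicates = "branches"` switch exposes the alternative.
`paired_t_bonferroni()` reports raw p, `min(1, m·p)` and the `α/m`
threshold with the family size `m` stated explicitly. Gravity angles can
optionally be folded to [0, 90°] (`fold_gravity`) for comparison against
protractor-style manual measurements that do not distinguish
up-from-down; the default is off.

## The phantom generator

`tree_spec()`/`build_tree()` grow a recursive bifurcating tree:

| parameter | default | meaning |
|---|---|---|
| `generations` | 6 | trachea = generation 1 |
| `diameter_scale` | 1.2 × 0.75^(g−1) mm | mouse-like: 1.2 mm trachea, ratio 0.75 |
| `length_scale` | 2 × diameter | L/D ≈ 2 |
| `branch_angle_mean`, `sd` | 35°, 8° | daughter departure angles, clipped to [10°, 80°] |
| `daughter_asymmetry` | 0.8 | minor/major daughter diameter ratio |
| `curvature` | 0 | sagitta of a circular-arc bow, as a fraction of length |
| `prune_prob` | 0 | probability a subtree (generation ≥ 3) is absent |

The trachea runs along +y; the main bronchi are tilted toward −z so the
lungs hang below the trachea and the anatomical gravity construction is
exercised non-trivially (a tree in a single plane through the trachea
would make it degenerate). Each bifurcation plane rotates ~90° about the
parent axis per generation, which spreads the tree through 3D and keeps
cousin branches apart. The main bronchi are never pruned (a lung has two),
so gravity is always defined for `generations ≥ 2`. Randomness is drawn
from per-branch substreams keyed by `(seed, label)`, so pruning one
subtree cannot perturb its siblings' geometry — stable fixtures.

Branches are rasterized as capsules (hemispherically capped tubes), which
has two virtues: the voxel volume has a closed-form value to test against
(πr²L + 4/3πr³), and the medial axis of a capsule is exactly its segment,
so skeleton accuracy is testable voxel by voxel. Ground truth (lengths as
chords, realized angles, gravity angles, Raabe labels by true diameter)
is computed analytically from the generated geometry, not by running any
part of the measurement pipeline.

`inject_artifacts()` reproduces the defect classes real scans exhibit:
thin `touching_branches` bridges (removable by the opening),
`closed_loop` bridges thicker than the opening bandwidth, `spur_nub`
protrusions (the annular-ligament class), and `trifurcation`s (a third
daughter at an existing bifurcation, placed out of the daughters' plane
and away from the rest of the tree). Bridge endpoints are chosen
mid-branch between genuinely separated surfaces and away from third
branches: near a shared node the cast is a fused web, where a bridge
fills a solid disk instead of closing a handle and no loop results.

What the phantoms deliberately do *not* emulate: grayscale noise and
reconstruction artifacts (inputs are clean binary), airway wall tissue,
lobe-specific anatomy (the sharp medial-lobe turn some strains show is
representable via `curvature` but not reproduced), and non-circular
airway cross-sections. Passing the recovery suite therefore demonstrates
the geometry processing is correct at scanner-like resolution, not that
segmentation of noisy grayscale data is solved.

## Numerical choices and degenerate inputs

* Thinning uses the exact (Felzenszwalb–Huttenlocher) squared EDT;
  outside-the-grid counts as background.
* Junction clusters within 2 voxels merge; the 0.1 mm trifurcation
  intermediates produce coincident nodes whose zero chord is flagged
  rather than measured.
* Skeletons with no terminal voxel (closed structures) are rejected;
  isolated skeleton cycles that touch no junction are closed onto a
  synthetic node so QC's loop resolution can remove them.
* Ties in the resampling vote go to foreground; ties in Raabe labeling
  break by subtree size then a fixed spatial rule; equal-EDT voxels in
  thinning pop in scan order — all deterministic, so a config and seed
  fully determine every output.
* Angles are computed through a clamped arccos ([−1, 1]) and always land
  in [0°, 180°].

## Problem sizes used in validation

The shipped tests run entirely on generated phantoms: a complete
6-generation mouse-scale cast rasterized at 35 µm (grid ≈ 190×250×250,
about 260k foreground voxels) for the airway-census checks, 3–4-generation
casts at 40 µm for per-branch recovery, artifact handling and rigid-motion
invariance, and axis-aligned capsules for the skeleton and
hydraulic-diameter oracles. At these sizes the recovery results are:
lengths within max(2 voxels, 3%), diameters within 5%, branch and gravity
angles within 5° of analytic truth, and all 63 airways of the first six
generations are found and labeled correctly. Finer grids sharpen the
diameters further but add nothing to the logic under test.

## Known limitations

* The hydraulic-diameter average is computed over retained planes only; a
  branch dominated by discharged planes near a dense junction can carry a
  valid flag yet rest on few sections. The number of retained planes is
  deliberately not exposed as a quality score yet.
* Sibling branches whose capsules overlap most of their length (departure
  angles well below ~20° at L/D = 2) merge in the cast itself; the
  skeleton then resolves them late or not at all. This is the physical
  resolution limit of cast morphometry, not a recoverable artifact.
* The generator draws angles independently per bifurcation; real strains
  have correlated, lobe-specific geometry. Strain comparisons on
  phantoms exercise the statistics, not strain biology.
* Manual-morphometry tables are consumed only through the shared CSV
  schema; transcription conventions (e.g., folded gravity angles) must be
  declared by the caller via `fold_gravity`.
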