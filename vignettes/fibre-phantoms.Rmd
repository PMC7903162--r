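---
title: "Growing white-matter fibre phantoms: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing white-matter fibre phantoms: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fibrephantom)
```

## The problem

Monte Carlo simulation of diffusion MRI needs synthetic white-matter
geometries -- numerical phantoms -- whose microstructure (fibre volume
fraction, radius distribution, orientation dispersion, cross-sectional
shape) is known exactly and resembles real tissue. Packing pre-made
fibres densely is hard; real axons instead *grow* into available space
under chemical guidance. This package generates phantoms by imitating that
process: fibres grow one-by-one on a discrete spatial network, steered by a
cost function that balances progress towards a target against the space
left by earlier fibres, and are finally meshed into watertight, pairwise
non-intersecting surfaces suitable for particle simulations.

## The growth model

**Initial configuration.** The user specifies a box region `L` (um), a
target fibre volume fraction `rho`, a radius distribution (gamma with mean
`mu_r` and standard deviation `sigma_r`), and an orientation model per
bundle: parallel, Watson (axial, concentration `kappa`) or an elliptically
symmetric angular Gaussian (mean vector `mu`, anisotropy `gamma`). Circles
with the sampled radii are packed on each bundle's entry face up to `rho`;
each packed circle is a fibre start point with target diameter `d0` equal
to the packed diameter. A direction drawn from the orientation model
projects each start point onto the region boundary, giving the fibre's
target point. The space is seeded with `N` uniformly pseudorandom growth
nodes, connected by their 3D Delaunay tetrahedralisation.

**Growth.** Fibres grow in a seeded random order. From its current head
node a fibre may step to any Delaunay neighbour `c`; each candidate is
scored

    l = lt + f * ld
    lt = 1/2 * (|s - c| / (1 + |s - c|)) * (1 - cos(theta))
    ld = max(0, (d0 - dc) / d0)

where `theta` is the angle between the step and the direction to the
target, and `dc` is the maximum fibre diameter sustainable at the
candidate without hitting an existing fibre. The fibre takes the cheapest
step (greedy best-first); `f = 0.2` by default so progress towards the
target dominates. The realised radius at each node is `min(d0, dc)/2`:
fibres shrink where space is tight. After a fibre completes, every node
within the tracking cutoff of its capsule chain has `dc` min-updated to
twice its clearance from the fibre surface; nodes inside the fibre become
occupied and unusable.

Four optional mechanisms modify this loop:

* **Fibre collapse** -- a stuck fibre (no accessible neighbour) retreats
  along its own path by `g0 + k * delta` (defaults 2 and 5 um, so the
  escalation sequence is 2, 7, 12, 17, 22, 27 um), blacklists the
  abandoned nodes, and regrows; after the sixth stuck event it is removed
  from the phantom.
* **Dynamic network** -- after each completed fibre, `N_added` (default
  2500) new nodes are scattered in a shell around its path (radial offset
  1.05-2 local radii) and inserted incrementally into the triangulation,
  so later fibres have candidates to grow along or around it.
* **Fasciculation** -- the diameter cost becomes bundle-conditional: when
  the bundle nearest to the candidate is the fibre's own,
  `ld = |(d0 - dc)/d0|`, which also penalises moving *away* from the
  bundle and so draws same-bundle fibres together.
* **Global relaxation** -- after growth, every interior skeleton point is
  iteratively nudged by the sum of signed unit interactions with its 10
  nearest other-fibre points (repulsive inside the touching distance
  `r_i + r_j`, attractive outside), each sweep capped at `0.2 r_i`.

**Meshing.** Each fibre's skeleton is resampled into metaball sources
(spacing half the minimum radius) carrying the compact-support kernel
`K(q) = (1 - q^2)^3`, `q = distance / (2 r)`. The fibre surface is the
isosurface of its own positive field plus the *negative* fields of all
previously meshed fibres, so later fibres deform organically around
earlier ones instead of intersecting them. Isosurfaces are extracted by
marching tetrahedra and verified pairwise with an exact triangle-triangle
test.

**Morphometry.** Centre lines connect the area-weighted centroids of 100
equidistant cross-sections of each mesh (after aligning its end-to-end
vector with z). Segment directions feed a spherical histogram on a
subdivided icosahedron (level 3, 1280 faces; forwards and backwards, so it
is antipodally symmetric by construction, normalised per steradian) and
the angle-from-axis summary (`mu_theta`, `sigma_theta`, folded to [0, 90]
degrees). Cross-section areas give circle-equivalent diameters
(`d = 2 sqrt(A/pi)`). Virtual histology rasterises mesh-plane intersection
polygons into labelled images (default 5 nm pixels) from which per-axon
circularity (`4 pi A / P^2`), convexity (`A / A_hull`), moment-ellipse
eccentricity and `A/(pi r_max^2)` (minimum-enclosing-circle radius) are
computed; axons touching the image edge are excluded.

## Parameters that matter

| parameter | meaning | default | tested range |
|---|---|---|---|
| `region_size` | growth box edge (um) | 10 | 0-50 |
| `target_density` | fibre volume fraction | 0.75 | 0-0.8 |
| `radius_mean`, `radius_std` | gamma radius moments (um) | 0.5, 0.1 | 0.5-2, 0.1-0.5 |
| `watson_kappa` | axial concentration | 8 | 4-100 |
| `n_nodes` | growth nodes | 2e5 | up to 1e7 |
| `cost_weight` (`f`) | diameter-cost weight | 0.2 | 0-0.5 |
| `collapse_initial` (`g0`), `collapse_increment` (`delta`) | retreat schedule (um) | 2, 5 | 1-5 |
| `n_added` | dynamic nodes per fibre | 2500 | 0-5000 |

Values outside the tested ranges warn rather than error. A phantom's
*output* morphology never matches the inputs exactly: removed fibres and
forced shrinkage lower the density, and discrete zig-zag paths add
apparent dispersion, so dispersion should always be measured on the result
rather than read off the inputs.

## Numerical and design choices

* **Radius distribution.** The family is a free choice; we use a gamma
  parameterised by mean and standard deviation (`shape = mu^2/sigma^2`),
  the usual convention for axon-radius phantoms, degenerating to a
  constant at `sigma = 0`.
* **Face packing.** Random sequential insertion saturates near 55% area
  fraction, below the densities of interest, so packing uses random
  placement followed by pairwise-repulsion relaxation with gradual radius
  inflation; if the target is infeasible the most-squeezed circles are
  dropped and the best valid packing returned with a warning.
* **`dc` convention.** The sustainable *diameter* at a node is defined as
  twice the node's clearance from the nearest fibre surface, so a fibre
  centred there with diameter `dc` just touches. Clearance queries treat
  fibres as capsule chains (spheres swept along segments, radii linearly
  interpolated).
* **Clearance cutoff.** Nodes farther than `track_radius` (default 6 um)
  from every fibre keep an infinite-`dc` sentinel with no bundle label;
  this bounds update cost and is exact within the cutoff.
* **Saturated fasciculation.** The bundle-attraction branch is evaluated
  with clearance saturated at `2 d0`, keeping `ld` within [0, 1] like
  every other cost term. Without saturation the attraction grows without
  bound with distance from the bundle and, at the finite node densities
  used here, overwhelms the bounded direction term: fibres whose targets
  lie laterally off the bundle then wander and are removed, and the
  mechanism *lowers* the achieved density instead of raising it. The
  saturation point `2 d0` is where the plain shrinkage branch also reaches
  its extreme value of 1.
* **Completion.** A fibre completes when its head is within the network's
  90th-percentile Delaunay edge length of the target, or past the plane of
  the target's face; the final point then snaps onto the target. The
  tolerance is computed once on the initial network.
* **Tie-breaks and cycles.** Equal-cost candidates resolve to the lowest
  node index; a fibre never revisits a node on its own current path; nodes
  offering less than `0.1 d0` are treated as inaccessible (configurable),
  which prevents filament-thin fibres the mesher could not represent.
* **Relaxation stopping.** The literal synchronous update oscillates at
  the step cap once contacts form (the signed force does not vanish at
  equilibrium), so sweeps stop after ten consecutive sweeps without a new
  best total-overlap value (relative tolerance 1e-4, sweep budget 200),
  and the best configuration seen is returned -- the final overlap
  therefore never exceeds the initial one. Endpoints stay fixed and radii
  are never modified.
* **Isolevel calibration.** For a chain of equal sources the field at
  lateral distance `r` is computed analytically and used as the isolevel,
  so a straight constant-radius fibre meshes to exactly its nominal
  radius; an isolated single source yields a sphere of its radius at level
  `(3/4)^3`. Marching tetrahedra run on a Kuhn 6-tet cell split (voxel a
  quarter of the minimum radius by default) with vertices root-polished by
  bisection on the exact field, which removes linear-interpolation bias.
* **Exclusion clip.** The negative field alone cannot prevent surface
  crossings when skeletons interpenetrate deeply (the new surface crosses
  a prior one wherever its own field reaches twice the isolevel there).
  The marching field therefore also clips the new fibre against every
  previously meshed fibre's own isosurface with a 10% field margin -- a
  hard exclusion on top of the organic negative-field deformation.
* **Collision retries.** Discretisation can still leave grazing contacts
  between meshes extracted on unaligned grids; when the exact triangle
  test finds any, the fibre is re-extracted with the exclusion margin
  widened by 1.6x, up to four times. Meshing order is growth order, so
  early fibres keep their undeformed shape.
* **Harness orientation measurement.** The experiment harnesses measure
  angle statistics on skeletons boxcar-smoothed over three mean radii of
  arc length. This approximates the mesh centre-line measurement -- the
  metaball surface averages the discrete skeleton at the radius scale --
  at a fraction of its cost; the window was calibrated once against mesh
  centre-line statistics on a desk-scale phantom. Morphometry on meshes
  remains the reference route.
* **Meshing cost guards.** Fibres squeezed to the growth-time radius
  floor would demand impractically fine voxel grids; the per-fibre default
  resolution and source spacing are clamped from below at a tenth of the
  fibre's mean radius, and a cell budget coarsens the grid (with a
  warning) for extreme cases. Accuracy is traded only at pinch points.
* **Seeds.** One master seed drives every stage through fixed per-stage
  derived seeds, so packing, directions, node clouds, growth order,
  dynamic insertion and relaxation jitter are each independently
  reproducible, and a phantom is bitwise reproducible from its
  configuration alone.

## What the generator does and does not emulate

The synthetic conditions reproduce the study design the method was built
for: single or perpendicularly crossing bundles in boxes up to tens of
micrometres, gamma radii around 0.5 um, Watson or ESAG dispersion, target
densities up to 75% -- the empirical ceiling for this growth style. The
generator does not emulate myelin sheaths, glial cells, periodic
boundaries, spatially varying density, or the coupling between crossing
bundles' entry densities and the density actually realised in the crossing
region. Passing tests therefore demonstrate correctness of the growth,
meshing and measurement machinery under these idealised conditions, not
fidelity to any particular tissue sample.

## Problem sizes used by the test-suite

The full-fidelity sweep conditions (20 um region, 2.5e6 nodes) take hours
per phantom; the package's experiments therefore define three presets. The
test suite and the acceptance script run the `reduced` preset (10 um
region, 2e5 nodes) for input-versus-output sweeps and the `mini` preset
(6 um region, 3e4 nodes) for mechanism ablations; both keep every
morphological target of the full conditions. These sizes are the package's
own choice of desk-scale study conditions and are stated here so results
can be compared like-for-like.

## Known limitations

* Growth is strictly sequential; grown fibres are rigid, so pockets of
  inaccessible space can form and the achieved density falls short of the
  target, increasingly so at small scale.
* Orientation output is biased upward at low dispersion (zig-zag paths on
  a discrete network add angular noise), so output `mu_theta` exceeds the
  target at high `kappa`.
* The global relaxation is a contact-resolution pass, not an optimiser;
  with the literal update rule it cannot be iterated to a fixed point.
* Meshes are exact isosurfaces of the calibrated field only for straight,
  constant-radius fibres; bends and radius changes deviate within about
  one voxel, and fibre tips round off short of a capsule's hemispherical
  cap (up to about half a radius), which is inherent to metaball chains.
* The ESAG parameter-to-covariance mapping follows the standard
  unit-determinant construction; other conventions exist, and the choice
  matters only for anisotropic dispersion.
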