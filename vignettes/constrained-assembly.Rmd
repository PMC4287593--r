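---
title: "Building constrained macromolecular assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building constrained macromolecular assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molassembly)
```

Many biological structures are built by repeating one protein: actin
filaments, microtubules, and the fibrin strands that pair into the
protofibrils of a blood clot. A scientist exploring such a structure wants
to place a handful of rigid molecular surfaces, forbid impossible overlaps,
respect experimentally known distances, replicate a monomer into a
filament, and finally animate the result. `molassembly` implements that
computational core: rigid-transform algebra, chain replication from an
example pair, collision detection tuned to these workflows, penalty-based
placement with sliding contact, spring-rest-length layout, and keyframe
sampling. Everything runs headless on meshes and small atomic structures.

## Rigid transforms and the chain replication law

A pose is a proper rotation $R$ plus a translation $t$ (Å), acting on
column points as $p' = Rp + t$. Composition is matrix-product order:
`rt_compose(T1, T2)` applies `T2` first. The central identity is the
*chain law*: place two copies of a monomer at world poses $T_A$ and $T_B$;
their relative transform in $A$'s local frame is
$T_{AB} = T_A^{-1} T_B$, so $T_B = T_A \, T_{AB}$, and copy $i$ (1-based)
of the repeated structure sits at

$$T_i = T_A \, T_{AB}^{\,i-1}.$$

Consequently the relative transform between copies $i$ and $j$ is
$T_{AB}^{\,j-i}$ — it depends only on the offset $j - i$. Both the live
regeneration of a chain while its example pair is edited
(`chain_from_pair`, `set_internal_transform`) and the collision shortcut
below rest on this constancy, and the test suite checks it to $10^{-8}$ on
randomized chains.

Every rigid motion is a *screw*: rotation by an angle about an axis plus a
translation (the *rise*) along it. `screw_decompose` recovers axis, angle
$\in (-\pi, \pi]$ and rise, which for a filament repeat are the familiar
twist/rise helical parameters (an actin-like repeat is roughly $-166.7°$
twist and $27.5$ Å rise per subunit). Degenerate cases are fixed by
convention: a pure translation reports angle 0 with the axis along the
translation through the origin; at angle $\pi$, where both axis signs
describe the same rotation, the sign making the first nonzero axis
component positive is returned. Decompose-then-reconstruct round-trips to
$10^{-7}$.

```{r helix}
helix <- screw_transform(list(axis_direction = c(0, 0, 1),
                              axis_point = c(0, 0, 0),
                              angle = -166.7 * pi / 180, rise = 27.5))
monomer <- make_fixture("blob", semi_axes = c(12, 9, 7), seed = 4)
chain <- chain_from_pair(monomer, rt_identity(),
                         TB = helix, n = 13)
describe_helix(chain)
```

## Collision detection

Pairwise mesh tests use an axis-aligned bounding-box tree per mesh, built
once in the mesh's local frame (median split on the longest centroid axis,
leaf size 4) and refitted through the relative pose at query time, so
moving an object never rebuilds its tree. Triangle pairs are tested with a
separating-axis test; *touching counts as colliding* (ties resolve toward
contact — the conservative choice for overlap avoidance). The tree path is
validated against an exhaustive all-triangle-pairs reference
(`collide_pair_brute`) for exact contact-set equality on randomized scenes.

Two workflow-specific reductions cut the quadratic cost of scene checks:

* **Pose-mode filtering.** While a user manipulates $m$ objects out of
  $n$, the other $n - m$ cannot move, so only pairs involving a moving
  object need testing: at most $m \cdot n$ object-pair tests
  (`scene_collisions`), instead of $\binom{n}{2}$.
* **Chain-internal shortcut.** Within a repeated chain, copies $i$ and
  $i+k$ stand in the same relative pose for every $i$ and share one
  geometry, so copy 1 against copy $1+k$ decides *all* pairs at offset
  $k$. `chain_internal_collisions` performs exactly $n - 1$ pair tests and
  expands hits to the implied pairs, copying the representative pair's
  contact list (identical relative pose implies identical contact
  topology).

`tests_performed` counts object-pair tree queries, not triangle tests, and
both bounds are asserted unconditionally in the suite.

## Pose-mode physics

Manipulated objects are pulled toward a target pose by a wrench
proportional to the pose error: force $k_t (t_\text{target} - t)$ and
torque $k_r \log(R_\text{target} R^\top)$ (axis–angle). Collision response
acts **only on manipulated objects**: for each contact, a penalty force of
`response_gain` along the contact triangle normal of the *other* body
(oriented away from it), with torque from the contact offset. Everything
else in the scene is immovable by construction — the suite asserts
non-manipulated poses are bitwise unchanged across arbitrary stepping.
Because the response is purely normal, a pulled object slides tangentially
along an obstacle while being held out of it, which is the behaviour that
makes docking workflows usable.

A rejection variant (`physics_step_reject`) applies the tracker-driven
candidate pose only when it is collision-free. It is kept as a comparison
mode: once in contact, nearly every candidate still collides, so objects
stick and tangential sliding stalls — the paired fixtures in the suite
show the response mode reaching > 90 % of a tangential target where the
rejection mode reaches < 10 %.

Integration is semi-implicit Euler with unit mass and inertia: this is a
pose controller, not a dynamics simulator, so only parameter ratios
matter. Defaults, all overridable:

| parameter | default | unit | rationale |
|---|---|---|---|
| `k_translate` | 1 | force/Å | scale anchor |
| `k_rotate` | 1 | torque/rad | isotropic with translation |
| `dt` | 0.1 | time | with damping, near-critical settling |
| `damping` | 0.8 | per-step velocity retention | ≈ critical for unit stiffness; free poses settle in a few hundred steps |
| `response_gain` | 10 | force/contact | dominates unit-scale pulls even with one contact |
| `max_speed` | 0.5 | Å/time and rad/time | bounds per-step motion to 0.05 Å: penalty forces scale with contact count, and an uncapped impulse ejects barely-touching objects; the cap also bounds tunnelling depth per step |
| `penetration_tolerance` | 0.1 | Å | acceptable residual overlap |
| `convergence_tol` | $10^{-4}$ | wrench norm | position error $10^{-4}$ Å at unit stiffness |
| `max_iterations` | 2000 | steps | in sustained contact the wrench cannot vanish; the cap is the intended stop there |

Penetration is reported as the largest distance a contact-triangle vertex
sits behind the opposing contact plane — an inexpensive diagnostic, not an
exact minimum translation distance. Whether the original interactive
system applied contact torque as well as force is not documented; both are
applied here, which is the package's own choice.

## Spring connectors and layout

A connector ties local attachment points on two objects. In *visual* mode
it only records that the objects are linked (e.g. a disordered linker with
no solved structure). In *force* mode it is a Hookean spring with rest
length $L_0$: with $d$ the vector between world attachment points, the
wrench on each endpoint is $\pm k\,(\lVert d\rVert - L_0)\,\hat d$ plus the
attachment-offset torque. Rest lengths encode experimentally known
separations (FRET, two-color localization), so relaxing the network
(`relax_layout`) drives the scene toward layouts consistent with the data:
all spring-connected objects integrate under spring wrenches plus collision
response until the net per-object wrench vanishes. Infeasible networks do
not error — they settle at force balance (two contradictory springs of
equal stiffness between the same pair settle at the mean of their rest
lengths) and the per-connector residuals $|\lVert d\rVert - L_0|$ report
the tension. Tie-break: coincident endpoints with $L_0 > 0$ have no
defined direction, so a fixed $+x$ direction seeds the separation.
Terminus snapping (`snap_to_terminus`) sets an attachment to a chain's
first or last α-carbon in record order, the operational definition of the
N/C terminus here. "Fixed-length" links are high-stiffness springs
(multiply `stiffness`), keeping a single solver.

## Meshes, surfaces and bounding boxes

Fixture surfaces (`make_fixture`) are subdivided icospheres, scaled
ellipsoids, or *blobs* — ellipsoids with a smooth seeded radial
perturbation (a few cosine-power bumps, ±12 % radius by default) that mimic
the lumpiness of a real molecular surface while keeping volume within a
predictable band of the generating ellipsoid. They are deterministic per
seed and leave the caller's RNG stream untouched. What they do *not*
emulate: real solvent-excluded topography (pockets, tunnels), mesh
irregularity from surface tessellators, or any flexibility — every test
conclusion is about rigid-body geometry, not conformational realism.

`surface_from_atoms` stands in for a true solvent-excluded (Connolly)
surface with a Gaussian-density isosurface: the field
$\sum_i \exp\!\big(-(\lVert p - c_i\rVert^2 - (r_i + p_\text{probe})^2)/\sigma^2\big)$
is sampled on a regular grid (default spacing 0.5 Å, probe 1.4 Å, blending
σ = 1 Å) and the level-1 surface is extracted by marching *tetrahedra*
(each cell split into six tetrahedra sharing a main diagonal, so faces
match across cells and the mesh is watertight by construction — every edge
is shared by exactly two triangles, asserted in the suite). A single atom
yields a sphere at $r_\text{vdW} + p_\text{probe}$ to within the grid
interpolation error; overlapping atoms blend into one component. This is a
shape proxy adequate for layout and collision work, not for surface-area
chemistry.

Oriented bounding boxes use the eigenvectors of the vertex covariance —
the standard interactive-graphics OBB, deterministic and cheap, not the
minimum-volume box. One honest caveat: under tied eigenvalues (a sphere, a
cube) the principal axes are mathematically arbitrary, so the box of a
rotated cube is *not* the rotated box of the cube; orientation recovery is
only guaranteed for meshes with a simple covariance spectrum, and the
tests use distinct-extent boxes accordingly.

## Animation

Keyframes store pose, color, group membership and visibility at a time
point, at most one per object per time. Positions between keyframes follow
a Catmull–Rom spline in the time domain (cubic Hermite with
finite-difference tangents, one-sided at the ends): the curve passes
through every keyframe at its keyframe time, which the timeline-scrub
behaviour requires, and two keyframes degenerate to exact linear
interpolation. A centripetal chord-length parameterization was considered
and rejected because it decouples curve parameter from time and would need
an arc-length inversion to sample by time. Orientations interpolate by
piecewise shortest-arc quaternion slerp (samples stay orthonormal to
$10^{-9}$); colors linearly; group membership and visibility switch
stepwise, holding the latest keyframe at or before the sample time.
`export_frames` samples $\lfloor (t_1 - t_0)\,\text{fps} \rfloor + 1$
frames at $t_0 + k/\text{fps}$ into neutral per-frame records (JSON-lines
with row-major 4×4 matrices), the hand-off point to any renderer.

## Scenes, persistence and the command line

A scene is a table of rigid mesh instances (pose, color, group) plus
groups, chain records, connectors, a timeline and physics parameters,
persisted as human-diffable JSON with 4×4 row-major poses. Meshes are
stored by provenance (fixture spec or OBJ path), never inlined; loading
rebuilds them bit-identically. Unknown keys and dangling id references
fail loudly by name. Copy/paste (`duplicate`) and group export/import give
fresh ids throughout — collisions are resolved by remapping, never
overwriting. The `inst/cli/molassembly.R` script exposes the same
functions as subcommands (`fixture`, `build-chain`, `collide-check`,
`place`, `relax`, `animate-export`, `info`).

## Problem sizes and limitations

The randomized suites use scenes of 4–10 objects with fixture meshes of
20–320 triangles, 50–100 seeds per property, chains up to $n = 50$, and
physics runs capped at 2000 steps — sizes at which the exhaustive
triangle-pair oracle remains a practical ground truth while still
exercising every code path; the guarantees tested (exact oracle equality,
test-count bounds, the chain law) are size-independent statements.

Known limitations: rigid bodies only (no flexibility, no dynamics with
momentum transfer between objects); penalty contact resolves overlap to a
tolerance rather than exactly; the Gaussian isosurface is not a true
solvent-excluded surface; covariance OBBs degrade under tied spectra; and
orientation splines are piecewise slerp, continuous but not
tangent-smooth across interior keyframes.
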