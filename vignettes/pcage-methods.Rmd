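---
title: "Characterizing near-miss polyhedral cages: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing near-miss polyhedral cages: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcage)
```

## The problem

A polyhedral cage (p-cage) is an assembly of planar polygonal faces
separated by holes: every face edge is either shared with exactly one other
face or borders a hole, two faces share at most one edge, and each face has
at least three neighbours.  The motivating objects are engineered protein
cages — most prominently the TRAP-cage, built from 24 nearly regular
hendecagons, each sharing an edge with five neighbours and leaving 38 holes
(32 triangular, six octagonal).  A perfectly regular cage with that
connectivity is geometrically impossible, but it exists as a *near-miss*:
every edge length and corner angle is within a small tolerance of the
regular polygon's.  This package characterizes all homogeneous (equal face
edge count P) *connectivity-invariant* near-miss p-cages with deformations
below 10% for P between 6 and 17.

## Hole-polyhedra and the combinatorial model

Joining the centres of adjacent faces produces the *hole-polyhedron*: its
vertices are the p-cage faces, its edges the shared edges, its faces the
holes.  Connectivity invariance (any face can be mapped to any other by a
graph automorphism preserving shared versus hole edges) forces the
hole-polyhedron to be a vertex-transitive convex polyhedron.  When
reflections are excluded — mirror-image assembly paths are not equivalent
for chiral protein building blocks — the eligible solids are the prisms and
antiprisms, the Platonic solids, and 11 of the 13 Archimedean solids (the
truncated cuboctahedron and truncated icosidodecahedron are only
vertex-transitive through reflections and are excluded).  `build_solid()`
constructs the 31 supported solids as oriented combinatorial polyhedra:
faces are stored anticlockwise seen from outside, and each vertex stores the
anticlockwise cyclic order of its incident faces (its *corners*).

Two conventions deserve mention.  The square prism is represented once, as
the cube with its full rotation group of order 24.  The triangular antiprism
`ta` is combinatorially an octahedron, but it is kept as a separate entry
with the antiprism's dihedral rotation group (order 6), mirroring the
catalog convention of listing both; cages generated from `ta` and from `Poc`
can therefore coincide geometrically.

Automorphisms are computed on the rotation system (the directed-edge
structure): an automorphism is determined by the image of one directed edge,
propagated through the next-in-face and reverse operators; propagating
through the reversed cycle instead yields the orientation-reversing
elements, which are flagged and used only for chiral deduplication.

## Enumerating hole-edge distributions

A face with P edges at a vertex of degree Eh contributes one shared edge per
incident solid edge and distributes the remaining `P - Eh` edges between the
surrounding holes: positive corner labels `a_i` with `Eh + sum(a_i) = P`.
The distribution is connectivity-invariant exactly when the subgroup of
rotations preserving every label is still transitive on vertices.  Because
such a labeling is constant on the corner orbits of its stabilizer, the
enumeration loops over the vertex-transitive subgroups of the rotation group
(the full subgroup lattice is computed once per solid and cached), assigns
values to corner orbits through compositions at a base vertex, and merges
duplicates.  One representative is kept per rotation orbit, and
`dedup_chiral()` removes one member of each mirror pair — labelings on the
chiral snub solids have no mirror partners and are never merged.

Names follow the catalog convention `SYM_P<p>_<a>_<b>_...`: labels are read
anticlockwise around a vertex starting on the base polygon for prisms and
antiprisms, on the smallest face for Archimedean solids (square and pentagon
for the two snubs), and on any face for Platonic solids, taking the smallest
admissible reading.  The octahedron's two diagram families are
distinguished as `Poc1` (two opposite all-`a` faces) and `Poc2` (labels
constant per face and properly two-coloured), with the `Poc1` reading
anchored on its invariant opposite face pair.  Where two structurally
distinct labelings still read identically (this happens on the icosahedron,
whose five label roles admit cyclic shifts that no rotation realizes), a
deterministic letter suffix keeps the names unique.

## Pruning constraints

Before any geometry is built, each hole is tested with two necessary
conditions derived from flattening the *sub-face hole*, the chordal Q-gon
that closes each face's run of hole edges (`hole_spec()`):

* the projected angle-sum bound
  `P <= (2 * sum(q_i + 1)/(Q - 2)) * (1 + kappa_t * (P - 2)/2)`
  (`angle_constraint_ok()`), which at `kappa_t = 0` and unit contributions
  reduces to `P <= 4Q/(Q - 2)`;
* the polygon inequality on the chord lengths,
  `A_j <= (1 + kappa_t)/(1 - kappa_t) * sum_{i != j} A_i`, with the
  left-hand chord evaluated at the uniform deformation factor
  `K = 1/(1 + kappa_t)` and the right-hand chords at `K = 1 + kappa_t`
  (`length_constraint_ok()`), tested for every choice of j.

The threshold deformation `kappa_t = 0.1` expresses the 10% near-miss
tolerance.  `prune_configuration()` applies both tests to every hole;
`use_angle = FALSE` restricts the filter to the chord inequality.  Under the
default (both constraints, chiral deduplication, `ta` and `Poc` both
listed), the P = 6..17 sweep leaves 5301 candidate configurations; with the
chord inequality alone it leaves 7404.  The corresponding catalog published
for this family quotes 5743, a value between the two readings that we could
not reproduce exactly under any defensible combination of the conventions
(we audited the deformation direction of K, the relaxation prefactor, the
`ta` duplication, orbit-weighted counting, and chiral handling); the
package's pipeline keeps the two-constraint reading, which is what its own
optimizer consumes.

## Geometry, functional, and metrics

`build_topology()` realizes a labeling as an incidence structure: one P-gon
per solid vertex, whose anticlockwise edge sequence alternates a shared edge
per incident solid edge with `a_i` hole edges on the intervening hole.
Shared-edge node copies are identified (two faces traverse a shared edge in
opposite directions), giving `NN = N*P - 2*E` nodes, and the free edges
trace one boundary cycle per solid face — the holes, whose lengths equal the
sums of the labels around the dual face.

`initial_embedding()` places each face as a regular unit-edge P-gon on its
solid vertex at a radius chosen so neighbouring faces nearly touch, rotated
so shared edges point at the neighbours, then relaxes a mechanical model of
semi-rigid faces joined by zero-rest-length springs at the shared-node
copies: rigid Kabsch fits of each regular face to the running node-class
means, iterated to stagnation, after which the copies are merged by
averaging (the faces pick up their first slight deformation here).

The quality functional (`total_q()`) is the weighted sum of five
non-negative terms computed in C++: squared relative edge-length deviations
from `L_f = 1`; squared corner-angle deviations from `pi(1 - 2/P)` radians
(the iso-weight calibration of these two is the first-order identity
`(dl/l)^2 = (dtheta)^2` for a stretched isoceles right triangle, verified
numerically in the test suite); the squared out-of-plane components of the
facelet normals; and Heaviside counts of face-convexity and cage-convexity
violations.  The printed positivity conditions for the two convexity counts
are implemented as violation counts (`H(-x)`), which is the orientation
consistent with minimization, and the boundary is not penalized (`H(0) =
0`, with a 1e-12 guard against floating-point ties).  The cage-convexity
term has two variants: the edge-midpoint condition (default) and the
normal-tip distance condition, selectable per run for cages that prefer
concave configurations.  Default weights are `c_l = c_a = 1`,
`c_p = 1000`, `c_cf = c_cp = 100`.

The reported metrics are `delta_l` (largest absolute edge-length deviation),
`delta_a` (largest relative angle deviation), and the pairwise face
dissimilarities `omega_l`, `omega_a`, minimized over cyclic relabelings
(shifts 1..P-1) and maximized over face pairs.  Faces are never constrained
to be congruent; for most optimized cages `omega > 0`.

## Optimization protocol

`optimize_cage()` treats every node coordinate as a free parameter:

1. simulated-annealing Metropolis over all nodes (geometric cooling from
   `temp0 = 0.05`, per-node Gaussian proposals with the step adapted towards
   30% acceptance), reproducible through the R RNG;
2. a sweep of 100 weight points with `c_l + c_a = 2`, the ratio log-spaced
   over `[1e-2, 1e2]`.  The sweep walks outward from the balanced point in
   both directions with warm starts; at the balanced point the pipeline also
   restarts from the raw embedding, because an aggressive annealing phase
   occasionally trades the best basin away.  Each point is deepened by a
   short Barzilai-Borwein descent and an L-BFGS stage;
3. golden-section refinement of the weight ratio around the sweep's best
   point, selecting the cage minimizing `max(delta_l, delta_a)`;
4. a final polish: L-BFGS, a coordinate pattern search (which can hop the
   tiny non-smooth steps the Heaviside terms introduce), L-BFGS again, and a
   Nelder-Mead simplex step.

The descent stages use a central-difference numerical gradient (step 1e-6)
evaluated in C++; the functional is smooth wherever the convexity counts are
locally zero, which is the case in the basins that matter.  This goes
beyond a purely derivative-free protocol, and is the package's main
numerical liberty: without it the snub-cube P = 11 cage stalls near 0.7%
deformation, whereas the full stack reaches 0.496% reproducibly across
seeds (the published figure for that geometry is 0.5%), and regular cages
relax to residuals near 3e-7, comfortably under the 1e-5 classification
threshold.

Classification: `regular` when `max(delta_l, delta_a) <= 1e-5` (one order
of slack above the observed 1e-6..1e-7 residuals, to absorb platform
variation), `near-miss` up to 0.1, `rejected` above; `degenerate`
(`detect_degenerate()`: two non-adjacent hole-boundary nodes within 0.05
edge lengths — a pinched hole, e.g. `tp_P8_1_1_3` collapsing onto the
octahedral `Poc1_P8_1_1_1_1` cage) and `self-intersecting` override.
Self-intersection (`cage_self_intersects()`) tests all facelet pairs from
different faces with a Möller triangle-triangle test (plane-side epsilon
1e-9), skipping pairs that share a cage node: contact along shared edges
and at hole corners is structural.

## The fixture generator

`make_fixture()` supplies the test geometries: the exact regular cage of 12
unit-edge decagons on the icosahedral hole-polyhedron (decagons inscribed in
dodecahedron face planes — all five functional terms vanish there);
Gaussian-noise perturbations of it with stated sigma; a pinched-hole cage;
and a self-intersecting cage.  These emulate the local structure the
optimizer sees — near-regular faces, spring-closed shared edges — but not
everything about real candidates: they are highly symmetric, their holes are
small, and no fixture exhibits the ring-like prism geometries where
self-intersection actually arises in the catalog, so passing the fixture
tests shows correctness of the functional and detectors, not optimizer
coverage of all 5301 candidates.

## Problem sizes and costs

The full catalog (about 5.3 thousand stochastic optimizations) is far
beyond a desk-scale run; the package's own validation uses the complete
sweep for P = 6 and P = 7 plus a panel of individually named cages, with
the full-depth configuration reserved for the snub-cube and icosahedral
worked examples.  A single Asc_P11 optimization takes a few seconds at the
default configuration; enumeration plus pruning of all 31 solids for
P = 6..17 takes on the order of a minute.

## Known limitations

* The candidate count depends on conventions the source catalog leaves
  open (see the pruning section); the package documents its reading rather
  than matching the published total exactly.
* Global optimality is not guaranteed: the sweep plus multi-start descent
  consistently reproduces the known reference geometries, but a cage
  classified `rejected` could in principle own an undiscovered better
  basin.
* The `ta`/`Poc` double listing can produce geometrically coincident cages
  under different names, as in the source catalog.
* Hull convexity is enforced only through the pairwise local conditions,
  not by computing the hull.
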