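# pcage

Enumeration and geometric optimization of near-miss polyhedral cages
(p-cages) in R.

A p-cage is an assembly of planar polygonal faces separated by holes: every
face edge is shared with exactly one other face or borders a hole.  The
engineered TRAP protein cage — 24 nearly regular 11-gons, each sharing an
edge with five neighbours around 38 holes — is the motivating example: a
perfectly regular cage with that connectivity is impossible, but a
*near-miss* version exists in which all edge lengths and angles deviate from
the regular polygon by well under 1%.  `pcage` characterizes all homogeneous
*connectivity-invariant* p-cages (all faces with the same edge count P,
every face equivalent to every other under a rotation of the assembly) for
P = 6–17, the family relevant to protein-cage design.

The pipeline:

1. **Hole-polyhedra** (`build_solid()`): the dual solids whose vertices
   carry the cage faces — prisms, antiprisms, Platonic, and 11 Archimedean
   solids — as oriented combinatorial polyhedra with their rotation groups
   (`rotation_group()`, computed on the directed-edge rotation system).
2. **Hole-edge distributions** (`enumerate_distributions()`): all
   connectivity-invariant assignments of corner labels `a_i >= 1` with
   `Eh + sum(a_i) = P` at every vertex, enumerated through the
   vertex-transitive subgroups of the rotation group, with mirror pairs
   removed by `dedup_chiral()`.
3. **Pruning** (`prune_configuration()`): two necessary conditions per hole
   at threshold deformation `kappa_t = 0.1` — a projected angle-sum bound
   and a polygon inequality on the chord lengths of each face's hole-edge
   run.
4. **Realization** (`optimize_cage()`): embed each candidate (semi-rigid
   spring relaxation), then minimize the face-deformation functional
   `Q = c_l Q_length + c_a Q_angle + c_p Q_planar + c_cf Q_ConvFace + c_cp
   Q_ConvPol` over all node positions (Metropolis annealing, a 100-point
   sweep of `c_l/c_a` with `c_l + c_a = 2`, golden-section refinement, and
   deterministic descent polish), and classify by the maximum deformations
   `delta_l = max|l - 1|` and `delta_a = max|alpha - alpha_0|/alpha_0`:
   **regular** (≤ 1e-5), **near-miss** (≤ 0.1), **rejected**, with
   **degenerate** (pinched holes) and **self-intersecting** (Möller
   triangle test) overrides.

Results come back as tibbles; fitted cages have `tidy()`/`glance()`
methods and `autoplot()` displays, and geometries export to OFF/OBJ.

## Worked example: the TRAP-cage geometry

```r
library(pcage)

e <- dedup_chiral(enumerate_distributions("Asc", 11))
lab <- e[e$name == "Asc_P11_2_1_1_1_1", ]   # snub cube, square face gives 2
topo <- build_topology(lab)
topo
#> <pcage_topology> Asc_P11_2_1_1_1_1: N=24 faces of P=11 edges, NN=144 nodes,
#>   38 holes (3-edge x32, 8-edge x6)

oc <- optimize_cage(lab, pcage_config(seed = 1))
oc
#> <pcage_optimized> Asc_P11_2_1_1_1_1: near-miss (delta_l=0.00496,
#>   delta_a=0.00496, c_l=0.99)
```

The 24 hendecagons close into the snub-cube connectivity with every edge
and angle within 0.496% of the regular 11-gon — the p-cage is a near-miss,
visually indistinguishable from a regular assembly.  A known regular cage
relaxes to numerical residuals instead:

```r
e <- enumerate_distributions("Pic", 10)
oc <- optimize_cage(e[1, ], pcage_config(seed = 5))
#> <pcage_optimized> Pic_P10_1_1_1_1_1: regular (delta_l=2.99e-07, ...)
```

See `vignette("pcage-methods")` for the model, the constraints, the
functional, and every tunable parameter.

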