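---
title: "Building curvature-organized coarse-grained membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building curvature-organized coarse-grained membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membuildr)
```

## The problem and the model

A coarse-grained membrane simulation needs an overlap-free starting
structure whose *lateral* organization is plausible: lipids such as
cardiolipin accumulate in negatively curved regions of organelle
membranes, proteins cluster at characteristic curvatures, and letting a
randomly mixed membrane sort itself costs orders of magnitude more compute
than building it sorted. `membuildr` separates that problem into three
stages — geometry, organization, instantiation — connected by a single
intermediate object, the *point folder*: two per-leaflet tables of surface
elements, each with position, area, unit normal, principal curvatures
`c1 >= c2` and directions, a domain tag, and an open-edge flag.

The sign convention is fixed throughout: normals point outward, and a
sphere of radius R seen from outside has `c1 = c2 = +1/R`; mean curvature
is `H = (c1 + c2)/2`, and the lipid-preference scale is `2H` (so a lipid's
intrinsic curvature preference `C0` is its preferred value of `2H`, in
nm⁻¹). All lengths are nm, areas nm², curvatures nm⁻¹.

## Geometry: orientation, curvature, leaflet offsetting

**Orientation and cutting.** Triangle windings are made globally
consistent by breadth-first propagation over shared edges (non-manifold
edges are refused). On a nonorientable surface some adjacency must
conflict; the conflicting edges found by the (deterministic, sorted-order)
traversal form a cut seam whose vertices are duplicated, turning e.g. a
Möbius strip into an orientable open band — its rim and seam vertices are
then ordinary open edges, available for edge-specific lipid placement via
`edge_domain()`. Closed meshes are finally oriented outward (signed
volume ≥ 0).

**Curvature estimation.** Per vertex, the neighbor ring (1-ring, escalated
to the 2-ring below 5 neighbors, which keeps open-edge vertices usable) is
expressed in the local tangent frame and a quadratic height function
`h(u,v) = (a u² + 2b uv + c v²)/2` is least-squares fitted; the shape
operator `-[[a,b],[b,c]]` yields principal curvatures and directions. A
quadric fit was chosen over cotangent-Laplacian mean curvature because the
builder needs full principal *directions* (for lipid frames and protein
azimuths) and a one-sided estimate that degrades gracefully at open
edges; rank-deficient fits fall back to zero curvature with a flag. On
analytic fixtures (sphere, cylinder, sine sheet) the median curvature
error is below 5% at the test resolutions, and the estimate is invariant
under rigid motion and scales as 1/s under scaling by s — both are tested
properties. Vertex areas use the barycentric (one-third) rule, which
conserves total area exactly and is robust to obtuse triangles.

**Leaflet offsetting.** Each mid-surface element is moved `±t/2` along its
normal (default bilayer thickness `t = 3.8` nm, a typical coarse-grained
bilayer). Offsetting a curved surface changes areas and curvatures; the
parallel-surface transforms `c' = c/(1 + s c)` and
`A' = A (1 + s c1)(1 + s c2)` are applied so that, e.g., a vesicle of
radius 10 nm gets an outer leaflet with the area of a sphere of radius
11.9 nm — otherwise the outer leaflet would be under-packed and the inner
over-packed relative to the area per lipid. (Whether to transform or copy
mid-surface values was a genuinely open choice; the transform is validated
against the concentric-sphere closed form in the tests and is isolated in
one internal function.) Inner-leaflet curvatures are negated after the
transform because that leaflet is seen from the flipped normal; the
condition `1 + s c > 0` is checked and a violation (bilayer thicker than
the curvature radius) is a hard error naming the vertex.

## Organization: quotas, Boltzmann weights, domains

`dop_assign()` draws one lipid type per point from

\[ P(l) \propto \exp(-k_l\,(2H - C_{0,l})^2), \]

restricted and renormalized over the types that still have quota. Two
design choices deserve explanation:

* **Largest-remainder quotas, ties by spec order.** The requested
  fractions are converted to integer per-leaflet quotas before any draw,
  so the realized composition is *exact* for every seed — a property the
  acceptance tests assert over 50 seeds. The alternative
  (resample-on-exhaust) makes late points' distributions depend on the
  visit order in a biased way.
* **Log-space weights.** The per-point normalization is invariant under
  shifting all log-weights, so weights are computed as
  `exp(logw - max(logw))`. At extreme `k` naive weights underflow to zero
  for *all* types, which would silently degrade the draw to uniform; the
  shift keeps exact ratios at any `k`. A consequence worth knowing: with a
  `C0` far outside the attainable `2H` range and very large `k`, the
  biased type is almost never *chosen* while the unbiased type has quota,
  so its quota is eventually forced onto randomly-ordered leftover points
  — extreme sharpness with an unattainable preference degrades toward
  uniformity rather than a step. At the moderate sharpness of practical
  interest (`k ≈ 1–250`) enrichment is monotone in `H`, which is the
  tested property.

Points are visited in seeded random order to avoid systematic bias; the
same seed reproduces the assignment bit-for-bit.

`dai_euclidean()` assigns circular domains by straight-line distance —
fast, but on folded or stacked membranes the ball can intersect
geometrically close yet geodesically distant membrane; `dai_geodesic()`
runs multi-source Dijkstra (via `igraph`) over the point adjacency
inherited from the mesh (or the analytical grid), with edges weighted by
Euclidean length, and never leaks across membranes. The geodesic set is
always a subset of the Euclidean set at equal radius (graph distance ≥
chord distance); on a 4-neighbor grid the graph metric is L1, so matching
the Euclidean disc requires inflating the radius by up to √2 — the tests
encode exactly that lattice factor. Repeated domain assignments
overwrite: the last execution wins on overlaps. `inu_place()` uses the
same Boltzmann weight as a softmax *across points* for protein positions,
with draws without replacement and a Euclidean collision radius;
exhausting the candidates is an error that reports how many copies were
placed. Pores (`make_pore()`) record an exclusion and flag points within
the radius — geodesic when adjacency is available, Euclidean otherwise.

## Instantiation: templates, proteins, solvent, files

Lipid templates (LIB dialect: `[ NAME ]` header, `bead <name> <x> <y> <z>`
lines; head bead first, at maximal z) are rotated so local +z maps to the
point normal, given a seeded random azimuth (avoiding crystalline
artifacts), and anchored head-at-point with tails toward the mid-surface.
One lipid per point is a deliberate contract: packing density is
controlled by mesh resolution / `apl_hint`, not by the placer, and
`place_lipids()` warns when a point's area deviates >20% from a declared
APL. `libmaker()` builds a template from a single-residue GRO by centroid
translation and principal-axis alignment (head sign chosen so the first
bead has z ≥ 0).

Proteins are placed with geometric center at the inclusion's mid-surface
position plus `z_offset` along the local normal — `z_offset = 0` centers
the protein in the membrane — with +z aligned to the normal and azimuth
from the inclusion orientation; no post-placement relaxation is performed,
so a pre-oriented structure file is the user's responsibility. Lipids
whose anchor lies within the collision radius of the inclusion axis
(distance projected onto the tangent plane) are removed; the projected
radius is this package's convention for the clearance rule.

`write_gro()` pins the GROMACS fixed-width dialect (3-decimal nm,
round-half-even, atom/residue numbers modulo 100 000, no velocities);
`write_top()` derives `[ molecules ]` by run-length encoding of residue
instances in bead order, which is exactly the GROMACS contract.
`solvate_box()` tiles an equilibrated water template, deletes solvent
within a cutoff of any solute bead using a periodic cell list (the tests
audit it against a brute-force O(N²) oracle), and substitutes ions for
randomly chosen waters one-for-one. Wall beads — virtual beads on every
stride-th mid-surface point plus an index group and a position-restraint
stanza — let an analytical shape be held in place during simulation.

## Synthetic fixtures and what the tests do (and do not) show

`make_mesh()` generates the icosphere, cylinder-with-caps, torus, Möbius
band, sine sheet and flat grid; `make_toy_structures()` writes a toy
four-lipid library (POPC/CDL/CHOL/DLPC-like bead *geometries*, not force
fields), a rigid 50-bead protein rod and a 3 nm cube of 216 single-bead
waters (8 beads/nm³). These shapes have known analytic curvature, which
is what makes them oracles; they emulate the *geometry* of real inputs.
They do not emulate chemical detail: passing tests demonstrate correct
construction (composition exactness, frames, clearances, formats), not
that any particular force field will find the structure near equilibrium.
Problem sizes in the default test run are kept at a few hundred to a few
thousand points per fixture — the package's intended desk-scale regime;
behaviour at those sizes is what the suite certifies.

## Numerical choices and limitations

* Internal indices are 1-based (R); every on-disk dialect (.tsi, point
  folder, Edges.dat) is 0-based. Ids never mix: conversion happens at
  read/write only.
* Curvature quintile/χ² uniformity, sign tests and monotonicity checks run
  at fixed seeds; they certify the implementation, not fresh randomness.
* Vesicle folders use a Fibonacci sphere (uniform-area, deterministic) and
  carry no adjacency, so geodesic operations on them require a meshed
  sphere instead.
* The Euclidean DAI artifact on stacked membranes is intentional,
  documented behaviour (and the reason the geodesic variant exists).
* Analytical flat/sine/cylinder membranes are periodic in-plane and have
  no open edges; nanodisc-style rims come from meshed open sheets.
* No energy minimization, relaxation, force-field parameters or velocity
  generation: the output is an *initial structure* that must be minimized
  and equilibrated by the simulation engine.
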