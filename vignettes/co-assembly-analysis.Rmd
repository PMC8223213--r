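---
title: "Quantifying peptide–drug co-assembly in MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying peptide–drug co-assembly in MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggtraj)
```

## The problem

Cationic antimicrobial peptides such as CM15 (+6 net charge) and polyanionic
drugs such as suramin (−6) form electrostatically driven co-assemblies in
solution, and the presence and composition of a lipid bilayer can either
promote or completely suppress that aggregation. Coarse-grained molecular
dynamics can follow tens of such molecules for microseconds, but the raw
trajectory is just coordinates: deciding what counts as an aggregate, how a
given aggregate grew, and whether molecules are membrane-bound requires a
defined, reproducible computation. `aggtraj` implements that computation as
a tested package:

1. **Aggregate identification.** In every frame the centers of mass (COMs)
   of the solute molecules are clustered with DBSCAN using Euclidean
   (optionally minimum-image) distances, a neighborhood radius
   $\varepsilon$ = 1.5 nm and a minimum neighborhood size of 2. Each
   cluster is an aggregate; unclustered molecules are free.
2. **Lineage backtracking.** The biggest aggregate of the last frame is
   selected, and for each earlier frame the aggregate sharing the most
   molecules is taken as its predecessor. The membership difference per
   step — molecules gained and lost, broken down by species — is the
   growth/shrink record of that aggregate.
3. **Membrane-relative observables.** Lipids are assigned to leaflets by
   the z position of their phosphorus reference particle; the *surface
   distance* of a molecule is
   $\min(|z_\mathrm{COM} - z_\mathrm{top\,P}|,\;
         |z_\mathrm{COM} - z_\mathrm{bot\,P}|)$,
   using the instantaneous per-frame leaflet phosphorus z-COMs. Contact
   counts, the complex ratio and the average aggregation number complete
   the per-frame metric series.

## The clustering model and its conventions

DBSCAN with `min_points = 2` and a *self-inclusive* neighborhood count is
exactly the connected components of the graph joining COMs within
$\varepsilon$: every clustered point has at least one neighbor, so every
clustered point is a core point and the notorious border-point ambiguity of
DBSCAN vanishes. This makes the partition deterministic, order-independent
and cheaply verifiable against an independent union-find/graph oracle —
which the test suite does on hundreds of random instances. The alternative
convention (the point does not count toward `min_points`) and general
`min_points > 2` are implemented behind flags; for the general case border
points join the cluster of their *nearest* core neighbor, distance ties
resolved toward the lower canonical aggregate, again for bit-reproducibility.

Aggregates are canonicalized by (size descending, smallest member id), so
identical inputs in any order produce identical outputs, and the focal/
predecessor tie-breaks of the lineage step (largest aggregate, then
smallest minimum molecule id; largest overlap, then larger candidate, then
smallest minimum id) are fully specified for the same reason.

Distances default to the minimum-image convention, which is the physically
correct metric in a periodic box; `pbc_mode = "none"` restores naive
Euclidean distances for replication of analyses that ignored periodicity.
$\varepsilon$ is configured in nm internally (1.5 nm = 15 Å); the CLI
accepts either unit with an explicit suffix.

## Parameters that matter

| parameter | default | unit | meaning |
|---|---|---|---|
| `epsilon` | 1.5 | nm | DBSCAN neighborhood radius over molecular COMs |
| `min_points` | 2 | count | minimum (self-inclusive) neighborhood size |
| `pbc_mode` | minimum-image | — | distance convention in the periodic box |
| `cutoff` | 0.6 | nm | any-particle-to-any-lipid-particle contact criterion |
| `weighting` | geometric | — | COM weighting (mass-weighted for all-atom input) |
| `agg_num_convention` | in-aggregates | — | numerator of the average aggregation number |
| `stride` | 1 | frames | subsampling of the analyzed trajectory |

Two of these deserve comment because the underlying definitions are
genuinely open:

* **Contact cutoff.** No published criterion accompanies bilayer contact
  counts of this kind; 0.6 nm is a common heavy-atom/coarse-grained contact
  range. Conclusions should be checked for cutoff sensitivity; the value is
  configuration, not physics.
* **Average aggregation number.** "Total number of molecules divided by the
  number of aggregates" is ambiguous about whether free molecules belong in
  the numerator. The default divides the number of molecules *in
  aggregates* by the number of aggregates (which yields values like 34–35
  when two large aggregates coexist with a few monomers); `"all"` divides
  the full solute count. Both are computed from the same partition; neither
  is asserted to be the original authors' choice.

Similarly open: whether COMs should be mass-weighted. For coarse-grained
beads masses are near-uniform, so the default is geometric; mass weighting
is available and recorded in the echoed configuration.

## Centers of mass under periodic boundaries

A molecule whose particles straddle the box boundary must be made whole
before averaging: every particle is unwrapped by minimum image relative to
the molecule's first particle, the (weighted) mean is taken, and the result
is wrapped back into the primary box. A molecule whose unwrapped extent
exceeds half the box in any dimension is rejected as ambiguous rather than
silently mis-wrapped — the same philosophy applies to triclinic boxes,
which the readers refuse outright (all supported systems are rectangular).

## The synthetic world

The reference microsecond trajectories behind the published observables are
not deposited, so the package ships a generator that *plants* the
structure the analyzer is supposed to find. It is a stated world, not a
simulation:

* Cluster membership follows an explicit event schedule (merge, split,
  dissolve, bind, release); nothing is kinetic.
* Cluster centers perform a bounded random walk constrained to stay ≥ 6 nm
  apart (4ε) and members are placed within a 0.3 nm jitter radius (≤ ε/4)
  of their center, so any two members of a cluster are within 0.6 nm ≤ ε
  of each other and any two molecules of different clusters are ≥ 5.4 nm
  > ε apart: the planted partition is recovered *exactly* by the default
  clustering, which is what makes acceptance checks exact rather than
  approximate.
* Free molecules keep ≥ 6 nm from cluster centers and ≥ 2ε from each
  other, so they are always noise.
* The optional membrane is two flat z-planes of single-particle lipids
  carrying the phosphorus-reference role, with small in-plane jitter.
  Bound molecules sit 0.3 nm above a thinned grid of lipid sites (grid
  spacing 2 nm > ε), inside the 0.6 nm contact cutoff but too far apart to
  cluster with each other.
* One seeded RNG stream (Mersenne–Twister, fixed normal/sample kinds)
  drives every draw; the seed is recorded in the fixture header, and all
  coordinates are rounded to the 10⁻⁶ nm grid of the native text format so
  that write-then-load is the identity.

The default system size is 36 + 36 molecules of two species, matching the
studied co-assembly system; frame spacing is 10 ns as in the original
1000-frame analyses, but the preset trajectories are 50–100 frames long so
the whole suite runs in seconds. Three presets script the three
qualitative regimes observed in different environments: complete
aggregation in water (ending in a single 72-molecule aggregate), membrane
saturation (an early 2:2 complex dissolves and all 36 peptides end bound,
none aggregated — the charged-bilayer regime), and an intermediate regime
where aggregates and membrane contacts coexist (the zwitterionic-bilayer
regime).

What a green test therefore establishes: the analyzer recovers planted
partitions exactly, reconstructs scripted growth histories exactly, and
reports the scripted end states of the three regimes. What it does *not*
establish: anything about force fields, kinetics, aggregate shapes, or the
numerical values that real MD trajectories would produce. The generator
has no physics; the published headline numbers (e.g. average aggregation
numbers of 34–35 in water) are not reproducible without the original
trajectories and are not asserted anywhere in the suite.

## Numerical choices and degenerate inputs

* Distance comparisons use `<=` at the threshold; ties at exactly
  $\varepsilon$ join.
* A lipid exactly at the bilayer midplane z-COM goes to the **top**
  leaflet (documented tie-break).
* `average_aggregation_number` of a frame with no aggregates is defined as
  0 (the quantity is otherwise undefined; the time series stays total).
* Population (divide-by-N) standard deviations for k-closest distance
  tables, switchable to sample convention.
* The lineage of an aggregate that has zero overlap with every aggregate
  of the previous frame records a *nucleation* boundary (empty reference
  set) and continues backward with the empty set; how the original
  analysis handled this case is not stated anywhere, and the choice is
  flagged as this package's own.
* CSV floats are written as the shortest decimal string that reparses to
  the identical double: full precision and byte-stable reruns at once.

## Worked example

```{r demo}
fixture <- file.path(tempdir(), "demo.traj")
simulate_fixture("demo", fixture, seed = 1)
out <- file.path(tempdir(), "demo-out")
res <- analyze_trajectory(fixture, out_dir = out)
res$metrics[c(1, 4, 5, 12), c("frame", "time_ns", "n_aggregates",
                              "avg_aggregation_number", "complex_ratio")]
cat(res$summary, sep = "\n")
```

The demo scenario plants two 2:2 aggregates that merge at frame 5; the
analysis recovers exactly that: two aggregates of four molecules each
(aggregation number 4, complex ratio 1) until frame 4, one aggregate of
eight afterwards, and a single +4 growth event at frame 5 in the focal
lineage.

## Limitations

* Structure input is GRO/PDB (single- or multi-frame); compressed binary
  trajectory formats (XTC/TRR) are not read — convert with standard tools
  (`gmx trjconv`) or use the native text fixture format.
* The bilayer is assumed planar and z-normal; no curvature or undulation
  correction, no local surface definition.
* Lineage follows a single focal chain, as in the original backtracking
  procedure; there is no global aggregate correspondence across all
  aggregates and no kinetic modeling of events.
* Orthorhombic boxes only.
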