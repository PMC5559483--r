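---
title: "Adaptive bandit-guided exploration of a protein-ligand landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive bandit-guided exploration of a protein-ligand landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptivebind)
```

## The problem

Unbiased simulation of ligand binding is dominated by metastability:
competing interactions make the energy landscape rugged, so trajectories
oversample a few long-lived states (solvent bulk, surface vestibules, decoy
sub-pockets) while the productive route into the binding site is
undersampled. Throwing more independent trajectories at the problem helps
only slowly, because every trajectory pays the same waiting times in the
same traps.

`adaptivebind` implements the iterative remedy: an *epoch* consists of a
swarm of `N` short trajectories of `l` Monte Carlo steps, whose snapshots
are clustered into a persistent discretization of the explored space;
the starting structures for the next epoch are then *spawned* from cluster
centers according to a multi-armed-bandit reward. Cluster memory converts
transient excursions into permanent restart points, so progress along a
difficult route ratchets instead of being washed out.

## Clustering

Snapshots are clustered with the single-pass leader algorithm on the ligand
RMSD (no superposition — all coordinates share the rigid receptor frame; no
ligand-symmetry correction). A snapshot joins the first cluster, in creation
order, whose center is within that cluster's RMSD threshold; otherwise it
founds a new cluster. The centroid distance, a lower bound on the RMSD, is
tested first and prunes most RMSD evaluations without changing the result
(the test suite checks exact equivalence against an unpruned
implementation). With `k` final clusters and `n` snapshots per epoch the
comparison count is bounded by `k * n`.

Cluster thresholds depend on the protein-ligand contact ratio `c` —
(alpha-carbon, ligand-heavy-atom) pairs closer than 8 angstroms, strictly,
divided by the number of ligand atoms. The default step table is 5 A for
`c <= 0.5` (solvent), 4 A for `c <= 0.75`, 3 A for `c <= 1`, 2 A for
`c > 1` (protein frame): discretization is finest exactly where ruggedness
grows with contacts. The two printed anchor bands are the solvent and
protein-frame values; the intermediate rungs of the table are this package's
choice and are configurable via `threshold_policy()`.

## Spawning

Every cluster is an arm. The diffusive (default) reward is

    r = rho / C

with `C` the cluster's visit count (its center counts once) and `rho` a
density. Seeds for the next epoch are allocated in proportion to the
rewards — Thompson-style proportional sampling realized as one multinomial
draw (or, optionally, deterministic largest-remainder apportionment). The
`1/C` factor guarantees that in the long run the ratio of populations
between any two clusters tends to the ratio of their densities; the test
suite verifies this to within 5% on a two-cluster chain after 200 epochs.

Three density modes are provided. `constant` (`rho = 1`) is the pure
diffusive baseline. `inverse_volume` takes `rho` proportional to the
inverse cluster volume with volume proportional to the threshold cubed.
The shipped default is `contacts`: a step table increasing with `c`
(1 / 2 / 4 / 16 over the bands `c <= 0.5`, `<= 2`, `<= 8`, `> 8`), on the
premise that high-contact regions are harder to sample and deserve
proportionally more seeds. On the desk-scale toy system the inverse-volume
proxy degenerates — nearly every near-receptor cluster shares the finest
threshold, making `rho` effectively constant — whereas the contact bands
still separate the buried interior from the surface blanket; this is why
`contacts` is the default here. All three remain available and configurable.

Metric-guided rewards use per-cluster extrema of a recorded metric (e.g.
the interaction energy). When maximizing, `r_i = m_i_min - m_min`; when
minimizing, `r_i = m_max - m_i_max`, where the unsubscripted extrema run
over all clusters. Pairing minimization with the per-cluster *maximum* is
the published convention and is implemented exactly as stated; because a
cluster is then scored by its worst recorded value, `reward_metric(...,
use_best = TRUE)` is provided as a documented alternative that scores each
cluster by its best value for the chosen sense. The default is the
published pairing; the switch is never applied silently.

The epsilon-greedy strategy sends `round((1 - epsilon) * N)` seeds (half-up)
after the metric reward and the remainder after the diffusive reward. The
default is `epsilon = 0.5`, an even exploration/exploitation split: metric
guidance is purely exploitative — it concentrates effort where good metric
values have already been seen and pays off once the low-energy region has
been discovered — while only the diffusive fraction sustains discovery of
new regions. On routes whose entry is energetically uphill (as in the
shipped toy system, where the published minimize-reward scores clusters by
their worst recorded energy and therefore avoids the barrier region
entirely until the pocket is found), a smaller diffusive fraction starves
the discovery phase, so an even split is the safer default; the fraction is
configurable per run. At `epsilon` 0 or 1 the plan is identical to the
pure strategies at the same RNG seed. When every reward is zero (one
cluster, or all metrics equal) allocation falls back to uniform so
exploration proceeds.

## The toy simulator

The sampler contract — a function from (seed conformation, `l`, RNG seed)
to exactly `l` metric-annotated snapshots — is deliberately engine-agnostic;
`read_snapshots()` lets the clustering/spawning analysis run offline on
multi-model PDB output of any other engine. The shipped sampler is a
rigid-body Metropolis walker whose move rules follow the reference engine's
control parameters: 3 A translations while the surrogate exposure exceeds
0.6, translations drawn uniformly from 0.75-1.5 A in the protein vicinity,
the translation direction kept for four consecutive steps, rotations
uniform in 20-60 degrees about a random axis through the ligand centroid,
Metropolis acceptance at `kT = 1` (surrogate units), and rejected proposals
re-emitting the previous snapshot so trajectories always have length `l`.
Exposure is the documented contact surrogate `1 - min(c / 2, 1)`, not a
molecular-surface SASA.

The synthetic receptor is represented at two resolutions. Sterics use a
dense point cloud: a spherical shell (radius 6 A, 200 points) with a 30
degree aperture continued by a walled tunnel (radius 4.2 A, 100 points) up
to 13.5 A, sealed so the five-point rigid ligand (offsets 0.8 A) cannot
leak between wall points, with two half-disc baffles inside the tunnel
(at z = 10.2 and 5.8, on alternating sides) that force an S-shaped
passage. Contacts use a sparse alpha-carbon subset (a coarse shell
lattice plus a tunnel collar), mirroring the convention that contacts are
counted against alpha carbons only; with the dense cloud the 8 A cutoff
would make `c` effectively binary over a system this small, while the
sparse sites give a realistic gradient from `c > 10` in the pocket through
the intermediate bands to `c = 0` in the bulk.

The energy surface is two attractive Gaussian wells — the native pose at
the pocket center (depth 8, width 1.8 A) and a metastable decoy sub-pocket
beside the tunnel mouth at (6.5, 0, 9.5) (depth 4, width 2.8 A) — plus a
smooth desolvation-like barrier dome filling the tunnel (height 4.5,
Gaussian in z centered at 7.5 with width 3 A and lateral falloff), a
soft-core repulsion `10 * (1 - d/2)^2` against surface points closer than
2 A, and a harmonic wall confining the ligand centroid to a sphere of
radius 10.5 A centered midway between the native and initial poses (the
reference protocol restrains the ligand to such a sphere; the radius here
is the smallest containing both poses with margin, keeping the desk-scale
search volume proportionate). The initial pose sits 20 A from the native
pose in the bulk. Depths, `kT`, `l = 4`, the 2.5 A binding criterion and
the 3000-step cap are the stated study conditions; the geometry realizing
them is this package's design.

Why this geometry: free walkers cannot park on the dome — its gradient
washes them back into the vestibule region and the decoy — so an
unassisted traversal must be nearly concerted, carries the full barrier
cost, and (because of the baffles) cannot ride a single persistent
translation direction through the tunnel. Leader-cluster centers on the
dome, by contrast, are permanent: one lucky excursion founds a restart
point, the freshly founded cluster has visit count 1 and therefore a large
reward, and the next epoch concentrates seeds exactly there. The adaptive
arm therefore climbs the dome in threshold-sized stages whose per-stage
cost is a small fraction of the total barrier, and short hops around the
baffle edges are unaffected by the tortuosity that defeats concerted runs.
This is the mechanism the whole method exists to exploit, realized at desk
scale.

What the toy deliberately does not emulate: protein flexibility (the
receptor is rigid; no backbone perturbation), physical force fields and
solvent, real SASA, ligand internal degrees of freedom, and any
thermodynamic calibration. Passing the shipped benchmark therefore shows
that the adaptive machinery exploits cluster memory and bandit reallocation
as designed — not that it will show identical speed-ups on any particular
real receptor.

## The benchmark

`benchmark_binding()` compares strategies at matched master seeds: for each
replicate, the first-passage binding time is the smallest per-trajectory
cumulative step at which any explorer's ligand RMSD to the native pose
drops below 2.5 A; runs that never bind within the 3000-step budget are
assigned 3000, bounding the comparison from below. Means and standard
deviations are taken over ten replicates by default. Runs stop at the end
of the epoch in which binding first occurs: trajectories advance in
lockstep and the epoch completes normally, so the early stop cannot change
the estimator. Binding times are reported in per-trajectory MC steps, so
adaptive and independent arms are compared on the same axis.

All randomness derives from one master seed through a counter-based
splitter (`mix_seed()`): each (epoch, trajectory) pair and each spawning
decision consumes its own child stream, so adaptive and independent arms
consume comparable streams, identical master seeds reproduce runs
bit-for-bit, and the two arms coincide exactly over epoch 0 (before any
feedback exists).

Problem sizes used by the tests and the acceptance script — `N = 32`
explorers, `l = 4`, ten replicates, a 3000-step cap, clustering batches up
to a few hundred snapshots — were chosen so the full suite runs in minutes
on a single core while the benchmark effect remains measurable.

## Numerical choices and degenerate inputs

* Contact test is strictly `< 8` A; a pair at exactly the cutoff is not a
  contact.
* New-cluster thresholds and densities are frozen at creation time from the
  center's contact ratio; centers are immutable (within-cluster alternative
  starting structures are a known extension, not implemented).
* Largest-remainder apportionment breaks remainder ties by cluster creation
  order, making deterministic allocation fully reproducible.
* All-zero rewards (single cluster, degenerate first epoch, identical
  metrics) fall back to uniform allocation.
* Metrics are write-once per conformation; clusters update extrema only for
  metrics a snapshot actually carries.
* The detailed-balance check runs the documented 1-D reduction along the
  channel axis on a tame variant (native depth 3, decoy depth 2, dome
  height 1) so a 150k-step chain crosses between wells many times; the
  shipped wells are intentionally too deep for that to happen in test time.
* Seeds derived from the master seed stay below 2^31; `with_seed()` scopes
  every stochastic operation so library calls never disturb the caller's
  RNG state.

## Known limitations

The leader partition depends on input order (a property of the algorithm,
not a bug); only the membership invariant is order-independent. The toy
ligand is rigid, so the reported RMSD conflates translation and rotation
only. Contact ratios on a desk-scale receptor remain coarser than on a
real protein even with the sparse alpha-carbon frame, so the intermediate
threshold bands are exercised over a narrow spatial band. Binding-time
distributions on the toy system are heavy-tailed; with ten replicates the
Welch comparison in the acceptance suite is the appropriate granularity,
and individual replicate times scatter widely around the means.
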