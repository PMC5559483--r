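# adaptivebind

Adaptive, bandit-guided exploration of protein–ligand binding landscapes.

Unbiased sampling of ligand binding is dominated by metastability: competing
interactions make the energy landscape rugged, trajectories oversample a few
long-lived states (bulk, surface vestibules, decoy sub-pockets) and
undersample the productive route into the binding site. `adaptivebind`
implements the iterative remedy for people who study binding mechanisms with
Monte Carlo (or any snapshot-producing engine): run *epochs* of `N` short
trajectories of `l` steps each, cluster every snapshot into a persistent
discretization of the explored space, and *spawn* the next epoch's starting
structures from cluster centers according to a multi-armed-bandit reward.
Cluster memory turns transient excursions into permanent restart points, so
progress along a hard route ratchets instead of washing out.

The machinery:

* **Leader clustering on ligand RMSD** (no superposition; shared receptor
  frame), accelerated by the centroid-distance lower bound, with at most
  `k * n` comparisons for `k` clusters and `n` snapshots. Cluster RMSD
  thresholds shrink with the protein–ligand contact ratio
  `c` = (Cα, ligand-heavy-atom) pairs within 8 Å per ligand atom — from 5 Å
  in the solvent (`c ≤ 0.5`) to 2 Å in the protein frame (`c > 1`).
* **Bandit spawning.** Each cluster is an arm with reward

      r = ρ / C        (inversely proportional: density over visit count)

  or a metric-guided reward from per-cluster metric extrema
  (`r_i = m_i,min − m_min` when maximizing, `r_i = m_max − m_i,max` when
  minimizing). Seeds are allocated proportionally to rewards (Thompson-style
  multinomial draw, or deterministic largest-remainder apportionment), and
  the ε-greedy strategy splits the swarm between the metric and diffusive
  schemes. The `1/C` factor guarantees cluster populations converge to the
  density ratio in the long run.
* **A desk-scale toy simulator** — a rigid five-point ligand exploring a
  synthetic receptor (buried native well behind a walled, baffled entry
  tunnel carrying a desolvation-like barrier; a metastable decoy side pocket
  at the mouth) with Metropolis dynamics and the reference move rules (3 Å
  exposed / 0.75–1.5 Å buried translations, 20–60° rotations, 4-step
  direction persistence) — so the adaptive-versus-independent first-passage
  benchmark runs end-to-end in minutes on one CPU.
* **Multi-model PDB I/O** (via bio3d) so the clustering/spawning analysis can
  be applied offline to snapshots produced by any other sampling engine, plus
  TSV reports and a YAML run configuration.

## Worked example

```r
library(adaptivebind)

sys <- build_toy_system(1)            # deterministic synthetic complex
sys
#> <toy_system> 306 surface points (19 alpha carbons), 5 ligand atoms,
#>   wells 8.0/4.0, kT 1.00
contact_ratio(sys$native_pose, sys$receptor)   # buried:  13.6  (c > 1)
contact_ratio(sys$initial_pose, sys$receptor)  # solvent: 0     (c <= 0.5)

par <- adaptive_params(n_trajectories = 32, steps_per_epoch = 4,
                       max_total_steps = 3000,
                       master_seed = mix_seed(1, 3, 1),  # benchmark replicate 1
                       early_stop = TRUE)
rec <- run_adaptive(toy_sampler(sys), sys, par)
rec
#> <run_record> adaptive: 29 epochs x 32 trajectories x 4 steps; binding at 113
binding_time(rec)                     # first-passage, per-trajectory MC steps
#> [1] 113
n_clusters(rec$state)
#> [1] 230

head(cluster_table(rec$state), 3)
#>   id contact_ratio threshold density visit_count min_energy max_energy ...
#> 1  0           1.8         2       2          38   1.53e-03     0.0624 ...
#> 2  1           1.6         2       2          34   1.43e-02     1.6535 ...
#> 3  2           2.8         2       4          35  -4.15e-05     0.0743 ...
```

The numbers mean: starting 20 Å from the buried pose, 32 adaptive explorers
found a ligand pose within 2.5 Å RMSD of the native structure at MC step 113
of each explorer's 3000-step budget, having discretized the explored space
into 230 clusters (solvent clusters at 5 Å threshold and density 1, buried
ones at 2 Å and density up to 16). First-passage times on this landscape are
heavy-tailed — this replicate is a fast one; the benchmark below averages
over ten.

Compare strategies on the shipped system (ten replicates each; several
minutes):

```r
tab <- benchmark_binding(toy_sampler, sys, n_grid = 32, repeats = 10,
                         strategies = c("independent",
                                        "inversely_proportional",
                                        "epsilon_greedy"),
                         base_seed = 1)
tab
#>                 strategy n_trajectories mean_steps sd_steps n_binding_events repeats
#> 1            independent             32     2392.8 875.5790                4      10
#> 2 inversely_proportional             32     1398.9 961.4028                9      10
#> 3         epsilon_greedy             32     2261.0 676.5148                7      10
```

Independent explorers mostly exhaust the 3000-step budget (binding times of
3000 are censored runs, counted at the cap); the adaptive inversely
proportional strategy binds in roughly 1400 steps on average — a 1.7×
speed-up on this system — and the energy-guided ε-greedy variant also beats
the baseline, paying for its exploitative half until the pocket has been
discovered.

Offline analysis of external trajectories:

```r
snaps <- read_snapshots("trajectory.pdb", ligand_resname = "LIG")
res <- analyze_snapshots(snaps$conformations, snaps$frame, n_seeds = 32)
write_cluster_table(res$state, "clusters.tsv")
write_spawning_report(res$plan, "spawning.tsv")
```

A thin command-line wrapper with `run`, `benchmark`, `analyze` and
`export-centers` subcommands is installed at
`system.file("cli", "adaptivebind.R", package = "adaptivebind")`.

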