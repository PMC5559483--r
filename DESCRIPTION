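Package: adaptivebind
Title: Adaptive Bandit-Guided Exploration of Protein-Ligand Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Iterative adaptive exploration of protein-ligand binding
    landscapes: short swarms of Monte Carlo trajectories are clustered with
    a leader algorithm over ligand RMSD (with centroid-distance pruning and
    contact-dependent cluster thresholds), and the starting structures for
    the next round are chosen by multi-armed-bandit spawning strategies
    (inversely proportional and epsilon-greedy reward schemes allocated by
    Thompson-style proportional sampling). Ships a desk-scale rigid-body
    Metropolis simulator of a buried binding pocket with a metastable decoy
    site, so the adaptive-versus-independent first-passage binding-time
    benchmark runs end-to-end on one CPU. Reads and writes multi-model PDB
    snapshots for offline clustering and spawning analysis of externally
    produced trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
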