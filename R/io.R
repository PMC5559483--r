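# Multi-model PDB snapshot I/O, run configuration, and tabular reports.
# PDB parsing goes through bio3d; writing uses a fixed-column formatter so
# MODEL/ENDMDL framing and the element column are always populated.

#' Read snapshot trajectories from a multi-model PDB file
#'
#' Parses a multi-model PDB produced by any sampling engine: the receptor
#' frame is taken from the alpha carbons of model 1, and one ligand
#' [conformation()] is extracted per model from the heavy atoms (element not
#' hydrogen) of the given residue name. Atom order is taken from the file and
#' is consistent across models.
#'
#' @param path Path to a (multi-model) PDB file.
#' @param ligand_resname Residue name of the ligand (e.g. `"LIG"`).
#' @param contact_cutoff Contact cutoff for the returned frame (default 8 A).
#' @return List with `frame` (a [receptor_frame()]) and `conformations`
#'   (list of [conformation()], one per model, `step` = model number).
#' @export
read_snapshots <- function(path, ligand_resname = "LIG", contact_cutoff = 8.0) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop(sprintf("failed to parse '%s' as multi-model PDB (models must share one atom table): %s",
                                 path, conditionMessage(e))))
  atoms <- pdb$atom
  is_ca <- atoms$type == "ATOM" & atoms$elety == "CA"
  if (!any(is_ca))
    stop(sprintf("no alpha carbons found in '%s'", path))
  elem <- toupper(trimws(atoms$elesy))
  is_lig <- atoms$resid == ligand_resname & elem != "H" & elem != "D"
  if (!any(is_lig))
    stop(sprintf("ligand residue '%s' not found in model 1 of '%s'",
                 ligand_resname, path))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  model_coords <- function(m, sel) {
    matrix(xyz[m, as.vector(rbind(3 * which(sel) - 2, 3 * which(sel) - 1,
                                  3 * which(sel)))],
           ncol = 3, byrow = TRUE)
  }
  frame <- receptor_frame(model_coords(1L, is_ca), contact_cutoff)
  confs <- lapply(seq_len(nrow(xyz)), function(m) {
    conformation(model_coords(m, is_lig), step = m)
  })
  list(frame = frame, conformations = confs)
}

#' Write conformations as a multi-model PDB trajectory
#'
#' Emits standards-conformant fixed-column records: one MODEL/ENDMDL block
#' per conformation (1-based model numbering), the receptor alpha carbons as
#' ATOM records and the ligand atoms as HETATM records, element column
#' populated (C for ligand atoms).
#'
#' @param confs List of [conformation()]s (same atom count).
#' @param frame Optional [receptor_frame()] written into every model.
#' @param path Output file path.
#' @param ligand_resname Residue name for the ligand records.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(confs, path, frame = NULL,
                            ligand_resname = "LIG") {
  stopifnot(length(confs) >= 1L)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(confs)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    if (!is.null(frame)) {
      ca <- frame$calpha_coords
      for (i in seq_len(nrow(ca))) {
        serial <- serial + 1L
        writeLines(pdb_record("ATOM", serial, "CA", "ALA", "A", i,
                              ca[i, ], "C"), con)
      }
    }
    lig <- coords_of(confs[[m]])
    for (i in seq_len(nrow(lig))) {
      serial <- serial + 1L
      writeLines(pdb_record("HETATM", serial, sprintf("C%d", i),
                            ligand_resname, "B", 900L, lig[i, ], "C"), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

pdb_record <- function(type, serial, name, resn, chain, resno, xyz, element) {
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial %% 100000L, substr(name, 1, 4), resn, chain,
          resno %% 10000L, xyz[1], xyz[2], xyz[3], 1.0, 0.0, element)
}

#' Export cluster centers as a multi-model PDB
#'
#' @param state A [clustering_state()].
#' @param path Output path.
#' @param with_receptor Include the receptor alpha carbons in each model.
#' @return `path`, invisibly.
#' @export
export_centers <- function(state, path, with_receptor = FALSE) {
  if (n_clusters(state) == 0L) stop("clustering state has no clusters")
  write_snapshots(cluster_centers(state), path,
                  frame = if (with_receptor) state$frame else NULL)
}

#' Offline clustering and spawning of externally produced snapshots
#'
#' Runs the full analysis phase of one adaptive epoch on a batch of snapshot
#' conformations: leader clustering ([add_conformations()]) in the given
#' order, followed by one [spawn()] call. This produces, offline, exactly the
#' clustering state and plan an in-run epoch would produce on the same
#' snapshots in the same order.
#'
#' @param snapshots List of [conformation()]s (non-empty).
#' @param frame A [receptor_frame()].
#' @param n_seeds Seeds to allocate for a hypothetical next epoch.
#' @param spawning A [spawning_params()].
#' @param tpolicy,dpolicy Clustering policies.
#' @param rng_seed Seed for stochastic allocation.
#' @return List with `state` (the [clustering_state()]) and `plan` (the
#'   [spawn()] plan).
#' @export
analyze_snapshots <- function(snapshots, frame, n_seeds = 8L,
                              spawning = spawning_params(),
                              tpolicy = threshold_policy(),
                              dpolicy = density_policy(),
                              rng_seed = 0L) {
  if (length(snapshots) == 0L)
    stop("empty input: no snapshot conformations to analyze")
  state <- clustering_state(frame, tpolicy, dpolicy)
  add_conformations(state, snapshots)
  plan <- spawn(state, spawning, n_seeds, rng_seed = rng_seed)
  list(state = state, plan = plan)
}

#' Write the cluster table as TSV
#' @param state A [clustering_state()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(state, path) {
  utils::write.table(cluster_table(state), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a spawning plan report as TSV
#'
#' One row per cluster: id, reward, allocation probability, allocated seeds.
#'
#' @param plan A [spawn()] plan.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spawning_report <- function(plan, path) {
  tab <- data.frame(id = as.integer(names(plan$counts)),
                    reward = unname(plan$rewards),
                    probability = unname(plan$probabilities),
                    seeds = unname(plan$counts))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

config_defaults <- function() {
  list(
    schema_version = 1L,
    strategy = "inversely_proportional",
    epsilon = 0.5,
    metric_name = "energy",
    metric_sense = "minimize",
    allocation_mode = "stochastic",
    n_trajectories = 32L,
    steps_per_epoch = 4L,
    max_total_steps = 3000L,
    binding_rmsd_cutoff = 2.5,
    master_seed = 1L,
    build_seed = 1L,
    threshold_c_bounds = c(0.5, 0.75, 1.0),
    threshold_values = c(5.0, 4.0, 3.0),
    threshold_terminal = 2.0,
    density_mode = "contacts",
    exposed_translation = 3.0,
    buried_translation_range = c(0.75, 1.5),
    exposure_cutoff = 0.6,
    rotation_range = c(20, 60),
    direction_persistence = 4L,
    kT = 1.0)
}

#' Read a run configuration file
#'
#' A single YAML document holding the adaptive, spawning, move and toy-system
#' parameters. Unknown keys are rejected; missing keys are filled with the
#' package defaults. Use [write_run_config()] to echo the completed
#' configuration into a run directory for provenance.
#'
#' @param path YAML file path.
#' @return A named list (class `"run_config"`) with all defaults filled.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defs <- config_defaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown))
    stop(sprintf("unknown configuration keys: %s",
                 paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defs, raw)
  structure(cfg, class = c("run_config", "list"))
}

#' Write a run configuration file
#' @param cfg A config list from [read_run_config()] (or a plain list of
#'   overrides, completed with defaults).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  cfg <- utils::modifyList(config_defaults(), unclass(cfg))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Assemble run objects from a configuration
#'
#' @param cfg A config list from [read_run_config()].
#' @return List with `system`, `sampler`, `params`, `tpolicy`, `dpolicy`
#'   ready for [run_adaptive()] / [run_independent()].
#' @export
config_to_run <- function(cfg) {
  sys <- build_toy_system(build_seed = cfg$build_seed, kT = cfg$kT)
  moves <- move_params(cfg$exposed_translation, cfg$buried_translation_range,
                       cfg$exposure_cutoff, cfg$rotation_range,
                       cfg$direction_persistence)
  sp <- spawning_params(strategy = cfg$strategy, epsilon = cfg$epsilon,
                        metric_name = cfg$metric_name,
                        metric_sense = cfg$metric_sense,
                        allocation_mode = cfg$allocation_mode)
  par <- adaptive_params(cfg$n_trajectories, cfg$steps_per_epoch,
                         cfg$max_total_steps, cfg$binding_rmsd_cutoff,
                         cfg$master_seed, sp)
  list(system = sys, sampler = toy_sampler(sys, moves), params = par,
       tpolicy = threshold_policy(cfg$threshold_c_bounds,
                                  cfg$threshold_values,
                                  cfg$threshold_terminal),
       dpolicy = density_policy(cfg$density_mode))
}
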