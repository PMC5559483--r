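#' Adaptive run parameters
#'
#' @param n_trajectories Explorers per epoch `N` (>= 1).
#' @param steps_per_epoch Steps per trajectory per epoch `l` (default 4):
#'   short enough to exploit communication between explorers, long enough for
#'   new conformations to advance.
#' @param max_total_steps Per-trajectory cumulative step budget (default
#'   3000); runs that never bind are assigned this cap as their binding time.
#' @param binding_rmsd_cutoff Ligand RMSD to the native pose below which a
#'   binding event is recorded (default 2.5 A).
#' @param master_seed Master seed; every random stream in the run is derived
#'   from it.
#' @param spawning A [spawning_params()].
#' @param early_stop If `TRUE`, stop at the end of the first epoch in which a
#'   binding event is observed. The epoch always completes, so the recorded
#'   first-passage step is unaffected; default `FALSE` (run the full budget).
#' @return An object of class `"adaptive_params"`.
#' @export
adaptive_params <- function(n_trajectories,
                            steps_per_epoch = 4L,
                            max_total_steps = 3000L,
                            binding_rmsd_cutoff = 2.5,
                            master_seed = 1L,
                            spawning = spawning_params(),
                            early_stop = FALSE) {
  stopifnot(n_trajectories >= 1L, steps_per_epoch >= 1L,
            max_total_steps >= steps_per_epoch, binding_rmsd_cutoff > 0,
            inherits(spawning, "spawning_params"))
  structure(list(n_trajectories = as.integer(n_trajectories),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 max_total_steps = as.integer(max_total_steps),
                 binding_rmsd_cutoff = binding_rmsd_cutoff,
                 master_seed = as.integer(master_seed),
                 spawning = spawning,
                 early_stop = isTRUE(early_stop)),
            class = "adaptive_params")
}

#' Wrap the toy simulator into the sampler contract
#'
#' A sampler is any function `f(seed_conf, l, rng_seed)` returning an ordered
#' list of exactly `l` [conformation()]s with metrics filled. This helper
#' binds [mc_trajectory()] to a system and move set.
#'
#' @param system A [build_toy_system()] object.
#' @param moves A [move_params()].
#' @return A sampler function.
#' @export
toy_sampler <- function(system, moves = move_params()) {
  force(system); force(moves)
  function(seed_conf, l, rng_seed) {
    mc_trajectory(seed_conf, system, moves, l, rng_seed)
  }
}

#' Run the adaptive exploration loop
#'
#' Iterates epochs of sampling, clustering and spawning. Epoch 0 starts all
#' `N` trajectories from the initial conformation; each later epoch starts
#' them from the cluster centers dictated by [spawn()] on the accumulated
#' clustering state. Every (epoch, trajectory) pair consumes its own child
#' RNG stream derived from the master seed, so runs are fully reproducible.
#'
#' @param sampler A sampler function (see [toy_sampler()]).
#' @param system A [build_toy_system()] object, or a list with fields
#'   `receptor` (a [receptor_frame()]), `initial_pose` and optionally
#'   `native_pose`.
#' @param params An [adaptive_params()].
#' @param tpolicy,dpolicy Threshold and density policies for the clustering
#'   state.
#' @param verbose If `TRUE`, report per epoch (via [message()]): epoch index,
#'   new clusters, total cluster count, snapshots processed, cumulative
#'   comparison count, and the Shannon entropy of the spawning plan.
#' @return An object of class `"run_record"`: list with `epochs` (per epoch,
#'   a list of `N` trajectories, each a list of `l` [conformation()]s),
#'   `plans` (per-epoch [spawn()] plans), `state` (the final
#'   [clustering_state()]), `binding_step` (first-passage step or `NA`),
#'   `params`, and `mode = "adaptive"`.
#' @export
run_adaptive <- function(sampler, system, params,
                         tpolicy = threshold_policy(),
                         dpolicy = density_policy(),
                         verbose = FALSE) {
  stopifnot(is.function(sampler), inherits(params, "adaptive_params"))
  state <- clustering_state(system$receptor, tpolicy, dpolicy)
  run_epochs(sampler, system, params, state, verbose = verbose)
}

#' Run the non-adaptive baseline
#'
#' `N` independent trajectories from the initial conformation for the full
#' step budget, with no clustering feedback: each trajectory always continues
#' from its own last conformation. Sampling is chunked into epochs of `l`
#' steps consuming the same child RNG streams as [run_adaptive()], so the two
#' arms are comparable at matched master seeds (and identical over epoch 0,
#' before any feedback has occurred).
#'
#' @inheritParams run_adaptive
#' @return A `"run_record"` with `state = NULL`, `plans = list()` and
#'   `mode = "independent"`.
#' @export
run_independent <- function(sampler, system, params, verbose = FALSE) {
  stopifnot(is.function(sampler), inherits(params, "adaptive_params"))
  run_epochs(sampler, system, params, state = NULL, verbose = verbose)
}

run_epochs <- function(sampler, system, params, state, verbose = FALSE) {
  adaptive <- !is.null(state)
  N <- params$n_trajectories
  l <- params$steps_per_epoch
  n_epochs <- params$max_total_steps %/% l
  native <- system$native_pose
  initial <- system$initial_pose
  if (is.null(initial)) stop("system must provide an initial_pose")

  epochs <- vector("list", n_epochs)
  plans <- vector("list", n_epochs)
  binding_step <- NA_integer_
  last_confs <- NULL    # independent mode: continuation points
  seeds_conf <- rep(list(initial), N)
  seeds_origin <- rep(NA_integer_, N)

  for (e in seq_len(n_epochs) - 1L) {
    trajs <- vector("list", N)
    for (t in seq_len(N) - 1L) {
      traj <- sampler(seeds_conf[[t + 1L]], l,
                      mix_seed(params$master_seed, 1L, e, t))
      if (!is.list(traj) || length(traj) != l)
        stop(sprintf("sampler contract violation: expected %d conformations, got %s",
                     l, length(traj)))
      for (j in seq_len(l)) {
        cf <- traj[[j]]
        cf$epoch <- e
        cf$trajectory <- t
        cf$step <- e * l + j
        cf$origin_cluster <- seeds_origin[t + 1L]
        traj[[j]] <- cf
      }
      trajs[[t + 1L]] <- traj
    }
    epochs[[e + 1L]] <- trajs

    # binding detection at the true step (the epoch completes normally)
    if (!is.null(native) && is.na(binding_step)) {
      for (t in seq_len(N)) {
        for (j in seq_len(l)) {
          cf <- trajs[[t]][[j]]
          r <- cf$metrics[["rmsd_to_native"]]
          if (is.null(r)) r <- ligand_rmsd(cf, native)
          if (!is.na(r) && r < params$binding_rmsd_cutoff &&
              (is.na(binding_step) || cf$step < binding_step))
            binding_step <- cf$step
        }
      }
    }

    last_epoch <- (e == n_epochs - 1L) ||
      (params$early_stop && !is.na(binding_step))

    if (adaptive) {
      # cluster in (trajectory, step) order, then spawn the next swarm
      k_before <- n_clusters(state)
      for (t in seq_len(N)) add_conformations(state, trajs[[t]])
      if (!last_epoch) {
        plan <- spawn(state, params$spawning, N,
                      rng_seed = mix_seed(params$master_seed, 2L, e))
        plans[[e + 1L]] <- plan
        if (verbose) {
          p <- plan$counts / plan$total
          p <- p[p > 0]
          message(sprintf(
            "epoch %d: new clusters %d, k = %d, n processed %d, comparisons %.0f, spawn entropy %.3f",
            e, n_clusters(state) - k_before, n_clusters(state),
            state$n_processed, state$comparison_count, -sum(p * log(p))))
        }
        seeds_conf <- vector("list", N)
        seeds_origin <- integer(N)
        i <- 1L
        for (idx in seq_along(plan$counts)) {
          cnt <- plan$counts[[idx]]
          if (cnt > 0L) {
            id <- as.integer(names(plan$counts)[idx])
            center <- get_cluster(state, id)$center
            for (s in seq_len(cnt)) {
              seeds_conf[[i]] <- center
              seeds_origin[i] <- id
              i <- i + 1L
            }
          }
        }
      }
    } else if (!last_epoch) {
      seeds_conf <- lapply(trajs, function(tr) tr[[l]])
    }

    if (last_epoch) {
      epochs <- epochs[seq_len(e + 1L)]
      plans <- plans[seq_len(e + 1L)]
      break
    }
  }

  structure(list(epochs = epochs, plans = plans, state = state,
                 binding_step = binding_step, params = params,
                 mode = if (adaptive) "adaptive" else "independent"),
            class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> %s: %d epochs x %d trajectories x %d steps; binding at %s\n",
              x$mode, length(x$epochs), x$params$n_trajectories,
              x$params$steps_per_epoch,
              if (is.na(x$binding_step)) "none" else x$binding_step))
  invisible(x)
}

#' First-passage binding time of a run
#'
#' The smallest per-trajectory cumulative step index (1-based) at which any
#' trajectory's conformation has ligand RMSD to the native pose below the
#' cutoff; runs with no such event are assigned the cap, which bounds the
#' comparison from below.
#'
#' @param record A [run_adaptive()] / [run_independent()] record.
#' @param native Native [conformation()] (defaults to the one the run already
#'   screened against, via the cached `rmsd_to_native` metric).
#' @param cutoff Binding RMSD cutoff in angstroms (default 2.5).
#' @param cap Step count assigned when no binding occurred (default 3000).
#' @return Integer step index, or `cap`.
#' @export
binding_time <- function(record, native = NULL, cutoff = 2.5, cap = 3000L) {
  stopifnot(inherits(record, "run_record"))
  best <- NA_integer_
  for (trajs in record$epochs) {
    for (traj in trajs) {
      for (cf in traj) {
        r <- if (is.null(native)) cf$metrics[["rmsd_to_native"]]
             else ligand_rmsd(cf, native)
        if (is.null(r))
          stop("no rmsd_to_native metric cached; supply `native`")
        if (r < cutoff && (is.na(best) || cf$step < best)) best <- cf$step
      }
    }
  }
  if (is.na(best)) as.integer(cap) else as.integer(best)
}

#' Benchmark adaptive against independent sampling
#'
#' For each (strategy, N) cell, runs `repeats` replicates at derived master
#' seeds and reports the mean and standard deviation of the first-passage
#' binding time, together with the number of replicates that actually bound
#' within the step budget. Strategy `"independent"` is the non-adaptive
#' baseline; any other name must be a [spawning_params()] strategy.
#'
#' @param sampler_factory Function `(system) -> sampler`; called once.
#' @param system A [build_toy_system()] object.
#' @param n_grid Integer vector of explorer counts `N`.
#' @param repeats Replicates per cell (>= 2; the reference protocol averages
#'   over ten).
#' @param strategies Character vector from `"independent"`,
#'   `"inversely_proportional"`, `"epsilon_greedy"`, `"metric_guided"`.
#' @param base_seed Seed from which the `repeats` master seeds are derived.
#' @param steps_per_epoch,max_total_steps,binding_rmsd_cutoff Passed to
#'   [adaptive_params()].
#' @param spawning_args Extra arguments for [spawning_params()] (e.g.
#'   `epsilon`, `metric_name`).
#' @return A `data.frame` with columns `strategy`, `n_trajectories`,
#'   `mean_steps`, `sd_steps`, `n_binding_events`, `repeats`, plus an
#'   attribute `"times"` holding the per-replicate binding times.
#' @export
benchmark_binding <- function(sampler_factory, system,
                              n_grid = 32L,
                              repeats = 10L,
                              strategies = c("independent",
                                             "inversely_proportional"),
                              base_seed = 1L,
                              steps_per_epoch = 4L,
                              max_total_steps = 3000L,
                              binding_rmsd_cutoff = 2.5,
                              spawning_args = list()) {
  stopifnot(repeats >= 2L)
  sampler <- sampler_factory(system)
  rows <- list()
  times_by_cell <- list()
  for (strategy in strategies) {
    for (N in n_grid) {
      times <- integer(repeats)
      for (r in seq_len(repeats)) {
        seed <- mix_seed(base_seed, 3L, r)
        sp <- if (strategy == "independent") spawning_params()
              else do.call(spawning_params, c(list(strategy = strategy),
                                              spawning_args))
        par <- adaptive_params(N, steps_per_epoch, max_total_steps,
                               binding_rmsd_cutoff, master_seed = seed,
                               spawning = sp, early_stop = TRUE)
        rec <- if (strategy == "independent")
          run_independent(sampler, system, par)
        else run_adaptive(sampler, system, par)
        times[r] <- binding_time(rec, cutoff = binding_rmsd_cutoff,
                                 cap = max_total_steps)
      }
      cell <- sprintf("%s_N%d", strategy, N)
      times_by_cell[[cell]] <- times
      rows[[cell]] <- data.frame(
        strategy = strategy, n_trajectories = as.integer(N),
        mean_steps = mean(times), sd_steps = stats::sd(times),
        n_binding_events = sum(times < max_total_steps),
        repeats = as.integer(repeats))
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "times") <- times_by_cell
  out
}
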