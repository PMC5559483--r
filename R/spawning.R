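#' Spawning strategy parameters
#'
#' Configures how seeds for the next epoch are distributed over clusters.
#' Three strategies:
#'
#' * `"inversely_proportional"` — diffusive exploration: each cluster's reward
#'   is its density over its visit count, `r = rho / C`, so rarely visited
#'   (potentially metastable) regions are re-seeded preferentially. In the
#'   long run the ratio of populations between any two clusters tends to the
#'   ratio of their densities.
#' * `"metric_guided"` — pure Thompson sampling on a metric reward (see
#'   [reward_metric()]).
#' * `"epsilon_greedy"` — a `1 - epsilon` fraction of the explorers follows
#'   the metric-guided reward and the remaining `epsilon` fraction the
#'   inversely proportional scheme.
#'
#' @param strategy One of `"inversely_proportional"`, `"epsilon_greedy"`,
#'   `"metric_guided"`.
#' @param epsilon Fraction of explorers kept on the diffusive scheme in
#'   `epsilon_greedy` (default 0.5: an even exploration/exploitation split;
#'   metric guidance is exploitative and pays off once low-metric regions
#'   have been discovered, while the diffusive fraction sustains discovery).
#' @param metric_name Metric driving metric-guided rewards (e.g. `"energy"`).
#' @param metric_sense `"minimize"` or `"maximize"` the metric.
#' @param use_best_value If `TRUE`, metric rewards score each cluster by its
#'   best recorded value for the chosen sense (its minimum when minimizing)
#'   rather than by the published convention, which pairs minimization with
#'   the per-cluster maximum. See [reward_metric()].
#' @param allocation_mode `"stochastic"` (multinomial draw) or
#'   `"deterministic"` (largest-remainder apportionment).
#' @return An object of class `"spawning_params"`.
#' @export
spawning_params <- function(strategy = c("inversely_proportional",
                                         "epsilon_greedy", "metric_guided"),
                            epsilon = 0.5,
                            metric_name = "energy",
                            metric_sense = c("minimize", "maximize"),
                            use_best_value = FALSE,
                            allocation_mode = c("stochastic", "deterministic")) {
  strategy <- match.arg(strategy)
  metric_sense <- match.arg(metric_sense)
  allocation_mode <- match.arg(allocation_mode)
  stopifnot(epsilon >= 0, epsilon <= 1)
  if (strategy %in% c("epsilon_greedy", "metric_guided") &&
      (!nzchar(metric_name)))
    stop("metric_name is required for metric-guided rewards")
  structure(list(strategy = strategy, epsilon = epsilon,
                 metric_name = metric_name, metric_sense = metric_sense,
                 use_best_value = isTRUE(use_best_value),
                 allocation_mode = allocation_mode),
            class = "spawning_params")
}

#' Inversely proportional cluster reward
#'
#' `r = rho / C`: the cluster density divided by its visit count. Strictly
#' decreasing in the visit count at fixed density, so effort drains away from
#' oversampled clusters.
#'
#' @param cluster A cluster record from [get_cluster()].
#' @return Positive reward.
#' @export
reward_inverse <- function(cluster) {
  stopifnot(cluster$visit_count >= 1L)
  cluster$density / cluster$visit_count
}

#' Metric-guided cluster reward
#'
#' Rewards a cluster by how far its recorded metric range reaches beyond the
#' worst cluster, following the published convention: when maximizing,
#' `r_i = m_i_min - m_min` (per-cluster minimum against the global minimum);
#' when minimizing, `r_i = m_max - m_i_max` (global maximum against the
#' per-cluster maximum). Rewards are non-negative and the globally worst
#' cluster scores exactly 0.
#'
#' Pairing "minimize" with the per-cluster *maximum* (rather than the
#' cluster's own best, i.e. minimum, value) is deliberate here because it is
#' the convention as published; set `use_best = TRUE` to score each cluster
#' by its best value for the chosen sense instead (`m_i_min` when minimizing,
#' `m_i_max` when maximizing). The global extrema are always taken over the
#' same statistic used for the clusters, so rewards stay non-negative.
#'
#' @param cluster A cluster record.
#' @param global_min,global_max Extrema of the relevant per-cluster statistic
#'   over all clusters.
#' @param sense `"maximize"` or `"minimize"`.
#' @param metric_name Name of the metric.
#' @param use_best Use the per-cluster best value instead of the published
#'   pairing (default `FALSE`).
#' @return Non-negative reward.
#' @export
reward_metric <- function(cluster, global_min, global_max,
                          sense = c("minimize", "maximize"),
                          metric_name = "energy", use_best = FALSE) {
  sense <- match.arg(sense)
  m_min <- cluster$metric_min[metric_name]
  m_max <- cluster$metric_max[metric_name]
  if (is.na(m_min) || is.na(m_max))
    stop(sprintf("cluster %d has no recorded values for metric '%s'",
                 cluster$id, metric_name))
  if (sense == "maximize") {
    unname(m_max * use_best + m_min * !use_best) - global_min
  } else {
    global_max - unname(m_min * use_best + m_max * !use_best)
  }
}

# per-cluster statistic feeding reward_metric, and its global extrema
metric_stat <- function(state, metric_name, sense, use_best) {
  vapply(state$clusters, function(cl) {
    v <- if (sense == "maximize") {
      if (use_best) cl$metric_max[metric_name] else cl$metric_min[metric_name]
    } else {
      if (use_best) cl$metric_min[metric_name] else cl$metric_max[metric_name]
    }
    if (is.na(v))
      stop(sprintf("cluster %d has no recorded values for metric '%s'",
                   cl$id, metric_name))
    unname(v)
  }, numeric(1))
}

#' Allocate seed trajectories across clusters
#'
#' Thompson-style proportional allocation: each cluster receives seeds in
#' proportion to its reward. In `stochastic` mode the counts are one draw
#' from a multinomial with probabilities `p_i = r_i / sum(r)`; in
#' `deterministic` mode they are the largest-remainder apportionment of
#' `N * p_i` (floors first, leftover seeds to the largest fractional parts,
#' ties broken by cluster order). When every reward is zero the allocation
#' falls back to uniform probabilities so exploration can proceed.
#'
#' @param rewards Named (by cluster id) or unnamed non-negative numeric
#'   vector of rewards, in cluster id order.
#' @param n_seeds Total number of seeds `N` (>= 1).
#' @param mode `"stochastic"` or `"deterministic"`.
#' @param rng_seed Integer seed for the stochastic draw.
#' @return An object of class `"spawning_plan"`: list with `counts` (integer
#'   vector summing to `n_seeds`, one entry per cluster), `total`, `rewards`,
#'   and `probabilities`.
#' @export
allocate_seeds <- function(rewards, n_seeds,
                           mode = c("stochastic", "deterministic"),
                           rng_seed = 0L) {
  mode <- match.arg(mode)
  if (length(rewards) < 1L) stop("at least one cluster is required")
  if (any(rewards < 0)) stop("invalid reward: rewards must be non-negative")
  if (n_seeds < 1L) stop("invalid argument: n_seeds must be >= 1")
  total <- sum(rewards)
  p <- if (total > 0) rewards / total else rep(1 / length(rewards), length(rewards))
  counts <- if (mode == "stochastic") {
    with_seed(rng_seed, as.integer(stats::rmultinom(1L, n_seeds, p)))
  } else {
    largest_remainder(n_seeds * p, n_seeds)
  }
  ids <- if (!is.null(names(rewards))) as.integer(names(rewards))
         else seq_along(rewards) - 1L
  structure(list(counts = stats::setNames(counts, ids),
                 total = as.integer(n_seeds),
                 rewards = stats::setNames(as.numeric(rewards), ids),
                 probabilities = stats::setNames(p, ids)),
            class = "spawning_plan")
}

# largest-remainder (Hamilton) apportionment of quotas summing to n
largest_remainder <- function(quota, n) {
  base <- floor(quota + 1e-9)           # guard against 3.9999999 floors
  rem <- quota - base
  left <- as.integer(round(n - sum(base)))
  counts <- as.integer(base)
  if (left > 0L) {
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    counts[take] <- counts[take] + 1L
  }
  counts
}

#' @export
print.spawning_plan <- function(x, ...) {
  cat(sprintf("<spawning_plan> %d seeds over %d clusters\n",
              x$total, length(x$counts)))
  invisible(x)
}

#' Compute the spawning plan for the next epoch
#'
#' Evaluates the configured strategy over the current clustering state and
#' allocates `n_seeds` starting structures. For `epsilon_greedy`,
#' `round((1 - epsilon) * N)` seeds (half-up rounding) are allocated by the
#' metric reward and the remainder by the inversely proportional reward; the
#' two partial plans are summed. At the limits `epsilon = 1` and
#' `epsilon = 0` the plan is identical to the pure inversely proportional
#' and pure metric-guided plans at the same seed. Each seeded trajectory
#' starts from its cluster's center conformation.
#'
#' @param state A [clustering_state()] with at least one cluster.
#' @param params A [spawning_params()].
#' @param n_seeds Total seeds `N` for the next epoch.
#' @param rng_seed Integer seed for stochastic allocation.
#' @return A [allocate_seeds()] plan covering every cluster id.
#' @export
spawn <- function(state, params, n_seeds, rng_seed = 0L) {
  stopifnot(inherits(state, "clustering_state"),
            inherits(params, "spawning_params"))
  k <- n_clusters(state)
  if (k < 1L) stop("spawning requires at least one cluster")
  ids <- 0:(k - 1L)

  inv_rewards <- function() {
    stats::setNames(vapply(state$clusters, reward_inverse, numeric(1)), ids)
  }
  met_rewards <- function() {
    stat <- metric_stat(state, params$metric_name, params$metric_sense,
                        params$use_best_value)
    r <- if (params$metric_sense == "maximize") stat - min(stat)
         else max(stat) - stat
    stats::setNames(r, ids)
  }

  switch(params$strategy,
    inversely_proportional =
      allocate_seeds(inv_rewards(), n_seeds, params$allocation_mode, rng_seed),
    metric_guided =
      allocate_seeds(met_rewards(), n_seeds, params$allocation_mode, rng_seed),
    epsilon_greedy = {
      n_metric <- as.integer(floor((1 - params$epsilon) * n_seeds + 0.5))
      n_inverse <- n_seeds - n_metric
      if (n_inverse == 0L)
        allocate_seeds(met_rewards(), n_seeds, params$allocation_mode, rng_seed)
      else if (n_metric == 0L)
        allocate_seeds(inv_rewards(), n_seeds, params$allocation_mode, rng_seed)
      else {
        pm <- allocate_seeds(met_rewards(), n_metric, params$allocation_mode,
                             mix_seed(rng_seed, 11L))
        pi_ <- allocate_seeds(inv_rewards(), n_inverse, params$allocation_mode,
                              mix_seed(rng_seed, 13L))
        structure(list(counts = pm$counts + pi_$counts,
                       total = as.integer(n_seeds),
                       rewards = pm$rewards,
                       probabilities = pm$probabilities),
                  class = "spawning_plan")
      }
    })
}
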