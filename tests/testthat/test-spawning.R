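mk_cluster <- function(id = 0L, density = 1, visits = 1L,
                       emin = NA_real_, emax = NA_real_) {
  list(id = id, density = density, visit_count = visits,
       metric_min = c(energy = emin), metric_max = c(energy = emax))
}

test_that("inversely proportional reward is density over visit count", {
  expect_equal(reward_inverse(mk_cluster(density = 1, visits = 1L)), 1.0)
  expect_equal(reward_inverse(mk_cluster(density = 2, visits = 4L)), 0.5)
  # doubling C halves the reward at fixed density
  r1 <- reward_inverse(mk_cluster(density = 3, visits = 10L))
  r2 <- reward_inverse(mk_cluster(density = 3, visits = 20L))
  expect_equal(r1 / r2, 2)
})

test_that("metric rewards follow the published extrema conventions", {
  # minimize: r_i = m_max - m_i_max; clusters with m_i_max {-5, -3}
  c1 <- mk_cluster(emin = -6, emax = -5)
  c2 <- mk_cluster(emin = -4, emax = -3)
  expect_equal(reward_metric(c1, global_min = -6, global_max = -3, "minimize"), 2)
  expect_equal(reward_metric(c2, global_min = -6, global_max = -3, "minimize"), 0)

  # maximize: r_i = m_i_min - m_min with m_i_min {1, 4, 7}
  cs <- list(mk_cluster(emin = 1, emax = 2), mk_cluster(emin = 4, emax = 5),
             mk_cluster(emin = 7, emax = 9))
  r <- vapply(cs, reward_metric, numeric(1), global_min = 1, global_max = 9,
              sense = "maximize")
  expect_equal(r, c(0, 3, 6))

  # identical metric values everywhere: all rewards zero
  same <- mk_cluster(emin = 2, emax = 2)
  expect_equal(reward_metric(same, 2, 2, "maximize"), 0)
  expect_equal(reward_metric(same, 2, 2, "minimize"), 0)

  # the documented switch scores by the per-cluster best value instead
  expect_equal(reward_metric(c1, global_min = -6, global_max = -4, "minimize",
                             use_best = TRUE), 2)

  expect_error(reward_metric(mk_cluster(), 0, 1, "minimize"),
               "no recorded values")
})

test_that("allocation sums to N, is proportional, and falls back to uniform", {
  # single cluster takes everything
  p <- allocate_seeds(c(`0` = 2.5), 8, "stochastic", rng_seed = 4)
  expect_identical(unname(p$counts), 8L)
  expect_identical(p$total, 8L)

  # symmetric deterministic split
  p <- allocate_seeds(c(1, 1), 4, "deterministic")
  expect_identical(unname(p$counts), c(2L, 2L))

  # stochastic counts approach N * p within 3 binomial standard deviations
  p <- allocate_seeds(c(3, 1), 40000, "stochastic", rng_seed = 123)
  expect_identical(sum(p$counts), 40000L)
  sd1 <- sqrt(40000 * 0.75 * 0.25)
  expect_lt(abs(p$counts[[1]] - 30000), 3 * sd1)

  # all-zero rewards: uniform fallback
  p <- allocate_seeds(c(0, 0, 0, 0), 8, "deterministic")
  expect_identical(unname(p$counts), rep(2L, 4))
  expect_equal(unname(p$probabilities), rep(0.25, 4))

  # reproducibility under a fixed seed
  p1 <- allocate_seeds(c(2, 1, 5), 50, "stochastic", rng_seed = 77)
  p2 <- allocate_seeds(c(2, 1, 5), 50, "stochastic", rng_seed = 77)
  expect_identical(p1$counts, p2$counts)

  expect_error(allocate_seeds(c(-1, 2), 5), "invalid reward")
  expect_error(allocate_seeds(c(1, 2), 0), "invalid argument")
})

test_that("deterministic allocation is largest-remainder apportionment", {
  # exhaustive check against an independent oracle for <= 4 clusters, N <= 20
  reward_levels <- c(0.3, 1, 2, 5)
  for (k in 1:4) {
    grids <- do.call(expand.grid, rep(list(reward_levels), k))
    for (g in seq_len(nrow(grids))) {
      r <- as.numeric(grids[g, ])
      for (n in c(1:8, 13, 20)) {
        got <- allocate_seeds(r, n, "deterministic")$counts
        want <- largest_remainder_oracle(r / sum(r), n)
        expect_identical(unname(got), want)
      }
    }
  }
})

test_that("spawn strategies reduce to their limits and split seeds by epsilon", {
  frame <- tiny_frame(seed = 21)
  st <- clustering_state(frame)
  set.seed(5)
  centers <- lapply(1:4, function(i)
    conformation(matrix(rnorm(15, sd = 1), ncol = 3) +
                   matrix(c(30 * i, 0, 0), 5, 3, byrow = TRUE),
                 metrics = list(energy = -i)))
  add_conformations(st, centers)
  expect_identical(n_clusters(st), 4L)

  inv <- spawning_params("inversely_proportional")
  met <- spawning_params("metric_guided", metric_name = "energy",
                         metric_sense = "minimize")
  e1 <- spawning_params("epsilon_greedy", epsilon = 1)
  e0 <- spawning_params("epsilon_greedy", epsilon = 0)

  expect_identical(spawn(st, e1, 16, rng_seed = 3)$counts,
                   spawn(st, inv, 16, rng_seed = 3)$counts)
  expect_identical(spawn(st, e0, 16, rng_seed = 3)$counts,
                   spawn(st, met, 16, rng_seed = 3)$counts)

  # epsilon = 0.25, N = 8: 6 metric-guided + 2 inverse seeds (half-up rounding)
  e25 <- spawning_params("epsilon_greedy", epsilon = 0.25,
                         allocation_mode = "deterministic")
  metd <- spawning_params("metric_guided", allocation_mode = "deterministic")
  invd <- spawning_params("inversely_proportional",
                          allocation_mode = "deterministic")
  got <- spawn(st, e25, 8, rng_seed = 1)$counts
  want <- spawn(st, metd, 6, rng_seed = 1)$counts +
    spawn(st, invd, 2, rng_seed = 1)$counts
  expect_identical(got, want)
  expect_identical(sum(got), 8L)

  # plans always cover every cluster and sum to N
  pl <- spawn(st, inv, 37, rng_seed = 10)
  expect_identical(sum(pl$counts), 37L)
  expect_identical(names(pl$counts), as.character(0:3))
})

test_that("iterated inverse spawning balances visit counts on a 2-cluster chain", {
  # Two clusters with equal densities; spawned trajectories always stay in
  # their cluster, so each epoch adds the allocated counts to the visits.
  # The 1/C reward drives the visit-count ratio to the density ratio (one).
  C <- c(1, 100)  # strongly unbalanced start
  set.seed(2024)
  for (epoch in 1:200) {
    r <- vapply(1:2, function(i)
      reward_inverse(mk_cluster(density = 1, visits = C[i])), numeric(1))
    plan <- allocate_seeds(r, 10, "stochastic", rng_seed = epoch)
    C <- C + unname(plan$counts)
  }
  expect_lt(abs(C[1] / C[2] - 1), 0.05)
})
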