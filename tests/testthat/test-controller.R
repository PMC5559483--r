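# a sampler that never moves: returns l copies of the seed conformation
frozen_sampler <- function(seed_conf, l, rng_seed) {
  lapply(seq_len(l), function(j)
    conformation(seed_conf$coords, step = j,
                 metrics = list(energy = 0,
                                rmsd_to_native = NA_real_)))
}

small_system <- function(seed = 1) build_toy_system(seed)

test_that("epoch bookkeeping: N x l conformations per epoch, consecutive steps", {
  sys <- small_system()
  par <- adaptive_params(3, steps_per_epoch = 4, max_total_steps = 12,
                         master_seed = 5)
  rec <- run_adaptive(toy_sampler(sys), sys, par)
  expect_length(rec$epochs, 3)  # 12 / 4
  for (e in seq_along(rec$epochs)) {
    expect_length(rec$epochs[[e]], 3)
    for (t in seq_along(rec$epochs[[e]])) {
      traj <- rec$epochs[[e]][[t]]
      expect_length(traj, 4)
      expect_identical(vapply(traj, `[[`, integer(1), "step"),
                       as.integer((e - 1) * 4 + 1:4))
      expect_identical(vapply(traj, `[[`, integer(1), "epoch"),
                       rep(as.integer(e - 1), 4))
    }
  }
  # total conformations = N * l * epochs
  expect_identical(rec$state$n_processed, 3L * 4L * 3L)
})

test_that("a sampler that never moves yields one cluster that takes all seeds", {
  sys <- small_system()
  par <- adaptive_params(4, steps_per_epoch = 4, max_total_steps = 20,
                         master_seed = 2)
  rec <- run_adaptive(frozen_sampler, sys, par)
  expect_identical(n_clusters(rec$state), 1L)
  for (pl in rec$plans) {
    if (is.null(pl)) next
    expect_identical(unname(pl$counts), 4L)
  }
  expect_true(is.na(rec$binding_step))
  expect_identical(binding_time(rec, native = sys$native_pose, cap = 3000L),
                   3000L)
})

test_that("runs are bit-identical under the same master seed", {
  sys <- small_system()
  for (ctor in list(run_adaptive, run_independent)) {
    par <- adaptive_params(4, steps_per_epoch = 4, max_total_steps = 24,
                           master_seed = 11)
    r1 <- ctor(toy_sampler(sys), sys, par)
    r2 <- ctor(toy_sampler(sys), sys, par)
    expect_identical(rapply(r1$epochs, identity, how = "list"),
                     rapply(r2$epochs, identity, how = "list"))
    expect_identical(lapply(r1$plans, `[[`, "counts"),
                     lapply(r2$plans, `[[`, "counts"))
    expect_identical(r1$binding_step, r2$binding_step)
    if (!is.null(r1$state))
      expect_identical(cluster_table(r1$state), cluster_table(r2$state))
  }
})

test_that("adaptive and independent arms agree over epoch 0 at matched seeds", {
  sys <- small_system()
  par <- adaptive_params(3, steps_per_epoch = 4, max_total_steps = 8,
                         master_seed = 31)
  ra <- run_adaptive(toy_sampler(sys), sys, par)
  ri <- run_independent(toy_sampler(sys), sys, par)
  expect_identical(lapply(ra$epochs[[1]], function(tr) lapply(tr, `[[`, "coords")),
                   lapply(ri$epochs[[1]], function(tr) lapply(tr, `[[`, "coords")))
})

test_that("samplers violating the trajectory-length contract are rejected", {
  sys <- small_system()
  bad <- function(seed_conf, l, rng_seed) list(seed_conf)
  par <- adaptive_params(2, steps_per_epoch = 4, max_total_steps = 8)
  expect_error(run_adaptive(bad, sys, par), "contract violation")
})

test_that("binding time is the first sub-cutoff step, capped when absent", {
  mk_rec <- function(rmsd_seqs, l = 3L) {
    epochs <- list(lapply(seq_along(rmsd_seqs), function(t) {
      lapply(seq_len(l), function(j)
        conformation(matrix(j, 1, 3), trajectory = t - 1L, step = j,
                     metrics = list(rmsd_to_native = rmsd_seqs[[t]][j])))
    }))
    structure(list(epochs = epochs, plans = list(), state = NULL,
                   binding_step = NA_integer_,
                   params = NULL, mode = "independent"),
              class = "run_record")
  }
  # RMSD sequence (5.0, 3.0, 2.4) with cutoff 2.5: first binding at step 3
  expect_identical(binding_time(mk_rec(list(c(5, 3, 2.4))), cutoff = 2.5), 3L)
  # nothing below the cutoff: assigned the cap
  expect_identical(binding_time(mk_rec(list(c(5, 4, 3))), cutoff = 2.5,
                                cap = 3000L), 3000L)
  # already bound at the first step
  expect_identical(binding_time(mk_rec(list(c(1, 5, 5))), cutoff = 2.5), 1L)

  # monotone under union of trajectories: an extra explorer can only find
  # binding earlier or at the same step
  r1 <- mk_rec(list(c(5, 3, 2.4)))
  r2 <- mk_rec(list(c(5, 3, 2.4), c(5, 2.0, 5)))
  expect_lte(binding_time(r2), binding_time(r1))
})

test_that("the benchmark table reports repeats, means and binding counts", {
  sys <- small_system()
  tab <- benchmark_binding(toy_sampler, sys, n_grid = 2L, repeats = 3L,
                           strategies = c("independent",
                                          "inversely_proportional"),
                           base_seed = 4L, max_total_steps = 40L)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$repeats, c(3L, 3L))
  times <- attr(tab, "times")
  expect_length(times$independent_N2, 3)
  expect_equal(tab$mean_steps[1], mean(times$independent_N2))
  expect_true(all(tab$n_binding_events <= 3))

  # the same arm at the same seeds reproduces exactly
  tab2 <- benchmark_binding(toy_sampler, sys, n_grid = 2L, repeats = 3L,
                            strategies = "independent",
                            base_seed = 4L, max_total_steps = 40L)
  expect_identical(attr(tab2, "times")$independent_N2, times$independent_N2)
})
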