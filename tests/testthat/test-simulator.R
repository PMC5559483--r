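test_that("toy system construction is deterministic and satisfies its invariants", {
  s1 <- build_toy_system(3)
  s2 <- build_toy_system(3)
  expect_identical(s1$surface_points, s2$surface_points)
  expect_identical(s1$receptor$calpha_coords, s2$receptor$calpha_coords)
  expect_identical(s1$native_pose$coords, s2$native_pose$coords)

  s3 <- build_toy_system(4)
  expect_false(identical(s1$surface_points, s3$surface_points))

  # contact bands: native buried, initial solvent-exposed
  expect_gt(contact_ratio(s1$native_pose, s1$receptor), 1)
  expect_lte(contact_ratio(s1$initial_pose, s1$receptor), 0.5)

  # initial pose starts far from the native pose
  expect_gte(centroid_distance(s1$initial_pose, s1$native_pose), 15)

  # energy ordering: native < decoy < bulk
  offs <- sweep(s1$native_pose$coords, 2, colMeans(s1$native_pose$coords), "-")
  decoy_pose <- sweep(offs, 2, s1$decoy_center, "+")
  e <- c(native = toy_energy(s1$native_pose, s1),
         decoy = toy_energy(decoy_pose, s1),
         bulk = toy_energy(s1$initial_pose, s1))
  expect_true(e["native"] < e["decoy"] && e["decoy"] < e["bulk"])
})

test_that("the energy surface is minimized at the native pose (grid oracle)", {
  sys <- build_toy_system(1)
  offs <- sweep(sys$native_pose$coords, 2,
                colMeans(sys$native_pose$coords), "-")
  # ~10^4-point grid scan of centroid positions in the accessible region
  gx <- seq(-8, 8, length.out = 20)
  gz <- seq(-4, 16, length.out = 25)
  grid <- as.matrix(expand.grid(x = gx, y = gx, z = gz))
  en <- apply(grid, 1, function(p) toy_energy(sweep(offs, 2, p, "+"), sys))
  best <- grid[which.min(en), ]
  expect_lt(sqrt(sum((best - sys$native_center)^2)), 1.0)

  # far from the receptor and both wells (but inside the confinement
  # sphere) only the Gaussian tails of the wells and barrier dome remain
  far <- sweep(offs, 2, c(0, -7, 17), "+")
  expect_lt(abs(toy_energy(far, sys)), 0.01)
})

test_that("exposure is the documented contact-based surrogate", {
  frame1 <- receptor_frame(matrix(c(1e6, 1e6, 1e6), 1))
  fake <- list(receptor = frame1)
  bulk <- matrix(0, 5, 3)
  expect_equal(exposure(bulk, fake), 1.0)

  # c = 1: one alpha carbon within 8 A of each of the 5 atoms -> exposure 0.5
  frame2 <- receptor_frame(matrix(c(0, 0, 2), 1))
  expect_equal(contact_ratio(bulk, frame2), 1)
  expect_equal(exposure(bulk, list(receptor = frame2)), 0.5)

  # saturation: c >= 2 -> exposure 0
  frame3 <- receptor_frame(rbind(c(0, 0, 2), c(0, 0, -2), c(0, 2, 0)))
  expect_gte(contact_ratio(bulk, frame3), 2)
  expect_equal(exposure(bulk, list(receptor = frame3)), 0)

  # monotone non-increasing in the contact ratio on the real system
  sys <- build_toy_system(1)
  zs <- seq(20, 0, by = -2)
  cs <- vapply(zs, function(z)
    contact_ratio(sweep(sys$native_pose$coords, 2, c(0, 0, z), "+"),
                  sys$receptor), numeric(1))
  es <- vapply(zs, function(z)
    exposure(sweep(sys$native_pose$coords, 2, c(0, 0, z), "+"), sys),
    numeric(1))
  expect_true(all(diff(es[order(cs)]) <= 1e-12))
})

test_that("the Metropolis rule accepts downhill always and uphill at exp(-dE/kT)", {
  # downhill proposals never consult the RNG
  set.seed(1)
  expect_true(all(metropolis_accept(c(-5, -0.1, 0), 1)))

  # dE = kT: long-run acceptance ~ exp(-1) within 3 sigma over 1e5 trials
  set.seed(42)
  acc <- metropolis_accept(rep(1, 1e5), 1)
  p <- exp(-1)
  expect_lt(abs(mean(acc) - p), 3 * sqrt(p * (1 - p) / 1e5))

  # zero-temperature limit: uphill moves are never accepted
  set.seed(7)
  expect_false(any(metropolis_accept(rep(0.5, 100), 1e-12)))
})

test_that("trajectories have exact length, filled metrics, and are reproducible", {
  sys <- build_toy_system(1)
  tr <- mc_trajectory(sys$initial_pose, sys, move_params(), l = 6, rng_seed = 9)
  expect_length(tr, 6)
  for (cf in tr) {
    expect_s3_class(cf, "conformation")
    expect_true(is.finite(cf$metrics$energy))
    expect_equal(cf$metrics$rmsd_to_native,
                 ligand_rmsd(cf, sys$native_pose))
  }
  tr2 <- mc_trajectory(sys$initial_pose, sys, move_params(), l = 6, rng_seed = 9)
  expect_identical(lapply(tr, `[[`, "coords"), lapply(tr2, `[[`, "coords"))
  tr3 <- mc_trajectory(sys$initial_pose, sys, move_params(), l = 6, rng_seed = 10)
  expect_false(identical(lapply(tr, `[[`, "coords"),
                         lapply(tr3, `[[`, "coords")))

  # near-zero temperature from the energy minimum: every proposal is uphill
  # and rejected, so the snapshot repeats the seed conformation
  cold <- build_toy_system(1, kT = 1e-9)
  trc <- mc_trajectory(cold$native_pose, cold, move_params(), l = 5,
                       rng_seed = 3)
  for (cf in trc) expect_equal(cf$coords, cold$native_pose$coords)
})

test_that("a long 1-D chain reproduces Boltzmann two-well occupancies", {
  # 1-D reduction along the channel axis of a tame two-well variant:
  # shallow wells and a low dome so the chain crosses many times
  # on-axis decoy, no baffles: a clean two-well profile along the z axis
  sys <- build_toy_system(1, native_depth = 3, decoy_depth = 2,
                          barrier_height = 1, baffle_z = numeric(0),
                          decoy_center = c(0, 0, 11.8))
  offs <- sweep(sys$native_pose$coords, 2,
                colMeans(sys$native_pose$coords), "-")
  e_of <- function(z) toy_energy(sweep(offs, 2, c(0, 0, z), "+"), sys)

  lo <- -2; hi <- 15; split <- 5.8  # split near the dome top
  set.seed(1)
  z <- 0; ez <- e_of(z)
  n_steps <- 150000
  burn_in <- 5000
  occ_a <- 0L; occ_b <- 0L
  for (i in seq_len(n_steps)) {
    zp <- z + runif(1, -1.2, 1.2)
    if (zp > lo && zp < hi) {
      ep <- e_of(zp)
      if (metropolis_accept(ep - ez, sys$kT)) { z <- zp; ez <- ep }
    }
    if (i > burn_in) {
      if (z < split) occ_a <- occ_a + 1L else occ_b <- occ_b + 1L
    }
  }
  grid <- seq(lo, hi, by = 0.02)
  w <- exp(-vapply(grid, e_of, numeric(1)) / sys$kT)
  boltz <- sum(w[grid < split]) / sum(w[grid >= split])
  expect_lt(abs((occ_a / occ_b) / boltz - 1), 0.10)
})
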