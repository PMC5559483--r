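# Toy rigid-body protein-ligand Monte Carlo.
#
# The receptor is a fixed rigid body represented at two resolutions: a dense
# point cloud (all-atom-like surface, used for soft-core sterics) shaped as a
# spherical shell with an aperture along +z continued by a walled entry
# tunnel whose mouth hosts a metastable vestibule (decoy) site, and a sparse
# subset of alpha-carbon sites (used for protein-ligand contact counting, as
# contacts are defined against alpha carbons only). The ligand is a small
# rigid body (centroid plus tetrahedral offsets). The energy surface is two
# attractive Gaussian wells (native pose at the pocket center, shallower
# decoy at the tunnel mouth), a smooth desolvation-like barrier dome filling
# the tunnel, a pairwise soft-core repulsion against receptor points, and a
# harmonic wall confining the ligand centroid to a sphere -- mirroring the
# usual practice of restraining the ligand to a sphere spanning the initial
# and bound poses.

#' Build the synthetic protein-ligand toy system
#'
#' Deterministically constructs (from `build_seed`) a synthetic receptor and
#' ligand that reproduce the statistical structure adaptive sampling
#' exploits: a buried native pose reachable only through a narrow walled
#' tunnel that carries a smooth desolvation-like energy barrier, a metastable
#' vestibule (decoy) sub-pocket at the tunnel mouth where unassisted
#' trajectories pool, and contact ratios that span both the solvent band
#' (initial pose, `c <= 0.5`) and the protein frame (native pose, `c > 1`).
#'
#' Geometry (defaults): pocket shell of `n_shell` points at `pocket_radius`
#' from the origin with points within `aperture_deg` of +z removed (the
#' aperture); a tunnel of `n_channel` points on a cylinder of radius
#' `channel_radius` from `channel_bottom` to `channel_top` along +z,
#' continuing the aperture outward; the decoy well at `decoy_center` sits at
#' the tunnel mouth (its walls are the decoy sub-pocket); native ligand pose
#' at the origin; initial pose at `(0, 0, initial_z)`, about 20 A from the
#' native pose. The barrier dome is a Gaussian bump in z centered mid-tunnel
#' with lateral Gaussian falloff, so that entering the pocket requires a
#' staged uphill traversal the energy gradient constantly undoes for a free
#' walker. The confinement sphere is centered midway between the native and
#' initial poses.
#'
#' @param build_seed Integer seed for the jitter applied to receptor points.
#' @param n_atoms Ligand heavy atoms (centroid + offsets), default 5.
#' @param atom_spread Radial extent of the ligand offsets in angstroms.
#' @param pocket_radius,n_shell,aperture_deg Pocket shell geometry (dense
#'   surface cloud).
#' @param n_shell_ca,n_tunnel_ca Number of alpha-carbon sites on the shell
#'   and around the tunnel; contacts (and hence cluster thresholds,
#'   densities and exposure) are counted against these sparse sites only,
#'   so the contact ratio decays from the protein frame (`c > 1`) through
#'   the intermediate bands to the solvent (`c <= 0.5`) over a few
#'   angstroms, as it does for a real receptor.
#' @param channel_radius,channel_bottom,channel_top,n_channel Entry tunnel
#'   geometry (cylinder wall of receptor points continuing the aperture).
#' @param baffle_z Heights of two half-disc baffles inside the tunnel
#'   (alternating sides), forcing an S-shaped passage: a concerted straight
#'   run cannot thread the tunnel, while short threshold-sized hops around
#'   the baffle edges can.
#' @param barrier_height,barrier_center,barrier_width,barrier_lateral Smooth
#'   desolvation-like barrier dome inside the tunnel: height (kT surrogate
#'   units), center and width along z (angstroms), lateral Gaussian width.
#' @param decoy_center Center of the metastable vestibule well at the tunnel
#'   mouth.
#' @param initial_z Centroid z of the initial (bulk) pose; must put the
#'   initial pose at least 15 A from the native centroid.
#' @param native_depth,decoy_depth Well depths, kcal/mol surrogate
#'   (native deeper than decoy).
#' @param native_width,decoy_width Gaussian well widths in angstroms.
#' @param repulsion_radius Soft-core repulsion radius in angstroms.
#' @param repulsion_strength Repulsion prefactor.
#' @param kT Temperature factor in the same surrogate units.
#' @param box_radius Confinement sphere radius in angstroms.
#' @return An object of class `"toy_system"` with fields `receptor`
#'   (a [receptor_frame()]), `native_pose`, `initial_pose` (both
#'   [conformation()]s) and the energy parameters.
#' @export
#' @examples
#' sys <- build_toy_system(1)
#' contact_ratio(sys$native_pose, sys$receptor)   # > 1, protein frame
#' contact_ratio(sys$initial_pose, sys$receptor)  # 0, bulk
build_toy_system <- function(build_seed = 1L,
                             n_atoms = 5L,
                             atom_spread = 0.8,
                             pocket_radius = 6.0,
                             n_shell = 200L,
                             n_shell_ca = 14L,
                             n_tunnel_ca = 6L,
                             aperture_deg = 30,
                             channel_radius = 4.2,
                             channel_bottom = 4.6,
                             channel_top = 13.5,
                             n_channel = 100L,
                             barrier_height = 4.5,
                             barrier_center = 7.5,
                             baffle_z = c(10.2, 5.8),
                             barrier_width = 3.0,
                             barrier_lateral = 3.0,
                             decoy_center = c(6.5, 0, 9.5),
                             initial_z = 20.0,
                             native_depth = 8.0,
                             decoy_depth = 4.0,
                             native_width = 1.8,
                             decoy_width = 2.8,
                             repulsion_radius = 2.0,
                             repulsion_strength = 10.0,
                             kT = 1.0,
                             box_radius = 10.5) {
  stopifnot(n_atoms >= 1L, atom_spread > 0, pocket_radius > 0,
            length(decoy_center) == 3L,
            aperture_deg > 0, aperture_deg < 90,
            channel_radius > 0, channel_top > channel_bottom,
            barrier_height >= 0, barrier_width > 0, barrier_lateral > 0,
            native_depth > decoy_depth, decoy_depth > 0,
            native_width > 0, decoy_width > 0,
            repulsion_radius > 0, kT > 0, box_radius > 0)

  pts <- with_seed(mix_seed(build_seed, 101L), {
    shell <- fibonacci_sphere(n_shell) * pocket_radius
    shell <- shell + matrix(stats::rnorm(length(shell), sd = 0.15),
                            ncol = 3)  # break exact symmetry
    keep <- shell[, 3] / sqrt(rowSums(shell^2)) < cos(aperture_deg * pi / 180)
    shell <- shell[keep, , drop = FALSE]
    n_rings <- max(2L, round(n_channel / 10))
    zs <- seq(channel_bottom, channel_top, length.out = n_rings)
    per_ring <- ceiling(n_channel / n_rings)
    tube <- do.call(rbind, lapply(seq_len(n_rings), function(i) {
      a <- 2 * pi * (seq_len(per_ring) - 1) / per_ring + i * pi / per_ring
      cbind(channel_radius * cos(a), channel_radius * sin(a),
            rep(zs[i], per_ring))
    }))
    tube <- tube + matrix(stats::rnorm(length(tube), sd = 0.1), ncol = 3)
    # half-disc baffles on alternating sides of the tunnel axis
    baffles <- NULL
    if (length(baffle_z)) {
      for (i in seq_along(baffle_z)) {
        side <- if (i %% 2L == 1L) 1 else -1
        for (r in c(1.2, 2.4)) {
          na <- max(3L, round(pi * r / 1.2))
          a <- seq(-pi / 2 + 0.3, pi / 2 - 0.3, length.out = na)
          baffles <- rbind(baffles,
                           cbind(side * r * cos(a), r * sin(a),
                                 rep(baffle_z[i], na)))
        }
      }
      baffles <- baffles + matrix(stats::rnorm(length(baffles), sd = 0.08),
                                  ncol = 3)
    }
    tube <- rbind(tube, baffles)
    # sparse alpha-carbon sites: a coarse shell lattice plus a tunnel collar
    ca_shell <- fibonacci_sphere(n_shell_ca) * pocket_radius
    ca_shell <- ca_shell[ca_shell[, 3] / pocket_radius <
                           cos(aperture_deg * pi / 180), , drop = FALSE]
    ca_ang <- 2 * pi * (seq_len(n_tunnel_ca) - 1) / n_tunnel_ca
    ca_tube <- cbind((channel_radius + 1) * cos(ca_ang),
                     (channel_radius + 1) * sin(ca_ang),
                     rep(c(channel_bottom + 2, channel_top - 1),
                         length.out = n_tunnel_ca))
    list(surface = rbind(shell, tube), calpha = rbind(ca_shell, ca_tube))
  })
  receptor <- receptor_frame(pts$calpha, contact_cutoff = 8.0)

  # rigid ligand template: centroid + regular offsets, zero-mean
  offsets <- ligand_template(n_atoms, atom_spread)
  native_center <- c(0, 0, 0)
  initial_center <- c(0, 0, initial_z)
  native_pose <- conformation(sweep(offsets, 2, native_center, "+"))
  initial_pose <- conformation(sweep(offsets, 2, initial_center, "+"))

  sys <- structure(list(
    receptor = receptor,
    surface_points = pts$surface,
    surface_norm2 = rowSums(pts$surface^2),
    max_atom_radius = max(sqrt(rowSums(offsets^2))),
    native_pose = native_pose,
    initial_pose = initial_pose,
    native_center = native_center,
    decoy_center = decoy_center,
    box_center = (native_center + initial_center) / 2,
    box_radius = box_radius,
    native_depth = native_depth, decoy_depth = decoy_depth,
    native_width = native_width, decoy_width = decoy_width,
    barrier_height = barrier_height, barrier_center = barrier_center,
    barrier_width = barrier_width, barrier_lateral = barrier_lateral,
    repulsion_radius = repulsion_radius,
    repulsion_strength = repulsion_strength,
    kT = kT,
    build_seed = as.integer(build_seed)),
    class = "toy_system")

  # construction invariants
  d0 <- sqrt(sum((colMeans(native_pose$coords) -
                    colMeans(initial_pose$coords))^2))
  if (d0 < 15)
    stop("toy system construction error: initial pose closer than 15 A to native")
  e_nat <- toy_energy(native_pose, sys)
  e_dec <- toy_energy(conformation(sweep(offsets, 2, sys$decoy_center, "+")), sys)
  e_bulk <- toy_energy(initial_pose, sys)
  if (!(e_nat < e_dec && e_dec < e_bulk))
    stop(sprintf(paste0("toy system construction error: energies not ordered ",
                        "native (%.2f) < decoy (%.2f) < bulk (%.2f)"),
                 e_nat, e_dec, e_bulk))
  sys
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf(paste0("<toy_system> %d surface points (%d alpha carbons), ",
                     "%d ligand atoms, wells %.1f/%.1f, kT %.2f\n"),
              nrow(x$surface_points), nrow(x$receptor$calpha_coords),
              nrow(x$native_pose$coords),
              x$native_depth, x$decoy_depth, x$kT))
  invisible(x)
}

# near-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

# zero-mean rigid ligand template: first atom at the centroid, the rest on a
# sphere of radius `spread` at near-tetrahedral directions
ligand_template <- function(n_atoms, spread) {
  if (n_atoms == 1L) return(matrix(0, 1, 3))
  dirs <- fibonacci_sphere(n_atoms - 1L) * spread
  offs <- rbind(matrix(0, 1, 3), dirs)
  sweep(offs, 2, colMeans(offs), "-")
}

#' Toy interaction energy of a ligand pose
#'
#' Sum of two attractive Gaussian wells evaluated at the ligand centroid
#' (native and decoy), the desolvation-like barrier dome filling the entry
#' tunnel, a pairwise soft-core repulsion `k * (1 - d / r_rep)^2` over
#' (receptor point, ligand atom) pairs closer than the repulsion radius, and
#' a harmonic wall outside the confinement sphere. Far from all receptor points and wells (and inside the sphere)
#' the energy is zero. Stands in for the protein-ligand interaction energy
#' used for pose discrimination; by construction it is minimized at the
#' native pose.
#'
#' @param conf A [conformation()] with the system's ligand atom count.
#' @param system A [build_toy_system()] object.
#' @return Energy in kcal/mol surrogate units.
#' @export
toy_energy <- function(conf, system) {
  lig <- coords_of(conf)
  cen <- colMeans(lig)
  d_nat2 <- sum((cen - system$native_center)^2)
  d_dec2 <- sum((cen - system$decoy_center)^2)
  e <- -system$native_depth * exp(-d_nat2 / (2 * system$native_width^2)) -
        system$decoy_depth * exp(-d_dec2 / (2 * system$decoy_width^2))
  # desolvation-like dome along the tunnel, with lateral falloff
  e <- e + system$barrier_height *
    exp(-(cen[3] - system$barrier_center)^2 / (2 * system$barrier_width^2)) *
    exp(-(cen[1]^2 + cen[2]^2) / (2 * system$barrier_lateral^2))
  rp <- system$surface_points
  rr <- system$repulsion_radius
  # prefilter surface points by centroid distance: only points within
  # rr + ligand radius of the centroid can repel any atom
  reach <- (rr + system$max_atom_radius)^2
  cen2 <- sum(cen^2)
  near <- which(system$surface_norm2 + cen2 - 2 * drop(rp %*% cen) < reach)
  if (length(near)) {
    rpn <- rp[near, , drop = FALSE]
    d2 <- outer(rowSums(lig^2), rowSums(rpn^2), "+") - 2 * tcrossprod(lig, rpn)
    close <- d2 < rr^2
    if (any(close)) {
      d <- sqrt(pmax(d2[close], 0))
      e <- e + system$repulsion_strength * sum((1 - d / rr)^2)
    }
  }
  d_box <- sqrt(sum((cen - system$box_center)^2))
  if (d_box > system$box_radius)
    e <- e + 10 * (d_box - system$box_radius)^2
  e
}

#' Surrogate solvent exposure of a pose
#'
#' A contact-based stand-in for the relative solvent-accessible surface
#' area: `1 - min(c / c_sat, 1)` with saturation at `c_sat = 2` contacts per
#' ligand atom. Equals 1 in the bulk, decreases monotonically with the
#' contact ratio, and reaches 0 when the ligand is deeply buried. Gates the
#' translation magnitude of Monte Carlo moves.
#'
#' @param conf A [conformation()].
#' @param system A [build_toy_system()] object.
#' @param c_sat Contact ratio at which exposure saturates to 0.
#' @return Exposure in `[0, 1]`.
#' @export
exposure <- function(conf, system, c_sat = 2.0) {
  1 - min(contact_ratio(conf, system$receptor) / c_sat, 1)
}

#' Monte Carlo move parameters
#'
#' Rigid-body proposal rules for the toy sampler: large (3 A) translations
#' while the ligand is solvent exposed (exposure above `exposure_cutoff`),
#' short translations drawn uniformly from `buried_translation_range` in the
#' protein vicinity; the translation direction is redrawn every
#' `direction_persistence` steps; each proposal also rotates the ligand by a
#' uniform angle in `rotation_range` (degrees) about a random axis through
#' its centroid.
#'
#' @param exposed_translation Translation magnitude (A) for exposed poses.
#' @param buried_translation_range Two-element range (A) for buried poses.
#' @param exposure_cutoff Exposure above which the large translation is used.
#' @param rotation_range Two-element rotation angle range in degrees.
#' @param direction_persistence Steps between redraws of the translation
#'   direction.
#' @return An object of class `"move_params"`.
#' @export
move_params <- function(exposed_translation = 3.0,
                        buried_translation_range = c(0.75, 1.5),
                        exposure_cutoff = 0.6,
                        rotation_range = c(20, 60),
                        direction_persistence = 4L) {
  stopifnot(exposed_translation > 0,
            length(buried_translation_range) == 2L,
            diff(buried_translation_range) >= 0,
            buried_translation_range[1] > 0,
            length(rotation_range) == 2L, diff(rotation_range) >= 0,
            direction_persistence >= 1L)
  structure(list(exposed_translation = exposed_translation,
                 buried_translation_range = as.numeric(buried_translation_range),
                 exposure_cutoff = exposure_cutoff,
                 rotation_range = as.numeric(rotation_range),
                 direction_persistence = as.integer(direction_persistence)),
            class = "move_params")
}

#' Metropolis acceptance rule
#'
#' Accepts a proposal with probability `min(1, exp(-delta_e / kT))`.
#' Vectorised over `delta_e`; draws its uniforms from the current RNG stream.
#'
#' @param delta_e Energy change(s) of the proposal(s).
#' @param kT Temperature factor (> 0).
#' @return Logical vector of acceptances.
#' @export
metropolis_accept <- function(delta_e, kT) {
  stopifnot(kT > 0)
  accept <- delta_e <= 0
  uphill <- which(!accept)
  if (length(uphill))
    accept[uphill] <- stats::runif(length(uphill)) < exp(-delta_e[uphill] / kT)
  accept
}

# uniform random rotation matrix: uniform axis, angle in [lo, hi] degrees
random_rotation <- function(lo, hi) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, lo, hi) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

#' Run one toy Monte Carlo trajectory
#'
#' Fulfils the sampler contract of [run_adaptive()]: from a seed
#' conformation, performs `l` Metropolis steps and returns exactly `l`
#' snapshot conformations. Each step proposes a rigid translation (magnitude
#' gated by [exposure()]) plus a rigid rotation about the ligand centroid and
#' accepts with probability `min(1, exp(-dE/kT))`; on rejection the previous
#' conformation is repeated as that step's snapshot, so trajectories always
#' have length `l`. The metrics `"energy"` and `"rmsd_to_native"` are filled
#' on every snapshot.
#'
#' @param seed_conf Starting [conformation()].
#' @param system A [build_toy_system()] object.
#' @param moves A [move_params()].
#' @param l Number of steps (and snapshots).
#' @param rng_seed Integer seed; all randomness in the trajectory flows from
#'   it.
#' @return List of `l` [conformation()] objects (indices are filled by the
#'   controller).
#' @export
mc_trajectory <- function(seed_conf, system, moves = move_params(), l,
                          rng_seed = 0L) {
  stopifnot(l >= 1L, inherits(system, "toy_system"),
            inherits(moves, "move_params"))
  with_seed(rng_seed, {
    cur <- coords_of(seed_conf)
    e_cur <- toy_energy(cur, system)
    native <- system$native_pose$coords
    n <- nrow(cur)
    out <- vector("list", l)
    direction <- NULL
    for (step in seq_len(l)) {
      if (is.null(direction) ||
          (step - 1L) %% moves$direction_persistence == 0L) {
        direction <- stats::rnorm(3)
        direction <- direction / sqrt(sum(direction^2))
      }
      exp_cur <- exposure(cur, system)
      mag <- if (exp_cur > moves$exposure_cutoff) moves$exposed_translation
             else stats::runif(1, moves$buried_translation_range[1],
                               moves$buried_translation_range[2])
      cen <- colMeans(cur)
      R <- random_rotation(moves$rotation_range[1], moves$rotation_range[2])
      prop <- (cur - matrix(cen, n, 3, byrow = TRUE)) %*% t(R) +
        matrix(cen + mag * direction, n, 3, byrow = TRUE)
      e_prop <- toy_energy(prop, system)
      if (metropolis_accept(e_prop - e_cur, system$kT)) {
        cur <- prop
        e_cur <- e_prop
      }
      d <- cur - native
      out[[step]] <- structure(
        list(coords = cur, epoch = 0L, trajectory = 0L, step = step,
             metrics = list(energy = e_cur,
                            rmsd_to_native = sqrt(sum(d * d) / n)),
             origin_cluster = NA_integer_),
        class = "conformation")
    }
    out
  })
}

#' Energy profile along the channel axis
#'
#' One-dimensional reduction of [toy_energy()]: the energy of the ligand in
#' its native orientation with the centroid at `(0, 0, z)`. Used to document
#' and test the two-well structure (native well at `z = 0`, decoy well in
#' the channel) and the Boltzmann occupancy of a long Metropolis chain.
#'
#' @param system A [build_toy_system()] object.
#' @param z Numeric vector of centroid z positions (angstroms).
#' @return Numeric vector of energies.
#' @export
channel_energy_profile <- function(system, z) {
  offs <- sweep(system$native_pose$coords, 2,
                colMeans(system$native_pose$coords), "-")
  vapply(z, function(zi) {
    toy_energy(sweep(offs, 2, c(0, 0, zi), "+"), system)
  }, numeric(1))
}
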