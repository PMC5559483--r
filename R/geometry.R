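#' Ligand RMSD between two conformations
#'
#' Root-mean-square deviation over matched ligand heavy atoms, computed in
#' the shared receptor frame: no superposition and no symmetry-equivalent
#' atom remapping is performed, so the value reflects the actual displacement
#' of the ligand relative to the receptor.
#'
#' @param a,b [conformation()] objects (or bare coordinate matrices) with the
#'   same number of atoms in the same order.
#' @return RMSD in angstroms (non-negative, symmetric in its arguments).
#' @export
#' @examples
#' a <- conformation(diag(3))
#' b <- conformation(diag(3) + 1)
#' ligand_rmsd(a, b)  # sqrt(3): every atom moved by (1,1,1)
ligand_rmsd <- function(a, b) {
  pa <- coords_of(a); pb <- coords_of(b)
  check_same_atoms(pa, pb)
  d <- pa - pb
  sqrt(sum(d * d) / nrow(pa))
}

#' Centroid distance between two conformations
#'
#' Euclidean distance between the ligand centroids. By the power-mean
#' (Jensen) inequality this never exceeds [ligand_rmsd()] on the same pair,
#' so it serves as a cheap lower bound that lets the leader clustering prune
#' RMSD evaluations. Under a pure rigid translation the two quantities are
#' equal.
#'
#' @inheritParams ligand_rmsd
#' @return Centroid separation in angstroms.
#' @export
centroid_distance <- function(a, b) {
  pa <- coords_of(a); pb <- coords_of(b)
  check_same_atoms(pa, pb)
  sqrt(sum((colMeans(pa) - colMeans(pb))^2))
}

check_same_atoms <- function(pa, pb) {
  if (nrow(pa) != nrow(pb))
    stop(sprintf("atom count mismatch: %d vs %d ligand atoms",
                 nrow(pa), nrow(pb)))
  invisible(TRUE)
}

#' Protein-ligand contact ratio
#'
#' Counts (alpha carbon, ligand atom) pairs strictly closer than the frame's
#' contact cutoff and divides by the number of ligand atoms. The ratio `c` is
#' the package's proxy for landscape ruggedness: `c <= 0.5` characterises
#' solvent-exposed poses, `c > 1` poses in the protein frame.
#'
#' @param conf A [conformation()] (or coordinate matrix).
#' @param frame A [receptor_frame()].
#' @return Non-negative contact ratio (contacts per ligand atom).
#' @export
contact_ratio <- function(conf, frame) {
  stopifnot(inherits(frame, "receptor_frame"))
  lig <- coords_of(conf)
  ca <- frame$calpha_coords
  cut2 <- frame$contact_cutoff^2
  # squared pair distances via the expansion |x-y|^2 = |x|^2 + |y|^2 - 2 x.y
  d2 <- outer(rowSums(lig^2), rowSums(ca^2), "+") - 2 * tcrossprod(lig, ca)
  sum(d2 < cut2) / nrow(lig)
}

#' Contact-dependent RMSD threshold policy
#'
#' Cluster similarity thresholds are a non-increasing step function of the
#' contact ratio `c`: wide clusters in the solvent where the landscape is
#' smooth, tight clusters against the protein where ruggedness grows with the
#' number of contacts. The default table steps from 5 A in the bulk
#' (`c <= 0.5`) down to 2 A in the protein frame (`c > 1`):
#'
#' | band            | threshold |
#' |-----------------|-----------|
#' | c <= 0.5        | 5 A       |
#' | 0.5 < c <= 0.75 | 4 A       |
#' | 0.75 < c <= 1   | 3 A       |
#' | c > 1           | 2 A       |
#'
#' @param c_bounds Strictly increasing upper bounds of the bands.
#' @param thresholds Non-increasing thresholds (angstroms), one per bound.
#' @param terminal Threshold for `c` above the last bound.
#' @return An object of class `"threshold_policy"`.
#' @seealso [threshold_for()]
#' @export
threshold_policy <- function(c_bounds = c(0.5, 0.75, 1.0),
                             thresholds = c(5.0, 4.0, 3.0),
                             terminal = 2.0) {
  stopifnot(length(c_bounds) == length(thresholds), length(c_bounds) >= 1L)
  if (any(diff(c_bounds) <= 0))
    stop("c_bounds must be strictly increasing")
  all_thr <- c(thresholds, terminal)
  if (any(diff(all_thr) > 1e-12))
    stop("thresholds must be non-increasing in c")
  if (any(all_thr <= 0)) stop("thresholds must be positive")
  structure(list(c_bounds = as.numeric(c_bounds),
                 thresholds = as.numeric(thresholds),
                 terminal = as.numeric(terminal)),
            class = "threshold_policy")
}

#' Evaluate the threshold policy at a contact ratio
#'
#' @param c Non-negative contact ratio (vectorised).
#' @param policy A [threshold_policy()].
#' @return Cluster RMSD threshold(s) in angstroms.
#' @export
#' @examples
#' threshold_for(0.3, threshold_policy())  # 5 A: solvent band
#' threshold_for(1.5, threshold_policy())  # 2 A: protein frame
threshold_for <- function(c, policy = threshold_policy()) {
  stopifnot(inherits(policy, "threshold_policy"), all(c >= 0))
  vapply(c, function(ci) {
    i <- which(ci <= policy$c_bounds)
    if (length(i)) policy$thresholds[i[1L]] else policy$terminal
  }, numeric(1))
}

#' Cluster density policy
#'
#' The density `rho` weights a cluster's reward (`r = rho / C`) and encodes
#' where sampling effort should concentrate. Three modes:
#'
#' * `"constant"` — `rho = 1` everywhere (pure diffusive exploration).
#' * `"inverse_volume"` — `rho` inversely proportional to the cluster volume,
#'   with volume taken proportional to the RMSD threshold cubed:
#'   `rho = (reference_threshold / threshold)^3`. Small buried clusters get
#'   proportionally more seeds.
#' * `"contacts"` — a step-function lookup on the contact ratio (the
#'   default): density grows with the number of protein-ligand contacts, on
#'   the premise that high-contact regions are rugged, harder to sample, and
#'   should receive proportionally more seeds. Default bands:
#'   `c <= 0.5` (solvent) 1, `c <= 2` 2, `c <= 8` 4, `c > 8` (buried) 16.
#'
#' @param mode One of `"constant"`, `"inverse_volume"`, `"contacts"`.
#' @param reference_threshold Reference threshold (angstroms) assigned
#'   density 1 in `inverse_volume` mode; defaults to the largest band of the
#'   default threshold table.
#' @param c_bounds,densities,terminal_density Band table for `contacts` mode.
#' @return An object of class `"density_policy"`.
#' @seealso [density_for()]
#' @export
density_policy <- function(mode = c("contacts", "inverse_volume", "constant"),
                           reference_threshold = 5.0,
                           c_bounds = c(0.5, 2.0, 8.0),
                           densities = c(1.0, 2.0, 4.0),
                           terminal_density = 16.0) {
  mode <- match.arg(mode)
  stopifnot(reference_threshold > 0)
  if (mode == "contacts") {
    stopifnot(length(c_bounds) == length(densities))
    if (any(diff(c_bounds) <= 0)) stop("c_bounds must be strictly increasing")
    if (any(c(densities, terminal_density) <= 0))
      stop("densities must be positive")
  }
  structure(list(mode = mode,
                 reference_threshold = as.numeric(reference_threshold),
                 c_bounds = as.numeric(c_bounds),
                 densities = as.numeric(densities),
                 terminal_density = as.numeric(terminal_density)),
            class = "density_policy")
}

#' Evaluate the density policy
#'
#' @param c Contact ratio at the cluster center.
#' @param threshold Cluster RMSD threshold in angstroms.
#' @param policy A [density_policy()].
#' @return Positive density `rho`.
#' @export
#' @examples
#' density_for(0.2, 5, density_policy("constant"))        # 1
#' density_for(1.5, 2.5, density_policy("inverse_volume")) # (5/2.5)^3 = 8
#' density_for(12, 2, density_policy("contacts"))          # 16: buried band
density_for <- function(c, threshold, policy = density_policy()) {
  stopifnot(inherits(policy, "density_policy"), threshold > 0)
  switch(policy$mode,
    constant = 1.0,
    inverse_volume = (policy$reference_threshold / threshold)^3,
    contacts = {
      i <- which(c <= policy$c_bounds)
      if (length(i)) policy$densities[i[1L]] else policy$terminal_density
    })
}
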