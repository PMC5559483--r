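#' Ligand snapshot
#'
#' A conformation is one snapshot of the ligand: its heavy-atom coordinates in
#' the shared receptor frame, bookkeeping indices locating it in the sampling
#' run (epoch, trajectory, step), and a cache of metric values (for example
#' `"energy"` or `"rmsd_to_native"`).
#'
#' Coordinates are Cartesian angstroms. No superposition is ever applied:
#' all conformations are assumed to live in the fixed frame of the receptor,
#' so the ligand RMSD between two conformations measures genuine displacement
#' and not internal rearrangement alone.
#'
#' @param coords Numeric matrix, one row per ligand heavy atom, three columns
#'   (x, y, z in angstroms). Atom order is significant and must be consistent
#'   across all conformations that are compared.
#' @param epoch Integer >= 0, adaptive epoch the snapshot belongs to.
#' @param trajectory Integer >= 0, index of the explorer within its epoch.
#' @param step Integer >= 1, cumulative per-trajectory step index (1-based).
#' @param metrics Named list of finite numeric scalars. A metric, once set
#'   for a name, is immutable (see [set_metric()]).
#' @param origin_cluster Integer id of the cluster the trajectory was spawned
#'   from, or `NA` for trajectories started from the initial structure.
#'
#' @return An object of class `"conformation"`.
#' @seealso [ligand_rmsd()], [centroid_distance()], [contact_ratio()]
#' @export
#' @examples
#' conformation(matrix(rnorm(15), ncol = 3))
conformation <- function(coords, epoch = 0L, trajectory = 0L, step = 1L,
                         metrics = list(), origin_cluster = NA_integer_) {
  coords <- as_coord_matrix(coords)
  if (nrow(coords) == 0L)
    stop("conformation requires at least one ligand atom")
  if (!all(is.finite(coords)))
    stop("conformation coordinates must be finite")
  stopifnot(epoch >= 0L, trajectory >= 0L, step >= 1L)
  structure(
    list(coords = coords,
         epoch = as.integer(epoch),
         trajectory = as.integer(trajectory),
         step = as.integer(step),
         metrics = metrics,
         origin_cluster = as.integer(origin_cluster)),
    class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> %d atoms, epoch %d, trajectory %d, step %d\n",
              nrow(x$coords), x$epoch, x$trajectory, x$step))
  if (length(x$metrics))
    cat("  metrics:", paste(sprintf("%s=%.4g", names(x$metrics),
                                    unlist(x$metrics)), collapse = ", "), "\n")
  invisible(x)
}

#' Record a metric value on a conformation
#'
#' Metric values are write-once: re-setting an already recorded name to a
#' different value is an error, so downstream cluster extrema stay coherent.
#'
#' @param conf A [conformation()].
#' @param name Metric name.
#' @param value Finite numeric scalar.
#' @return The updated conformation.
#' @export
set_metric <- function(conf, name, value) {
  stopifnot(inherits(conf, "conformation"), is.character(name),
            length(value) == 1L, is.finite(value))
  old <- conf$metrics[[name]]
  if (!is.null(old)) {
    if (!isTRUE(all.equal(old, value)))
      stop(sprintf("metric '%s' is already set (%.6g) and is immutable", name, old))
    return(conf)
  }
  conf$metrics[[name]] <- as.numeric(value)
  conf
}

#' Fixed receptor reference frame
#'
#' The protein is represented by its alpha-carbon coordinates only; ligand
#' contacts are counted against these points with a strict distance cutoff
#' (a pair closer than `contact_cutoff` is a contact; a pair at exactly the
#' cutoff is not).
#'
#' @param calpha_coords Numeric matrix of alpha-carbon coordinates (n x 3, in
#'   angstroms).
#' @param contact_cutoff Contact distance cutoff in angstroms (default 8).
#' @return An object of class `"receptor_frame"`.
#' @export
receptor_frame <- function(calpha_coords, contact_cutoff = 8.0) {
  calpha_coords <- as_coord_matrix(calpha_coords)
  if (nrow(calpha_coords) == 0L)
    stop("receptor_frame requires at least one alpha carbon")
  if (!all(is.finite(calpha_coords)))
    stop("receptor coordinates must be finite")
  if (!(is.numeric(contact_cutoff) && length(contact_cutoff) == 1L &&
        contact_cutoff > 0))
    stop("contact_cutoff must be a positive scalar")
  structure(list(calpha_coords = calpha_coords,
                 contact_cutoff = as.numeric(contact_cutoff)),
            class = "receptor_frame")
}

#' @export
print.receptor_frame <- function(x, ...) {
  cat(sprintf("<receptor_frame> %d alpha carbons, contact cutoff %.1f A\n",
              nrow(x$calpha_coords), x$contact_cutoff))
  invisible(x)
}

# coerce to an n x 3 double matrix; accepts a vector of length 3 as one atom
as_coord_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) %% 3L != 0L)
      stop("coordinates must have length divisible by 3")
    x <- matrix(as.numeric(x), ncol = 3L, byrow = TRUE)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must have 3 columns")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

coords_of <- function(x) {
  if (inherits(x, "conformation")) x$coords else as_coord_matrix(x)
}
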