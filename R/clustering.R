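#' Clustering state: leader clusters persistent across epochs
#'
#' Creates the mutable container for leader clustering. The state holds the
#' ordered list of clusters (in creation order), the active threshold and
#' density policies, the receptor frame used for contact ratios, and a
#' diagnostic count of cluster comparisons. It has reference semantics (an
#' environment), so [assign_conformation()] and [add_conformations()] update
#' it in place and the same state accumulates across epochs.
#'
#' Each cluster stores an immutable center conformation, the RMSD threshold
#' fixed from the center's contact ratio at creation time, the density
#' `rho`, the visit count `C` (the center counts as the first visit), and
#' running per-metric extrema over all member conformations.
#'
#' @param frame A [receptor_frame()].
#' @param tpolicy A [threshold_policy()].
#' @param dpolicy A [density_policy()].
#' @return An object of class `"clustering_state"`.
#' @seealso [assign_conformation()], [add_conformations()], [cluster_table()]
#' @export
clustering_state <- function(frame,
                             tpolicy = threshold_policy(),
                             dpolicy = density_policy()) {
  stopifnot(inherits(frame, "receptor_frame"),
            inherits(tpolicy, "threshold_policy"),
            inherits(dpolicy, "density_policy"))
  st <- new.env(parent = emptyenv())
  st$clusters <- list()       # cluster records, creation order; id = index - 1
  st$centroids <- matrix(numeric(0), ncol = 3)  # k x 3 cluster centroids
  st$thresholds <- numeric(0)
  st$frame <- frame
  st$tpolicy <- tpolicy
  st$dpolicy <- dpolicy
  st$comparison_count <- 0
  st$n_processed <- 0L
  class(st) <- "clustering_state"
  st
}

#' @export
print.clustering_state <- function(x, ...) {
  cat(sprintf("<clustering_state> %d clusters, %d conformations, %g comparisons\n",
              n_clusters(x), x$n_processed, x$comparison_count))
  invisible(x)
}

#' Number of clusters in a clustering state
#' @param state A [clustering_state()].
#' @return Integer cluster count `k`.
#' @export
n_clusters <- function(state) length(state$clusters)

#' Retrieve one cluster record
#' @param state A [clustering_state()].
#' @param id Cluster id (0-based, creation order).
#' @return A list with fields `id`, `center`, `threshold`, `contact_ratio`,
#'   `density`, `visit_count`, `metric_min`, `metric_max`.
#' @export
get_cluster <- function(state, id) {
  stopifnot(id >= 0, id < n_clusters(state))
  state$clusters[[id + 1L]]
}

#' Assign one conformation to the leader clustering
#'
#' Scans clusters in creation order. For each cluster the centroid distance
#' is tested first: if it already reaches the cluster threshold the RMSD
#' cannot be below it (the centroid distance is a lower bound) and the RMSD
#' evaluation is skipped. The conformation joins the first cluster whose
#' center is within its RMSD threshold (strict `<`); its visit count and
#' metric extrema are updated. If no cluster matches, the conformation
#' founds a new cluster whose threshold and density follow the active
#' policies evaluated at its contact ratio.
#'
#' The diagnostic `comparison_count` grows by the number of clusters
#' inspected: the index of the matching cluster, or the current cluster count
#' when a new cluster is founded. Over a batch of `n` conformations it is
#' therefore bounded by `k * n` with `k` the final number of clusters.
#'
#' @param state A [clustering_state()]; modified in place.
#' @param conf A [conformation()].
#' @return The id (0-based integer) of the cluster that received `conf`.
#' @export
assign_conformation <- function(state, conf) {
  stopifnot(inherits(state, "clustering_state"), inherits(conf, "conformation"))
  k <- n_clusters(state)
  lig <- conf$coords
  if (k > 0L && nrow(state$clusters[[1L]]$center$coords) != nrow(lig))
    stop(sprintf("atom count mismatch: %d vs %d ligand atoms",
                 nrow(state$clusters[[1L]]$center$coords), nrow(lig)))
  state$n_processed <- state$n_processed + 1L

  if (k > 0L) {
    cen <- colMeans(lig)
    # centroid distances to every cluster center (vectorised lower bound)
    cd <- sqrt(rowSums((state$centroids -
                          matrix(cen, k, 3, byrow = TRUE))^2))
    candidates <- which(cd < state$thresholds)
    for (j in candidates) {           # ascending: creation-order first match
      cl <- state$clusters[[j]]
      d <- lig - cl$center$coords
      rmsd <- sqrt(sum(d * d) / nrow(lig))
      if (rmsd < cl$threshold) {
        state$comparison_count <- state$comparison_count + j
        cl$visit_count <- cl$visit_count + 1L
        cl <- update_extrema(cl, conf$metrics)
        state$clusters[[j]] <- cl
        return(cl$id)
      }
    }
    state$comparison_count <- state$comparison_count + k
  }

  # found a new cluster with conf as its (immutable) center
  c_ratio <- contact_ratio(conf, state$frame)
  thr <- threshold_for(c_ratio, state$tpolicy)
  rho <- density_for(c_ratio, thr, state$dpolicy)
  cl <- list(id = k, center = conf, threshold = thr,
             contact_ratio = c_ratio, density = rho, visit_count = 1L,
             metric_min = numeric(0), metric_max = numeric(0))
  cl <- update_extrema(cl, conf$metrics)
  state$clusters[[k + 1L]] <- cl
  state$centroids <- rbind(state$centroids, colMeans(lig))
  state$thresholds <- c(state$thresholds, thr)
  cl$id
}

update_extrema <- function(cl, metrics) {
  for (nm in names(metrics)) {
    v <- metrics[[nm]]
    cur_min <- cl$metric_min[nm]
    cl$metric_min[nm] <- if (is.na(cur_min)) v else min(cur_min, v)
    cur_max <- cl$metric_max[nm]
    cl$metric_max[nm] <- if (is.na(cur_max)) v else max(cur_max, v)
  }
  cl
}

#' Cluster a batch of conformations
#'
#' Applies [assign_conformation()] sequentially in the given order (callers
#' order batches by trajectory then step). The comparison count increase is
#' bounded by `k * n` where `k` is the final cluster count and `n` the batch
#' size.
#'
#' @param state A [clustering_state()]; modified in place.
#' @param confs List of [conformation()] objects.
#' @return The state, invisibly (it is updated in place).
#' @export
add_conformations <- function(state, confs) {
  for (conf in confs) assign_conformation(state, conf)
  invisible(state)
}

#' Tabular summary of a clustering state
#'
#' One row per cluster in creation order: id, contact ratio at the center,
#' RMSD threshold, density, visit count, and per-metric extrema columns
#' (`min_<name>`, `max_<name>`) for every metric seen.
#'
#' @param state A [clustering_state()].
#' @return A `data.frame`.
#' @export
cluster_table <- function(state) {
  k <- n_clusters(state)
  if (k == 0L)
    return(data.frame(id = integer(0), contact_ratio = numeric(0),
                      threshold = numeric(0), density = numeric(0),
                      visit_count = integer(0)))
  tab <- data.frame(
    id = vapply(state$clusters, `[[`, integer(1), "id"),
    contact_ratio = vapply(state$clusters, `[[`, numeric(1), "contact_ratio"),
    threshold = vapply(state$clusters, `[[`, numeric(1), "threshold"),
    density = vapply(state$clusters, `[[`, numeric(1), "density"),
    visit_count = vapply(state$clusters, `[[`, integer(1), "visit_count"))
  metric_names <- unique(unlist(lapply(state$clusters,
                                       function(cl) names(cl$metric_min))))
  for (nm in metric_names) {
    tab[[paste0("min_", nm)]] <- vapply(state$clusters, function(cl) {
      v <- cl$metric_min[nm]; if (is.na(v)) NA_real_ else unname(v)
    }, numeric(1))
    tab[[paste0("max_", nm)]] <- vapply(state$clusters, function(cl) {
      v <- cl$metric_max[nm]; if (is.na(v)) NA_real_ else unname(v)
    }, numeric(1))
  }
  tab
}

#' Cluster center conformations
#'
#' @param state A [clustering_state()].
#' @return List of [conformation()] centers in creation (id) order.
#' @export
cluster_centers <- function(state) {
  lapply(state$clusters, `[[`, "center")
}
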