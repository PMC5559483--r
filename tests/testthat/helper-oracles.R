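# Independent brute-force oracles and fixture builders used across tests.

# per-atom brute-force RMSD, no linear algebra shortcuts
rmsd_brute <- function(a, b) {
  pa <- if (inherits(a, "conformation")) a$coords else a
  pb <- if (inherits(b, "conformation")) b$coords else b
  acc <- 0
  for (i in seq_len(nrow(pa))) {
    acc <- acc + (pa[i, 1] - pb[i, 1])^2 + (pa[i, 2] - pb[i, 2])^2 +
      (pa[i, 3] - pb[i, 3])^2
  }
  sqrt(acc / nrow(pa))
}

# brute-force contact ratio by explicit pair enumeration
contact_brute <- function(lig, ca, cutoff = 8) {
  n <- 0L
  for (i in seq_len(nrow(lig))) {
    for (j in seq_len(nrow(ca))) {
      if (sqrt(sum((lig[i, ] - ca[j, ])^2)) < cutoff) n <- n + 1L
    }
  }
  n / nrow(lig)
}

# naive leader clustering: always computes the RMSD, no centroid pruning.
# Returns per-conformation cluster ids (0-based) and the center indices.
leader_naive <- function(confs, frame, tpolicy = threshold_policy()) {
  centers <- list()
  thresholds <- numeric(0)
  ids <- integer(length(confs))
  for (i in seq_along(confs)) {
    assigned <- NA_integer_
    for (j in seq_along(centers)) {
      if (rmsd_brute(confs[[i]], centers[[j]]) < thresholds[j]) {
        assigned <- j - 1L
        break
      }
    }
    if (is.na(assigned)) {
      centers[[length(centers) + 1L]] <- confs[[i]]
      thresholds <- c(thresholds,
                      threshold_for(contact_ratio(confs[[i]], frame), tpolicy))
      assigned <- length(centers) - 1L
    }
    ids[i] <- assigned
  }
  list(ids = ids, n_clusters = length(centers))
}

# independent largest-remainder apportionment oracle
largest_remainder_oracle <- function(p, n) {
  q <- n * p
  base <- floor(q + 1e-9)
  counts <- as.integer(base)
  left <- n - sum(counts)
  if (left > 0) {
    rem <- q - base
    ord <- order(-rem, seq_along(rem))
    for (i in seq_len(left)) counts[ord[i]] <- counts[ord[i]] + 1L
  }
  counts
}

# random conformation batch in a box, fixed atom count
random_confs <- function(n, n_atoms = 5, seed = 1, scale = 10,
                         center = c(0, 0, 0)) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    conformation(matrix(stats::rnorm(3 * n_atoms, sd = scale), ncol = 3) +
                   matrix(center, n_atoms, 3, byrow = TRUE),
                 step = i,
                 metrics = list(energy = stats::rnorm(1)))
  })
}

# a small receptor frame for clustering tests
tiny_frame <- function(n = 20, seed = 99, cutoff = 8) {
  set.seed(seed)
  receptor_frame(matrix(stats::rnorm(3 * n, sd = 4), ncol = 3), cutoff)
}
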