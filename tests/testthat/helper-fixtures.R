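# Shared fixtures, built in code at test time.

# Small, well-separated simulation spec for parameter-recovery checks.
sep_spec <- function(n_subj = 4L, n_trs = 200L, d = 6L, K = 3L,
                     scale = 3, seed = 7L, noise = 1, dwell = 7 / 1.5) {
  sim_spec(n_subjects_per_group = n_subj, n_trs = n_trs, n_networks = d,
           n_states = K, mean_scale = scale, covariance_scale = noise,
           expected_dwell_trs = dwell, seed = seed)
}

# Coupling with one feature plus interaction and AR structure.
small_coupling <- function(seed = 3L, sigma_u = 0.5) {
  coupling_spec(beta0 = -1, beta_group = 0.2,
                beta_feature = c(arthur_speaking = 0.5, verb = 0.3),
                beta_interaction = c(arthur_speaking = -0.4),
                gamma_ar = c(1.0, 0.3), sigma_u = sigma_u, seed = seed)
}

# Hand-built state pattern with given active networks (value 0.5) on a
# 17-network grid.
pat <- function(active, occupancy = 0.1, group = "combined", model_K = 4L,
                state_index = 1L, d = 17L) {
  mu <- numeric(d)
  mu[active] <- 0.5
  state_pattern(mean = mu, occupancy = occupancy, group = group,
                model_K = model_K, state_index = state_index,
                split_half_r = 0.9, ci_width_max = 0.1)
}

# Brute-force average-linkage agglomerative clustering with a distance cut;
# independent oracle for cluster_states (returns membership partition as a
# list of sorted index vectors, itself sorted for comparison).
brute_average_linkage <- function(D, h) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(clusters) - 1L))
      for (j in seq.int(i + 1L, length(clusters))) {
        dd <- mean(D[clusters[[i]], clusters[[j]]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    if (bestd > h) break
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  part <- lapply(clusters, sort)
  part[order(vapply(part, min, 1L))]
}

# Partition induced by an assignment vector, in canonical order.
assignment_partition <- function(assignment) {
  part <- lapply(sort(unique(assignment)), function(id)
    sort(which(assignment == id)))
  part[order(vapply(part, min, 1L))]
}
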