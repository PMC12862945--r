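# Consensus clustering of reliable state patterns pooled across groups and
# model sizes: Jaccard distance between active-network sets, average-linkage
# agglomerative clustering, occupancy-based cluster ordering, consensus
# binary patterns, provenance labels, threshold-stability sweep, and
# representative-state selection.

#' Active-network set of a state pattern
#'
#' Networks whose mean activation exceeds `theta_act`.  By default only
#' positive activations count as "active"; `rule = "abs"` uses absolute
#' values.
#'
#' @param pattern a `state_pattern` or bare numeric vector.
#' @param theta_act activation threshold (default 0.1).
#' @param rule `"positive"` (default) or `"abs"`.
#' @return integer vector of active network indices.
#' @export
active_set <- function(pattern, theta_act = 0.1,
                       rule = c("positive", "abs")) {
  rule <- match.arg(rule)
  mu <- if (inherits(pattern, "state_pattern")) pattern$mean else
    as.numeric(pattern)
  which(if (rule == "abs") abs(mu) > theta_act else mu > theta_act)
}

#' Jaccard distance between two active-network sets
#'
#' `1 - |intersection| / |union|`.  Two empty sets are treated as identical
#' null patterns (distance 0).
#'
#' @param set_a,set_b integer or character vectors (treated as sets).
#' @return distance in `[0, 1]`.
#' @export
jaccard_distance <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  un <- length(union(set_a, set_b))
  if (un == 0L) return(0)
  1 - length(intersect(set_a, set_b)) / un
}

#' Jaccard similarity between two binary vectors
#' @param a,b 0/1 vectors of equal length.
#' @return similarity in `[0, 1]`; two all-zero vectors give 1.
#' @export
jaccard_similarity_binary <- function(a, b) {
  1 - jaccard_distance(which(a != 0), which(b != 0))
}

#' Cluster state patterns by active-network overlap
#'
#' Computes pairwise Jaccard distances between the patterns' active-network
#' sets, applies agglomerative hierarchical clustering with average linkage,
#' and cuts the dendrogram at distance `1 - similarity_threshold`.  Clusters
#' are then immediately reordered by total fractional occupancy (the sum of
#' member occupancies) so that cluster 1 is the most frequently expressed
#' pattern, not necessarily the one with most member states; ties break by
#' member count, then first appearance.  Each cluster gets a consensus
#' binary pattern and a provenance label.
#'
#' @param patterns list of `state_pattern`s (>= 1).
#' @param similarity_threshold dendrogram cut as a similarity (default 0.8,
#'   i.e. cut at Jaccard distance 0.2).
#' @param theta_act,rule active-set definition (see [active_set()]).
#' @return object of class `cluster_solution`: `assignment` (per-pattern
#'   cluster id, occupancy-ordered, 1-based), `clusters` (list with
#'   `members`, `consensus`, `total_occupancy`, `label`), `threshold`, and
#'   the `active_sets` used.
#' @export
cluster_states <- function(patterns, similarity_threshold = 0.8,
                           theta_act = 0.1, rule = "positive") {
  if (length(patterns) == 0L) stop("empty pattern pool")
  n_networks <- length(patterns[[1L]]$mean)
  sets <- lapply(patterns, active_set, theta_act = theta_act, rule = rule)
  if (any(lengths(sets) == 0L))
    warning("some patterns have empty active sets; ",
            "they are treated as identical null patterns")
  n <- length(patterns)
  if (n == 1L) {
    assignment <- 1L
  } else {
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L))
      for (j in seq.int(i + 1L, n))
        D[i, j] <- D[j, i] <- jaccard_distance(sets[[i]], sets[[j]])
    hc <- hclust(as.dist(D), method = "average")
    assignment <- cutree(hc, h = 1 - similarity_threshold + 1e-12)
  }
  occ <- vapply(patterns, `[[`, 1, "occupancy")
  raw_ids <- sort(unique(assignment))
  tot <- vapply(raw_ids, function(id) sum(occ[assignment == id]), 1)
  sizes <- vapply(raw_ids, function(id) sum(assignment == id), 1L)
  first <- vapply(raw_ids, function(id) min(which(assignment == id)), 1L)
  ord <- order(-tot, -sizes, first)
  relabel <- integer(max(raw_ids))
  relabel[raw_ids[ord]] <- seq_along(raw_ids)
  new_assign <- relabel[assignment]
  clusters <- lapply(seq_along(raw_ids), function(cid) {
    members <- which(new_assign == cid)
    list(members = members,
         consensus = consensus_pattern(patterns[members],
                                       n_networks = n_networks,
                                       theta_act = theta_act, rule = rule),
         total_occupancy = sum(occ[members]),
         label = label_provenance(vapply(patterns[members], `[[`, "",
                                         "group")))
  })
  structure(list(assignment = new_assign, clusters = clusters,
                 threshold = similarity_threshold,
                 active_sets = sets),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> %d patterns in %d clusters (t = %.2f)\n",
              length(x$assignment), length(x$clusters), x$threshold))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  %d: %d states, total occupancy %.3f, %s\n", i,
                length(cl$members), cl$total_occupancy, cl$label))
  }
  invisible(x)
}

#' Consensus binary pattern of a cluster
#'
#' A network is included iff it is active in at least 50% of the member
#' states (the boundary is inclusive: active in exactly half counts).  An
#' empty consensus is allowed, with a warning.
#'
#' @param members list of `state_pattern`s.
#' @param n_networks pattern length.
#' @param theta_act,rule active-set definition (see [active_set()]).
#' @param min_fraction inclusion threshold (default 0.5).
#' @return 0/1 vector of length `n_networks`.
#' @export
consensus_pattern <- function(members, n_networks = length(members[[1L]]$mean),
                              theta_act = 0.1, rule = "positive",
                              min_fraction = 0.5) {
  counts <- numeric(n_networks)
  for (p in members) {
    act <- active_set(p, theta_act = theta_act, rule = rule)
    counts[act] <- counts[act] + 1
  }
  cons <- as.integer(counts / length(members) >= min_fraction)
  if (!any(cons == 1L))
    warning("consensus pattern is empty (no network active in >= ",
            min_fraction * 100, "% of member states)")
  cons
}

#' Provenance label of a cluster
#'
#' A cluster with member states from both the affair and paranoia models is
#' context-general; a cluster with states from only combined/balanced
#' models (which pool both contexts) is also labeled context-general;
#' otherwise the cluster is context-specific, tagged with its dominant
#' context group.
#'
#' @param groups character vector of member provenance groups.
#' @return `"context-general"`, `"context-specific:affair"` or
#'   `"context-specific:paranoia"`.
#' @export
label_provenance <- function(groups) {
  has_a <- "affair" %in% groups
  has_p <- "paranoia" %in% groups
  if (has_a && has_p) return("context-general")
  if (!has_a && !has_p) return("context-general")
  paste0("context-specific:", if (has_a) "affair" else "paranoia")
}

#' Stability of the clustering across similarity thresholds
#'
#' Clusters the pool at each threshold, then compares the consensus
#' patterns of the top `top_n` clusters (by total occupancy) between each
#' consecutive pair of thresholds using greedy best matching on Jaccard
#' similarity.  Reports the per-transition matched similarities, their
#' mean, and the fraction at or above `high`.
#'
#' @inheritParams cluster_states
#' @param thresholds similarity thresholds to sweep (default 0.60-0.90 in
#'   steps of 0.05).
#' @param top_n number of top clusters compared (default 5).
#' @param high similarity level counted as "maintained" (default 0.7).
#' @return list with `pairs` (`data.frame`: `from`, `to`, `cluster_from`,
#'   `cluster_to`, `similarity`), `mean_similarity` and `fraction_high`.
#' @export
threshold_stability <- function(patterns,
                                thresholds = seq(0.60, 0.90, by = 0.05),
                                top_n = 5L, high = 0.7, theta_act = 0.1,
                                rule = "positive") {
  sols <- lapply(thresholds, function(t)
    cluster_states(patterns, similarity_threshold = t,
                   theta_act = theta_act, rule = rule))
  pairs <- data.frame(from = numeric(0), to = numeric(0),
                      cluster_from = integer(0), cluster_to = integer(0),
                      similarity = numeric(0))
  if (length(thresholds) >= 2L) {
    for (i in seq_len(length(thresholds) - 1L)) {
      c1 <- head(sols[[i]]$clusters, top_n)
      c2 <- head(sols[[i + 1L]]$clusters, top_n)
      S <- matrix(0, length(c1), length(c2),
                  dimnames = list(seq_along(c1), seq_along(c2)))
      for (a in seq_along(c1))
        for (b in seq_along(c2))
          S[a, b] <- jaccard_similarity_binary(c1[[a]]$consensus,
                                               c2[[b]]$consensus)
      # greedy best matching: repeatedly take the most similar unmatched pair
      while (nrow(S) > 0L && ncol(S) > 0L) {
        ij <- which(S == max(S), arr.ind = TRUE)[1L, ]
        pairs <- rbind(pairs, data.frame(
          from = thresholds[i], to = thresholds[i + 1L],
          cluster_from = as.integer(rownames(S)[ij[1L]]),
          cluster_to = as.integer(colnames(S)[ij[2L]]),
          similarity = S[ij[1L], ij[2L]]))
        S <- S[-ij[1L], -ij[2L], drop = FALSE]
      }
    }
  }
  list(pairs = pairs,
       mean_similarity = if (nrow(pairs)) mean(pairs$similarity) else
         NA_real_,
       fraction_high = if (nrow(pairs)) mean(pairs$similarity >= high) else
         NA_real_)
}

#' Spearman similarity among cluster activation patterns
#'
#' Rank correlations across the network channels of representative or
#' consensus patterns.
#'
#' @param pattern_matrix clusters x networks numeric matrix (one pattern
#'   per row).
#' @return symmetric Spearman correlation matrix.
#' @export
cluster_similarity <- function(pattern_matrix) {
  pattern_matrix <- as.matrix(pattern_matrix)
  cor(t(pattern_matrix), method = "spearman")
}

#' Select a cluster's representative state from the combined-group models
#'
#' Scans combined-group models in ascending model size; within a model,
#' states are ordered by fractional occupancy (descending).  The first
#' member of the cluster encountered is the representative.
#'
#' @param solution a [cluster_states()] result.
#' @param cluster_id 1-based (occupancy-ordered) cluster id.
#' @param patterns the pattern pool the solution was built from.
#' @return list with `model_K`, `state_index`, and the pool `pattern_index`.
#' @export
select_representative <- function(solution, cluster_id, patterns) {
  members <- solution$clusters[[cluster_id]]$members
  groups <- vapply(patterns[members], `[[`, "", "group")
  members <- members[groups == "combined"]
  if (length(members) == 0L)
    stopf("cluster %d has no combined-group member state", cluster_id)
  ks <- vapply(patterns[members], `[[`, 1L, "model_K")
  occ <- vapply(patterns[members], `[[`, 1, "occupancy")
  pick <- members[order(ks, -occ)][1L]
  list(model_K = patterns[[pick]]$model_K,
       state_index = patterns[[pick]]$state_index,
       pattern_index = pick)
}
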