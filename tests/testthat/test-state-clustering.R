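# Consensus clustering of state patterns: active sets, Jaccard metric,
# average-linkage clustering, ordering, consensus, provenance,
# representatives.

test_that("active_set follows the positive-only and absolute rules", {
  mu <- c(0.2, -0.3, 0.05, 0.15)
  expect_equal(active_set(mu), c(1L, 4L))
  expect_equal(active_set(mu, rule = "abs"), c(1L, 2L, 4L))
  expect_length(active_set(c(0.1, -0.1, 0.05)), 0)
})

test_that("jaccard_distance basics and metric axioms on random triples", {
  expect_equal(jaccard_distance(c(1, 3), c(1, 3)), 0)
  expect_equal(jaccard_distance(1:2, 3:4), 1)
  expect_equal(jaccard_distance(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(jaccard_distance(integer(0), integer(0)), 0)
  set.seed(81)
  for (i in 1:200) {
    a <- which(rbinom(10, 1, 0.4) == 1)
    b <- which(rbinom(10, 1, 0.4) == 1)
    c <- which(rbinom(10, 1, 0.4) == 1)
    dab <- jaccard_distance(a, b); dbc <- jaccard_distance(b, c)
    dac <- jaccard_distance(a, c)
    expect_gte(dab, 0); expect_lte(dab, 1)
    expect_equal(dab, jaccard_distance(b, a))
    expect_lte(dac, dab + dbc + 1e-12) # triangle inequality
    if (setequal(a, b)) expect_equal(dab, 0)
  }
})

test_that("two-block fixture yields exactly two clusters at any threshold", {
  block1 <- lapply(1:3, function(i) pat(1:5, occupancy = 0.1,
                                        state_index = i, model_K = 5L))
  block2 <- lapply(1:3, function(i) pat(10:14, occupancy = 0.2,
                                        group = "affair", state_index = i,
                                        model_K = 5L))
  pool <- c(block1, block2)
  for (t in c(0.2, 0.5, 0.8)) {
    sol <- cluster_states(pool, similarity_threshold = t)
    expect_length(sol$clusters, 2)
  }
  # heavier-occupancy block gets id 1 although both have 3 members
  sol <- cluster_states(pool, 0.8)
  expect_equal(sol$assignment, c(2L, 2L, 2L, 1L, 1L, 1L))
  expect_equal(sol$clusters[[1]]$total_occupancy, 0.6)
  # occupancy beats member count
  pool2 <- c(block1, block2[1:2])
  sol2 <- cluster_states(pool2, 0.8)
  expect_equal(sol2$clusters[[1]]$total_occupancy, 0.4)
  expect_length(sol2$clusters[[1]]$members, 2)
})

test_that("cluster_states agrees with a brute-force average-linkage oracle", {
  set.seed(82)
  for (rep in 1:10) {
    pool <- lapply(1:8, function(i)
      pat(sort(sample(1:17, sample(3:8, 1))), occupancy = runif(1, 0, 0.3),
          state_index = 1L, model_K = 2L))
    n <- length(pool)
    D <- matrix(0, n, n)
    sets <- lapply(pool, active_set)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- jaccard_distance(sets[[i]], sets[[j]])
    t <- 0.7
    sol <- suppressWarnings(cluster_states(pool, similarity_threshold = t))
    expect_identical(assignment_partition(sol$assignment),
                     brute_average_linkage(D, 1 - t + 1e-12))
  }
})

test_that("clustering is invariant to the input order of patterns", {
  set.seed(83)
  pool <- lapply(1:10, function(i)
    pat(sort(sample(1:17, sample(4:8, 1))), occupancy = runif(1, 0, 0.3),
        state_index = 1L, model_K = 2L))
  sol <- cluster_states(pool, 0.75)
  perm <- sample(10)
  solp <- cluster_states(pool[perm], 0.75)
  # same partition of the same elements, and same occupancy-ordered ids
  expect_identical(solp$assignment, sol$assignment[perm])
})

test_that("raising the threshold only refines clusters", {
  set.seed(84)
  pool <- lapply(1:12, function(i)
    pat(sort(sample(1:17, sample(3:9, 1))), occupancy = runif(1, 0, 0.3),
        state_index = 1L, model_K = 2L))
  prev <- NULL
  for (t in seq(0.6, 0.9, by = 0.05)) {
    sol <- suppressWarnings(cluster_states(pool, t))
    if (!is.null(prev)) {
      # every cluster at the higher threshold sits inside one lower cluster
      for (p in assignment_partition(sol$assignment)) {
        holders <- unique(prev[p])
        expect_length(holders, 1)
      }
    }
    prev <- sol$assignment
  }
})

test_that("consensus pattern uses an inclusive 50% boundary", {
  members3 <- list(pat(c(1, 2)), pat(c(1, 2)), pat(c(1, 3)))
  cons <- consensus_pattern(members3, n_networks = 17)
  expect_equal(which(cons == 1L), c(1L, 2L)) # 2/3 = 67% for net 2
  members4 <- list(pat(c(1, 2)), pat(c(1, 2)), pat(c(1, 3)), pat(c(1, 3)))
  cons4 <- consensus_pattern(members4, n_networks = 17)
  expect_equal(which(cons4 == 1L), c(1L, 2L, 3L)) # exactly 50% included
  expect_warning(consensus_pattern(list(pat(1), pat(2), pat(3)),
                                   n_networks = 17), "empty")
})

test_that("provenance labels follow the cross-context rule", {
  expect_equal(label_provenance(c("affair", "paranoia", "combined")),
               "context-general")
  expect_equal(label_provenance(c("paranoia", "combined")),
               "context-specific:paranoia")
  expect_equal(label_provenance(c("affair", "balanced")),
               "context-specific:affair")
  expect_equal(label_provenance(c("combined", "balanced")),
               "context-general")
})

test_that("threshold stability reports perfect scores for stable pools", {
  block1 <- lapply(1:3, function(i) pat(1:5, 0.2, state_index = i,
                                        model_K = 5L))
  block2 <- lapply(1:3, function(i) pat(10:14, 0.1, group = "affair",
                                        state_index = i, model_K = 5L))
  rep1 <- threshold_stability(c(block1, block2),
                              thresholds = seq(0.6, 0.9, 0.05))
  expect_true(all(rep1$pairs$similarity == 1))
  expect_equal(rep1$mean_similarity, 1)
  expect_equal(rep1$fraction_high, 1)
  single <- threshold_stability(c(block1, block2), thresholds = 0.8)
  expect_equal(nrow(single$pairs), 0)
})

test_that("Spearman cluster similarity matches the rank-then-Pearson oracle", {
  set.seed(85)
  M <- matrix(rnorm(4 * 17), 4)
  S <- cluster_similarity(M)
  expect_equal(diag(S), rep(1, 4))
  expect_equal(unname(S), unname(cor(apply(M, 1, rank))), tolerance = 1e-12)
  expect_equal(cluster_similarity(rbind(1:17, 17:1))[1, 2], -1)
})

test_that("representative selection scans combined models by ascending K", {
  pool <- list(
    pat(1:4, 0.30, group = "combined", model_K = 2L, state_index = 1L),
    pat(1:4, 0.10, group = "combined", model_K = 6L, state_index = 3L),
    pat(1:4, 0.20, group = "affair", model_K = 2L, state_index = 2L),
    pat(10:13, 0.15, group = "affair", model_K = 7L, state_index = 1L))
  sol <- cluster_states(pool, 0.8)
  rep1 <- select_representative(sol, 1, pool)
  expect_equal(rep1$model_K, 2L)
  expect_equal(rep1$state_index, 1L)
  # cluster with members only in K=6 and K=7 combined models -> K=6 wins
  pool2 <- list(
    pat(1:4, 0.1, group = "combined", model_K = 7L, state_index = 2L),
    pat(1:4, 0.1, group = "combined", model_K = 6L, state_index = 4L))
  sol2 <- cluster_states(pool2, 0.8)
  expect_equal(select_representative(sol2, 1, pool2)$model_K, 6L)
  # no combined member -> explicit error
  expect_error(select_representative(sol, 2, pool), "no combined-group")
})
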