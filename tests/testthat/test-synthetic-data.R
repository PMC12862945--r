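# Synthetic-data generators: Markov/Gaussian dataset, annotation streams,
# logistic occupancy and button presses.

test_that("single-state spec gives constant paths and pure-noise emissions", {
  spec <- sim_spec(n_subjects_per_group = 2, n_trs = 100, n_networks = 4,
                   n_states = 1, seed = 1)
  sim <- generate_hmm_dataset(spec)
  for (p in sim$truth$paths) expect_true(all(p == 1L))
  # z-scored noise: per-column mean 0, sd 1 (population convention)
  X <- sim$series[[1]]$data
  expect_lt(max(abs(colMeans(X))), 1e-8)
  expect_lt(max(abs(sqrt(colMeans(sweep(X, 2, colMeans(X))^2)) - 1)), 1e-8)
})

test_that("dwell segments are geometric with the requested mean and variance", {
  # ~2 x 10^5 pooled dwell segments; mean 1/(1-a), variance a/(1-a)^2
  dwell <- 7 / 1.5
  spec <- sim_spec(n_subjects_per_group = 1, n_trs = 5e5, n_networks = 2,
                   n_states = 3, mean_scale = 2, expected_dwell_trs = dwell,
                   seed = 11)
  sim <- generate_hmm_dataset(spec)
  segs <- unlist(lapply(sim$truth$paths, function(p) {
    r <- rle(p)$lengths
    r[-c(1L, length(r))] # drop censored first/last segments
  }))
  expect_gt(length(segs), 1e5)
  a <- 1 - 1 / dwell
  expect_lt(abs(mean(segs) - dwell) / dwell, 0.01)
  expect_lt(abs(var(segs) - a / (1 - a)^2) / (a / (1 - a)^2), 0.03)
})

test_that("state frequencies match the stationary distribution (eigen oracle)", {
  spec <- sep_spec(n_subj = 4, n_trs = 451, d = 6, K = 3, seed = 2)
  sim <- generate_hmm_dataset(spec)
  A <- dwell_transition_matrix(3, spec$expected_dwell_trs)
  pi0 <- stationary_distribution(A) # eigen-analysis oracle
  expect_equal(sum(pi0), 1, tolerance = 1e-12)
  counts <- tabulate(unlist(sim$truth$paths), 3)
  n <- sum(counts)
  # Markov-autocorrelation-corrected standard error of an occupancy rate
  a <- A[1, 1]
  rho <- a - (1 - a) / 2
  se <- sqrt(pi0 * (1 - pi0) / n * (1 + rho) / (1 - rho))
  expect_true(all(abs(counts / n - pi0) < 3 * se))
})

test_that("requested covariance must be positive definite", {
  bad <- matrix(1, 2, 2) # singular
  expect_error(sim_spec(n_networks = 2, n_states = 2,
                        state_means = rbind(c(1, 0), c(0, 1)),
                        state_covs = list(bad, diag(2))),
               "positive definite")
})

test_that("feature streams honor degenerate and long-run rates", {
  cp <- coupling_spec(feature_rates = list(
    off = list(rate = 0, run = 3), on = list(rate = 1, run = 3),
    arthur_speaking = list(rate = 0.5, run = 2),
    adjective = list(rate = 0.2, run = 4),
    lee_girl_together = list(rate = 0.15, run = 5),
    verb = list(rate = 0.55, run = 2)), seed = 5)
  ft <- generate_feature_streams(cp, 1e5)
  expect_true(all(ft$off == 0L))
  expect_true(all(ft$on == 1L))
  # rate 0.5 / run 2 has zero lag-1 autocorrelation: iid oracle applies
  expect_lt(abs(mean(ft$arthur_speaking) - 0.5), 0.01 * 0.5)
  # autocorrelated stream: 4 sigma band from the two-state-chain variance
  p <- 0.2; p_off <- 1 / 4; p_on <- p * p_off / (1 - p)
  rho <- 1 - p_off - p_on
  se <- sqrt(p * (1 - p) * (1 + rho) / (1 - rho) / 1e5)
  expect_lt(abs(mean(ft$adjective) - p), 4 * se)
  # composites are elementwise products
  expect_identical(ft$lee_girl_verb,
                   as.integer(ft$lee_girl_together * ft$verb))
})

test_that("mean run length of generated streams matches the request", {
  cp <- coupling_spec(feature_rates = list(
    arthur_speaking = list(rate = 0.3, run = 8)), seed = 9)
  ft <- generate_feature_streams(cp, 2e5)
  r <- rle(ft$arthur_speaking)
  runs <- r$lengths[r$values == 1L]
  runs <- runs[-c(1L, length(runs))]
  expect_lt(abs(mean(runs) - 8) / 8, 0.03)
})

test_that("occupancy rates converge to the inverse-logit oracle", {
  base <- coupling_spec(feature_rates = list(), beta0 = 0, sigma_u = 0,
                        seed = 2)
  ft0 <- data.frame(tr_index = seq_len(1e5) - 1L)
  r0 <- generate_state_occupancy(ft0, base, +1, n_subjects = 1, seed = 2)
  expect_lt(abs(mean(r0$outcomes) - 0.5), 0.01)

  cp1 <- coupling_spec(feature_rates = list(), beta0 = -1.0986,
                       sigma_u = 0, seed = 3)
  r1 <- generate_state_occupancy(ft0, cp1, +1, n_subjects = 1, seed = 3)
  expect_lt(abs(mean(r1$outcomes) - 0.25), 0.01)

  # cancellation: always-on feature with beta_feature = -beta0
  cp2 <- coupling_spec(feature_rates = list(verb = list(rate = 1, run = 2)),
                       beta0 = -0.81, beta_feature = c(verb = 0.81),
                       sigma_u = 0, seed = 4)
  ft2 <- generate_feature_streams(cp2, 1e5)
  r2 <- generate_state_occupancy(ft2, cp2, +1, n_subjects = 1, seed = 4)
  expect_lt(abs(mean(r2$outcomes) - 0.5), 0.01)
})

test_that("AR(1)-on-outcome stationary rate matches the two-state-chain oracle", {
  # no features, gamma_1 only: y_t is itself a two-state Markov chain with
  # P(1|0) = plogis(b0), P(1|1) = plogis(b0 + g1); stationary rate is
  # p01 / (p01 + 1 - p11)
  b0 <- -1; g1 <- 1.5
  cp <- coupling_spec(feature_rates = list(), beta0 = b0,
                      gamma_ar = c(g1, 0), sigma_u = 0, seed = 6)
  ft <- data.frame(tr_index = seq_len(2e5) - 1L)
  r <- generate_state_occupancy(ft, cp, +1, n_subjects = 1, seed = 6)
  p01 <- plogis(b0); p11 <- plogis(b0 + g1)
  target <- p01 / (p01 + 1 - p11)
  rho <- p11 - p01
  se <- sqrt(target * (1 - target) * (1 + rho) / (1 - rho) / 2e5)
  expect_lt(abs(mean(r$outcomes) - target), 4 * se)
})

test_that("button presses: degenerate, group-flip and overdispersion behavior", {
  ft <- generate_feature_streams(small_coupling(seed = 8), 1e4)
  dead <- coupling_spec(feature_rates = list(), beta0 = -20, sigma_u = 0,
                        seed = 8)
  expect_true(all(generate_button_presses(
    data.frame(tr_index = ft$tr_index), dead, +1, n_subjects = 2,
    seed = 8)$outcomes == 0L))

  # interaction flips the realized effect of the feature between groups
  cp <- coupling_spec(feature_rates = list(
    arthur_speaking = list(rate = 0.3, run = 8)), beta0 = -1,
    beta_interaction = c(arthur_speaking = 0.8), sigma_u = 0, seed = 9)
  ftc <- generate_feature_streams(cp, 1e4)
  on <- ftc$arthur_speaking == 1L
  ra <- generate_button_presses(ftc, cp, +1, n_subjects = 1, seed = 10)
  rp <- generate_button_presses(ftc, cp, -1, n_subjects = 1, seed = 11)
  diff_a <- mean(ra$outcomes[1, on]) - mean(ra$outcomes[1, !on])
  diff_p <- mean(rp$outcomes[1, on]) - mean(rp$outcomes[1, !on])
  expect_gt(diff_a, 0.05)
  expect_lt(diff_p, -0.05)

  # large sigma_u: between-subject variance of press counts exceeds the
  # binomial expectation for the pooled rate
  cpo <- coupling_spec(feature_rates = list(), beta0 = -1, sigma_u = 2,
                       seed = 12)
  ro <- generate_button_presses(data.frame(tr_index = seq_len(300) - 1L),
                                cpo, +1, n_subjects = 60, seed = 12)
  counts <- rowSums(ro$outcomes)
  phat <- mean(ro$outcomes)
  expect_gt(var(counts), 2 * 300 * phat * (1 - phat))
})

test_that("all generators are bit-identical under a fixed seed", {
  spec <- sep_spec(seed = 21)
  expect_identical(generate_hmm_dataset(spec), generate_hmm_dataset(spec))
  cp <- small_coupling(seed = 22)
  expect_identical(generate_feature_streams(cp, 500),
                   generate_feature_streams(cp, 500))
  ft <- generate_feature_streams(cp, 200)
  expect_identical(generate_state_occupancy(ft, cp, +1, 5, seed = 23),
                   generate_state_occupancy(ft, cp, +1, 5, seed = 23))
  expect_identical(generate_button_presses(ft, cp, -1, 5, seed = 24),
                   generate_button_presses(ft, cp, -1, 5, seed = 24))
  # and the session RNG stream is left untouched
  set.seed(99); before <- .Random.seed
  invisible(generate_feature_streams(cp, 50))
  expect_identical(.Random.seed, before)
})
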