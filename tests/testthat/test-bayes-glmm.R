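# MAP Bayesian logistic mixed models: design construction, closed-form and
# ML oracles, direction probabilities, Bayesian FDR, group effects.

test_that("build_design codes groups, lags and interactions correctly", {
  ft <- data.frame(tr_index = 0:4, verb = c(1L, 0L, 1L, 1L, 0L),
                   noun = c(0L, 1L, 0L, 0L, 1L))
  occ <- rbind(c(1, 0, 1, 1, 0), c(0, 1, 0, 0, 1))
  des <- build_design(ft, occ, c("affair", "paranoia"))
  expect_equal(unname(des$X[1:5, "group"]), rep(1, 5))
  expect_equal(unname(des$X[6:10, "group"]), rep(-1, 5))
  # AR columns padded with 0 at each subject's first TRs
  expect_equal(unname(des$X[c(1, 6), "lag1"]), c(0, 0))
  expect_equal(unname(des$X[c(1, 2, 6, 7), "lag2"]), rep(0, 4))
  expect_equal(unname(des$X[2:5, "lag1"]), occ[1, 1:4])
  expect_equal(unname(des$X[3:5, "lag2"]), occ[1, 1:3])
  # interaction columns are brute-force products
  expect_equal(unname(des$X[, "group:verb"]),
               unname(des$X[, "group"] * des$X[, "verb"]))
  expect_error(build_design(ft, occ, c("affair", "unknown")), "unknown")
  expect_error(build_design(ft, occ[, 1:4], c("affair", "paranoia")),
               "TRs")
})

test_that("flat-prior intercept fits match closed-form logit oracles", {
  # 25 successes / 75 failures -> beta0 = ln(1/3)
  ft <- data.frame(tr_index = 0:99)
  y <- matrix(c(rep(1, 25), rep(0, 75)), 1)
  des <- build_design(ft, y, "affair", n_lags = 0)
  des$X <- des$X[, "(Intercept)", drop = FALSE] # intercept-only
  fit <- fit_map(des, prior_spec(tau = Inf), random_intercept = FALSE)
  expect_equal(unname(fit$coefficients), log(1 / 3), tolerance = 1e-6)

  # balanced outcome -> beta0 = 0
  y2 <- matrix(rep(c(1, 0), 50), 1)
  des2 <- build_design(ft, y2, "affair", n_lags = 0)
  des2$X <- des2$X[, "(Intercept)", drop = FALSE]
  fit2 <- fit_map(des2, prior_spec(tau = Inf), random_intercept = FALSE)
  expect_equal(unname(fit2$coefficients), 0, tolerance = 1e-8)

  # 2x2 table: rates 30/50 on vs 20/50 off -> beta = ln(2.25)
  ft3 <- data.frame(tr_index = 0:99, f = rep(c(1L, 0L), each = 50))
  y3 <- matrix(c(rep(1, 30), rep(0, 20), rep(1, 20), rep(0, 30)), 1)
  des3 <- build_design(ft3, y3, "affair", n_lags = 0)
  des3$X <- des3$X[, c("(Intercept)", "f")]
  fit3 <- fit_map(des3, prior_spec(tau = Inf), random_intercept = FALSE)
  expect_equal(unname(fit3$coefficients["f"]), log(2.25), tolerance = 1e-6)
  expect_equal(unname(exp(fit3$coefficients["f"])), 2.25,
               tolerance = 1e-5)
})

test_that("flat-prior fits equal the ML logistic oracle on random designs", {
  set.seed(111)
  for (i in 1:20) {
    n <- 150
    X <- cbind(1, matrix(rbinom(n * 3, 1, 0.4), n))
    colnames(X) <- c("(Intercept)", "a", "b", "c")
    beta <- rnorm(4, 0, 0.7)
    y <- rbinom(n, 1, plogis(X %*% beta))
    if (all(y == 0) || all(y == 1)) next
    des <- structure(list(X = X, y = y, subject = rep(1L, n),
                          subject_ids = "s1", group_codes = 1,
                          feature_cols = integer(0),
                          interaction_cols = integer(0),
                          lag_cols = integer(0)), class = "glmm_design")
    fit <- fit_map(des, prior_spec(tau = Inf), random_intercept = FALSE)
    oracle <- glm(y ~ X - 1, family = binomial(),
                  control = list(epsilon = 1e-12))
    expect_lt(max(abs(coef(oracle) - fit$coefficients)), 1e-6)
  }
})

test_that("direction probabilities follow the Gaussian approximation", {
  ft <- data.frame(tr_index = 0:199, f = rep(c(1L, 0L), each = 100))
  y <- matrix(rep(c(1, 0, 0, 1), 50), 1)
  des <- build_design(ft, y, "affair", n_lags = 0)
  des$X <- des$X[, c("(Intercept)", "f")]
  fit <- fit_map(des, prior_spec(tau = Inf), random_intercept = FALSE)
  dp <- direction_probability(fit)
  expect_equal(unname(dp),
               unname(pnorm(fit$coefficients / fit$sd)), tolerance = 1e-12)
  # balanced within each feature level -> both effects 0, dp 0.5
  expect_equal(unname(dp), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("Bayesian FDR reproduces the hand-computed running-mean example", {
  res <- bayesian_fdr(c(0.99, 0.98, 0.97, 0.60), alpha = 0.05)
  expect_equal(res$credible, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$adjusted_prob,
               1 - c(0.01, 0.015, 0.02, 0.115), tolerance = 1e-12)
  # flipped directions are handled through p* = max(p, 1-p)
  res2 <- bayesian_fdr(c(0.01, 0.98, 0.03, 0.60), alpha = 0.05)
  expect_equal(res2$credible, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(bayesian_fdr(rep(1, 5))$credible))
  expect_false(any(bayesian_fdr(rep(0.5, 5))$credible))
})

test_that("group effects obey the deviation-coding identities", {
  ft <- generate_feature_streams(small_coupling(seed = 112), 300)
  occA <- generate_state_occupancy(ft, small_coupling(seed = 112), +1,
                                   n_subjects = 6, seed = 113)
  occP <- generate_state_occupancy(ft, small_coupling(seed = 112), -1,
                                   n_subjects = 6, seed = 114)
  des <- build_design(ft, rbind(occA$outcomes, occP$outcomes),
                      rep(c("affair", "paranoia"), each = 6),
                      feature_names = c("arthur_speaking", "verb"))
  fit <- fit_map(des)
  ge <- group_effects(fit)
  for (f in c("arthur_speaking", "verb")) {
    bj <- fit$coefficients[f]
    bg <- fit$coefficients[paste0("group:", f)]
    ga <- ge[ge$feature == f & ge$group == "affair", ]
    gp <- ge[ge$feature == f & ge$group == "paranoia", ]
    expect_equal(ga$log_odds, unname(bj + bg), tolerance = 1e-12)
    expect_equal(gp$log_odds, unname(bj - bg), tolerance = 1e-12)
    # geometric-mean and half-difference identities
    expect_equal(exp(unname(bj)), sqrt(ga$or * gp$or), tolerance = 1e-12)
    expect_equal(exp(unname(bg)), sqrt(ga$or / gp$or), tolerance = 1e-12)
  }
})

test_that("Bayesian FDR is calibrated when effects are drawn from the prior", {
  # sign-error calibration: true effects beta ~ N(0, 0.3^2) observed with
  # standard error 0.1; a flagged claim is an error iff its claimed
  # direction disagrees with the true sign.  Under a correct model the
  # expected sign-error proportion among flagged effects stays below alpha.
  set.seed(118)
  n_rep <- 300; m <- 50; se <- 0.1
  errs <- numeric(n_rep); flags <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    beta <- rnorm(m, 0, 0.3)
    z <- beta / se + rnorm(m)
    dp <- pnorm(z) # P(effect > 0) under the Gaussian approximation
    res <- bayesian_fdr(dp, alpha = 0.05)
    claimed_pos <- dp > 0.5
    wrong <- res$credible & (claimed_pos != (beta > 0))
    errs[r] <- sum(wrong); flags[r] <- sum(res$credible)
  }
  expect_gt(sum(flags), 0)
  expect_lte(sum(errs) / sum(flags), 0.05 + 0.02)
})

test_that("random intercepts absorb subject heterogeneity", {
  cp <- coupling_spec(feature_rates = list(), beta0 = -0.5, sigma_u = 1.2,
                      seed = 115)
  ft <- data.frame(tr_index = 0:299)
  occ <- generate_state_occupancy(ft, cp, +1, n_subjects = 15, seed = 116)
  des <- build_design(ft, occ$outcomes, rep("affair", 15), n_lags = 2)
  des$X <- des$X[, c("(Intercept)", "lag1", "lag2")]
  fit <- fit_map(des, prior_spec())
  expect_gt(fit$sigma_u2, 0.2) # heterogeneity detected
  expect_gt(cor(fit$u, occ$u), 0.7) # intercepts track the truth
})

test_that("representative occupancy is the equality scan of decoded paths", {
  paths <- list(c(1L, 2L, 2L, 3L), c(2L, 2L, 1L, 1L))
  occ <- representative_occupancy(paths, 2L)
  expect_equal(occ, rbind(c(0L, 1L, 1L, 0L), c(1L, 1L, 0L, 0L)))
  # K = 2 complement property
  p2 <- list(c(1L, 2L, 1L), c(2L, 2L, 1L))
  expect_equal(representative_occupancy(p2, 1L) +
                 representative_occupancy(p2, 2L),
               matrix(1L, 2, 3))
  expect_warning(representative_occupancy(paths, 9L), "never visited")
  set.seed(117)
  rp <- lapply(1:3, function(i) sample(1:4, 50, replace = TRUE))
  oracle <- t(vapply(rp, function(p) as.integer(p == 3L), integer(50)))
  expect_equal(representative_occupancy(rp, 3L), oracle)
})

test_that("constant outcomes are rejected", {
  ft <- data.frame(tr_index = 0:9)
  des <- build_design(ft, matrix(1, 1, 10), "affair", n_lags = 0)
  expect_error(fit_map(des), "constant")
})
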