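# Synthetic-data generators.
#
# These generators produce datasets with exactly the statistical structure
# the downstream analysis assumes: first-order Markov state sequences with
# multivariate-Gaussian network emissions, bursty binary annotation streams,
# logistic state occupancy / button-press series with AR(2) outcome lags and
# subject-level random intercepts.  They provide ground truth for every
# stage of the pipeline.

#' Simulation specification for the HMM data generator
#'
#' Describes a stationary Markov chain over `n_states` brain states with
#' multivariate-Gaussian network emissions.  The self-transition probability
#' is derived from the expected dwell time, `a = 1 - 1/expected_dwell_trs`,
#' so that generated dwell segments are geometric with the requested mean;
#' remaining transition mass is spread uniformly over the other states.
#'
#' @param n_subjects_per_group subjects per context group (two groups are
#'   generated, labeled `affair` and `paranoia`).
#' @param n_trs time points per subject (default 451, the usable story
#'   window at TR = 1.5 s).
#' @param n_networks number of network channels (default 17).
#' @param tr_seconds TR duration in seconds (default 1.5).
#' @param n_states number of latent states.
#' @param state_means `n_states x n_networks` matrix of emission means (z
#'   units).  Default: deterministic block patterns in which state `k`
#'   activates its own subset of networks at `mean_scale`.
#' @param mean_scale amplitude of the default block patterns.
#' @param covariance_scale emission noise SD; emission covariance is
#'   `covariance_scale^2 * I` unless `state_covs` is given.
#' @param state_covs optional list of `n_states` full covariance matrices;
#'   each must be symmetric positive definite.
#' @param expected_dwell_trs expected dwell time in TRs (default 7 s / 1.5 s
#'   = 4.67 TRs).
#' @param seed integer RNG seed.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(n_subjects_per_group = 19L, n_trs = 451L,
                     n_networks = 17L, tr_seconds = 1.5, n_states = 4L,
                     state_means = NULL, mean_scale = 1,
                     covariance_scale = 1, state_covs = NULL,
                     expected_dwell_trs = 7 / 1.5, seed = 1L) {
  stopifnot(is_count(n_subjects_per_group, 1L), is_count(n_trs, 1L),
            is_count(n_networks, 1L), is_count(n_states, 1L),
            tr_seconds > 0, covariance_scale > 0)
  if (expected_dwell_trs < 1)
    stopf("expected_dwell_trs must be >= 1 TR, got %g", expected_dwell_trs)
  if (is.null(state_means))
    state_means <- default_state_means(n_states, n_networks, mean_scale)
  state_means <- as.matrix(state_means)
  if (!identical(dim(state_means), c(as.integer(n_states),
                                     as.integer(n_networks))))
    stopf("state_means must be %d x %d", n_states, n_networks)
  if (n_states > 1L && anyDuplicated(apply(state_means, 1L, paste,
                                           collapse = ",")))
    stop("state_means rows must be distinct when n_states > 1")
  if (!is.null(state_covs)) {
    stopifnot(length(state_covs) == n_states)
    for (k in seq_len(n_states)) {
      ok <- tryCatch({ chol(state_covs[[k]]); TRUE },
                     error = function(e) FALSE)
      if (!ok)
        stopf("state_covs[[%d]] is not symmetric positive definite", k)
    }
  }
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 n_trs = as.integer(n_trs),
                 n_networks = as.integer(n_networks),
                 tr_seconds = tr_seconds, n_states = as.integer(n_states),
                 state_means = state_means,
                 covariance_scale = covariance_scale,
                 state_covs = state_covs,
                 expected_dwell_trs = expected_dwell_trs,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# Deterministic well-separated mean patterns: state k activates the
# networks congruent to k modulo n_states.
#' @noRd
default_state_means <- function(n_states, n_networks, scale = 1) {
  m <- matrix(0, n_states, n_networks)
  for (k in seq_len(n_states))
    m[k, which((seq_len(n_networks) - 1L) %% n_states == (k - 1L))] <- scale
  m
}

#' Transition matrix implied by an expected dwell time
#'
#' Self-transition probability `a = 1 - 1/dwell_trs` gives geometric dwell
#' segments with mean `dwell_trs`; off-diagonal mass is uniform.
#' @param n_states number of states.
#' @param dwell_trs expected dwell time in TRs (>= 1).
#' @return row-stochastic `n_states x n_states` matrix.
#' @export
dwell_transition_matrix <- function(n_states, dwell_trs) {
  stopifnot(is_count(n_states, 1L), dwell_trs >= 1)
  if (n_states == 1L) return(matrix(1, 1L, 1L))
  a <- 1 - 1 / dwell_trs
  A <- matrix((1 - a) / (n_states - 1L), n_states, n_states)
  diag(A) <- a
  A
}

#' Stationary distribution of a Markov transition matrix
#'
#' Leading left eigenvector, normalized to the simplex.
#' @param A row-stochastic matrix.
#' @return probability vector.
#' @export
stationary_distribution <- function(A) {
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Generate a synthetic multi-subject network time-series dataset
#'
#' Draws, for each subject, a stationary Markov state path (self-transition
#' probability implied by the spec's expected dwell time) and Gaussian
#' network emissions around the active state's mean, then z-scores each
#' subject's series (population-SD convention) exactly as the real pipeline
#' does before HMM fitting.
#'
#' @param spec a [sim_spec()].
#' @return list with `series` (list of `network_series`, groups `affair`
#'   then `paranoia`) and `truth` (list: per-subject true `paths` with
#'   states in `1..n_states`, plus the generating `state_means`,
#'   `transition` and `stationary` distributions).
#' @export
generate_hmm_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  A <- dwell_transition_matrix(spec$n_states, spec$expected_dwell_trs)
  pi0 <- stationary_distribution(A)
  chols <- if (is.null(spec$state_covs)) {
    rep(list(diag(spec$covariance_scale, spec$n_networks)), spec$n_states)
  } else {
    lapply(spec$state_covs, function(S) t(chol(S)))
  }
  groups <- c("affair", "paranoia")
  n_tot <- 2L * spec$n_subjects_per_group
  with_seed(spec$seed, {
    series <- vector("list", n_tot)
    paths <- vector("list", n_tot)
    for (s in seq_len(n_tot)) {
      path <- simulate_markov_path(spec$n_trs, A, pi0)
      noise <- matrix(rnorm(spec$n_trs * spec$n_networks), spec$n_trs)
      X <- spec$state_means[path, , drop = FALSE]
      for (k in seq_len(spec$n_states)) {
        idx <- which(path == k)
        if (length(idx))
          X[idx, ] <- X[idx, , drop = FALSE] +
            noise[idx, , drop = FALSE] %*% t(chols[[k]])
      }
      grp <- groups[(s - 1L) %/% spec$n_subjects_per_group + 1L]
      id <- sprintf("sub-%02d", s)
      series[[s]] <- zscore_subject(network_series(id, grp, X,
                                                   spec$tr_seconds))
      paths[[s]] <- path
      names(paths)[s] <- id
    }
    list(series = series,
         truth = list(paths = paths, state_means = spec$state_means,
                      transition = A, stationary = pi0))
  })
}

#' @noRd
simulate_markov_path <- function(n, A, pi0) {
  K <- nrow(A)
  if (K == 1L) return(rep(1L, n))
  path <- integer(n)
  path[1L] <- sample.int(K, 1L, prob = pi0)
  u <- runif(n - 1L)
  cumA <- t(apply(A, 1L, cumsum))
  for (t in 2:n)
    path[t] <- findInterval(u[t - 1L], cumA[path[t - 1L], ]) + 1L
  path
}

#' Coupling specification for annotation-driven binary outcomes
#'
#' Parameters of the logistic data-generating model
#' `logit P(y_it = 1) = beta0 + beta_group g_i + sum_j beta_feature[j] f_jt
#'  + sum_j beta_interaction[j] g_i f_jt + gamma_ar[1] y_{i,t-1} +
#'  gamma_ar[2] y_{i,t-2} + u_i`, with `u_i ~ N(0, sigma_u^2)` and the group
#' deviation-coded +1 (affair) / -1 (paranoia).  Also carries per-feature
#' marginal statistics (on-rate and mean run length) for the bursty binary
#' annotation streams.
#'
#' @param feature_rates named list; each element is `list(rate=, run=)`
#'   giving the stationary on-probability and mean on-run length in TRs.
#'   Defaults cover the character-speech and part-of-speech annotations the
#'   analysis uses.
#' @param beta0,beta_group intercept and group main effect (log-odds).
#' @param beta_feature,beta_interaction named numeric vectors of per-feature
#'   main and group-interaction effects; names must be features present in
#'   the generated table (composites allowed).
#' @param gamma_ar length-2 numeric, AR coefficients on lagged outcomes.
#' @param sigma_u SD of the subject random intercept (>= 0).
#' @param seed integer RNG seed.
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(feature_rates = default_feature_rates(),
                          beta0 = -1, beta_group = 0,
                          beta_feature = numeric(0),
                          beta_interaction = numeric(0),
                          gamma_ar = c(0, 0), sigma_u = 0.5, seed = 1L) {
  stopifnot(length(gamma_ar) == 2L, sigma_u >= 0)
  for (nm in names(feature_rates)) {
    fr <- feature_rates[[nm]]
    if (fr$rate < 0 || fr$rate > 1)
      stopf("feature '%s': rate must be in [0, 1]", nm)
    if (fr$rate > 0 && fr$rate < 1 && fr$run < 1)
      stopf("feature '%s': mean run length must be >= 1 TR", nm)
  }
  structure(list(feature_rates = feature_rates, beta0 = beta0,
                 beta_group = beta_group, beta_feature = beta_feature,
                 beta_interaction = beta_interaction,
                 gamma_ar = as.numeric(gamma_ar), sigma_u = sigma_u,
                 seed = as.integer(seed)),
            class = "coupling_spec")
}

# Default marginal statistics of the annotation streams.  The source study
# does not report run lengths or rates, so these are fixed, field-plausible
# choices: character speech comes in multi-TR blocks, parts of speech are
# frequent and short-lived.
#' @export
#' @rdname coupling_spec
default_feature_rates <- function() {
  list(arthur_speaking   = list(rate = 0.30, run = 8),
       lee_speaking      = list(rate = 0.25, run = 6),
       girl_speaking     = list(rate = 0.08, run = 3),
       lee_girl_together = list(rate = 0.15, run = 5),
       verb              = list(rate = 0.55, run = 2),
       noun              = list(rate = 0.60, run = 2),
       adjective         = list(rate = 0.25, run = 1.5),
       adverb            = list(rate = 0.20, run = 1.5))
}

#' Generate bursty binary annotation streams
#'
#' Each base feature is an independent two-state Markov chain parameterized
#' by its stationary on-rate `p` and mean on-run length `L`: the off-switch
#' probability is `1/L` and the on-switch probability `p / ((1-p) L)`.
#' Composite features (`lee_girl_verb`, `arthur_adjective`) are the
#' elementwise products of their parents when the parents are present.
#'
#' @param coupling a [coupling_spec()].
#' @param n_trs number of TRs to generate.
#' @param seed optional seed overriding `coupling$seed`.
#' @return a `data.frame` with `tr_index` (0-based) and one 0/1 column per
#'   feature.
#' @export
generate_feature_streams <- function(coupling, n_trs,
                                     seed = coupling$seed) {
  stopifnot(inherits(coupling, "coupling_spec"), is_count(n_trs, 1L))
  with_seed(seed, {
    cols <- lapply(names(coupling$feature_rates), function(nm) {
      fr <- coupling$feature_rates[[nm]]
      simulate_binary_chain(n_trs, fr$rate, fr$run)
    })
    names(cols) <- names(coupling$feature_rates)
    tab <- data.frame(tr_index = seq_len(n_trs) - 1L, cols,
                      check.names = FALSE)
    build_composites(tab, strict = FALSE)
  })
}

#' @noRd
simulate_binary_chain <- function(n, rate, run) {
  if (rate <= 0) return(integer(n))
  if (rate >= 1) return(rep(1L, n))
  p_off <- 1 / run                      # on -> off
  p_on <- rate * p_off / (1 - rate)     # off -> on
  if (p_on > 1)
    stopf("rate %g with run length %g is infeasible (off->on prob %g > 1)",
          rate, run, p_on)
  x <- integer(n)
  x[1L] <- rbinom(1L, 1L, rate)
  u <- runif(n - 1L)
  for (t in 2:n)
    x[t] <- if (x[t - 1L] == 1L) as.integer(u[t - 1L] >= p_off)
            else as.integer(u[t - 1L] < p_on)
  x
}

# Shared logistic sequence generator for state occupancy and button presses.
#' @noRd
simulate_logistic_outcomes <- function(features, coupling, group_code,
                                       n_subjects, seed) {
  stopifnot(group_code %in% c(-1, 1))
  fmat <- as.matrix(features[, setdiff(colnames(features), "tr_index"),
                             drop = FALSE])
  bf <- coupling$beta_feature
  bi <- coupling$beta_interaction
  missing <- setdiff(union(names(bf), names(bi)), colnames(fmat))
  if (length(missing))
    stopf("coupling names features absent from the table: %s",
          paste(missing, collapse = ", "))
  n_trs <- nrow(fmat)
  base <- coupling$beta0 + coupling$beta_group * group_code
  if (length(bf)) base <- base + fmat[, names(bf), drop = FALSE] %*% bf
  if (length(bi)) base <- base + group_code *
      (fmat[, names(bi), drop = FALSE] %*% bi)
  base <- rep(as.numeric(base), length.out = n_trs)
  g <- coupling$gamma_ar
  with_seed(seed, {
    u_i <- rnorm(n_subjects, 0, coupling$sigma_u)
    out <- matrix(0L, n_subjects, n_trs)
    for (s in seq_len(n_subjects)) {
      y1 <- 0L; y2 <- 0L # lags before t = 1 are defined as 0
      for (t in seq_len(n_trs)) {
        eta <- base[t] + g[1L] * y1 + g[2L] * y2 + u_i[s]
        y <- rbinom(1L, 1L, plogis(eta))
        out[s, t] <- y
        y2 <- y1; y1 <- y
      }
    }
    list(outcomes = out, u = u_i)
  })
}

#' Generate binary state-occupancy sequences from the logistic ground truth
#'
#' Draws, per subject, a Bernoulli sequence from the deviation-coded
#' logistic model with AR(2) outcome lags and subject random intercepts
#' (lagged outcomes before the first TR are 0).
#'
#' @inheritParams generate_feature_streams
#' @param features feature table from [generate_feature_streams()].
#' @param group_code +1 (affair) or -1 (paranoia).
#' @param n_subjects number of subjects to simulate.
#' @return list with `outcomes` (`n_subjects x n_trs` 0/1 matrix) and `u`
#'   (realized subject intercepts).
#' @export
generate_state_occupancy <- function(features, coupling, group_code,
                                     n_subjects = 19L,
                                     seed = coupling$seed) {
  simulate_logistic_outcomes(features, coupling, group_code, n_subjects,
                             seed)
}

#' Generate behavioral button presses from the logistic ground truth
#'
#' Identical generative engine as [generate_state_occupancy()] with a button
#' press in place of state occupancy; also returns press times (seconds, TR
#' midpoints) for exercising the raw-press ingestion path.
#'
#' @inheritParams generate_state_occupancy
#' @param tr_seconds TR duration used to convert press bins to seconds.
#' @return list with `outcomes`, `u`, and `press_times` (list of numeric
#'   vectors, seconds).
#' @export
generate_button_presses <- function(features, coupling, group_code,
                                    n_subjects = 19L, tr_seconds = 1.5,
                                    seed = coupling$seed) {
  res <- simulate_logistic_outcomes(features, coupling, group_code,
                                    n_subjects, seed)
  res$press_times <- lapply(seq_len(n_subjects), function(s) {
    (which(res$outcomes[s, ] == 1L) - 0.5) * tr_seconds
  })
  res
}
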