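# Gaussian-emission hidden Markov models: dwell-time-informed
# initialization, EM with restart selection, decoding, leave-one-subject-out
# cross-validation, and Hungarian state matching.

#' Initialize Gaussian HMM parameters
#'
#' Transition probabilities are initialized to favor an expected dwell time:
#' the diagonal is `1 - tr_s / expected_dwell_s` with off-diagonal mass
#' uniform.  This is a weak prior only; transition probabilities are
#' re-estimated during EM, so final dwell times are determined by the data.
#' Start probabilities are uniform, state means are standard-normal draws
#' under `seed`, and covariances are identity plus a small diagonal ridge.
#'
#' @param n_states number of states `K` (>= 1).
#' @param n_networks observation dimensionality.
#' @param expected_dwell_s expected dwell time in seconds (default 7).
#' @param tr_s TR duration in seconds (default 1.5); must not exceed the
#'   dwell time.
#' @param seed seed for the mean draws.
#' @param ridge diagonal ridge added to covariances (default 1e-6).
#' @return object of class `hmm_params`: `means` (K x d), `covs` (list of
#'   d x d), `transition`, `start`, `ridge`.
#' @export
init_hmm_params <- function(n_states, n_networks, expected_dwell_s = 7,
                            tr_s = 1.5, seed = 1L, ridge = 1e-6) {
  stopifnot(is_count(n_states, 1L), is_count(n_networks, 1L), ridge > 0)
  if (expected_dwell_s < tr_s)
    stopf("expected dwell (%gs) must be at least one TR (%gs)",
          expected_dwell_s, tr_s)
  A <- dwell_transition_matrix(n_states, expected_dwell_s / tr_s)
  means <- with_seed(seed,
                     matrix(rnorm(n_states * n_networks), n_states))
  structure(list(means = means,
                 covs = rep(list(diag(1 + ridge, n_networks)), n_states),
                 transition = A,
                 start = rep(1 / n_states, n_states),
                 ridge = ridge),
            class = "hmm_params")
}

# Per-state Gaussian log-densities for all rows of X (T x d) -> T x K.
# Cholesky-based; assumes covariances are positive definite (the EM ridge
# guarantees it).
#' @noRd
gaussian_logdens <- function(X, params) {
  K <- nrow(params$means)
  d <- ncol(X)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    L <- t(chol(params$covs[[k]]))
    Z <- forwardsolve(L, t(X) - params$means[k, ])
    out[, k] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(L))) +
                          colSums(Z^2))
  }
  out
}

# One EM run from given initial parameters over a list of sequences.
# Returns params, per-iteration log-likelihoods, and convergence info.
#' @noRd
em_run <- function(seqs, params, tol = 1e-4, maxit = 500L,
                   cov_type = c("full", "diag")) {
  cov_type <- match.arg(cov_type)
  K <- nrow(params$means)
  d <- ncol(params$means)
  eps <- params$ridge
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  for (it in seq_len(maxit)) {
    logA <- log(params$transition)
    logpi <- log(params$start)
    ll <- 0
    gamma_all <- vector("list", length(seqs))
    xi_sum <- matrix(0, K, K)
    start_acc <- numeric(K)
    for (s in seq_along(seqs)) {
      logB <- gaussian_logdens(seqs[[s]], params)
      fb <- hmm_forward_backward_cpp(logB, logA, logpi)
      ll <- ll + fb$loglik
      gamma_all[[s]] <- fb$gamma
      xi_sum <- xi_sum + fb$xi_sum
      start_acc <- start_acc + fb$gamma[1L, ]
    }
    if (!is.finite(ll)) stop("EM log-likelihood is not finite")
    ll_trace <- c(ll_trace, ll)
    if (it > 1L) {
      if (ll < ll_prev - 1e-8 * abs(ll_prev))
        stop("EM log-likelihood decreased; numerical failure")
      if ((ll - ll_prev) <= tol * abs(ll_prev)) {
        return(list(params = params, loglik = ll, ll_trace = ll_trace,
                    iterations = it, converged = TRUE))
      }
    }
    ll_prev <- ll
    # M-step
    G <- do.call(rbind, gamma_all)
    X <- do.call(rbind, seqs)
    w <- colSums(G)
    w <- pmax(w, 1e-12)
    means <- t(G) %*% X / w
    covs <- vector("list", K)
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2L, means[k, ])
      S <- crossprod(Xc * G[, k], Xc) / w[k]
      if (cov_type == "diag") S <- diag(diag(S), d)
      covs[[k]] <- S + diag(eps, d)
    }
    A <- xi_sum
    rs <- rowSums(A)
    for (k in seq_len(K))
      A[k, ] <- if (rs[k] > 0) A[k, ] / rs[k] else rep(1 / K, K)
    start <- start_acc / sum(start_acc)
    # keep strictly positive for log-space recursions
    A <- pmax(A, 1e-300); A <- A / rowSums(A)
    start <- pmax(start, 1e-300); start <- start / sum(start)
    params$means <- means
    params$covs <- covs
    params$transition <- A
    params$start <- start
  }
  list(params = params, loglik = ll_prev, ll_trace = ll_trace,
       iterations = maxit, converged = FALSE)
}

#' Fit a Gaussian HMM with restart selection
#'
#' Runs EM from `n_restarts` independent initializations (restart `r` is
#' seeded `base_seed + r - 1`, which drives the random mean draws; EM itself
#' is deterministic given the initialization) and returns the restart with
#' the highest training log-likelihood.  The per-iteration log-likelihood is
#' asserted non-decreasing on every run, and the diagonal ridge is
#' re-applied to every covariance at every M-step.
#'
#' @param series_list list of [network_series()] (z-scored), or a stacked
#'   object from [concatenate_subjects()].
#' @param n_states number of states `K` (2-20 in the standard sweep;
#'   `K = 1` is allowed for degenerate checks).
#' @param n_restarts independent initialization attempts (default 5).
#' @param base_seed seed for restart 1.
#' @param expected_dwell_s,tr_s dwell-time initialization (see
#'   [init_hmm_params()]).
#' @param tol relative log-likelihood convergence tolerance (default 1e-4).
#' @param maxit maximum EM iterations per restart (default 500).
#' @param cov_type `"full"` (default) or `"diag"` state covariances.
#' @param ridge covariance ridge (default 1e-6).
#' @return object of class `hmm_fit`: best `params`, `loglik`, `ll_trace`,
#'   `iterations`, `restarts` (per-restart seed, log-likelihood, status),
#'   and the control settings.
#' @export
fit_hmm <- function(series_list, n_states, n_restarts = 5L, base_seed = 1L,
                    expected_dwell_s = 7, tr_s = 1.5, tol = 1e-4,
                    maxit = 500L, cov_type = "full", ridge = 1e-6) {
  stopifnot(is_count(n_states, 1L), n_states <= 20L, is_count(n_restarts, 1L))
  seqs <- extract_sequences(series_list)
  d <- ncol(seqs[[1L]])
  runs <- vector("list", n_restarts)
  seeds <- base_seed + seq_len(n_restarts) - 1L
  for (r in seq_len(n_restarts)) {
    init <- init_hmm_params(n_states, d, expected_dwell_s, tr_s,
                            seed = seeds[r], ridge = ridge)
    runs[[r]] <- tryCatch(
      em_run(seqs, init, tol = tol, maxit = maxit, cov_type = cov_type),
      error = function(e) list(failed = TRUE, message = conditionMessage(e))
    )
  }
  ok <- !vapply(runs, function(x) isTRUE(x$failed), TRUE)
  if (!any(ok)) stop("all EM restarts failed")
  lls <- vapply(runs, function(x) if (isTRUE(x$failed)) -Inf else x$loglik,
                1)
  best <- which.max(lls)
  res <- runs[[best]]
  structure(list(params = res$params, loglik = res$loglik,
                 ll_trace = res$ll_trace, iterations = res$iterations,
                 converged = res$converged,
                 restarts = data.frame(seed = seeds, loglik = lls,
                                       failed = !ok),
                 n_states = as.integer(n_states),
                 control = list(n_restarts = n_restarts,
                                base_seed = base_seed,
                                expected_dwell_s = expected_dwell_s,
                                tr_s = tr_s, tol = tol, maxit = maxit,
                                cov_type = cov_type, ridge = ridge)),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf(
    "<hmm_fit> K = %d, loglik = %.2f (best of %d restarts), %d EM iter%s\n",
    x$n_states, x$loglik, nrow(x$restarts), x$iterations,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @noRd
extract_sequences <- function(series_list) {
  if (is.list(series_list) && !is.null(series_list$ranges))
    series_list <- split_subjects(series_list)
  if (inherits(series_list, "network_series"))
    series_list <- list(series_list)
  lapply(series_list, function(s) {
    if (inherits(s, "network_series")) s$data else as.matrix(s)
  })
}

#' Decode a series under a fitted HMM
#'
#' Viterbi most-likely joint path plus forward-backward posterior state
#' probabilities.
#'
#' @param fit an [fit_hmm()] result (or bare `hmm_params`).
#' @param series a [network_series()] or TR x network matrix.
#' @return object of class `state_sequence`: `subject_id`, `path` (1-based
#'   states), `posterior` (TR x K, rows sum to 1), `loglik`.
#' @export
decode_states <- function(fit, series) {
  params <- if (inherits(fit, "hmm_fit")) fit$params else fit
  X <- if (inherits(series, "network_series")) series$data else
    as.matrix(series)
  if (ncol(X) != ncol(params$means))
    stopf("series has %d networks but the model expects %d",
          ncol(X), ncol(params$means))
  logB <- gaussian_logdens(X, params)
  logA <- log(params$transition)
  logpi <- log(params$start)
  fb <- hmm_forward_backward_cpp(logB, logA, logpi)
  path <- hmm_viterbi_cpp(logB, logA, logpi) + 1L
  structure(list(subject_id = if (inherits(series, "network_series"))
                   series$subject_id else NA_character_,
                 path = path, posterior = fb$gamma, loglik = fb$loglik),
            class = "state_sequence")
}

#' Held-out log-likelihood of a series under a fitted HMM
#' @inheritParams decode_states
#' @return scalar log-likelihood.
#' @export
series_loglik <- function(fit, series) {
  params <- if (inherits(fit, "hmm_fit")) fit$params else fit
  X <- if (inherits(series, "network_series")) series$data else
    as.matrix(series)
  hmm_loglik_cpp(gaussian_logdens(X, params), log(params$transition),
                 log(params$start))
}

#' Match states across two models with the Hungarian algorithm
#'
#' Finds the permutation of model B's states maximizing the summed Pearson
#' correlation between matched mean activation vectors.
#'
#' @param means_a,means_b K x d matrices of state means (equal K).
#' @return list with `permutation` (`permutation[i]` is the row of
#'   `means_b` matched to row `i` of `means_a`), `correlations` (matched
#'   Pearson r), and `total` (their sum).
#' @export
match_states <- function(means_a, means_b) {
  means_a <- as.matrix(means_a); means_b <- as.matrix(means_b)
  if (nrow(means_a) != nrow(means_b))
    stopf("state counts differ (%d vs %d); cross-K matching is out of scope",
          nrow(means_a), nrow(means_b))
  C <- cor(t(means_a), t(means_b))
  perm <- hungarian_solve(max(C) - C)
  r <- C[cbind(seq_len(nrow(C)), perm)]
  list(permutation = perm, correlations = r, total = sum(r))
}

# O(n^3) Hungarian assignment (potentials formulation).  Returns, for each
# row, the column of the minimum-cost perfect matching.
#' @noRd
hungarian_solve <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  # arrays indexed 0..n stored at offset +1; row/col 0 are virtual
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) out[p[j + 1L]] <- j
  out
}

#' Leave-one-subject-out cross-validation of an HMM
#'
#' For each fold a group-level model is trained on all but one subject and
#' evaluated on the held-out subject.  Cross-fold pattern reliability is the
#' mean Hungarian-matched correlation of state means over all fold pairs.
#'
#' @inheritParams fit_hmm
#' @param ... further arguments passed to [fit_hmm()].
#' @return list with `fold_loglik` (held-out log-likelihood per fold),
#'   `mean_loglik` (per-fold mean), `reliability` (mean matched correlation
#'   over fold pairs), and `fold_means` (list of K x d matrices).
#' @export
loocv_hmm <- function(series_list, n_states, n_restarts = 5L,
                      base_seed = 1L, ...) {
  seqs <- extract_sequences(series_list)
  n <- length(seqs)
  if (n < 3L) stop("LOOCV needs at least 3 subjects")
  fold_ll <- numeric(n)
  fold_means <- vector("list", n)
  for (i in seq_len(n)) {
    fit <- fit_hmm(seqs[-i], n_states, n_restarts = n_restarts,
                   base_seed = base_seed, ...)
    fold_ll[i] <- series_loglik(fit, seqs[[i]])
    fold_means[[i]] <- fit$params$means
  }
  pair_r <- c()
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n))
      pair_r <- c(pair_r,
                  mean(match_states(fold_means[[i]],
                                    fold_means[[j]])$correlations))
  list(fold_loglik = fold_ll, mean_loglik = mean(fold_ll),
       reliability = mean(pair_r), fold_means = fold_means)
}
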