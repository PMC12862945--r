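# MAP-estimated Bayesian logistic mixed models for binary TR series (brain
# state occupancy or button presses): deviation-coded group, feature x group
# interactions, AR(2) outcome lags, subject random intercepts, curvature-
# based posterior uncertainty, direction probabilities, Bayesian FDR, and
# odds-ratio decompositions into group-specific effects.

#' Prior specification for the MAP logistic mixed model
#'
#' Fixed effects get independent Normal(0, tau^2) priors; the random-
#' intercept variance gets an Inverse-Gamma(a0, b0) prior.  The defaults
#' (tau = 2.5 on binary predictors, Inverse-Gamma(2, 1)) are standard
#' weakly-informative choices.
#'
#' @param tau prior SD of fixed effects (`Inf` for a flat prior).
#' @param a0,b0 Inverse-Gamma shape and scale for the random-intercept
#'   variance.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(tau = 2.5, a0 = 2, b0 = 1) {
  stopifnot(tau > 0, a0 > 0, b0 > 0)
  structure(list(tau = tau, a0 = a0, b0 = b0), class = "prior_spec")
}

#' Build the GLMM design from per-TR features and binary outcome series
#'
#' Stacks subjects into long form with a fixed, recorded column order:
#' intercept, deviation-coded group (+1 affair / -1 paranoia), feature main
#' effects, group x feature interactions, then AR outcome lags (lags before
#' each subject's first TRs are padded with 0).
#'
#' @param features `data.frame` or matrix of per-TR 0/1 annotation columns
#'   (a `tr_index` column is ignored); shared by all subjects.
#' @param outcomes subjects x TR 0/1 matrix (or list of vectors).
#' @param groups per-subject labels (`"affair"`/`"paranoia"`) or codes
#'   (+1/-1).
#' @param n_lags number of AR outcome lags (default 2).
#' @param feature_names optional subset/order of feature columns to use.
#' @return object of class `glmm_design`: `X` (fixed-effect matrix), `y`,
#'   `subject` (integer index), `subject_ids`, and column bookkeeping
#'   (`feature_cols`, `interaction_cols`, `lag_cols`).
#' @export
build_design <- function(features, outcomes, groups, n_lags = 2L,
                         feature_names = NULL) {
  if (is.list(outcomes) && !is.matrix(outcomes))
    outcomes <- do.call(rbind, outcomes)
  outcomes <- as.matrix(outcomes)
  n_subj <- nrow(outcomes); n_trs <- ncol(outcomes)
  if (length(groups) != n_subj)
    stopf("%d group labels for %d subjects", length(groups), n_subj)
  g <- if (is.numeric(groups)) {
    if (!all(groups %in% c(-1, 1))) stop("numeric group codes must be +/-1")
    as.numeric(groups)
  } else {
    if (!all(groups %in% c("affair", "paranoia")))
      stopf("unknown group label(s): %s",
            paste(setdiff(groups, c("affair", "paranoia")), collapse = ", "))
    ifelse(groups == "affair", 1, -1)
  }
  fmat <- as.matrix(as.data.frame(features)[
    , setdiff(colnames(as.data.frame(features)), "tr_index"), drop = FALSE])
  if (!is.null(feature_names)) {
    missing <- setdiff(feature_names, colnames(fmat))
    if (length(missing))
      stopf("missing feature column(s): %s", paste(missing, collapse = ", "))
    fmat <- fmat[, feature_names, drop = FALSE]
  }
  if (nrow(fmat) != n_trs)
    stopf("features have %d TRs but outcomes have %d", nrow(fmat), n_trs)
  J <- ncol(fmat)
  feat_nm <- colnames(fmat)
  rows_per <- n_trs
  n <- n_subj * rows_per
  X <- matrix(0, n, 2L + 2L * J + n_lags)
  colnames(X) <- c("(Intercept)", "group", feat_nm,
                   if (J) paste0("group:", feat_nm),
                   if (n_lags) paste0("lag", seq_len(n_lags)))
  y <- numeric(n)
  subject <- integer(n)
  for (s in seq_len(n_subj)) {
    rows <- (s - 1L) * rows_per + seq_len(rows_per)
    ys <- as.numeric(outcomes[s, ])
    X[rows, 1L] <- 1
    X[rows, 2L] <- g[s]
    if (J) {
      X[rows, 2L + seq_len(J)] <- fmat
      X[rows, 2L + J + seq_len(J)] <- g[s] * fmat
    }
    for (l in seq_len(n_lags))
      X[rows, 2L + 2L * J + l] <- c(rep(0, l), ys[seq_len(rows_per - l)])
    y[rows] <- ys
    subject[rows] <- s
  }
  structure(list(X = X, y = y, subject = subject,
                 subject_ids = rownames(outcomes) %||%
                   as.character(seq_len(n_subj)),
                 group_codes = g,
                 feature_cols = if (J) 2L + seq_len(J) else integer(0),
                 interaction_cols = if (J) 2L + J + seq_len(J) else
                   integer(0),
                 lag_cols = if (n_lags) 2L + 2L * J + seq_len(n_lags) else
                   integer(0)),
            class = "glmm_design")
}

#' Fit the logistic mixed model by maximum a posteriori estimation
#'
#' Maximizes the Bernoulli log-likelihood plus the log priors jointly over
#' the fixed effects, the subject intercepts and the random-intercept
#' variance by block alternation: Newton steps on `(beta, u)` given
#' `sigma_u^2`, then the closed-form penalized update
#' `sigma_u^2 = (sum(u_i^2) + 2 b0) / (n_subj + 2 a0 + 2)`.  Posterior SDs
#' come from the inverse curvature (Laplace approximation) of the penalized
#' objective at the optimum; the full fixed-effect covariance block is kept
#' so that linear combinations (group-specific effects) get correct
#' variances.
#'
#' @param design a [build_design()] result.
#' @param priors a [prior_spec()].
#' @param random_intercept include subject random intercepts
#'   (default `TRUE`; `FALSE` gives a plain penalized/flat logistic fit).
#' @param tol convergence tolerance on the max-abs parameter change
#'   (default 1e-6).
#' @param maxit maximum outer iterations (default 200).
#' @return object of class `glmm_fit`: `coefficients`, `sd`, `vcov`,
#'   `u` (subject intercepts), `sigma_u2`, `direction_prob`
#'   (`P(effect > 0)` per coefficient), `results` table (estimate, sd, OR,
#'   CI, direction probability), plus design bookkeeping.
#' @export
fit_map <- function(design, priors = prior_spec(),
                    random_intercept = TRUE, tol = 1e-6, maxit = 200L) {
  stopifnot(inherits(design, "glmm_design"), inherits(priors, "prior_spec"))
  X <- design$X; y <- design$y
  if (all(y == 0) || all(y == 1))
    stop("outcome is constant (all 0 or all 1)")
  p <- ncol(X)
  n_subj <- length(unique(design$subject))
  S <- if (random_intercept) n_subj else 0L
  # augmented design: fixed effects then subject indicators
  if (S) {
    Z <- matrix(0, nrow(X), S)
    Z[cbind(seq_len(nrow(X)), design$subject)] <- 1
    W <- cbind(X, Z)
  } else W <- X
  theta <- numeric(p + S)
  sigma2 <- 1
  prec_fixed <- if (is.finite(priors$tau)) 1 / priors$tau^2 else 0
  for (outer in seq_len(maxit)) {
    theta_old <- theta; sigma2_old <- sigma2
    pen <- c(rep(prec_fixed, p), rep(if (S) 1 / sigma2 else 0, S))
    # Newton iterations on (beta, u) at fixed sigma2
    for (inner in seq_len(100L)) {
      eta <- as.numeric(W %*% theta)
      mu <- plogis(eta)
      w <- mu * (1 - mu)
      grad <- as.numeric(crossprod(W, y - mu)) - pen * theta
      H <- crossprod(W * w, W)
      diag(H) <- diag(H) + pen
      step <- tryCatch(solve(H, grad), error = function(e)
        stop("MAP Newton step failed: singular curvature (separation?)"))
      # step-halving to keep the penalized objective from diverging
      obj <- function(th) {
        e <- as.numeric(W %*% th)
        # stable log(1 + exp(e)) = max(e, 0) + log1p(exp(-|e|))
        sum(y * e - (pmax(e, 0) + log1p(exp(-abs(e))))) -
          sum(pen * th^2) / 2
      }
      f0 <- obj(theta); lambda <- 1
      repeat {
        cand <- theta + lambda * step
        if (obj(cand) >= f0 - 1e-10 || lambda < 1e-4) break
        lambda <- lambda / 2
      }
      theta <- cand
      if (max(abs(lambda * step)) < tol) break
    }
    if (S) {
      u <- theta[p + seq_len(S)]
      sigma2 <- (sum(u^2) + 2 * priors$b0) / (S + 2 * priors$a0 + 2)
    }
    if (max(abs(theta - theta_old)) < tol &&
        abs(sigma2 - sigma2_old) < tol) break
    if (outer == maxit)
      stop("MAP estimation did not converge within ", maxit,
           " outer iterations")
  }
  beta <- theta[seq_len(p)]
  names(beta) <- colnames(X)
  if (!random_intercept && prec_fixed == 0 && any(abs(beta) > 15))
    warning("coefficient beyond +/-15 in flat-prior mode: possible ",
            "separation; consider prior regularization")
  # Laplace curvature at the optimum
  eta <- as.numeric(W %*% theta)
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  pen <- c(rep(prec_fixed, p), rep(if (S) 1 / sigma2 else 0, S))
  H <- crossprod(W * w, W)
  diag(H) <- diag(H) + pen
  V <- solve(H)
  vcov_beta <- V[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(vcov_beta) <- list(names(beta), names(beta))
  sds <- sqrt(diag(vcov_beta))
  dp <- pnorm(ifelse(sds > 0, beta / sds,
                     ifelse(beta == 0, 0, sign(beta) * Inf)))
  fit <- structure(list(coefficients = beta, sd = sds, vcov = vcov_beta,
                        u = if (S) theta[p + seq_len(S)] else numeric(0),
                        sigma_u2 = if (S) sigma2 else NA_real_,
                        direction_prob = dp,
                        feature_cols = design$feature_cols,
                        interaction_cols = design$interaction_cols,
                        lag_cols = design$lag_cols,
                        priors = priors,
                        random_intercept = random_intercept),
                   class = "glmm_fit")
  fit$results <- odds_ratio_table(fit)
  fit
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> %d fixed effects, %d subjects, sigma_u^2 = %s\n",
              length(x$coefficients), length(x$u),
              if (is.na(x$sigma_u2)) "none" else
                sprintf("%.3f", x$sigma_u2)))
  print(x$results, digits = 3)
  invisible(x)
}

#' Per-coefficient odds ratios with 95% intervals
#'
#' `OR = exp(beta)`, interval `exp(beta +/- 1.96 sd)`.
#' @param fit a [fit_map()] result.
#' @return `data.frame`: term, estimate, sd, OR, CI bounds, `P(effect>0)`.
#' @export
odds_ratio_table <- function(fit) {
  z <- qnorm(0.975)
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             sd = unname(fit$sd),
             or = exp(unname(fit$coefficients)),
             or_low = exp(unname(fit$coefficients - z * fit$sd)),
             or_high = exp(unname(fit$coefficients + z * fit$sd)),
             p_positive = unname(fit$direction_prob))
}

#' Posterior direction probabilities
#'
#' Gaussian (Laplace) approximation: `P(effect > 0) = Phi(beta / sd)`.
#' @param fit a [fit_map()] result.
#' @return named numeric vector of probabilities.
#' @export
direction_probability <- function(fit) fit$direction_prob

#' Bayesian false discovery rate on direction probabilities
#'
#' For each coefficient the posterior error of its dominant direction is
#' `e = 1 - max(P(>0), 1 - P(>0))`.  Errors are sorted ascending and the
#' largest prefix whose running mean stays at or below `alpha` is flagged
#' credible; each coefficient's FDR-adjusted posterior probability is one
#' minus the running mean at its rank.
#'
#' @param direction_probs numeric vector of `P(effect > 0)` values (e.g.
#'   [direction_probability()]).
#' @param alpha target false discovery rate (default 0.05; the "adjusted
#'   probability exceeds 0.95" rule).
#' @return `data.frame` in the input order: `p_direction`, `error`,
#'   `adjusted_prob`, `credible`.
#' @export
bayesian_fdr <- function(direction_probs, alpha = 0.05) {
  pstar <- pmax(direction_probs, 1 - direction_probs)
  e <- 1 - pstar
  ord <- order(e)
  run_mean <- cumsum(e[ord]) / seq_along(e)
  credible_sorted <- run_mean <= alpha
  # largest prefix: everything up to the last rank satisfying the bound
  kmax <- if (any(credible_sorted)) max(which(credible_sorted)) else 0L
  credible <- logical(length(e))
  credible[ord[seq_len(kmax)]] <- TRUE
  adjusted <- numeric(length(e))
  adjusted[ord] <- 1 - run_mean
  data.frame(p_direction = direction_probs, error = e,
             adjusted_prob = adjusted, credible = credible)
}

#' Group-specific effects under deviation coding
#'
#' With group coded +1 (affair) / -1 (paranoia), a feature's group-specific
#' log-odds are `beta_j + beta_gj` (affair) and `beta_j - beta_gj`
#' (paranoia); the main-effect OR is the geometric mean of the two group
#' ORs and the interaction OR is the exponential of half their log
#' difference.  Variances use the full covariance of the linear
#' combination (`var_j + var_gj +/- 2 cov`).
#'
#' @param fit a [fit_map()] result whose design had interaction columns.
#' @return `data.frame`: feature, group, log-odds, sd, OR, CI bounds,
#'   `P(effect>0)`.
#' @export
group_effects <- function(fit) {
  jj <- fit$feature_cols; gg <- fit$interaction_cols
  stopifnot(length(jj) == length(gg))
  out <- NULL
  z <- qnorm(0.975)
  for (i in seq_along(jj)) {
    bj <- fit$coefficients[jj[i]]; bg <- fit$coefficients[gg[i]]
    vj <- fit$vcov[jj[i], jj[i]]; vg <- fit$vcov[gg[i], gg[i]]
    cv <- fit$vcov[jj[i], gg[i]]
    for (grp in c("affair", "paranoia")) {
      sgn <- if (grp == "affair") 1 else -1
      est <- unname(bj + sgn * bg)
      v <- max(vj + vg + 2 * sgn * cv, 0)
      sdv <- sqrt(v)
      out <- rbind(out, data.frame(
        feature = names(fit$coefficients)[jj[i]], group = grp,
        log_odds = est, sd = sdv, or = exp(est),
        or_low = exp(est - z * sdv), or_high = exp(est + z * sdv),
        p_positive = if (sdv > 0) pnorm(est / sdv) else
          as.numeric(est > 0)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Binary occupancy series of a representative state
#'
#' 1 iff the subject's decoded state at a TR equals the representative
#' state.
#'
#' @param paths list of decoded 1-based state paths.
#' @param state_index the representative state's index in its model.
#' @return subjects x TR 0/1 matrix.
#' @export
representative_occupancy <- function(paths, state_index) {
  out <- do.call(rbind, lapply(paths, function(p)
    as.integer(p == state_index)))
  if (all(out == 0L))
    warning("representative state ", state_index,
            " is never visited; outcome is all zeros")
  out
}
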