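# Reliability screening of fitted states: fractional occupancy, bootstrap
# confidence intervals on mean activation, split-half pattern reliability,
# and the three-criterion filter that builds the pool of state patterns
# consumed by the clustering stage.

#' Fractional occupancy of each state
#'
#' Fraction of all subject-TRs assigned to each state.
#'
#' @param paths list of decoded state paths (1-based integer vectors), or a
#'   single vector.
#' @param n_states number of states `K`.
#' @return length-`K` numeric vector summing to 1.
#' @export
fractional_occupancy <- function(paths, n_states) {
  if (!is.list(paths)) paths <- list(paths)
  all_trs <- unlist(paths, use.names = FALSE)
  stopifnot(all(all_trs >= 1L), all(all_trs <= n_states))
  tabulate(all_trs, nbins = n_states) / length(all_trs)
}

#' Bootstrap confidence intervals for a state's mean activation
#'
#' Percentile intervals from `B` resamples (with replacement) of the TRs
#' assigned to a state.
#'
#' @param rows TR x network matrix of the data rows assigned to the state.
#' @param B number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return `data.frame` with one row per network: `low`, `high`, `width`.
#' @export
bootstrap_ci <- function(rows, B = 1000L, level = 0.95, seed = 1L) {
  rows <- as.matrix(rows)
  n <- nrow(rows)
  stopifnot(n >= 2L, B >= 2L, level > 0, level < 1)
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    means <- matrix(0, B, ncol(rows))
    for (b in seq_len(B))
      means[b, ] <- colMeans(rows[idx[b, ], , drop = FALSE])
    a <- (1 - level) / 2
    lo <- apply(means, 2L, quantile, probs = a, names = FALSE)
    hi <- apply(means, 2L, quantile, probs = 1 - a, names = FALSE)
    data.frame(network = colnames(rows) %||% seq_len(ncol(rows)),
               low = lo, high = hi, width = hi - lo)
  })
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split-half reliability of a state's mean activation pattern
#'
#' The TRs assigned to the state are divided into two halves, mean
#' activation patterns are estimated separately, and their Pearson
#' correlation is returned.  The default split is chronological (first vs
#' second half of the assigned TRs, in assignment order), the reading most
#' conservative against temporal autocorrelation; `"interleaved"` uses
#' odd/even TRs.
#'
#' @inheritParams bootstrap_ci
#' @param method `"chronological"` (default) or `"interleaved"`.
#' @return Pearson correlation between the two half-mean patterns.
#' @export
split_half_reliability <- function(rows,
                                   method = c("chronological",
                                              "interleaved")) {
  method <- match.arg(method)
  rows <- as.matrix(rows)
  n <- nrow(rows)
  if (n < 4L) return(NA_real_)
  first <- if (method == "chronological") seq_len(n %/% 2L)
           else seq(1L, n, by = 2L)
  m1 <- colMeans(rows[first, , drop = FALSE])
  m2 <- colMeans(rows[-first, , drop = FALSE])
  if (sd(m1) == 0 || sd(m2) == 0) return(NA_real_)
  cor(m1, m2)
}

#' Screen a fitted model's states with the three reliability criteria
#'
#' A state passes iff (1) at least one network's mean activation deviates
#' from baseline by more than `theta_act` in absolute value, (2) its
#' bootstrap CI widths are below `theta_ci`, and (3) its split-half pattern
#' correlation exceeds `theta_sh`.  States with fewer than `min_trs`
#' assigned TRs automatically fail.  Each retained state is packaged as a
#' `state_pattern` carrying its fractional occupancy and full provenance
#' (group, model size, original and normalized state index).
#'
#' @param fit an [fit_hmm()] result.
#' @param paths list of decoded paths for the subjects the model was fit on.
#' @param data list of the corresponding TR x network matrices (or
#'   [network_series()]).
#' @param group provenance label: `"affair"`, `"paranoia"`, `"combined"` or
#'   `"balanced"`.
#' @param theta_act minimum activation threshold (default 0.1 z units).
#' @param theta_ci maximum bootstrap CI width (default 0.3).
#' @param theta_sh minimum split-half correlation (default 0.5).
#' @param ci_scope `"all"` (default) requires every network's CI to be
#'   narrow; `"active"` only the supra-threshold networks'.
#' @param min_trs minimum assigned TRs for a state to be evaluable
#'   (default 10).
#' @param B,seed bootstrap settings (see [bootstrap_ci()]).
#' @param split_method split-half convention (see
#'   [split_half_reliability()]).
#' @return list with `patterns` (list of `state_pattern`) and `rejections`
#'   (`data.frame`: `state_index`, `reason`).
#' @export
filter_states <- function(fit, paths, data, group = "combined",
                          theta_act = 0.1, theta_ci = 0.3, theta_sh = 0.5,
                          ci_scope = c("all", "active"), min_trs = 10L,
                          B = 1000L, seed = 1L,
                          split_method = "chronological") {
  ci_scope <- match.arg(ci_scope)
  stopifnot(group %in% c("affair", "paranoia", "combined", "balanced"))
  K <- fit$n_states
  mats <- extract_sequences(data)
  stopifnot(length(mats) == length(paths))
  all_rows <- do.call(rbind, mats)
  all_path <- unlist(paths, use.names = FALSE)
  stopifnot(nrow(all_rows) == length(all_path))
  occ <- fractional_occupancy(paths, K)
  patterns <- list()
  rej <- data.frame(state_index = integer(0), reason = character(0))
  for (k in seq_len(K)) {
    mu <- fit$params$means[k, ]
    rows <- all_rows[all_path == k, , drop = FALSE]
    reason <- NULL
    ci <- NULL; shr <- NA_real_
    if (nrow(rows) < min_trs) {
      reason <- "insufficient_trs"
    } else if (max(abs(mu)) <= theta_act) {
      reason <- "activation"
    } else {
      ci <- bootstrap_ci(rows, B = B, seed = seed + k)
      widths <- if (ci_scope == "all") ci$width
                else ci$width[abs(mu) > theta_act]
      if (any(widths >= theta_ci)) {
        reason <- "ci_width"
      } else {
        shr <- split_half_reliability(rows, method = split_method)
        if (is.na(shr) || shr <= theta_sh) reason <- "split_half"
      }
    }
    if (is.null(reason)) {
      patterns[[length(patterns) + 1L]] <- state_pattern(
        mean = mu, occupancy = occ[k], group = group, model_K = K,
        state_index = k,
        max_abs_activation = max(abs(mu)),
        ci_width_max = max(ci$width), split_half_r = shr)
    } else {
      rej <- rbind(rej, data.frame(state_index = k, reason = reason))
    }
  }
  list(patterns = patterns, rejections = rej, occupancy = occ)
}

#' Construct a state pattern
#'
#' One state's mean activation vector with occupancy, reliability metrics
#' and provenance; the unit pooled across models for consensus clustering.
#'
#' @param mean numeric mean activation vector (z units).
#' @param occupancy fractional occupancy in `[0, 1]`.
#' @param group provenance group label.
#' @param model_K number of states of the source model.
#' @param state_index 1-based index of the state in the source model.
#' @param max_abs_activation,ci_width_max,split_half_r reliability metrics.
#' @return object of class `state_pattern` with derived
#'   `normalized_index = state_index / model_K`.
#' @export
state_pattern <- function(mean, occupancy, group, model_K, state_index,
                          max_abs_activation = max(abs(mean)),
                          ci_width_max = NA_real_,
                          split_half_r = NA_real_) {
  stopifnot(occupancy >= 0, occupancy <= 1,
            state_index >= 1L, state_index <= model_K)
  structure(list(mean = as.numeric(mean), occupancy = occupancy,
                 group = group, model_K = as.integer(model_K),
                 state_index = as.integer(state_index),
                 normalized_index = state_index / model_K,
                 max_abs_activation = max_abs_activation,
                 ci_width_max = ci_width_max,
                 split_half_r = split_half_r),
            class = "state_pattern")
}
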