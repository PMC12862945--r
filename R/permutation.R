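# Permutation tests of group differences in state occupancy time courses:
# random participant splits preserving group sizes, with an add-one
# corrected p-value.

#' Group difference in occupancy time courses
#'
#' Default statistic: the mean over TRs of the absolute difference between
#' the two groups' mean occupancy.  `"max_abs"` and `"sum_sq"` variants are
#' available; the choice is reported alongside any result.
#'
#' @param occupancy subjects x TR 0/1 (or probability) matrix.
#' @param labels per-subject group labels with exactly two levels.
#' @param statistic `"mean_abs"` (default), `"max_abs"` or `"sum_sq"`.
#' @return scalar statistic.
#' @export
occupancy_difference <- function(occupancy, labels,
                                 statistic = c("mean_abs", "max_abs",
                                               "sum_sq")) {
  statistic <- match.arg(statistic)
  occupancy <- as.matrix(occupancy)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("need exactly two groups")
  d <- colMeans(occupancy[labels == lv[1L], , drop = FALSE]) -
    colMeans(occupancy[labels == lv[2L], , drop = FALSE])
  switch(statistic,
         mean_abs = mean(abs(d)),
         max_abs = max(abs(d)),
         sum_sq = sum(d^2))
}

#' Permutation test of a group difference in temporal dynamics
#'
#' Builds a null distribution from random participant splits that preserve
#' the observed group sizes, and reports the add-one corrected p-value
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)` (never exactly 0).
#'
#' @inheritParams occupancy_difference
#' @param n_perm number of random splits (default 10000; below 100 a
#'   warning is issued).
#' @param seed RNG seed.
#' @return object of class `permutation_result`: `observed`, `null`
#'   (length `n_perm`), `p_value`, `n_perm`, `statistic`, `seed`.
#' @export
permutation_test <- function(occupancy, labels, n_perm = 10000L, seed = 1L,
                             statistic = c("mean_abs", "max_abs",
                                           "sum_sq")) {
  statistic <- match.arg(statistic)
  occupancy <- as.matrix(occupancy)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("need exactly two groups")
  if (n_perm < 100L) warning("n_perm < 100 gives a very coarse p-value")
  n <- nrow(occupancy)
  n1 <- sum(labels == lv[1L])
  observed <- occupancy_difference(occupancy, labels, statistic)
  null <- with_seed(seed, {
    out <- numeric(n_perm)
    # chunked indicator-matrix formulation: each permutation's group means
    # are rows of M %*% occupancy for a 0/1 membership matrix M
    chunk <- 2000L
    done <- 0L
    while (done < n_perm) {
      m <- min(chunk, n_perm - done)
      M <- matrix(0, m, n)
      for (r in seq_len(m)) M[r, sample.int(n, n1)] <- 1
      mean1 <- (M %*% occupancy) / n1
      mean2 <- ((1 - M) %*% occupancy) / (n - n1)
      d <- mean1 - mean2
      out[done + seq_len(m)] <- switch(statistic,
                                       mean_abs = rowMeans(abs(d)),
                                       max_abs = apply(abs(d), 1L, max),
                                       sum_sq = rowSums(d^2))
      done <- done + m
    }
    out
  })
  structure(list(observed = observed, null = null,
                 p_value = (1 + sum(null >= observed)) / (1 + n_perm),
                 n_perm = as.integer(n_perm), statistic = statistic,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %s = %.4f, p = %.4g (%d splits, seed %d)\n",
    x$statistic, x$observed, x$p_value, x$n_perm, x$seed))
  invisible(x)
}
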