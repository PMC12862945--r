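# Behavioral button presses: alignment of raw press times to the TR grid
# (with within-TR deduplication) and group agreement time courses.

#' Align button-press times to TR bins
#'
#' Each press lands in the bin containing it, `floor(time / bin_s)`
#' (0-based); multiple presses within one bin collapse to a single
#' response, and presses beyond the analysis window are dropped with a
#' logged count.
#'
#' @param press_times_s numeric press times in seconds (all >= 0).
#' @param bin_s bin width in seconds (the TR).
#' @param n_bins number of bins in the analysis window.
#' @return integer 0/1 vector of length `n_bins` with attribute `dropped`
#'   (number of presses past the window).
#' @export
align_presses <- function(press_times_s, bin_s, n_bins) {
  stopifnot(bin_s > 0, is_count(n_bins, 1L))
  if (any(press_times_s < 0)) stop("negative press time")
  bins <- floor(press_times_s / bin_s)
  dropped <- sum(bins >= n_bins)
  bins <- bins[bins < n_bins]
  y <- integer(n_bins)
  y[unique(bins) + 1L] <- 1L
  attr(y, "dropped") <- dropped
  y
}

#' Group agreement time course
#'
#' Per-bin proportion of subjects responding: the mean of the binary press
#' series across subjects.
#'
#' @param press_list list of equal-length 0/1 vectors (or a subjects x bins
#'   matrix).
#' @return numeric vector of per-bin proportions in `[0, 1]`.
#' @export
group_agreement <- function(press_list) {
  mat <- if (is.matrix(press_list)) press_list else
    do.call(rbind, lapply(press_list, as.integer))
  colMeans(mat)
}
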