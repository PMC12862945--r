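# Per-TR story annotation schema: binary character-speech and
# part-of-speech streams, composite features, and rasterization of
# BIDS-style event lists onto the TR grid.

# Canonical base and composite feature names.
#' @noRd
base_feature_names <- function() {
  c("arthur_speaking", "lee_speaking", "girl_speaking",
    "lee_girl_together", "verb", "noun", "adjective", "adverb")
}

#' Build composite annotation features
#'
#' Composites are elementwise products of their parent columns:
#' `lee_girl_verb = lee_girl_together * verb` (shared actions of Lee and
#' the girl) and `arthur_adjective = arthur_speaking * adjective`
#' (descriptive attributes attached to Arthur's speech).
#'
#' @param table `data.frame` of 0/1 annotation columns (a `tr_index` column
#'   is carried through untouched).
#' @param strict error if a parent column is missing (default `TRUE`); when
#'   `FALSE`, composites whose parents are absent are skipped.
#' @return the table with composite columns appended (existing composite
#'   columns are recomputed).
#' @export
build_composites <- function(table, strict = TRUE) {
  defs <- list(lee_girl_verb = c("lee_girl_together", "verb"),
               arthur_adjective = c("arthur_speaking", "adjective"))
  for (nm in names(defs)) {
    parents <- defs[[nm]]
    missing <- setdiff(parents, colnames(table))
    if (length(missing)) {
      if (strict)
        stopf("composite '%s' needs missing parent column(s): %s", nm,
              paste(missing, collapse = ", "))
      next
    }
    table[[nm]] <- as.integer(table[[parents[1L]]] * table[[parents[2L]]])
  }
  table
}

#' Rasterize a BIDS-style event list onto a TR grid
#'
#' Bin `b` (0-based) covers the half-open interval
#' `[b * bin_s, (b + 1) * bin_s)`; a feature's bit is set for every bin
#' overlapping `[onset, onset + duration)`.  Zero-duration events set the
#' bin containing their onset (point-event rule).
#'
#' @param events `data.frame` with columns `onset`, `duration` (seconds)
#'   and `trial_type` (feature name).
#' @param bin_s bin width in seconds (the TR, or 1.0 for the 1-s-resolution
#'   replication pathway).
#' @param n_bins number of bins in the grid.
#' @return `data.frame` with `tr_index` (0-based) and one 0/1 column per
#'   feature (ordered by first appearance).
#' @export
rasterize_events <- function(events, bin_s, n_bins) {
  stopifnot(all(c("onset", "duration", "trial_type") %in% colnames(events)),
            bin_s > 0, is_count(n_bins, 1L))
  if (any(events$onset < 0)) stop("negative event onset")
  if (any(events$duration < 0)) stop("negative event duration")
  feats <- unique(as.character(events$trial_type))
  out <- data.frame(tr_index = seq_len(n_bins) - 1L)
  for (f in feats) out[[f]] <- 0L
  for (i in seq_len(nrow(events))) {
    on <- events$onset[i]; dur <- events$duration[i]
    first <- floor(on / bin_s)
    last <- if (dur > 0) ceiling((on + dur) / bin_s) - 1 else first
    bins <- seq.int(max(0, first), min(n_bins - 1, last))
    if (first > n_bins - 1 || last < 0) next
    out[bins + 1L, as.character(events$trial_type[i])] <- 1L
  }
  out
}

#' Logical-OR downsampling of a binary TR table
#'
#' Collapses each block of `factor` consecutive bins into one bin that is
#' on iff any constituent bin is on; used to check rasterization
#' consistency across resolutions.
#'
#' @param table output of [rasterize_events()].
#' @param factor integer downsampling factor.
#' @return table on the coarser grid.
#' @export
downsample_or <- function(table, factor) {
  stopifnot(is_count(factor, 1L))
  n <- nrow(table)
  grp <- (table$tr_index %/% factor)
  feats <- setdiff(colnames(table), "tr_index")
  out <- data.frame(tr_index = sort(unique(grp)))
  for (f in feats)
    out[[f]] <- as.integer(tapply(table[[f]], grp, max)[as.character(out$tr_index)])
  rownames(out) <- NULL
  out
}
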