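# Time-series preparation: hemodynamic shift, trimming, parcel-to-network
# averaging, per-subject z-scoring and cross-subject concatenation.

#' Construct a network time series
#'
#' A `network_series` is one subject's TR x network matrix plus timing
#' metadata; the unit of HMM input.
#'
#' @param subject_id subject identifier.
#' @param group context label (`"affair"`, `"paranoia"` or `"none"`).
#' @param data numeric TR x network matrix (no missing values).
#' @param tr_seconds TR duration in seconds.
#' @param tr_offset number of TRs removed at scan onset (bookkeeping only).
#' @return object of class `network_series`.
#' @export
network_series <- function(subject_id, group = "none", data,
                           tr_seconds = 1.5, tr_offset = 0L) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("network series contains missing values")
  if (!group %in% c("affair", "paranoia", "none"))
    stopf("unknown group label '%s'", group)
  if (is.null(colnames(data)))
    colnames(data) <- sprintf("net_%02d", seq_len(ncol(data)))
  structure(list(subject_id = subject_id, group = group, data = data,
                 tr_seconds = tr_seconds, tr_offset = as.integer(tr_offset)),
            class = "network_series")
}

#' @export
print.network_series <- function(x, ...) {
  cat(sprintf("<network_series> %s (%s): %d TRs x %d networks, TR = %gs\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data),
              x$tr_seconds))
  invisible(x)
}

#' Hemodynamic shift and trimming of non-story TRs
#'
#' Aligns the BOLD series to stimulus time and removes the non-story
#' segments (e.g., onset music/silence and trailing silence).  Output row
#' `t` (1-based) holds the BOLD sample originally at index
#' `t + onset_exclude_trs + shift_trs`, so stimulus time `t` is paired with
#' the BOLD response `shift_trs` TRs later; the shift consumes rows from
#' the tail of the retained window, which therefore requires
#' `shift_trs <= offset_exclude_trs`.
#'
#' @param series a [network_series()] (or bare matrix).
#' @param shift_trs hemodynamic lag in TRs (default 3, about 4.5 s at
#'   TR = 1.5 s).
#' @param onset_exclude_trs,offset_exclude_trs TRs dropped at scan onset
#'   and offset.
#' @return object of the same type with `length - onset - offset` rows.
#' @export
shift_and_trim <- function(series, shift_trs = 3L, onset_exclude_trs = 0L,
                           offset_exclude_trs = 0L) {
  stopifnot(is_count(shift_trs), is_count(onset_exclude_trs),
            is_count(offset_exclude_trs))
  X <- if (inherits(series, "network_series")) series$data else
    as.matrix(series)
  n <- nrow(X)
  out_len <- n - onset_exclude_trs - offset_exclude_trs
  if (out_len < 1L)
    stopf(paste0("insufficient length: %d TRs minus %d onset and %d offset",
                 " exclusions leaves %d rows"),
          n, onset_exclude_trs, offset_exclude_trs, out_len)
  if (shift_trs > offset_exclude_trs)
    stopf(paste0("shift of %d TRs exceeds the %d offset-excluded TRs; the",
                 " shifted window would run past the recording"),
          shift_trs, offset_exclude_trs)
  rows <- seq.int(onset_exclude_trs + shift_trs + 1L, length.out = out_len)
  Y <- X[rows, , drop = FALSE]
  if (inherits(series, "network_series")) {
    series$data <- Y
    series$tr_offset <- series$tr_offset + as.integer(onset_exclude_trs)
    series
  } else Y
}

#' Average parcel time series into network time series
#'
#' Column `n` of the result is the unweighted mean of all parcel columns
#' mapped to network `n`.
#'
#' @param parcel_series TR x parcel numeric matrix with parcel identifiers
#'   as column names.
#' @param parcel_map `data.frame` with columns `parcel_id` and
#'   `network_label`; every parcel must map to exactly one network.
#' @return TR x network matrix, columns ordered by first appearance of each
#'   network in the map.
#' @export
parcels_to_networks <- function(parcel_series, parcel_map) {
  X <- as.matrix(parcel_series)
  stopifnot(all(c("parcel_id", "network_label") %in% colnames(parcel_map)))
  if (anyDuplicated(parcel_map$parcel_id))
    stop("parcel_map maps some parcel to more than one network")
  if (is.null(colnames(X)))
    stop("parcel_series needs parcel identifiers as column names")
  idx <- match(colnames(X), parcel_map$parcel_id)
  if (anyNA(idx))
    stopf("unmapped parcel(s): %s",
          paste(colnames(X)[is.na(idx)], collapse = ", "))
  labels <- as.character(parcel_map$network_label[idx])
  nets <- unique(as.character(parcel_map$network_label))
  out <- vapply(nets, function(nw) {
    rowMeans(X[, labels == nw, drop = FALSE])
  }, numeric(nrow(X)))
  colnames(out) <- nets
  out
}

#' Z-score each network channel across time
#'
#' Population-SD convention (divide by `N`, not `N - 1`); after z-scoring
#' every column has mean 0 and SD 1 to within 1e-8.
#'
#' @param series a [network_series()] or bare TR x network matrix.
#' @return same type, z-scored.
#' @export
zscore_subject <- function(series) {
  X <- if (inherits(series, "network_series")) series$data else
    as.matrix(series)
  if (nrow(X) < 2L) stop("z-scoring needs at least 2 TRs")
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  zero <- which(sdv == 0)
  if (length(zero))
    stopf("zero-variance network column(s): %s",
          paste(colnames(X)[zero], collapse = ", "))
  Y <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  if (inherits(series, "network_series")) { series$data <- Y; series }
  else Y
}

#' Concatenate subjects' series into one stacked matrix
#'
#' Preserves subject order and records each subject's row range so the
#' stack can be split back losslessly.
#'
#' @param series_list list of [network_series()].
#' @return list with `data` (stacked matrix), `ranges` (`data.frame`:
#'   `subject_id`, `group`, `start`, `end`, 1-based inclusive) and
#'   `tr_seconds`.
#' @export
concatenate_subjects <- function(series_list) {
  stopifnot(length(series_list) >= 1L,
            all(vapply(series_list, inherits, TRUE, "network_series")))
  mats <- lapply(series_list, `[[`, "data")
  lens <- vapply(mats, nrow, 1L)
  ends <- cumsum(lens)
  list(data = do.call(rbind, mats),
       ranges = data.frame(
         subject_id = vapply(series_list, `[[`, "", "subject_id"),
         group = vapply(series_list, `[[`, "", "group"),
         start = c(1L, head(ends, -1L) + 1L),
         end = ends),
       tr_seconds = series_list[[1L]]$tr_seconds)
}

#' Split a stacked matrix back into per-subject series
#'
#' Inverse of [concatenate_subjects()] using the recorded row ranges.
#' @param stacked result of [concatenate_subjects()].
#' @return list of [network_series()].
#' @export
split_subjects <- function(stacked) {
  lapply(seq_len(nrow(stacked$ranges)), function(i) {
    r <- stacked$ranges[i, ]
    network_series(r$subject_id, r$group,
                   stacked$data[r$start:r$end, , drop = FALSE],
                   stacked$tr_seconds)
  })
}
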