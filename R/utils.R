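# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' generators are reproducible without clobbering the session stream.
#' A `NULL` seed evaluates `expr` under the current stream.
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a stream so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Convert a duration in seconds to a whole number of TR bins.
#' Number of TRs spanned by a duration
#'
#' Used for config arithmetic such as turning printed onset/offset music and
#' silence durations into excluded TR counts, or a hemodynamic shift in TRs
#' into seconds.
#' @param seconds duration in seconds (scalar or vector; summed).
#' @param tr_s TR length in seconds.
#' @return integer number of TRs.
#' @examples
#' seconds_to_trs(c(18, 3, 15), 1.5) # 24 excluded TRs
#' @export
seconds_to_trs <- function(seconds, tr_s) {
  stopifnot(tr_s > 0, all(seconds >= 0))
  total <- sum(seconds) / tr_s
  out <- round(total)
  if (abs(total - out) > 1e-8)
    stop("durations are not a whole number of TRs: ", total)
  as.integer(out)
}

#' @noRd
is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Tiny djb2-style hash of a character scalar; used to stamp outputs with a
# config fingerprint without a heavyweight digest dependency.
#' @noRd
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
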