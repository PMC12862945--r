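# Plain-text readers and writers: TSV for all tabular interchange, JSON for
# nested results.  Every file written by the pipeline embeds the run's
# config fingerprint and seed as comment headers.

#' Write a network series as TSV
#'
#' Columns: `tr_index` (0-based) then one column per network.
#' @param series a [network_series()].
#' @param path output file.
#' @export
write_network_series_tsv <- function(series, path) {
  df <- data.frame(tr_index = seq_len(nrow(series$data)) - 1L,
                   series$data, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network series from TSV
#' @param path input file written by [write_network_series_tsv()].
#' @param subject_id,group,tr_seconds metadata for the reconstructed
#'   series.
#' @return a [network_series()].
#' @export
read_network_series_tsv <- function(path, subject_id = basename(path),
                                    group = "none", tr_seconds = 1.5) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  network_series(subject_id, group,
                 as.matrix(df[, setdiff(colnames(df), "tr_index"),
                              drop = FALSE]),
                 tr_seconds)
}

#' Write a feature (or press) table as TSV
#' @param table `data.frame`.
#' @param path output file.
#' @param header optional named character vector written as `# key: value`
#'   comment lines (e.g. config hash and seed).
#' @export
write_table_tsv <- function(table, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("# %s: %s", names(header), header), con)
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table (skipping comment headers)
#' @param path input file.
#' @return `data.frame`.
#' @export
read_table_tsv <- function(path) {
  read.delim(path, check.names = FALSE, comment.char = "#")
}

#' Serialize a pool of state patterns to a data frame / TSV
#'
#' One row per pattern: the mean activation columns, occupancy, provenance
#' and reliability columns — the interchange format consumed by the
#' clustering stage.
#' @param patterns list of `state_pattern`s.
#' @return `data.frame`.
#' @export
patterns_to_df <- function(patterns) {
  stopifnot(length(patterns) >= 1L)
  d <- length(patterns[[1L]]$mean)
  means <- do.call(rbind, lapply(patterns, `[[`, "mean"))
  colnames(means) <- sprintf("net_%02d", seq_len(d))
  data.frame(means,
             occupancy = vapply(patterns, `[[`, 1, "occupancy"),
             group = vapply(patterns, `[[`, "", "group"),
             model_K = vapply(patterns, `[[`, 1L, "model_K"),
             state_index = vapply(patterns, `[[`, 1L, "state_index"),
             normalized_index = vapply(patterns, `[[`, 1,
                                       "normalized_index"),
             max_abs_activation = vapply(patterns, `[[`, 1,
                                         "max_abs_activation"),
             ci_width_max = vapply(patterns, `[[`, 1, "ci_width_max"),
             split_half_r = vapply(patterns, `[[`, 1, "split_half_r"))
}

#' Rebuild a pattern pool from its data-frame serialization
#' @param df output of [patterns_to_df()] (or its TSV round-trip).
#' @return list of `state_pattern`s.
#' @export
df_to_patterns <- function(df) {
  mean_cols <- grep("^net_", colnames(df), value = TRUE)
  lapply(seq_len(nrow(df)), function(i)
    state_pattern(mean = as.numeric(df[i, mean_cols]),
                  occupancy = df$occupancy[i], group = df$group[i],
                  model_K = df$model_K[i], state_index = df$state_index[i],
                  max_abs_activation = df$max_abs_activation[i],
                  ci_width_max = df$ci_width_max[i],
                  split_half_r = df$split_half_r[i]))
}
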