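# Run configuration and the end-to-end pipeline driver:
# simulate -> prep -> fit HMMs per group and model size -> reliability
# filter -> consensus clustering -> representative-state GLMMs ->
# behavioral GLMM -> permutation test.

#' Default run configuration
#'
#' Collects every tunable constant of the pipeline with its standard value:
#' activation/CI/split-half screening thresholds (0.1, 0.3, 0.5), the
#' clustering similarity threshold (0.8) and sweep (0.6-0.9 by 0.05), the
#' model-size range (2-20 states), 5 EM restarts, a 7 s expected dwell at
#' TR = 1.5 s, a 3-TR hemodynamic shift, FDR level 0.05 (credibility rule
#' 0.95), and 10000 permutation splits.  The `sim` and `coupling` blocks
#' parameterize the synthetic-data generator; the balanced group subsamples
#' 9 affair + 10 paranoia subjects.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @return a nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    sim = list(n_subjects_per_group = 19L, n_trs = 451L, n_networks = 17L,
               tr_seconds = 1.5, n_states = 4L, mean_scale = 1,
               covariance_scale = 1, expected_dwell_trs = 7 / 1.5),
    prep = list(shift_trs = 3L, onset_exclude_trs = 0L,
                offset_exclude_trs = 0L),
    hmm = list(k_range = 2:20, n_restarts = 5L, expected_dwell_s = 7,
               tr_s = 1.5, tol = 1e-4, maxit = 500L, cov_type = "full",
               ridge = 1e-6),
    filter = list(theta_act = 0.1, theta_ci = 0.3, theta_sh = 0.5,
                  ci_scope = "all", B = 1000L, min_trs = 10L),
    clustering = list(similarity_threshold = 0.8,
                      sweep = seq(0.6, 0.9, by = 0.05), run_sweep = FALSE,
                      theta_act = 0.1, rule = "positive", n_top = 4L),
    balanced = list(n_affair = 9L, n_paranoia = 10L),
    coupling = list(beta0 = -1.5, beta_group = 0.2,
                    beta_feature = c(arthur_speaking = 0.4,
                                     lee_girl_together = 0.3),
                    beta_interaction = c(arthur_speaking = -0.3),
                    gamma_ar = c(1.5, 0.5), sigma_u = 0.5),
    glmm = list(tau = 2.5, a0 = 2, b0 = 1, n_lags = 2L, alpha = 0.05,
                features = c("arthur_speaking", "lee_speaking",
                             "girl_speaking", "lee_girl_together", "verb",
                             "noun", "adjective", "adverb",
                             "lee_girl_verb", "arthur_adjective")),
    permutation = list(n_perm = 10000L, statistic = "mean_abs")),
    class = "run_config")
}

# Deep-merge user overrides into the default config (unnamed or atomic
# values replace; named lists merge recursively).
#' @noRd
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full simulate-then-analyze pipeline
#'
#' Generates a synthetic dataset, forms the four analysis groups (affair,
#' paranoia, combined, and a seeded balanced subsample), fits Gaussian HMMs
#' across the configured model-size range per group, screens states with
#' the reliability filter, pools and clusters the surviving patterns,
#' selects representative states from the combined-group models, fits the
#' brain-state and behavioral MAP logistic mixed models against the
#' generated story annotations, and permutation-tests the group difference
#' in each representative state's occupancy time course.  Every stage is
#' seeded from `config$seed`, so reruns with the same config are
#' bit-identical.
#'
#' @param config a [default_config()] (possibly with overrides).
#' @param out_dir optional directory; when given, stage outputs are written
#'   as TSV/JSON stamped with the config fingerprint and seed.
#' @return a result bundle (nested list) with elements `data`, `groups`,
#'   `fits`, `patterns`, `clustering`, `representatives`, `brain_glmm`,
#'   `behavior`, `permutation`, and `config`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  cfg <- config
  seed <- cfg$seed
  hash <- config_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                       force = TRUE))
  stamp <- c(config_hash = hash, seed = as.character(seed))

  # --- simulate -------------------------------------------------------
  spec <- do.call(sim_spec, c(cfg$sim, list(seed = seed)))
  sim <- generate_hmm_dataset(spec)
  n_per <- cfg$sim$n_subjects_per_group
  affair_idx <- seq_len(n_per)
  paranoia_idx <- n_per + seq_len(n_per)
  balanced_idx <- with_seed(seed + 1L, c(
    sample(affair_idx, cfg$balanced$n_affair),
    sample(paranoia_idx, cfg$balanced$n_paranoia)))
  groups <- list(affair = affair_idx, paranoia = paranoia_idx,
                 combined = c(affair_idx, paranoia_idx),
                 balanced = sort(balanced_idx))

  coupling <- do.call(coupling_spec, c(cfg$coupling, list(seed = seed + 2L)))
  features <- generate_feature_streams(coupling, cfg$sim$n_trs)

  # --- fit HMMs per group and model size, filter states ---------------
  fits <- list()
  patterns <- list()
  rejections <- NULL
  combined_paths <- list() # paths per K for the combined group
  gi <- 0L
  for (g in names(groups)) {
    gi <- gi + 1L
    series_g <- sim$series[groups[[g]]]
    for (K in cfg$hmm$k_range) {
      fit <- fit_hmm(series_g, K, n_restarts = cfg$hmm$n_restarts,
                     base_seed = seed + 1000L * K + 100L * gi,
                     expected_dwell_s = cfg$hmm$expected_dwell_s,
                     tr_s = cfg$hmm$tr_s, tol = cfg$hmm$tol,
                     maxit = cfg$hmm$maxit, cov_type = cfg$hmm$cov_type,
                     ridge = cfg$hmm$ridge)
      paths <- lapply(series_g, function(s) decode_states(fit, s)$path)
      if (g == "combined") combined_paths[[as.character(K)]] <- paths
      fl <- filter_states(fit, paths, series_g, group = g,
                          theta_act = cfg$filter$theta_act,
                          theta_ci = cfg$filter$theta_ci,
                          theta_sh = cfg$filter$theta_sh,
                          ci_scope = cfg$filter$ci_scope,
                          min_trs = cfg$filter$min_trs, B = cfg$filter$B,
                          seed = seed + 10L * K + gi)
      patterns <- c(patterns, fl$patterns)
      if (nrow(fl$rejections))
        rejections <- rbind(rejections,
                            cbind(group = g, model_K = K, fl$rejections))
      fits[[paste(g, K, sep = "_")]] <- fit
    }
  }
  if (length(patterns) == 0L)
    stop("pipeline: no state passed the reliability filter")

  # --- consensus clustering -------------------------------------------
  clustering <- cluster_states(
    patterns, similarity_threshold = cfg$clustering$similarity_threshold,
    theta_act = cfg$clustering$theta_act, rule = cfg$clustering$rule)
  sweep_report <- if (isTRUE(cfg$clustering$run_sweep))
    threshold_stability(patterns, thresholds = cfg$clustering$sweep,
                        theta_act = cfg$clustering$theta_act,
                        rule = cfg$clustering$rule) else NULL

  # --- representative states and brain GLMMs --------------------------
  subj_groups <- vapply(sim$series[groups$combined], `[[`, "", "group")
  n_top <- min(cfg$clustering$n_top, length(clustering$clusters))
  priors <- prior_spec(cfg$glmm$tau, cfg$glmm$a0, cfg$glmm$b0)
  glmm_features <- intersect(cfg$glmm$features, colnames(features))
  representatives <- list()
  brain_glmm <- list()
  perm_results <- list()
  for (cid in seq_len(n_top)) {
    rep_state <- tryCatch(
      select_representative(clustering, cid, patterns),
      error = function(e) NULL)
    if (is.null(rep_state)) next
    representatives[[as.character(cid)]] <- rep_state
    paths <- combined_paths[[as.character(rep_state$model_K)]]
    occ <- representative_occupancy(paths, rep_state$state_index)
    if (all(occ == 0L) || all(occ == 1L)) next
    design <- build_design(features, occ, subj_groups,
                           n_lags = cfg$glmm$n_lags,
                           feature_names = glmm_features)
    fit <- fit_map(design, priors)
    fdr <- bayesian_fdr(direction_probability(fit), cfg$glmm$alpha)
    brain_glmm[[as.character(cid)]] <-
      list(fit = fit, fdr = cbind(term = names(fit$coefficients), fdr),
           group_effects = group_effects(fit))
    perm_results[[as.character(cid)]] <- permutation_test(
      occ, subj_groups, n_perm = cfg$permutation$n_perm,
      seed = seed + 3L + cid, statistic = cfg$permutation$statistic)
  }

  # --- behavioral GLMM -------------------------------------------------
  presses_a <- generate_button_presses(features, coupling, +1,
                                       n_subjects = n_per,
                                       tr_seconds = cfg$sim$tr_seconds,
                                       seed = seed + 4L)
  presses_p <- generate_button_presses(features, coupling, -1,
                                       n_subjects = n_per,
                                       tr_seconds = cfg$sim$tr_seconds,
                                       seed = seed + 5L)
  # round-trip through the raw press-time ingestion path
  press_mat <- do.call(rbind, lapply(
    c(presses_a$press_times, presses_p$press_times),
    align_presses, bin_s = cfg$sim$tr_seconds, n_bins = cfg$sim$n_trs))
  press_groups <- rep(c("affair", "paranoia"), each = n_per)
  beh_design <- build_design(features, press_mat, press_groups,
                             n_lags = cfg$glmm$n_lags,
                             feature_names = glmm_features)
  beh_fit <- fit_map(beh_design, priors)
  behavior <- list(
    fit = beh_fit,
    fdr = cbind(term = names(beh_fit$coefficients),
                bayesian_fdr(direction_probability(beh_fit),
                             cfg$glmm$alpha)),
    group_effects = group_effects(beh_fit),
    agreement = list(affair = group_agreement(presses_a$outcomes),
                     paranoia = group_agreement(presses_p$outcomes)))

  bundle <- list(data = sim, groups = groups, features = features,
                 fits = fits, patterns = patterns,
                 rejections = rejections, clustering = clustering,
                 sweep = sweep_report, representatives = representatives,
                 brain_glmm = brain_glmm, behavior = behavior,
                 permutation = perm_results,
                 config = cfg, config_hash = hash)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir, stamp)
  bundle
}

# Write the diff-able text outputs of a pipeline run.
#' @noRd
write_bundle <- function(bundle, out_dir, stamp) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table_tsv(bundle$features, file.path(out_dir, "features.tsv"),
                  header = stamp)
  write_table_tsv(patterns_to_df(bundle$patterns),
                  file.path(out_dir, "state_patterns.tsv"), header = stamp)
  cl <- bundle$clustering
  jsonlite::write_json(
    list(config_hash = unname(stamp[["config_hash"]]),
         seed = unname(stamp[["seed"]]),
         threshold = cl$threshold, assignment = cl$assignment,
         clusters = lapply(cl$clusters, function(x)
           list(members = x$members, consensus = x$consensus,
                total_occupancy = x$total_occupancy, label = x$label)),
         representatives = bundle$representatives,
         permutation = lapply(bundle$permutation, function(p)
           list(observed = p$observed, p_value = p$p_value,
                n_perm = p$n_perm, statistic = p$statistic))),
    file.path(out_dir, "clustering.json"), auto_unbox = TRUE, digits = NA)
  for (cid in names(bundle$brain_glmm))
    write_table_tsv(bundle$brain_glmm[[cid]]$fit$results,
                    file.path(out_dir, sprintf("glmm_brain_cluster%s.tsv",
                                               cid)), header = stamp)
  write_table_tsv(bundle$behavior$fit$results,
                  file.path(out_dir, "glmm_behavior.tsv"), header = stamp)
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write the synthetic dataset as TSV/JSON) and
#' `run-all` (full pipeline).  Options: `--config FILE` (JSON overrides of
#' [default_config()]), `--seed N`, `--out DIR`.
#'
#' @param args character vector (defaults to the trailing command-line
#'   arguments).
#' @return exit status 0 invisibly.
#' @export
storystates_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: storystates <simulate|run-all> [--config FILE] ",
         "[--seed N] [--out DIR]")
  cmd <- args[1L]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1L] < length(args)) args[i[1L] + 1L] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", "storystates_out")
  cfg <- default_config(seed)
  cfg_file <- opt("--config")
  if (!is.null(cfg_file))
    cfg <- merge_config(cfg, jsonlite::read_json(cfg_file,
                                                 simplifyVector = TRUE))
  cfg$seed <- seed
  if (cmd == "simulate") {
    spec <- do.call(sim_spec, c(cfg$sim, list(seed = seed)))
    sim <- generate_hmm_dataset(spec)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (s in sim$series)
      write_network_series_tsv(s, file.path(out, paste0(s$subject_id,
                                                        ".tsv")))
    jsonlite::write_json(sim$truth, file.path(out, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    message("wrote ", length(sim$series), " series to ", out)
  } else if (cmd == "run-all") {
    run_pipeline(cfg, out_dir = out)
    message("pipeline outputs written to ", out)
  } else {
    stop("unknown subcommand: ", cmd)
  }
  invisible(0L)
}
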