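# Shared, memoized study runs for the heavier replication suites, so several
# test files can reuse the same seeded studies without recomputing them.
.run_cache <- new.env(parent = emptyenv())

# One full analysis of a default-condition study under the given seed.
default_study_run <- function(seed) {
  key <- paste0("default_", seed)
  if (is.null(.run_cache[[key]])) {
    study <- simulate_study(sim_config(seed = seed))
    mat <- build_feature_matrix(study)
    scr <- screen_candidates(mat)
    idx <- resolve_planted(mat, study$truth$markers)
    planted_ids <- mat$features$feature_id[idx]
    fit <- wda(mat, screen = scr)
    scores <- score_study(mat, fit)
    oxy <- scores[scores$group == "oxygen", c("subject_id", "time_h", "q")]
    elev <- elevation_test(oxy)
    oxy_physio <- study$physio[study$physio$subject_id %in% oxy$subject_id, ]
    lat <- latency(elev, oxy_physio)
    .run_cache[[key]] <- list(
      n_candidates = sum(scr$is_candidate),
      n_planted_flagged = sum(scr$is_candidate[idx], na.rm = TRUE),
      n_background_flagged = sum(scr$is_candidate) -
        sum(scr$is_candidate[idx], na.rm = TRUE),
      n_selected = nrow(fit$markers),
      n_recovered = sum(fit$markers$feature_id %in% planted_ids),
      loso_auc = fit$loso_auc,
      first_elevation_h = lat$first_bs_elevation_h,
      first_pf_below_h = lat$first_pf_below_h,
      latency_h = lat$latency_h)
  }
  .run_cache[[key]]
}

# One null study (effect_multiplier = 1) under the given seed.
null_study_run <- function(seed) {
  key <- paste0("null_", seed)
  if (is.null(.run_cache[[key]])) {
    study <- simulate_study(sim_config(seed = seed, effect_multiplier = 1.0))
    mat <- build_feature_matrix(study)
    scr <- screen_candidates(mat)
    idx <- resolve_planted(mat, study$truth$markers)
    bg <- setdiff(seq_len(nrow(scr)), idx[!is.na(idx)])
    loso <- if (any(scr$is_candidate)) wda(mat, screen = scr)$loso_auc else NA_real_
    .run_cache[[key]] <- list(
      mean_background_auc_raw = mean(scr$auc_x_raw[bg]),
      n_candidates = sum(scr$is_candidate),
      n_background_candidates = sum(scr$is_candidate[bg]),
      loso_auc = loso)
  }
  .run_cache[[key]]
}
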