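#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain in one validated object:
#' generator settings, S/N threshold, retention tolerances, background mode,
#' prevalence floor, screening thresholds, WDA fitting options, the P/F
#' outcome threshold and the test level. Unknown fields are rejected by
#' normal argument matching; the effective configuration is echoed to the
#' output directory as YAML by [run_pipeline()].
#'
#' @param sim A [sim_config()] for the simulate stage.
#' @param snr_threshold Minimum peak S/N (default 400).
#' @param background `"subtract"` or `"ignore"`; see [build_feature_matrix()].
#' @param prevalence_floor Minimum feature prevalence (default 0.1).
#' @param tol_rt1,tol_rt2 Retention matching tolerances (seconds).
#' @param match_mz Require identical quant m/z for species identity.
#' @param tx,ty Screening thresholds (defaults 0.625 / 0.60).
#' @param max_markers Optional cap on fitted panel size.
#' @param weight_rule,boundary WDA options; see [wda()].
#' @param pf_threshold P/F outcome threshold in mmHg (default 350).
#' @param alpha Significance level for corrected tests.
#' @param seed Optional override of `sim$seed`.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(sim = sim_config(), snr_threshold = 400,
                            background = c("subtract", "ignore"),
                            prevalence_floor = 0.1,
                            tol_rt1 = 5, tol_rt2 = 0.1, match_mz = TRUE,
                            tx = 0.625, ty = 0.60, max_markers = NULL,
                            weight_rule = c("odds", "identity", "youden"),
                            boundary = c("strict", "inclusive"),
                            pf_threshold = 350, alpha = 0.05, seed = NULL) {
  background <- match.arg(background)
  weight_rule <- match.arg(weight_rule)
  boundary <- match.arg(boundary)
  stopifnot(inherits(sim, "sim_config"))
  fail <- function(field, msg) {
    stop(sprintf("pipeline_config: invalid '%s': %s", field, msg), call. = FALSE)
  }
  if (tx < 0 || tx > 1) fail("tx", "must lie in [0, 1]")
  if (ty < 0 || ty > 1) fail("ty", "must lie in [0, 1]")
  if (snr_threshold < 0) fail("snr_threshold", "must be >= 0")
  if (prevalence_floor < 0 || prevalence_floor > 1) {
    fail("prevalence_floor", "must lie in [0, 1]")
  }
  if (tol_rt1 <= 0 || tol_rt2 <= 0) fail("tol_rt1/tol_rt2", "must be positive")
  if (pf_threshold <= 0) fail("pf_threshold", "must be positive")
  if (alpha <= 0 || alpha >= 1) fail("alpha", "must lie in (0, 1)")
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  cfg <- list(sim = sim, snr_threshold = snr_threshold, background = background,
              prevalence_floor = prevalence_floor, tol_rt1 = tol_rt1,
              tol_rt2 = tol_rt2, match_mz = match_mz, tx = tx, ty = ty,
              max_markers = max_markers, weight_rule = weight_rule,
              boundary = boundary, pf_threshold = pf_threshold, alpha = alpha)
  structure(cfg, class = "pipeline_config")
}

.pipeline_stages <- c("simulate", "matrix", "screen", "fit", "score", "evaluate")

.log_line <- function(out_dir, quiet, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  cat(line, "\n", file = file.path(out_dir, "run.log"), append = TRUE, sep = "")
  if (!quiet) message(line)
}

#' Run the analysis pipeline
#'
#' Chains the stages `simulate` (write a synthetic study directory),
#' `matrix` (aligned, normalized feature matrix), `screen` (dual-ROC
#' candidate screening), `fit` (WDA model by LOSO forward selection),
#' `score` (breath score per sample) and `evaluate` (exposure and P/F
#' outcome ROC curves, per-timepoint elevation tests, latency, per-timepoint
#' group comparisons), writing each stage's artifacts into `out_dir` along
#' with the effective configuration (`config.yaml` inside the study
#' directory) and a structured log (`run.log`). Later stages read earlier
#' artifacts from `out_dir`, so stages can also be run one at a time.
#' Given the same configuration (including its seed) the run is
#' reproducible artifact-for-artifact.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param stages `"all"` or a subset of
#'   `c("simulate", "matrix", "screen", "fit", "score", "evaluate")`.
#' @param quiet Suppress console log messages.
#' @return Invisibly, a list with the in-memory stage results (`study`,
#'   `mat`, `screen`, `model`, `scores`, `evaluation`).
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(), stages = "all",
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(stages, "all")) stages <- .pipeline_stages
  stopifnot(all(stages %in% .pipeline_stages))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())

  get_study <- function() {
    if (is.null(st$study)) st$study <- read_study(out_dir)
    st$study
  }
  get_mat <- function() {
    if (is.null(st$mat)) {
      rds <- file.path(out_dir, "matrix.rds")
      st$mat <- if (file.exists(rds)) readRDS(rds) else {
        build_feature_matrix(get_study(), snr_threshold = config$snr_threshold,
                             background = config$background,
                             prevalence_floor = config$prevalence_floor,
                             tol_rt1 = config$tol_rt1, tol_rt2 = config$tol_rt2,
                             match_mz = config$match_mz)
      }
    }
    st$mat
  }

  for (stage in .pipeline_stages[.pipeline_stages %in% stages]) {
    switch(stage,
      simulate = {
        st$study <- simulate_study(config$sim)
        write_study(st$study, out_dir)
        .log_line(out_dir, quiet,
                  "simulate: seed %d, %d subjects, %d samples -> %s",
                  config$sim$seed, length(unique(st$study$manifest$subject_id)),
                  nrow(st$study$manifest), out_dir)
      },
      matrix = {
        st$mat <- build_feature_matrix(get_study(),
                                       snr_threshold = config$snr_threshold,
                                       background = config$background,
                                       prevalence_floor = config$prevalence_floor,
                                       tol_rt1 = config$tol_rt1,
                                       tol_rt2 = config$tol_rt2,
                                       match_mz = config$match_mz)
        write_feature_matrix(st$mat, file.path(out_dir, "matrix"))
        saveRDS(st$mat, file.path(out_dir, "matrix.rds"))
        .log_line(out_dir, quiet, "matrix: %d features x %d samples",
                  nrow(st$mat$A), ncol(st$mat$A))
      },
      screen = {
        st$screen <- screen_candidates(get_mat(), tx = config$tx, ty = config$ty)
        .write_csv_raw(screening_table(st$screen),
                       file.path(out_dir, "screening.csv"))
        .log_line(out_dir, quiet,
                  "screen: tx %.3f ty %.3f -> %d candidate(s) of %d features",
                  config$tx, config$ty, sum(st$screen$is_candidate),
                  nrow(st$screen))
      },
      fit = {
        if (is.null(st$screen)) {
          st$screen <- screen_candidates(get_mat(), tx = config$tx, ty = config$ty)
        }
        st$model <- wda(get_mat(), screen = st$screen,
                        max_markers = config$max_markers,
                        weight_rule = config$weight_rule,
                        boundary = config$boundary)
        .write_csv_raw(st$model$markers, file.path(out_dir, "model_markers.csv"))
        jsonlite::write_json(
          list(weight_rule = st$model$weight_rule,
               boundary = st$model$boundary,
               loso_auc = st$model$loso_auc,
               thresholds = list(tx = config$tx, ty = config$ty),
               selection_trace = st$model$trace),
          file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
        saveRDS(st$model, file.path(out_dir, "model.rds"))
        .log_line(out_dir, quiet, "fit: %d marker(s), LOSO exposure AUC %.4f",
                  nrow(st$model$markers), st$model$loso_auc)
      },
      score = {
        if (is.null(st$model)) st$model <- readRDS(file.path(out_dir, "model.rds"))
        st$scores <- score_study(get_mat(), st$model,
                                 tol_rt1 = config$tol_rt1,
                                 tol_rt2 = config$tol_rt2)
        .write_csv_raw(st$scores, file.path(out_dir, "breath_scores.csv"))
        .log_line(out_dir, quiet, "score: %d breath scores, range [%.3f, %.3f]",
                  nrow(st$scores), min(st$scores$q), max(st$scores$q))
      },
      evaluate = {
        if (is.null(st$scores)) {
          st$scores <- utils::read.csv(file.path(out_dir, "breath_scores.csv"))
        }
        physio <- if (!is.null(st$study)) st$study$physio else {
          read_physiology(file.path(out_dir, "physiology.csv"))
        }
        scores <- st$scores
        exposure <- scores$group == "oxygen" & scores$time_h > 0
        roc_exp <- roc_curve(scores$q, exposure)

        physio$pf <- pf_ratio(physio)
        key <- function(d) paste(d$subject_id, d$time_h)
        pf_at <- physio$pf[match(key(scores), key(physio))]
        po2t <- label_po2t(pf_at, config$pf_threshold)
        roc_out <- roc_curve(scores$q, po2t)

        oxy_scores <- scores[scores$group == "oxygen",
                             c("subject_id", "time_h", "q")]
        elev <- elevation_test(oxy_scores, alpha = config$alpha)
        oxy_physio <- physio[physio$subject_id %in% oxy_scores$subject_id, ]
        lat <- latency(elev, oxy_physio, pf_threshold = config$pf_threshold)
        physio$group <- scores$group[match(physio$subject_id, scores$subject_id)]
        gt <- group_timepoint_tests(physio[c("group", "time_h", "pf")], "pf",
                                    alpha = config$alpha)

        for (nm in c("roc_exposure", "roc_po2t")) {
          r <- if (nm == "roc_exposure") roc_exp else roc_out
          .write_csv_raw(data.frame(threshold = r$thresholds, tpr = r$tpr,
                                    fpr = r$fpr),
                         file.path(out_dir, paste0(nm, ".csv")))
        }
        .write_csv_raw(elev, file.path(out_dir, "elevation.csv"))
        .write_csv_raw(gt, file.path(out_dir, "group_tests.csv"))
        jsonlite::write_json(
          list(auc_exposure = roc_exp$auc, auc_po2t = roc_out$auc,
               first_bs_elevation_h = lat$first_bs_elevation_h,
               first_pf_below_h = lat$first_pf_below_h,
               latency_h = lat$latency_h, pf_threshold = config$pf_threshold),
          file.path(out_dir, "latency.json"), auto_unbox = TRUE, digits = NA,
          na = "null")
        st$evaluation <- list(roc_exposure = roc_exp, roc_po2t = roc_out,
                              elevation = elev, latency = lat,
                              group_tests = gt)
        .log_line(out_dir, quiet,
                  "evaluate: exposure AUC %.4f, P/F<%g AUC %.4f, latency %s h",
                  roc_exp$auc, config$pf_threshold, roc_out$auc,
                  format(lat$latency_h))
      })
  }
  invisible(list(study = st$study, mat = st$mat, screen = st$screen,
                 model = st$model, scores = st$scores,
                 evaluation = st$evaluation))
}
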