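#' Retention-window peak matching
#'
#' Two peaks are the same VOC species when their first-dimension retention
#' times differ by at most 5 s, their second-dimension retention times by at
#' most 0.1 s (both boundaries inclusive), and — when m/z matching is enabled,
#' the default — their quant m/z is identical.
#'
#' @param a,b Peak tables (see [peak_table()]) of equal length, or single
#'   rows; compared elementwise.
#' @param tol_rt1,tol_rt2 Retention-time tolerances in seconds.
#' @param match_mz Require identical quant m/z (default `TRUE`).
#' @return Logical vector.
#' @examples
#' a <- peak_table(171.30, 1.20, 78, 5000, 900)
#' b <- peak_table(175.30, 1.25, 78, 4000, 800)
#' match_peaks(a, b)
#' @export
match_peaks <- function(a, b, tol_rt1 = 5, tol_rt2 = 0.1, match_mz = TRUE) {
  ok <- abs(a$rt1 - b$rt1) <= tol_rt1 & abs(a$rt2 - b$rt2) <= tol_rt2
  if (match_mz) ok <- ok & a$mz == b$mz
  ok
}

#' Signal-to-noise filtering
#'
#' Retains peaks whose signal-to-noise ratio is at least `threshold`
#' (inclusive: a peak exactly at the threshold is kept). Row order is
#' preserved.
#'
#' @param peaks A peak table.
#' @param threshold Minimum acceptable S/N (default 400).
#' @return The filtered peak table.
#' @export
filter_snr <- function(peaks, threshold = 400) {
  stopifnot(threshold >= 0)
  peaks[peaks$snr >= threshold, , drop = FALSE]
}

#' Breathing-circuit background subtraction
#'
#' Computes alveolar-gradient-style abundances: each breath peak is matched
#' (by [match_peaks()]) to at most one background peak — the nearest by
#' first-dimension retention time, ties broken by second-dimension retention
#' time — and its area replaced by `max(0, breath - background)`. Unmatched
#' breath peaks pass through unchanged; background-only peaks are dropped.
#'
#' @param peaks Breath peak table.
#' @param background Paired circuit-background peak table.
#' @inheritParams match_peaks
#' @return The breath peak table with background-corrected areas.
#' @export
subtract_background <- function(peaks, background, tol_rt1 = 5, tol_rt2 = 0.1,
                                match_mz = TRUE) {
  if (!nrow(peaks) || !nrow(background)) return(peaks)
  for (i in seq_len(nrow(peaks))) {
    ok <- abs(background$rt1 - peaks$rt1[i]) <= tol_rt1 &
      abs(background$rt2 - peaks$rt2[i]) <= tol_rt2
    if (match_mz) ok <- ok & background$mz == peaks$mz[i]
    if (any(ok)) {
      cand <- which(ok)
      d1 <- abs(background$rt1[cand] - peaks$rt1[i])
      d2 <- abs(background$rt2[cand] - peaks$rt2[i])
      best <- cand[order(d1, d2)][1]
      peaks$area[i] <- max(0, peaks$area[i] - background$area[best])
    }
  }
  peaks
}

#' Greedy retention-window clustering of peaks into VOC features
#'
#' Pools peaks from all samples and groups them into feature clusters by a
#' deterministic greedy pass: peaks are visited in order of decreasing area
#' (ties: increasing rt1, then rt2, then sample order); each peak joins the
#' earliest-created cluster whose running-mean centroid it matches under the
#' retention-window rule (see [match_peaks()]) and that does not yet contain a
#' member from the peak's sample; otherwise it seeds a new cluster. Centroids
#' are the running means of member retention times; the consensus m/z is the
#' mode of member m/z values.
#'
#' @param peaks Pooled peak table with an additional integer column `sample`
#'   (1-based sample index).
#' @param n_samples Total number of samples (defaults to `max(peaks$sample)`).
#' @inheritParams match_peaks
#' @return A list with `assignment` (cluster index per input row) and
#'   `clusters`: a `data.frame` with `feature_id`, `centroid_rt1`,
#'   `centroid_rt2`, `consensus_mz`, `n_members` and `prevalence` (fraction of
#'   samples containing the feature).
#' @export
cluster_peaks <- function(peaks, n_samples = NULL, tol_rt1 = 5, tol_rt2 = 0.1,
                          match_mz = TRUE) {
  stopifnot("sample" %in% names(peaks))
  n <- nrow(peaks)
  if (is.null(n_samples)) n_samples <- if (n) max(peaks$sample) else 0L
  if (!n) {
    return(list(assignment = integer(0),
                clusters = data.frame(feature_id = character(0),
                                      centroid_rt1 = numeric(0),
                                      centroid_rt2 = numeric(0),
                                      consensus_mz = integer(0),
                                      n_members = integer(0),
                                      prevalence = numeric(0))))
  }
  ord <- order(-peaks$area, peaks$rt1, peaks$rt2, peaks$sample)
  rt1 <- peaks$rt1; rt2 <- peaks$rt2; mz <- peaks$mz; smp <- peaks$sample
  cl_rt1 <- numeric(n); cl_rt2 <- numeric(n); cl_n <- integer(n)
  cl_members <- vector("list", n)          # sample ids per cluster
  n_cl <- 0L
  assignment <- integer(n)
  buckets <- new.env(hash = TRUE, parent = emptyenv())  # mz -> cluster ids
  for (i in ord) {
    key <- if (match_mz) as.character(mz[i]) else ".all"
    cand <- buckets[[key]]
    hit <- 0L
    if (!is.null(cand)) {
      ok <- cand[abs(cl_rt1[cand] - rt1[i]) <= tol_rt1 &
                   abs(cl_rt2[cand] - rt2[i]) <= tol_rt2]
      for (k in ok) {                      # earliest-created matching cluster
        if (!smp[i] %in% cl_members[[k]]) { hit <- k; break }
      }
    }
    if (hit) {
      m <- cl_n[hit]
      cl_rt1[hit] <- (cl_rt1[hit] * m + rt1[i]) / (m + 1)
      cl_rt2[hit] <- (cl_rt2[hit] * m + rt2[i]) / (m + 1)
      cl_n[hit] <- m + 1L
      cl_members[[hit]] <- c(cl_members[[hit]], smp[i])
      assignment[i] <- hit
    } else {
      n_cl <- n_cl + 1L
      cl_rt1[n_cl] <- rt1[i]; cl_rt2[n_cl] <- rt2[i]; cl_n[n_cl] <- 1L
      cl_members[[n_cl]] <- smp[i]
      buckets[[key]] <- c(buckets[[key]], n_cl)
      assignment[i] <- n_cl
    }
  }
  consensus_mz <- if (match_mz) {
    vapply(seq_len(n_cl), function(k) mz[assignment == k][1L], numeric(1))
  } else {
    vapply(seq_len(n_cl), function(k) {
      v <- mz[assignment == k]
      as.numeric(names(sort(table(v), decreasing = TRUE))[1L])
    }, numeric(1))
  }
  list(assignment = assignment,
       clusters = data.frame(
         feature_id = sprintf("F%04d", seq_len(n_cl)),
         centroid_rt1 = cl_rt1[seq_len(n_cl)],
         centroid_rt2 = cl_rt2[seq_len(n_cl)],
         consensus_mz = as.integer(consensus_mz),
         n_members = cl_n[seq_len(n_cl)],
         prevalence = cl_n[seq_len(n_cl)] / n_samples))
}

#' Internal-standard normalization
#'
#' Divides integrated areas by the sample's internal-standard
#' (bromofluorobenzene) area, correcting run-to-run sensitivity drift. The
#' result is scale-invariant: multiplying every area and the internal-standard
#' area by a common factor leaves the normalized abundances unchanged.
#'
#' @param areas Numeric vector of peak areas.
#' @param is_area Positive internal-standard area of the same sample.
#' @return Normalized abundances `areas / is_area`.
#' @export
normalize_to_internal_standard <- function(areas, is_area) {
  if (!is.finite(is_area) || is_area <= 0) {
    stop("internal-standard area must be positive", call. = FALSE)
  }
  areas / is_area
}

#' Build the aligned, normalized feature matrix of a study
#'
#' Runs the per-sample processing chain — S/N filtering, optional
#' breathing-circuit background subtraction — then clusters the pooled peaks
#' into VOC features with [cluster_peaks()] and normalizes each member area to
#' the sample's internal standard. Features detected in fewer than
#' `prevalence_floor` of samples are dropped. A feature absent from a sample
#' is recorded as abundance 0 (absence of a peak is informative at fixed
#' detection settings).
#'
#' @param study A `voc_study` (from [simulate_study()] or [read_study()]).
#' @param snr_threshold Minimum S/N (default 400); see [filter_snr()].
#' @param background `"subtract"` (alveolar-gradient subtraction, default) or
#'   `"ignore"`.
#' @param prevalence_floor Minimum fraction of samples a feature must appear
#'   in (default 0.1).
#' @inheritParams match_peaks
#' @return A `voc_matrix` object: list with `features` (feature metadata,
#'   see [cluster_peaks()]), `samples` (per-sample metadata: `sample_id`,
#'   `subject_id`, `group`, `phase`, `time_h`, `internal_standard_area`) and
#'   `A`, the features x samples matrix of normalized abundances.
#' @examples
#' \donttest{
#' study <- simulate_study(sim_config(n_air = 2, n_oxygen = 2,
#'                                    n_background_voc = 40))
#' mat <- build_feature_matrix(study)
#' mat
#' }
#' @export
build_feature_matrix <- function(study, snr_threshold = 400,
                                 background = c("subtract", "ignore"),
                                 prevalence_floor = 0.1,
                                 tol_rt1 = 5, tol_rt2 = 0.1, match_mz = TRUE) {
  stopifnot(inherits(study, "voc_study"))
  background <- match.arg(background)
  n_samples <- length(study$samples)
  if (!n_samples) stop("no samples", call. = FALSE)
  keys <- names(study$samples)
  if (is.null(keys)) keys <- sprintf("S%03d", seq_len(n_samples))
  pooled <- vector("list", n_samples)
  meta <- vector("list", n_samples)
  for (j in seq_len(n_samples)) {
    s <- study$samples[[j]]
    if (!is.finite(s$internal_standard_area) || s$internal_standard_area <= 0) {
      stop(sprintf("sample '%s': internal-standard area must be positive", keys[j]),
           call. = FALSE)
    }
    p <- filter_snr(s$peaks, snr_threshold)
    if (background == "subtract") {
      p <- subtract_background(p, filter_snr(s$background, snr_threshold),
                               tol_rt1 = tol_rt1, tol_rt2 = tol_rt2,
                               match_mz = match_mz)
    }
    if (nrow(p)) p$sample <- j
    pooled[[j]] <- p
    meta[[j]] <- data.frame(sample_id = keys[j], subject_id = s$subject_id,
                            group = s$group, phase = s$phase, time_h = s$time_h,
                            internal_standard_area = s$internal_standard_area)
  }
  pooled <- do.call(rbind, c(pooled[vapply(pooled, nrow, 1L) > 0],
                             list(make.row.names = FALSE)))
  samples <- do.call(rbind, c(meta, list(make.row.names = FALSE)))
  cl <- cluster_peaks(pooled, n_samples = n_samples,
                      tol_rt1 = tol_rt1, tol_rt2 = tol_rt2, match_mz = match_mz)
  keep <- which(cl$clusters$prevalence >= prevalence_floor)
  features <- cl$clusters[keep, , drop = FALSE]
  rownames(features) <- NULL
  A <- matrix(0, nrow = length(keep), ncol = n_samples,
              dimnames = list(features$feature_id, keys))
  idx <- match(cl$assignment, keep)
  ok <- !is.na(idx)
  A[cbind(idx[ok], pooled$sample[ok])] <-
    pooled$area[ok] / samples$internal_standard_area[pooled$sample[ok]]
  structure(list(features = features, samples = samples, A = A),
            class = "voc_matrix")
}

#' @export
print.voc_matrix <- function(x, ...) {
  cat(sprintf("voc_matrix: %d features x %d samples (%d subjects)\n",
              nrow(x$A), ncol(x$A), length(unique(x$samples$subject_id))))
  cat(sprintf("  median prevalence %.2f; normalized abundance range [%.3g, %.3g]\n",
              stats::median(x$features$prevalence), min(x$A), max(x$A)))
  invisible(x)
}

#' Serialize a feature matrix to CSV
#'
#' Writes two CSVs: `<stem>_features.csv` (feature metadata) and
#' `<stem>_values.csv` with one row per feature/sample pair
#' (`feature_id, sample_id, subject_id, time_h, A`).
#'
#' @param mat A `voc_matrix`.
#' @param stem Output path stem.
#' @return Invisibly, the two file paths.
#' @export
write_feature_matrix <- function(mat, stem) {
  f_path <- paste0(stem, "_features.csv")
  v_path <- paste0(stem, "_values.csv")
  .write_csv_raw(mat$features, f_path)
  long <- data.frame(
    feature_id = rep(mat$features$feature_id, times = ncol(mat$A)),
    sample_id = rep(mat$samples$sample_id, each = nrow(mat$A)),
    subject_id = rep(mat$samples$subject_id, each = nrow(mat$A)),
    time_h = rep(mat$samples$time_h, each = nrow(mat$A)),
    A = as.vector(mat$A))
  .write_csv_raw(long, v_path)
  invisible(c(f_path, v_path))
}
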