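#' P/F oxygenation ratio
#'
#' The arterial oxygen partial pressure (PaO2, mmHg) divided by the fraction
#' of inspired oxygen (FiO2): the standard oxygenation index. Values below
#' 300 mmHg meet an ARDS criterion; this package's pulmonary-oxygen-toxicity
#' outcome uses the milder 350 mmHg threshold (see [label_po2t()]).
#'
#' @param pao2 PaO2 in mmHg (> 0), or a physiology `data.frame` with columns
#'   `pao2` and `fio2`.
#' @param fio2 FiO2 in (0, 1]; ignored when `pao2` is a data frame.
#' @return P/F ratio(s) in mmHg.
#' @examples
#' pf_ratio(475, 1.0)
#' pf_ratio(70, 0.209)
#' @export
pf_ratio <- function(pao2, fio2 = NULL) {
  if (is.data.frame(pao2)) {
    fio2 <- pao2$fio2
    pao2 <- pao2$pao2
  }
  if (any(fio2 <= 0)) stop("fio2 must be positive", call. = FALSE)
  pao2 / fio2
}

#' Pulmonary oxygen toxicity outcome label
#'
#' Flags mild hypoxemia: `TRUE` when the P/F ratio is strictly below
#' `threshold` (default 350 mmHg, chosen below normal but above the 300 mmHg
#' ARDS criterion).
#'
#' @param pf P/F ratio(s) in mmHg (> 0).
#' @param threshold Outcome threshold in mmHg.
#' @return Logical vector.
#' @examples
#' label_po2t(c(349.9, 350, 334))
#' @export
label_po2t <- function(pf, threshold = 350) {
  stopifnot(all(pf > 0))
  pf < threshold
}

#' Empirical ROC curve
#'
#' The standard empirical ROC over all distinct score thresholds, with the
#' area computed by the trapezoidal rule — numerically identical to the
#' Mann-Whitney AUC of the same scores ([mann_whitney_auc()]).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) class labels; both classes must be present.
#' @return A `roc_points` object: list with `thresholds` (descending; the
#'   first is `Inf`), `tpr`, `fpr` and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (!any(labels) || all(labels)) {
    stop("labels must contain both classes", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  tpr <- vapply(thr, function(t) sum(scores[labels] >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!labels] >= t) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_points")
}

#' @export
print.roc_points <- function(x, ...) {
  cat(sprintf("empirical ROC: %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' @export
plot.roc_points <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Subject-level bootstrap confidence interval for an AUC
#'
#' Percentile 95% interval over bootstrap resamples drawn at the subject
#' level (all samples of a resampled subject enter together), respecting the
#' repeated-measures structure. Resamples in which only one class survives
#' are discarded.
#'
#' @param scores,labels As in [roc_curve()].
#' @param subjects Subject id per sample.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed RNG seed; the interval is deterministic given the seed.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric `c(low, high)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, subjects, n_boot = 2000,
                             seed = 1L, conf = 0.95) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), length(scores) == length(subjects))
  if (!any(labels) || all(labels)) {
    stop("labels must contain both classes", call. = FALSE)
  }
  ids <- unique(subjects)
  by_subj <- split(seq_along(scores), factor(subjects, levels = ids))
  .with_seed(seed, {
    aucs <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      take <- unlist(by_subj[sample.int(length(ids), replace = TRUE)],
                     use.names = FALSE)
      lb <- labels[take]
      if (any(lb) && !all(lb)) {
        aucs[b] <- mann_whitney_auc(scores[take][lb], scores[take][!lb])
      }
    }
    aucs <- aucs[!is.na(aucs)]
    alpha <- (1 - conf) / 2
    stats::setNames(stats::quantile(aucs, c(alpha, 1 - alpha), names = FALSE,
                                    type = 7),
                    c("low", "high"))
  })
}

#' Per-timepoint breath-score elevation test
#'
#' For each exposure timepoint, a two-sided paired t-test of subjects' breath
#' scores against their own baseline means (mean score over times <= 0),
#' Bonferroni-corrected across the exposure timepoints. A timepoint is
#' flagged significant when the corrected p-value is below `alpha`.
#'
#' @param scores A `data.frame` with columns `subject_id`, `time_h`, `q`
#'   (e.g. the oxygen-group rows of [score_study()] output).
#' @param alpha Significance level after correction (default 0.05).
#' @return A `data.frame` with one row per exposure timepoint: `time_h`,
#'   `mean_delta` (mean within-subject score change from baseline), `p_raw`,
#'   `p_adj`, `significant`.
#' @seealso [latency()]
#' @export
elevation_test <- function(scores, alpha = 0.05) {
  stopifnot(all(c("subject_id", "time_h", "q") %in% names(scores)))
  base <- scores[scores$time_h <= 0, ]
  expo <- scores[scores$time_h > 0, ]
  if (!nrow(base) || !nrow(expo)) {
    stop("scores must contain baseline and exposure timepoints", call. = FALSE)
  }
  base_mean <- tapply(base$q, base$subject_id, mean)
  times <- sort(unique(expo$time_h))
  res <- lapply(times, function(t) {
    st <- expo[expo$time_h == t, ]
    paired <- st$subject_id[st$subject_id %in% names(base_mean)]
    if (length(paired) < 2) {
      stop(sprintf("fewer than 2 paired subjects at %g h", t), call. = FALSE)
    }
    x <- st$q[match(paired, st$subject_id)]
    y <- unname(base_mean[paired])
    d <- x - y
    p <- if (stats::sd(d) == 0) {
      if (all(d == 0)) 1 else 0       # constant nonzero shift: exact evidence
    } else {
      stats::t.test(x, y, paired = TRUE)$p.value
    }
    data.frame(time_h = t, mean_delta = mean(d), p_raw = p)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out$p_adj <- pmin(out$p_raw * length(times), 1)   # Bonferroni
  out$significant <- out$p_adj < alpha
  out
}

#' Latency between breath-score elevation and P/F decline
#'
#' The operational early-warning gap: the first exposure timepoint at which
#' the group mean P/F ratio drops below `pf_threshold`, minus the first
#' exposure timepoint with a significant breath-score elevation (from
#' [elevation_test()]). Either side may be "not reached", in which case the
#' latency is undefined (`NA`).
#'
#' @param elevation Output of [elevation_test()].
#' @param physio Physiology records of the same group (see
#'   [read_physiology()]); P/F is computed per record and averaged per
#'   timepoint.
#' @param pf_threshold P/F decrement cutoff in mmHg (default 350).
#' @return A `latency_report` object: list with `first_bs_elevation_h`,
#'   `first_pf_below_h`, `latency_h` (each `NA` when not reached).
#' @export
latency <- function(elevation, physio, pf_threshold = 350) {
  sig <- elevation$time_h[elevation$significant]
  first_bs <- if (length(sig)) min(sig) else NA_real_
  expo <- physio[physio$time_h > 0, ]
  pf_mean <- tapply(pf_ratio(expo), expo$time_h, mean)
  below <- as.numeric(names(pf_mean))[pf_mean < pf_threshold]
  first_pf <- if (length(below)) min(below) else NA_real_
  structure(list(first_bs_elevation_h = first_bs,
                 first_pf_below_h = first_pf,
                 latency_h = first_pf - first_bs,
                 pf_threshold = pf_threshold),
            class = "latency_report")
}

#' @export
print.latency_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "not reached" else sprintf("%g h", v)
  cat(sprintf("first significant breath-score elevation: %s\n",
              fmt(x$first_bs_elevation_h)))
  cat(sprintf("first group mean P/F < %g mmHg: %s\n", x$pf_threshold,
              fmt(x$first_pf_below_h)))
  cat(sprintf("latency: %s\n", fmt(x$latency_h)))
  invisible(x)
}

#' Per-timepoint two-group comparisons with Bonferroni correction
#'
#' Welch two-sample t-tests of a continuous measure between the two treatment
#' groups at each exposure timepoint, Bonferroni-corrected across the tested
#' timepoints (two-sided, alpha 0.05 by default). Timepoints missing a group
#' are skipped with a warning.
#'
#' @param df A `data.frame` with columns `group`, `time_h` and the measure.
#' @param value Name of the measure column (e.g. `"pf"` or `"q"`).
#' @param alpha Significance level after correction.
#' @return A `data.frame` per tested timepoint: `time_h`, group means,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
group_timepoint_tests <- function(df, value, alpha = 0.05) {
  stopifnot(all(c("group", "time_h", value) %in% names(df)))
  times <- sort(unique(df$time_h[df$time_h > 0]))
  res <- list()
  for (t in times) {
    st <- df[df$time_h == t, ]
    a <- st[[value]][st$group == "air"]
    b <- st[[value]][st$group == "oxygen"]
    if (length(a) < 2 || length(b) < 2) {
      warning(sprintf("timepoint %g h skipped: missing or singleton stratum", t),
              call. = FALSE)
      next
    }
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      stats::t.test(a, b)$p.value      # Welch by default
    }
    res[[length(res) + 1L]] <- data.frame(
      time_h = t, mean_air = mean(a), mean_oxygen = mean(b), p_raw = p)
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out$p_adj <- pmin(out$p_raw * nrow(out), 1)
  out$significant <- out$p_adj < alpha
  out
}
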