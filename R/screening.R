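#' Mann-Whitney area under the ROC curve
#'
#' The probability that a randomly chosen value from `values_pos` exceeds a
#' randomly chosen value from `values_neg`, counting ties as one half: the
#' Mann-Whitney U statistic divided by `n1 * n2`. Identical to the area under
#' the empirical ROC curve of the same scores.
#'
#' @param values_pos,values_neg Non-empty numeric vectors for the positive and
#'   negative class.
#' @return AUC in `[0, 1]`.
#' @examples
#' mann_whitney_auc(c(2, 3), c(0, 1))  # perfect separation: 1
#' mann_whitney_auc(c(1, 3), c(2, 4))  # 0.25
#' @export
mann_whitney_auc <- function(values_pos, values_neg) {
  n1 <- length(values_pos); n2 <- length(values_neg)
  if (!n1 || !n2) stop("both classes must be non-empty", call. = FALSE)
  r <- rank(c(values_pos, values_neg))        # midranks handle ties as 0.5
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Fold a directional AUC into two-sided discrimination.
.fold_auc <- function(auc) pmax(auc, 1 - auc)

#' Dual-axis ROC screening of candidate exposure biomarkers
#'
#' Screens every feature of a [build_feature_matrix()] matrix on two axes:
#' `auc_x`, the two-sided discrimination `max(AUC, 1 - AUC)` between
#' oxygen-group baseline samples (time <= 0) and oxygen-group exposure samples
#' (time >= 12 h); and `auc_y`, the two-sided discrimination between
#' oxygen-group and air-group exposure samples. A feature is a candidate when
#' `auc_x >= tx` and `auc_y >= ty` (both inclusive). The raw, un-folded AUCs
#' are retained (`auc_x_raw`, `auc_y_raw`), and `direction` records the sign
#' of the raw oxygen-exposure shift (`+1` if abundance rises under oxygen,
#' `-1` otherwise).
#'
#' @param mat A `voc_matrix`.
#' @param tx,ty Candidate thresholds on the folded x- and y-axis AUCs
#'   (defaults 0.625 and 0.60).
#' @return A `voc_screen` data frame, one row per feature: `feature_id`,
#'   `auc_x`, `auc_y`, `auc_x_raw`, `auc_y_raw`, `direction`, `prevalence`,
#'   `mean_abundance`, `is_candidate`.
#' @seealso [screening_table()], [wda()]
#' @export
screen_candidates <- function(mat, tx = 0.625, ty = 0.60) {
  stopifnot(inherits(mat, "voc_matrix"), tx >= 0, tx <= 1, ty >= 0, ty <= 1)
  s <- mat$samples
  oxy_base <- which(s$group == "oxygen" & s$time_h <= 0)
  oxy_exp <- which(s$group == "oxygen" & s$time_h > 0)
  air_exp <- which(s$group == "air" & s$time_h > 0)
  for (stratum in list(c("oxygen baseline", length(oxy_base)),
                       c("oxygen exposure", length(oxy_exp)),
                       c("air exposure", length(air_exp)))) {
    if (stratum[2] == "0") {
      stop(sprintf("no samples in the %s stratum", stratum[1]), call. = FALSE)
    }
  }
  n_feat <- nrow(mat$A)
  auc_x_raw <- auc_y_raw <- numeric(n_feat)
  for (i in seq_len(n_feat)) {
    v <- mat$A[i, ]
    auc_x_raw[i] <- mann_whitney_auc(v[oxy_exp], v[oxy_base])
    auc_y_raw[i] <- mann_whitney_auc(v[oxy_exp], v[air_exp])
  }
  out <- data.frame(
    feature_id = mat$features$feature_id,
    auc_x = .fold_auc(auc_x_raw), auc_y = .fold_auc(auc_y_raw),
    auc_x_raw = auc_x_raw, auc_y_raw = auc_y_raw,
    direction = ifelse(auc_x_raw > 0.5, 1, -1),
    prevalence = mat$features$prevalence,
    mean_abundance = rowMeans(mat$A),
    is_candidate = .fold_auc(auc_x_raw) >= tx & .fold_auc(auc_y_raw) >= ty)
  attr(out, "thresholds") <- c(tx = tx, ty = ty)
  class(out) <- c("voc_screen", "data.frame")
  out
}

#' Screening scatter table
#'
#' Orders screening records for plotting: one row per feature, sorted by
#' `max(auc_x, auc_y)` in decreasing order, carrying the two AUC axes,
#' prevalence, mean abundance and the candidate flag.
#'
#' @param records A `voc_screen` data frame from [screen_candidates()].
#' @return The reordered data frame.
#' @export
screening_table <- function(records) {
  if (!nrow(records)) stop("no screening records", call. = FALSE)
  out <- records[order(-pmax(records$auc_x, records$auc_y),
                       records$feature_id), ]
  rownames(out) <- NULL
  out
}
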