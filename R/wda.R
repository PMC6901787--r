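#' Single-marker contribution to the breath score
#'
#' Weighted digital analysis digitizes each marker by a cutoff crossing: a
#' marker contributes its full weight when `sign * (abundance - cutoff) > 0`
#' and zero otherwise. With sign -1 (the common case for compounds consumed
#' under oxidative stress) a marker therefore contributes exactly when its
#' normalized abundance falls strictly below the cutoff. Under the default
#' `"strict"` boundary rule an abundance exactly at the cutoff is inactive;
#' `"inclusive"` activates it.
#'
#' @param a Non-negative normalized abundance(s).
#' @param marker A marker parameter row or list with elements `weight`,
#'   `sign`, `cutoff`.
#' @param boundary `"strict"` (default) or `"inclusive"` cutoff-boundary rule.
#' @return Numeric vector: `marker$weight` where active, else 0.
#' @examples
#' benzene <- list(weight = 1.33, sign = -1, cutoff = 1.10)
#' marker_contribution(c(0.5, 1.10, 1.5), benzene)
#' @export
marker_contribution <- function(a, marker, boundary = c("strict", "inclusive")) {
  boundary <- match.arg(boundary)
  z <- marker$sign * (a - marker$cutoff)
  active <- if (boundary == "strict") z > 0 else z >= 0
  ifelse(active, marker$weight, 0)
}

#' Wrap a marker-parameter table as a WDA model
#'
#' Builds a scoring-ready `wda` object from a fixed marker table (for
#' example the packaged reference panel from [load_marker_params()]), without
#' fitting anything.
#'
#' @param markers Marker `data.frame` with columns `name`, `weight`, `sign`,
#'   `cutoff` and optionally `quant_mz`, `rt1`, `rt2` (needed to resolve
#'   markers against a feature matrix).
#' @param weight_rule Label recording how weights were derived.
#' @inheritParams marker_contribution
#' @return A `wda` object.
#' @seealso [wda()], [breath_score()], [score_study()]
#' @export
as_wda <- function(markers, weight_rule = "fixed",
                   boundary = c("strict", "inclusive")) {
  boundary <- match.arg(boundary)
  stopifnot(is.data.frame(markers),
            all(c("name", "weight", "sign", "cutoff") %in% names(markers)))
  if (anyDuplicated(markers$name)) stop("marker names must be unique", call. = FALSE)
  if (any(markers$weight <= 0)) stop("marker weights must be positive", call. = FALSE)
  if (any(!markers$sign %in% c(-1, 1))) stop("marker sign must be -1 or +1", call. = FALSE)
  structure(list(markers = markers, weight_rule = weight_rule,
                 boundary = boundary, loso_auc = NA_real_, trace = NULL),
            class = "wda")
}

#' Breath score of one sample
#'
#' The breath score Q is the sum of [marker_contribution()] over the model's
#' markers, evaluated on the sample's normalized marker abundances. It is
#' bounded between 0 and the sum of the model weights. A marker absent from
#' `abundances` scores as abundance 0; names in `abundances` that are not
#' model markers are ignored with a warning.
#'
#' @param abundances Named numeric vector of normalized abundances, names
#'   matching model marker names.
#' @param model A `wda` object.
#' @return The breath score (scalar).
#' @examples
#' panel <- as_wda(load_marker_params())
#' breath_score(setNames(rep(0, 6), load_marker_params()$name), panel)
#' @export
breath_score <- function(abundances, model) {
  stopifnot(inherits(model, "wda"))
  extra <- setdiff(names(abundances), model$markers$name)
  if (length(extra)) {
    warning("ignoring unknown marker(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  a <- abundances[match(model$markers$name, names(abundances))]
  a[is.na(a)] <- 0
  q <- 0
  for (i in seq_len(nrow(model$markers))) {
    q <- q + marker_contribution(a[[i]], model$markers[i, ], model$boundary)
  }
  unname(q)
}

#' Fit a digitizing cutoff by Youden-index maximization
#'
#' Chooses the abundance cutoff that maximizes the Youden index
#' (sensitivity + specificity - 1) of the digitized marker, where a value is
#' "active" when `direction * (value - cutoff) > 0`, the positive stratum is
#' expected active. Candidate cutoffs are the midpoints between adjacent
#' distinct values of the pooled strata; ties are broken toward the smaller
#' cutoff. If all pooled values are equal the common value is returned with a
#' warning.
#'
#' @param values_pos,values_neg Non-empty abundance vectors for the stratum
#'   expected active (e.g. exposure) and its complement.
#' @param direction `-1` (active below cutoff) or `+1` (active above).
#' @return The fitted cutoff (scalar).
#' @examples
#' fit_cutoff(c(0.1, 0.2), c(0.8, 0.9), direction = -1)  # 0.5
#' @export
fit_cutoff <- function(values_pos, values_neg, direction = -1) {
  if (!length(values_pos) || !length(values_neg)) {
    stop("both strata must be non-empty", call. = FALSE)
  }
  stopifnot(direction %in% c(-1, 1))
  pooled <- sort(unique(c(values_pos, values_neg)))
  if (length(pooled) == 1L) {
    warning("degenerate strata: all values equal; cutoff set to that value",
            call. = FALSE)
    return(pooled)
  }
  cuts <- (pooled[-length(pooled)] + pooled[-1]) / 2
  sp <- sort(values_pos); sn <- sort(values_neg)
  # No pooled value coincides with a midpoint, so "< cut" == "<= cut" here.
  # Integer cross-multiplied counts keep exact ties exact, so the tie-break
  # toward the smaller cutoff is deterministic.
  below_pos <- findInterval(cuts, sp)
  below_neg <- findInterval(cuts, sn)
  j <- if (direction < 0) below_pos * length(sn) - below_neg * length(sp)
       else below_neg * length(sp) - below_pos * length(sn)
  cuts[which.max(j)]          # cuts ascending: first max = smallest cutoff
}

#' Transform a C-statistic into a marker weight
#'
#' The default `"odds"` rule maps a marker's C-statistic (two-sided ROC AUC,
#' in `[0.5, 1)`) to the weight `c / (1 - c)`: an uninformative marker
#' (c = 0.5) gets unit weight and the weight grows monotonically with
#' discrimination. Alternative rules: `"identity"` (weight = c) and
#' `"youden"` (weight = 2c - 1; zero at c = 0.5, so only usable for strictly
#' informative markers).
#'
#' @param c_statistic AUC value(s) in `[0.5, 1)`; fold direction first
#'   (values below 0.5 are an error).
#' @param rule Weight transform.
#' @return Positive weight(s).
#' @examples
#' derive_weight(0.8)  # 4
#' @export
derive_weight <- function(c_statistic, rule = c("odds", "identity", "youden")) {
  rule <- match.arg(rule)
  if (any(c_statistic >= 1)) stop("C-statistic must be < 1", call. = FALSE)
  if (any(c_statistic < 0.5)) {
    stop("C-statistic must be >= 0.5 (fold direction first)", call. = FALSE)
  }
  switch(rule,
         odds = c_statistic / (1 - c_statistic),
         identity = c_statistic,
         youden = 2 * c_statistic - 1)
}

# Fit direction, cutoff and weight of one marker against binary labels.
# C-statistics hitting 1.0 under perfect separation are clamped just below 1
# so the odds weight transform stays finite.
.fit_marker <- function(v, labels, weight_rule, min_weight = 1e-6) {
  pos <- v[labels]; neg <- v[!labels]
  raw <- mann_whitney_auc(pos, neg)
  direction <- if (raw > 0.5) 1 else -1
  cutoff <- suppressWarnings(fit_cutoff(pos, neg, direction))
  cmax <- 1 - 1 / (2 * length(pos) * length(neg))
  cstat <- min(max(.fold_auc(raw), 0.5), cmax)
  weight <- max(derive_weight(cstat, weight_rule), min_weight)
  list(sign = direction, cutoff = cutoff, weight = weight, c_statistic = cstat)
}

#' Fit a weighted-digital-analysis breath-score model
#'
#' Fits the full WDA panel on an aligned feature matrix: starting from the
#' dual-ROC screening candidates, markers are added by greedy forward
#' selection, at each step choosing the candidate whose inclusion maximizes
#' the leave-one-subject-out (LOSO) cross-validated AUC of the combined
#' breath score against the exposure labels. Selection stops when no addition
#' improves the LOSO AUC by more than `improve_tol` (or `max_markers` is
#' reached); ties are broken by the candidate's screening `auc_y`, then by
#' name. Holding out whole subjects prevents leakage across the repeated
#' measures of one animal.
#'
#' Within every fold each marker is refit on the training subjects only: its
#' direction is the sign of the raw training AUC, its cutoff maximizes the
#' Youden index of the digitized marker ([fit_cutoff()]) and its weight is
#' the transformed training C-statistic ([derive_weight()]). The returned
#' model carries full-data parameters for the selected markers.
#'
#' @param x A `voc_matrix` from [build_feature_matrix()].
#' @param labels Logical vector, one per sample, marking the positive class.
#'   Default: oxygen-group exposure samples
#'   (`group == "oxygen" & time_h > 0`).
#' @param screen A `voc_screen` from [screen_candidates()], or `NULL` to
#'   screen internally with thresholds `tx`, `ty`. Only candidate rows enter
#'   selection.
#' @param tx,ty Screening thresholds when `screen` is `NULL`.
#' @param max_markers Optional cap on panel size.
#' @param weight_rule,boundary See [derive_weight()], [marker_contribution()].
#' @param improve_tol Minimum LOSO AUC improvement to keep adding markers.
#' @return A `wda` object: `markers` (name, quant m/z, retention centroids,
#'   weight, sign, cutoff per selected marker, in selection order),
#'   `weight_rule`, `boundary`, `loso_auc`, and `trace` (per-step selection
#'   record). Methods: `print`, `summary`, `coef`, `predict`, `plot`.
#' @examples
#' \donttest{
#' study <- simulate_study(sim_config(n_air = 3, n_oxygen = 3,
#'                                    n_background_voc = 60))
#' mat <- build_feature_matrix(study)
#' fit <- wda(mat)
#' fit
#' }
#' @export
wda <- function(x, labels = NULL, screen = NULL, tx = 0.625, ty = 0.60,
                max_markers = NULL, weight_rule = c("odds", "identity", "youden"),
                boundary = c("strict", "inclusive"), improve_tol = 1e-9) {
  stopifnot(inherits(x, "voc_matrix"))
  weight_rule <- match.arg(weight_rule)
  boundary <- match.arg(boundary)
  if (is.null(labels)) labels <- x$samples$group == "oxygen" & x$samples$time_h > 0
  labels <- as.logical(labels)
  stopifnot(length(labels) == ncol(x$A))
  if (!any(labels) || all(labels)) {
    stop("labels must contain both classes", call. = FALSE)
  }
  if (is.null(screen)) screen <- screen_candidates(x, tx = tx, ty = ty)
  cand <- screen[screen$is_candidate, , drop = FALSE]
  if (!nrow(cand)) stop("no candidate markers to select from", call. = FALSE)
  cand <- cand[order(-cand$auc_y, cand$feature_id), ]   # tie-break order
  cand_ids <- cand$feature_id
  rows <- match(cand_ids, x$features$feature_id)

  # Precompute the LOSO contribution matrix: C[j, f] is marker f's digital
  # contribution to sample j under parameters fit without j's subject. Marker
  # fits are independent of the surrounding panel, so each (fold, marker)
  # pair is fit exactly once regardless of how selection proceeds.
  subj <- x$samples$subject_id
  C <- matrix(0, nrow = ncol(x$A), ncol = length(cand_ids),
              dimnames = list(NULL, cand_ids))
  for (u in unique(subj)) {
    test <- subj == u
    train <- !test
    if (!any(labels[train]) || all(labels[train])) {
      stop(sprintf("fold '%s': training labels contain a single class", u),
           call. = FALSE)
    }
    for (k in seq_along(cand_ids)) {
      v <- x$A[rows[k], ]
      fit <- .fit_marker(v[train], labels[train], weight_rule)
      C[test, k] <- marker_contribution(v[test], fit, boundary)
    }
  }

  selected <- character(0)
  current <- numeric(ncol(x$A))
  cur_auc <- 0.5                       # empty model: constant score, all ties
  trace <- list()
  repeat {
    if (!is.null(max_markers) && length(selected) >= max_markers) break
    remaining <- setdiff(cand_ids, selected)
    if (!length(remaining)) break
    best_auc <- -Inf; best <- NA_character_
    for (f in remaining) {             # scan in tie-break order
      s <- current + C[, f]
      a <- mann_whitney_auc(s[labels], s[!labels])
      if (a > best_auc) { best_auc <- a; best <- f }
    }
    if (best_auc - cur_auc <= improve_tol) break
    selected <- c(selected, best)
    current <- current + C[, best]
    cur_auc <- best_auc
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(selected), feature_id = best, loso_auc = best_auc)
  }
  if (!length(selected)) {             # forced single best marker
    best_auc <- -Inf; best <- cand_ids[1]
    for (f in cand_ids) {
      a <- mann_whitney_auc(C[labels, f], C[!labels, f])
      if (a > best_auc) { best_auc <- a; best <- f }
    }
    selected <- best
    cur_auc <- best_auc
    trace[[1L]] <- data.frame(step = 1L, feature_id = best, loso_auc = best_auc)
  }

  frow <- match(selected, x$features$feature_id)
  fits <- lapply(frow, function(r) .fit_marker(x$A[r, ], labels, weight_rule))
  markers <- data.frame(
    name = selected,
    feature_id = selected,
    quant_mz = x$features$consensus_mz[frow],
    rt1 = x$features$centroid_rt1[frow],
    rt2 = x$features$centroid_rt2[frow],
    weight = vapply(fits, `[[`, numeric(1), "weight"),
    sign = vapply(fits, `[[`, numeric(1), "sign"),
    cutoff = vapply(fits, `[[`, numeric(1), "cutoff"),
    c_statistic = vapply(fits, `[[`, numeric(1), "c_statistic"))
  out <- as_wda(markers, weight_rule = weight_rule, boundary = boundary)
  out$loso_auc <- cur_auc
  out$trace <- do.call(rbind, c(trace, list(make.row.names = FALSE)))
  out$call <- match.call()
  out
}

# Resolve model markers to rows of a feature matrix: exact feature_id match
# when available, else the nearest centroid within the retention tolerances
# with matching quant m/z. Unresolved markers score as absent (abundance 0).
.resolve_markers <- function(mat, model, tol_rt1 = 5, tol_rt2 = 0.1) {
  m <- model$markers
  idx <- rep(NA_integer_, nrow(m))
  if (!is.null(m$feature_id)) {
    idx <- match(m$feature_id, mat$features$feature_id)
  }
  for (i in which(is.na(idx))) {
    if (is.null(m$rt1) || is.null(m$quant_mz)) next
    ok <- which(abs(mat$features$centroid_rt1 - m$rt1[i]) <= tol_rt1 &
                  abs(mat$features$centroid_rt2 - m$rt2[i]) <= tol_rt2 &
                  mat$features$consensus_mz == m$quant_mz[i])
    if (length(ok)) {
      d <- abs(mat$features$centroid_rt1[ok] - m$rt1[i]) +
        abs(mat$features$centroid_rt2[ok] - m$rt2[i]) * 50
      idx[i] <- ok[which.min(d)]
    }
  }
  idx
}

#' Score every sample of a study
#'
#' Applies a WDA model to a feature matrix: each model marker is resolved to
#' a matrix feature (exact id for models fitted on the same matrix, else
#' nearest centroid within the retention tolerances with matching quant m/z;
#' unresolved markers contribute via abundance 0) and each sample receives
#' its breath score.
#'
#' @param mat A `voc_matrix`.
#' @param model A `wda` object.
#' @param tol_rt1,tol_rt2 Marker-resolution retention tolerances (seconds).
#' @return A `data.frame` with one row per sample: `sample_id`, `subject_id`,
#'   `group`, `phase`, `time_h`, `q` (the breath score).
#' @export
score_study <- function(mat, model, tol_rt1 = 5, tol_rt2 = 0.1) {
  stopifnot(inherits(mat, "voc_matrix"), inherits(model, "wda"))
  idx <- .resolve_markers(mat, model, tol_rt1, tol_rt2)
  q <- numeric(ncol(mat$A))
  for (i in seq_len(nrow(model$markers))) {
    a <- if (is.na(idx[i])) rep(0, ncol(mat$A)) else mat$A[idx[i], ]
    q <- q + marker_contribution(a, model$markers[i, ], model$boundary)
  }
  out <- mat$samples[c("sample_id", "subject_id", "group", "phase", "time_h")]
  out$q <- q
  rownames(out) <- NULL
  out
}

#' @export
print.wda <- function(x, ...) {
  cat(sprintf("WDA breath-score model: %d marker(s), weight rule '%s', %s boundary\n",
              nrow(x$markers), x$weight_rule, x$boundary))
  if (!is.na(x$loso_auc)) {
    cat(sprintf("  leave-one-subject-out exposure AUC: %.3f\n", x$loso_auc))
  }
  cat(sprintf("  score range: [0, %.3f]\n", sum(x$markers$weight)))
  invisible(x)
}

#' @export
summary.wda <- function(object, ...) {
  structure(list(markers = object$markers, weight_rule = object$weight_rule,
                 boundary = object$boundary, loso_auc = object$loso_auc,
                 trace = object$trace),
            class = "summary.wda")
}

#' @export
print.summary.wda <- function(x, ...) {
  cat(sprintf("WDA breath-score model (weight rule '%s', %s boundary)\n",
              x$weight_rule, x$boundary))
  cat("\nMarkers:\n")
  print(x$markers, row.names = FALSE)
  if (!is.null(x$trace)) {
    cat("\nForward-selection trace (LOSO AUC after each step):\n")
    print(x$trace, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.wda <- function(object, ...) {
  stats::setNames(object$markers$weight, object$markers$name)
}

#' Predict breath scores from a fitted WDA model
#'
#' @param object A `wda` object.
#' @param newdata A `voc_matrix` (scored via [score_study()]) or a numeric
#'   matrix/data.frame of normalized abundances with one column per model
#'   marker.
#' @param ... Unused.
#' @return For a `voc_matrix`, the [score_study()] data frame; otherwise a
#'   numeric vector of breath scores, one per row of `newdata`.
#' @export
predict.wda <- function(object, newdata, ...) {
  if (inherits(newdata, "voc_matrix")) return(score_study(newdata, object))
  newdata <- as.matrix(newdata)
  vapply(seq_len(nrow(newdata)), function(i) {
    breath_score(stats::setNames(as.numeric(newdata[i, ]), colnames(newdata)),
                 object)
  }, numeric(1))
}

#' @export
plot.wda <- function(x, ...) {
  m <- x$markers
  op <- graphics::par(mar = c(9, 4, 2, 1))
  on.exit(graphics::par(op))
  bp <- graphics::barplot(m$weight, names.arg = m$name, las = 2,
                          ylab = "weight", cex.names = 0.7,
                          main = "WDA marker weights", ...)
  graphics::text(bp, m$weight / 2,
                 labels = sprintf("cut %.3g\nsign %+d", m$cutoff, m$sign),
                 cex = 0.6)
  invisible(x)
}
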