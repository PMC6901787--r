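# Independent brute-force oracles used to cross-check the implementation.

# Pairwise-counting AUC: fraction of (pos, neg) pairs with pos > neg, ties 0.5.
auc_brute <- function(pos, neg) {
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Naive re-derivation of the greedy retention-window clustering: explicit
# scan over clusters in creation order, centroids as sum/n, no bucketing.
cluster_oracle <- function(peaks, tol_rt1 = 5, tol_rt2 = 0.1, match_mz = TRUE) {
  ord <- order(-peaks$area, peaks$rt1, peaks$rt2, peaks$sample)
  clusters <- list()
  assignment <- integer(nrow(peaks))
  for (i in ord) {
    placed <- 0L
    for (k in seq_along(clusters)) {
      cl <- clusters[[k]]
      if (abs(cl$rt1sum / cl$n - peaks$rt1[i]) <= tol_rt1 &&
          abs(cl$rt2sum / cl$n - peaks$rt2[i]) <= tol_rt2 &&
          (!match_mz || cl$mz == peaks$mz[i]) &&
          !(peaks$sample[i] %in% cl$samples)) {
        placed <- k
        break
      }
    }
    if (placed) {
      cl <- clusters[[placed]]
      clusters[[placed]] <- list(rt1sum = cl$rt1sum + peaks$rt1[i],
                                 rt2sum = cl$rt2sum + peaks$rt2[i],
                                 n = cl$n + 1L, mz = cl$mz,
                                 samples = c(cl$samples, peaks$sample[i]))
      assignment[i] <- placed
    } else {
      clusters[[length(clusters) + 1L]] <- list(rt1sum = peaks$rt1[i],
                                                rt2sum = peaks$rt2[i],
                                                n = 1L, mz = peaks$mz[i],
                                                samples = peaks$sample[i])
      assignment[i] <- length(clusters)
    }
  }
  assignment
}

# Brute-force breath score: explicit per-marker loop over the digital rule.
score_brute <- function(abund, markers, boundary = "strict") {
  q <- 0
  for (i in seq_len(nrow(markers))) {
    a <- abund[[markers$name[i]]]
    if (is.null(a) || is.na(a)) a <- 0
    z <- markers$sign[i] * (a - markers$cutoff[i])
    active <- if (boundary == "strict") z > 0 else z >= 0
    if (active) q <- q + markers$weight[i]
  }
  q
}

random_peaks <- function(n, n_samples = 4, mz_values = c(50, 57, 78)) {
  data.frame(rt1 = runif(n, 100, 200), rt2 = runif(n, 0.8, 1.4),
             mz = sample(mz_values, n, replace = TRUE),
             area = rlnorm(n, 8, 1), snr = rlnorm(n, 7, 1),
             sample = sample.int(n_samples, n, replace = TRUE))
}

# A quick small-study configuration for unit tests; dots override defaults.
small_config <- function(...) {
  args <- list(n_air = 3L, n_oxygen = 3L, n_background_voc = 60L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Resolve planted markers to feature-matrix rows via their true coordinates.
resolve_planted <- function(mat, truth_markers, tol_rt1 = 5, tol_rt2 = 0.1) {
  vapply(seq_len(nrow(truth_markers)), function(i) {
    ok <- which(abs(mat$features$centroid_rt1 - truth_markers$rt1[i]) <= tol_rt1 &
                  abs(mat$features$centroid_rt2 - truth_markers$rt2[i]) <= tol_rt2 &
                  mat$features$consensus_mz == truth_markers$mz[i])
    if (length(ok)) ok[1] else NA_integer_
  }, integer(1))
}
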