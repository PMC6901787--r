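test_that("marker contributions follow the digital cutoff rule", {
  benzene <- list(weight = 1.33, sign = -1, cutoff = 1.10)
  expect_equal(marker_contribution(0.50, benzene), 1.33)
  expect_equal(marker_contribution(1.10, benzene), 0)       # strict boundary
  expect_equal(marker_contribution(1.10, benzene, boundary = "inclusive"), 1.33)
  up <- list(weight = 2, sign = 1, cutoff = 0.5)
  expect_equal(marker_contribution(0.5, up), 0)             # symmetric strictness
  expect_equal(marker_contribution(c(0.4, 0.6), up), c(0, 2))
})

test_that("breath scores sum active marker weights over the packaged panel", {
  panel <- as_wda(load_marker_params())
  nm <- load_marker_params()$name
  expect_equal(breath_score(stats::setNames(rep(0, 6), nm), panel), 7.96)
  above <- stats::setNames(load_marker_params()$cutoff + 1, nm)
  expect_equal(breath_score(above, panel), 0)
  only_benzene <- above
  only_benzene["benzene"] <- 0.5
  expect_equal(breath_score(only_benzene, panel), 1.33)
  expect_warning(breath_score(c(above, pentane = 1), panel), "unknown marker")
})

test_that("breath scores match a brute-force per-marker summation", {
  set.seed(5)
  for (i in 1:500) {
    n <- sample(1:8, 1)
    markers <- data.frame(name = sprintf("m%d", 1:n),
                          weight = runif(n, 0.5, 3),
                          sign = sample(c(-1, 1), n, replace = TRUE),
                          cutoff = round(runif(n, 0, 2), 2))
    boundary <- sample(c("strict", "inclusive"), 1)
    model <- as_wda(markers, boundary = boundary)
    a <- stats::setNames(round(runif(n, 0, 2), 2), markers$name)
    drop <- runif(n) < 0.2                 # absent markers score as zero
    got <- breath_score(a[!drop], model)
    want <- score_brute(as.list(a[!drop]), markers, boundary)
    expect_identical(got, want)
    expect_lte(got, sum(markers$weight))
    expect_gte(got, 0)
  }
})

test_that("score is monotone under abundance decreases when all signs are -1", {
  markers <- data.frame(name = c("a", "b"), weight = c(1, 2), sign = c(-1, -1),
                        cutoff = c(0.5, 1))
  model <- as_wda(markers)
  set.seed(8)
  for (i in 1:50) {
    x <- stats::setNames(runif(2, 0, 2), markers$name)
    y <- x - runif(2, 0, 0.5)
    expect_gte(breath_score(pmax(y, 0), model), breath_score(x, model))
  }
})

test_that("cutoff fitting maximizes the Youden index over value midpoints", {
  expect_equal(fit_cutoff(c(0.1, 0.2), c(0.8, 0.9), direction = -1), 0.5)
  expect_warning(cut0 <- fit_cutoff(c(1, 1), c(1, 1)), "degenerate")
  expect_equal(cut0, 1)

  # perfectly separated strata digitize with sensitivity = specificity = 1
  pos <- c(0.1, 0.15, 0.2); neg <- c(0.8, 0.9, 1.2)
  cut <- fit_cutoff(pos, neg, direction = -1)
  expect_true(all(pos < cut) && all(neg > cut))

  # identical strata: zero Youden everywhere, smallest midpoint returned
  v <- c(1, 2, 3)
  expect_equal(fit_cutoff(v, v, direction = -1), 1.5)

  # exhaustive-search oracle on random instances
  set.seed(12)
  for (i in 1:100) {
    pos <- round(runif(sample(2:10, 1), 0, 1), 2)
    neg <- round(runif(sample(2:10, 1), 0, 1), 2)
    dir <- sample(c(-1, 1), 1)
    pooled <- sort(unique(c(pos, neg)))
    if (length(pooled) < 2) next
    cuts <- (pooled[-length(pooled)] + pooled[-1]) / 2
    # exact integer Youden ranking so ties are true ties
    j <- vapply(cuts, function(ct) {
      act <- function(v) if (dir < 0) v < ct else v > ct
      sum(act(pos)) * length(neg) - sum(act(neg)) * length(pos)
    }, numeric(1))
    expect_equal(fit_cutoff(pos, neg, dir), cuts[which.max(j)])
  }
})

test_that("the C-statistic weight transform behaves as documented", {
  expect_equal(derive_weight(0.5), 1.0)
  expect_equal(derive_weight(0.8), 4.0)
  grid <- seq(0.5, 0.98, length.out = 50)
  expect_true(all(diff(derive_weight(grid)) > 0))
  expect_error(derive_weight(1), "< 1")
  expect_error(derive_weight(0.4), ">= 0.5")
  expect_equal(derive_weight(0.8, "identity"), 0.8)
  expect_equal(derive_weight(0.8, "youden"), 0.6)
})

test_that("forward selection finds a perfect marker among null candidates", {
  # Construct a feature matrix by hand: feature 1 is a deterministic perfect
  # marker (drops to zero in every positive sample), features 2..21 are noise.
  set.seed(99)
  n_subj <- 8
  samples <- data.frame(
    sample_id = sprintf("s%02d_%d", rep(1:n_subj, each = 9), rep(1:9, n_subj)),
    subject_id = sprintf("s%02d", rep(1:n_subj, each = 9)),
    group = rep(c("air", "oxygen"), each = 9 * n_subj / 2),
    phase = rep(c(rep("baseline", 3), rep("exposure", 6)), n_subj),
    time_h = rep(c(-24, -12, 0, 12, 24, 36, 48, 60, 72), n_subj),
    internal_standard_area = 1)
  labels <- samples$group == "oxygen" & samples$time_h > 0
  A <- matrix(rlnorm(21 * nrow(samples)), nrow = 21)
  A[1, ] <- ifelse(labels, 0.01, 1)
  features <- data.frame(feature_id = sprintf("F%02d", 1:21),
                         centroid_rt1 = seq(100, 500, length.out = 21),
                         centroid_rt2 = 1, consensus_mz = 50L + 1:21,
                         n_members = nrow(samples), prevalence = 1)
  mat <- structure(list(features = features, samples = samples, A = A),
                   class = "voc_matrix")
  scr <- screen_candidates(mat, tx = 0, ty = 0)    # everything is a candidate
  fit <- wda(mat, screen = scr)
  expect_identical(fit$trace$feature_id[1], "F01")
  expect_gte(fit$loso_auc, 0.99)

  capped <- wda(mat, screen = scr, max_markers = 3)
  expect_lte(nrow(capped$markers), 3L)

  expect_error(wda(mat, screen = scr[scr$auc_x > 2, ]), "no candidate")
})

test_that("fitted models score a study sample-per-sample within the weight bound", {
  study <- simulate_study(small_config(seed = 23))
  mat <- build_feature_matrix(study)
  fit <- wda(mat)
  scores <- score_study(mat, fit)
  expect_identical(nrow(scores), length(study$samples))
  expect_true(all(scores$q >= 0 & scores$q <= sum(fit$markers$weight)))

  # predict() on the matrix agrees with score_study()
  expect_equal(predict(fit, mat), scores)

  # methods surface the model sensibly
  expect_named(coef(fit), fit$markers$name)
  expect_output(print(fit), "WDA breath-score model")
  expect_output(print(summary(fit)), "Forward-selection trace")
})

test_that("the packaged panel scores any study within [0, 7.96]", {
  panel <- as_wda(load_marker_params())
  study <- simulate_study(small_config(seed = 29))
  mat <- build_feature_matrix(study)
  scores <- score_study(mat, panel)    # markers resolve by coordinates or score 0
  expect_true(all(scores$q >= 0 & scores$q <= 7.96 + 1e-12))
})
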