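test_that("retention-window matching applies inclusive tolerances", {
  a <- peak_table(171.30, 1.20, 78L, 5000, 900)
  expect_true(match_peaks(a, peak_table(175.30, 1.25, 78L, 1, 1)))
  expect_false(match_peaks(a, peak_table(176.40, 1.20, 78L, 1, 1)))
  expect_true(match_peaks(a, a))                         # reflexive
  b <- peak_table(100, 1.2, 78L, 1, 1)                   # exact 5 s edge
  expect_true(match_peaks(b, peak_table(105, 1.2, 78L, 1, 1)))
  expect_false(match_peaks(a, peak_table(171.30, 1.20, 79L, 1, 1)))
  expect_true(match_peaks(a, peak_table(171.30, 1.20, 79L, 1, 1), match_mz = FALSE))
})

test_that("the S/N filter keeps exactly the peaks at or above threshold", {
  p <- peak_table(rt1 = 1:4 * 100, rt2 = rep(1, 4), mz = rep(50L, 4),
                  area = rep(10, 4), snr = c(100, 399, 400, 900))
  expect_equal(filter_snr(p)$snr, c(400, 900))
  expect_equal(filter_snr(p, 0), p)
  expect_identical(nrow(filter_snr(p, 1000)), 0L)
})

test_that("background subtraction floors at zero and ignores unmatched peaks", {
  breath <- peak_table(rt1 = c(100, 200, 300), rt2 = rep(1, 3),
                       mz = rep(50L, 3), area = c(5000, 5000, 5000),
                       snr = rep(500, 3))
  bg <- peak_table(rt1 = c(101, 201, 600), rt2 = c(1.02, 0.98, 1),
                   mz = rep(50L, 3), area = c(1000, 6000, 100),
                   snr = rep(500, 3))
  out <- subtract_background(breath, bg)
  expect_equal(out$area, c(4000, 0, 5000))
  expect_identical(nrow(out), 3L)                    # background-only peak dropped
  expect_equal(subtract_background(breath, peak_table()), breath)

  # nearest background peak wins when several match
  bg2 <- peak_table(rt1 = c(103, 100.5), rt2 = c(1, 1), mz = c(50L, 50L),
                    area = c(100, 2000), snr = c(500, 500))
  out2 <- subtract_background(breath[1, ], bg2)
  expect_equal(out2$area, 3000)
})

test_that("greedy clustering agrees with a naive independent re-derivation", {
  set.seed(20)
  for (i in 1:50) {
    p <- random_peaks(sample(20:200, 1))
    got <- cluster_peaks(p)
    expect_identical(got$assignment, cluster_oracle(p))
    # at most one member per sample per cluster
    expect_false(any(duplicated(cbind(got$assignment, p$sample))))
    # final centroids are the member means
    for (k in seq_len(nrow(got$clusters))) {
      expect_equal(got$clusters$centroid_rt1[k], mean(p$rt1[got$assignment == k]))
    }
  }
  # mz-agnostic mode also matches the oracle
  p <- random_peaks(100)
  expect_identical(cluster_peaks(p, match_mz = FALSE)$assignment,
                   cluster_oracle(p, match_mz = FALSE))
})

test_that("clustering separates distant peaks and merges same-species peaks", {
  two <- data.frame(rt1 = c(150, 152), rt2 = c(1.0, 1.05), mz = c(78L, 78L),
                    area = c(100, 90), snr = c(500, 500), sample = c(1L, 2L))
  got <- cluster_peaks(two)
  expect_identical(nrow(got$clusters), 1L)
  expect_equal(got$clusters$prevalence, 1.0)

  apart <- data.frame(rt1 = c(150, 160), rt2 = c(1.0, 1.0), mz = c(78L, 78L),
                      area = c(100, 90), snr = c(500, 500), sample = c(1L, 2L))
  expect_identical(nrow(cluster_peaks(apart)$clusters), 2L)
})

test_that("normalization is scale invariant and guards the internal standard", {
  areas <- c(200, 0, 50)
  expect_equal(normalize_to_internal_standard(areas, 100), c(2, 0, 0.5))
  expect_equal(normalize_to_internal_standard(areas * 7, 100 * 7),
               normalize_to_internal_standard(areas, 100))
  expect_error(normalize_to_internal_standard(areas, 0), "positive")
})

test_that("the feature matrix contains the planted markers and valid abundances", {
  study <- simulate_study(small_config(seed = 9))
  mat <- build_feature_matrix(study)
  expect_true(all(mat$A >= 0))
  expect_true(all(mat$features$prevalence >= 0.1))
  idx <- resolve_planted(mat, study$truth$markers)
  expect_false(anyNA(idx))
  expect_gte(nrow(mat$A), 6L)
  expect_identical(ncol(mat$A), length(study$samples))

  expect_error(build_feature_matrix(structure(list(samples = list()),
                                              class = "voc_study")),
               "no samples")
})

test_that("sample order does not change the aligned abundances", {
  study <- simulate_study(small_config(n_background_voc = 30, seed = 13))
  perm <- sample(length(study$samples))
  study2 <- study
  study2$samples <- study$samples[perm]
  m1 <- build_feature_matrix(study)
  m2 <- build_feature_matrix(study2)
  key <- function(m) {
    long <- data.frame(
      rt1 = round(rep(m$features$centroid_rt1, ncol(m$A)), 6),
      mz = rep(m$features$consensus_mz, ncol(m$A)),
      sample = rep(m$samples$sample_id, each = nrow(m$A)),
      A = round(as.vector(m$A), 9))
    long <- long[long$A > 0, ]
    long[order(long$rt1, long$mz, long$sample), ]
  }
  k1 <- key(m1); k2 <- key(m2)
  rownames(k1) <- rownames(k2) <- NULL
  expect_equal(k1, k2)
})

test_that("single-sample studies give unit prevalence everywhere", {
  study <- simulate_study(small_config(n_background_voc = 20, seed = 2))
  study$samples <- study$samples[1]
  study$manifest <- study$manifest[1, ]
  mat <- build_feature_matrix(study)
  expect_true(all(mat$features$prevalence == 1.0))
})
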