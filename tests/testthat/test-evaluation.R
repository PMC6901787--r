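test_that("P/F ratios and outcome labels pin their boundary behavior", {
  expect_equal(pf_ratio(475, 1.0), 475)
  expect_equal(pf_ratio(70, 0.209), 334.928, tolerance = 1e-4)
  expect_error(pf_ratio(100, 0), "positive")
  ph <- data.frame(pao2 = c(400, 334), fio2 = c(1, 1))
  expect_equal(pf_ratio(ph), c(400, 334))

  expect_true(label_po2t(349.9))     # strictly below threshold
  expect_false(label_po2t(350.0))    # exactly at threshold
  expect_true(label_po2t(334))
  expect_false(label_po2t(350, threshold = 349))
  # monotone non-increasing in pf
  pf <- seq(250, 500, by = 5)
  expect_true(all(diff(as.integer(label_po2t(pf))) <= 0))
})

test_that("the empirical ROC curve is consistent with pairwise counting", {
  r <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1.0)
  r0 <- roc_curve(rep(1, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(r0$auc, 0.5)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  set.seed(44)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    scores <- sample(0:6, n, replace = TRUE) + round(runif(1), 2)
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, auc_brute(scores[labels], scores[!labels]),
                 tolerance = 1e-12)
    expect_equal(r$auc, mann_whitney_auc(scores[labels], scores[!labels]),
                 tolerance = 1e-12)
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  }
})

test_that("the ROC AUC agrees with an independent library implementation", {
  set.seed(45)
  scores <- rnorm(60)
  labels <- runif(60) < 0.4
  r <- roc_curve(scores, labels)
  ref <- pROC::auc(pROC::roc(response = labels, predictor = scores,
                             direction = "<", quiet = TRUE))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("subject-level bootstrap intervals are deterministic and calibrated", {
  set.seed(46)
  subjects <- rep(sprintf("s%02d", 1:12), each = 6)
  labels <- rep(c(TRUE, FALSE), each = 36)
  sep <- ifelse(labels, 1, 0) + rnorm(72, 0, 1e-3)
  ci <- bootstrap_auc_ci(sep, labels, subjects, n_boot = 300, seed = 7)
  expect_gt(ci[["low"]], 0.99)
  expect_identical(ci, bootstrap_auc_ci(sep, labels, subjects,
                                        n_boot = 300, seed = 7))

  # null scores: interval covers 0.5 in most replicate checks
  hits <- 0
  for (k in 1:20) {
    set.seed(100 + k)
    null_scores <- rnorm(72)
    ci <- bootstrap_auc_ci(null_scores, labels, subjects, n_boot = 200,
                           seed = k)
    if (ci[["low"]] <= 0.5 && ci[["high"]] >= 0.5) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("elevation testing flags shifted timepoints after correction", {
  subjects <- sprintf("s%02d", 1:10)
  times <- c(-24, -12, 0, 12, 24, 36, 48, 60, 72)
  base <- expand.grid(subject_id = subjects, time_h = times,
                      stringsAsFactors = FALSE)
  set.seed(50)
  base$q <- rnorm(nrow(base), 1, 0.1)

  # no shift: nothing significant
  none <- elevation_test(base)
  expect_false(any(none$significant))
  expect_identical(none$time_h, times[times > 0])
  # Bonferroni arithmetic: corrected p is raw p times the number of timepoints
  expect_equal(none$p_adj, pmin(none$p_raw * 6, 1))

  # uniform large shift at every exposure timepoint: everything significant
  big <- base
  big$q[big$time_h > 0] <- big$q[big$time_h > 0] + 100
  expect_true(all(elevation_test(big)$significant))

  # shift from 24 h onwards: first significant timepoint is 24 h
  onset <- base
  onset$q[onset$time_h >= 24] <- onset$q[onset$time_h >= 24] + 100
  flags <- elevation_test(onset)
  expect_identical(min(flags$time_h[flags$significant]), 24)

  expect_error(elevation_test(base[base$subject_id == "s01", ]),
               "fewer than 2 paired subjects")
})

test_that("latency is the gap between score elevation and P/F crossing", {
  elev <- data.frame(time_h = c(12, 24, 36), significant = c(FALSE, TRUE, TRUE))
  physio <- expand.grid(subject_id = sprintf("s%d", 1:4),
                        time_h = c(12, 24, 36, 48, 60, 72))
  physio$fio2 <- 1
  physio$pao2 <- ifelse(physio$time_h >= 60, 334, 420)
  lat <- latency(elev, physio)
  expect_equal(lat$first_bs_elevation_h, 24)
  expect_equal(lat$first_pf_below_h, 60)
  expect_equal(lat$latency_h, 36)
  expect_output(print(lat), "latency: 36 h")

  # P/F never crosses: latency undefined
  physio$pao2 <- 450
  lat2 <- latency(elev, physio)
  expect_true(is.na(lat2$first_pf_below_h) && is.na(lat2$latency_h))
  expect_output(print(lat2), "not reached")

  # crossing and elevation at the same timepoint: zero latency
  physio$pao2 <- ifelse(physio$time_h >= 24, 300, 450)
  expect_equal(latency(elev, physio)$latency_h, 0)
})

test_that("per-timepoint group tests apply the Bonferroni factor", {
  set.seed(60)
  df <- expand.grid(subject_id = sprintf("s%02d", 1:12),
                    time_h = c(12, 24, 36), stringsAsFactors = FALSE)
  df$group <- rep(c("air", "oxygen"), each = 6)[match(df$subject_id,
                                                      sprintf("s%02d", 1:12))]
  df$pf <- rnorm(nrow(df), 450, 5)
  same <- group_timepoint_tests(df, "pf")
  expect_false(any(same$significant))
  expect_equal(same$p_adj, pmin(same$p_raw * nrow(same), 1))

  df$pf[df$group == "oxygen"] <- df$pf[df$group == "oxygen"] - 300
  apart <- group_timepoint_tests(df, "pf")
  expect_true(all(apart$significant))

  df2 <- df[!(df$group == "oxygen" & df$time_h == 36), ]
  expect_warning(part <- group_timepoint_tests(df2, "pf"), "36")
  expect_identical(part$time_h, c(12, 24))
})
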