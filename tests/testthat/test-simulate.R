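test_that("the default study has the designed longitudinal structure", {
  study <- default_sim <- simulate_study(sim_config(n_background_voc = 30))
  m <- study$manifest
  expect_identical(length(unique(m$subject_id)), 22L)
  expect_identical(nrow(m), 198L)
  expect_identical(length(unique(m$subject_id[m$group == "air"])), 12L)
  expect_identical(length(unique(m$subject_id[m$group == "oxygen"])), 10L)
  expect_true(all(table(m$subject_id) == 9L))
  expect_setequal(unique(m$time_h), c(-24, -12, 0, 12, 24, 36, 48, 60, 72))
  expect_true(all((m$time_h <= 0) == (m$phase == "baseline")))
  expect_true(all(m$internal_standard_area > 0))
  # every sample carries the internal-standard peak
  for (s in study$samples[1:9]) {
    expect_true(any(s$peaks$mz == study$config$is_mz &
                      abs(s$peaks$rt1 - study$config$is_rt1) <= 5))
  }
})

test_that("identical seeds reproduce the study; different seeds do not", {
  cfg <- small_config(seed = 5)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a, b)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(a, d1); write_study(b, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(unname(tools::md5sum(file.path(d1, files))),
                   unname(tools::md5sum(file.path(d2, files))))
  c2 <- simulate_study(small_config(seed = 6))
  expect_false(identical(a$samples[[1]]$peaks$area, c2$samples[[1]]$peaks$area))
})

test_that("per-sample peak generation follows its stated noise model", {
  cfg <- sim_config(n_background_voc = 0L, n_planted_markers = 1L,
                    dropout_prob = 0)
  set.seed(1)
  state <- list(catalog = data.frame(voc_id = "MK01", rt1 = 300, rt2 = 1.1,
                                     mz = 78L, log_mean = 10, is_marker = TRUE,
                                     is_contaminant = FALSE),
                group = "air")
  sim <- simulate_sample_peaks(state, 0, cfg)
  expect_identical(nrow(sim$peaks), 2L)       # marker + internal standard

  # degenerate jitter: retention times equal the true coordinates
  cfg0 <- sim_config(rt1_jitter_sd = 0, rt2_jitter_sd = 0, dropout_prob = 0)
  sim0 <- simulate_sample_peaks(state, 0, cfg0)
  expect_identical(sim0$peaks$rt1[1], 300)
  expect_identical(sim0$peaks$rt2[1], 1.1)

  # Monte-Carlo: realized rt1 jitter SD within 15% of the configured SD
  set.seed(2)
  draws <- replicate(1000, simulate_sample_peaks(state, 0, cfg)$peaks$rt1[1])
  expect_lt(abs(sd(draws) - cfg$rt1_jitter_sd) / cfg$rt1_jitter_sd, 0.15)
})

test_that("oxygen-group physiology follows the planted P/F trajectory", {
  cfg <- sim_config(pf_noise_sd = 0)
  set.seed(1)
  oxy <- simulate_physiology(cfg, "oxygen")
  pf <- pf_ratio(oxy)
  expect_equal(pf[oxy$time_h == 60], 334)
  expect_equal(pf[oxy$time_h == 72], 300)
  expect_true(all(pf[oxy$time_h <= 0] == cfg$pf_air_mean))
  # first exposure time with mean P/F under 350 mmHg is 60 h on the noiseless path
  expo <- oxy[oxy$time_h > 0, ]
  expect_equal(min(expo$time_h[pf_ratio(expo) < 350]), 60)
  air <- simulate_physiology(cfg, "air")
  expect_true(all(pf_ratio(air) == cfg$pf_air_mean))
})

test_that("planted markers are separated and recoverable from true abundances", {
  study <- simulate_study(sim_config(n_background_voc = 30))
  tm <- study$truth$markers
  for (i in seq_len(nrow(tm) - 1)) {
    for (j in seq(i + 1, nrow(tm))) {
      expect_true(abs(tm$rt1[i] - tm$rt1[j]) > 10 ||
                    abs(tm$rt2[i] - tm$rt2[j]) > 0.2)
    }
  }
  # oracle AUC on latent abundances: baseline vs exposure within oxygen group
  ab <- study$truth$abundance
  oxy <- ab[ab$group == "oxygen", ]
  aucs <- vapply(tm$voc_id, function(v) {
    x <- oxy[oxy$voc_id == v, ]
    auc <- mann_whitney_auc(x$true_area[x$time_h > 0], x$true_area[x$time_h <= 0])
    max(auc, 1 - auc)
  }, numeric(1))
  expect_gt(mean(aucs), 0.9)
})

test_that("invalid simulator configurations name the offending field", {
  expect_error(sim_config(n_air = 0), "n_air")
  expect_error(sim_config(effect_onset_h = 30), "effect_onset_h")
  expect_error(sim_config(effect_multiplier = 0), "effect_multiplier")
  expect_error(sim_config(rt1_jitter_sd = 3), "rt1_jitter_sd")
  expect_error(sim_config(rt2_jitter_sd = 0.06), "rt2_jitter_sd")
  expect_error(sim_config(unknown_field = 1), "unused argument")
})
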