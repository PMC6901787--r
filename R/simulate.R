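# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable string hash (polynomial, mod 2^31 - 1) for per-subject RNG substreams:
# subject data are reproducible independently of generation order.
.stable_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Configuration for the longitudinal exposure-study simulator
#'
#' Defines the study conditions the simulator emulates: two treatment groups
#' (air, `n = 12`; oxygen, `n = 10`), three baseline breath samples at -24,
#' -12 and 0 h followed by six exposure samples every 12 h up to 72 h, about
#' 700 background VOC peaks per sample plus a spiked internal-standard
#' (bromofluorobenzene) peak, six planted marker compounds whose abundance
#' drops in the oxygen group from 24 h of exposure onwards, paired
#' breathing-circuit background samples, and arterial-blood-gas trajectories
#' in which the oxygen group's mean P/F ratio declines piecewise-linearly to
#' 334 mmHg at 60 h and 300 mmHg at 72 h while the air group stays near
#' 450 mmHg.
#'
#' @param n_air,n_oxygen Subjects per group.
#' @param baseline_times_h,exposure_times_h Collection times (hours relative
#'   to exposure start); baseline times must be `<= 0`.
#' @param n_background_voc Background VOC species per subject's breath.
#' @param rt1_range,rt2_range True retention-time ranges (seconds).
#' @param rt1_jitter_sd,rt2_jitter_sd Per-observation retention jitter SDs
#'   (seconds); each must stay strictly below half the corresponding matching
#'   tolerance (5 s / 0.1 s) so jitter cannot defeat alignment by itself.
#' @param abundance_log_mean,abundance_log_sd Lognormal parameters of
#'   per-sample peak areas around each VOC's own level.
#' @param voc_log_mean_sd Between-VOC spread of log mean abundance.
#' @param snr_log_mean,snr_log_sd Lognormal signal-to-noise parameters shared
#'   by every VOC (planted markers included, so that under a null effect
#'   planted and background species are statistically indistinguishable); the
#'   defaults straddle the 400 acceptance threshold, so a realistic minority
#'   of peaks is lost to the S/N filter.
#' @param n_planted_markers Number of planted marker compounds.
#' @param marker_log_mean Log mean area of planted markers.
#' @param effect_onset_h Exposure time (h) at which the oxygen-group marker
#'   shift begins; must lie on the exposure grid.
#' @param effect_multiplier Multiplier applied to oxygen-group marker
#'   abundance at times `>= effect_onset_h` (for `effect_direction = -1`;
#'   its reciprocal for `+1`). `1.0` disables the effect (null studies).
#' @param effect_direction `-1` (abundance decreases under oxygen, the
#'   default, matching an all-negative-sign panel) or `+1`.
#' @param dropout_prob Probability that a VOC is missing from a given sample.
#' @param contaminant_frac Fraction of background VOCs that are
#'   room/circuit contaminants, hence also present in background samples.
#' @param contaminant_attenuation Abundance multiplier of contaminants in the
#'   circuit background relative to breath.
#' @param is_area_nominal,is_area_cv Internal-standard nominal area and
#'   multiplicative (lognormal) coefficient of variation.
#' @param is_rt1,is_rt2,is_mz Internal-standard retention coordinates and
#'   quant m/z.
#' @param mz_range Integer quant m/z range for simulated VOCs.
#' @param pf_air_mean Air-group mean P/F ratio (mmHg).
#' @param pf_oxygen_path `data.frame(time_h, pf)` anchoring the oxygen-group
#'   mean P/F trajectory; linearly interpolated, constant at the first anchor
#'   for baseline times.
#' @param pf_noise_sd Per-measurement P/F noise SD (mmHg).
#' @param seed Master seed; per-subject substreams are derived from it by
#'   stable hashing of the subject id.
#' @return A `sim_config` object (validated list).
#' @seealso [simulate_study()]
#' @export
sim_config <- function(n_air = 12L, n_oxygen = 10L,
                       baseline_times_h = c(-24, -12, 0),
                       exposure_times_h = c(12, 24, 36, 48, 60, 72),
                       n_background_voc = 700L,
                       rt1_range = c(100, 900), rt2_range = c(0.5, 2),
                       rt1_jitter_sd = 1.0, rt2_jitter_sd = 0.02,
                       abundance_log_mean = 10, abundance_log_sd = 0.4,
                       voc_log_mean_sd = 1.0,
                       snr_log_mean = 6.9, snr_log_sd = 0.9,
                       n_planted_markers = 6L, marker_log_mean = 12.4,
                       effect_onset_h = 24, effect_multiplier = 0.25,
                       effect_direction = -1,
                       dropout_prob = 0.05,
                       contaminant_frac = 0.10, contaminant_attenuation = 0.5,
                       is_area_nominal = 5e5, is_area_cv = 0.10,
                       is_rt1 = 400, is_rt2 = 1.0, is_mz = 95L,
                       mz_range = c(30L, 250L),
                       pf_air_mean = 450,
                       pf_oxygen_path = data.frame(time_h = c(0, 60, 72),
                                                   pf = c(450, 334, 300)),
                       pf_noise_sd = 10,
                       seed = 101L) {
  cfg <- as.list(environment())
  fail <- function(field, msg) {
    stop(sprintf("sim_config: invalid '%s': %s", field, msg), call. = FALSE)
  }
  if (n_air < 1) fail("n_air", "group sizes must be >= 1")
  if (n_oxygen < 1) fail("n_oxygen", "group sizes must be >= 1")
  if (any(baseline_times_h > 0)) fail("baseline_times_h", "must be <= 0")
  if (any(exposure_times_h <= 0)) fail("exposure_times_h", "must be > 0")
  if (!effect_onset_h %in% exposure_times_h) {
    fail("effect_onset_h", "must lie on the exposure time grid")
  }
  if (effect_multiplier <= 0) fail("effect_multiplier", "must be positive")
  if (!effect_direction %in% c(-1, 1)) fail("effect_direction", "must be -1 or +1")
  if (rt1_jitter_sd < 0 || rt1_jitter_sd >= 2.5) {
    fail("rt1_jitter_sd", "must be in [0, 2.5): strictly below half the 5 s tolerance")
  }
  if (rt2_jitter_sd < 0 || rt2_jitter_sd >= 0.05) {
    fail("rt2_jitter_sd", "must be in [0, 0.05): strictly below half the 0.1 s tolerance")
  }
  if (dropout_prob < 0 || dropout_prob >= 1) fail("dropout_prob", "must be in [0, 1)")
  if (contaminant_frac < 0 || contaminant_frac > 1) {
    fail("contaminant_frac", "must be in [0, 1]")
  }
  if (is_area_nominal <= 0) fail("is_area_nominal", "must be positive")
  if (n_background_voc < 0) fail("n_background_voc", "must be >= 0")
  if (n_planted_markers < 0) fail("n_planted_markers", "must be >= 0")
  if (pf_noise_sd < 0) fail("pf_noise_sd", "must be >= 0")
  if (!is.data.frame(pf_oxygen_path) ||
      !all(c("time_h", "pf") %in% names(pf_oxygen_path))) {
    fail("pf_oxygen_path", "must be a data.frame with columns time_h, pf")
  }
  structure(cfg, class = "sim_config")
}

# Group mean P/F trajectory: air flat; oxygen piecewise linear between anchors,
# clamped at the first anchor for baseline times.
.pf_target <- function(config, group, time_h) {
  if (group == "air") return(rep(config$pf_air_mean, length(time_h)))
  path <- config$pf_oxygen_path[order(config$pf_oxygen_path$time_h), ]
  stats::approx(path$time_h, path$pf, xout = time_h, rule = 2)$y
}

# VOC catalog for one study: true retention coordinates, quant m/z and log
# abundance level per species, plus planted-marker metadata. Drawn under the
# master seed so that every subject shares one catalog.
.build_catalog <- function(config) {
  n_bg <- config$n_background_voc
  n_mk <- config$n_planted_markers
  catalog <- data.frame(
    voc_id = character(0), rt1 = numeric(0), rt2 = numeric(0),
    mz = integer(0), log_mean = numeric(0),
    is_marker = logical(0), is_contaminant = logical(0))
  if (n_bg > 0) {
    catalog <- data.frame(
      voc_id = sprintf("BG%04d", seq_len(n_bg)),
      rt1 = stats::runif(n_bg, config$rt1_range[1], config$rt1_range[2]),
      rt2 = stats::runif(n_bg, config$rt2_range[1], config$rt2_range[2]),
      mz = sample(seq(config$mz_range[1], config$mz_range[2]), n_bg, replace = TRUE),
      log_mean = stats::rnorm(n_bg, config$abundance_log_mean, config$voc_log_mean_sd),
      is_marker = FALSE,
      is_contaminant = FALSE)
    n_cont <- round(config$contaminant_frac * n_bg)
    catalog$is_contaminant[sample.int(n_bg, n_cont)] <- TRUE
  }
  if (n_mk > 0) {
    # Rejection-sample marker coordinates so planted markers are pairwise
    # separated by more than twice the matching tolerance in at least one
    # retention dimension, with distinct quant m/z.
    mk_rt1 <- numeric(0); mk_rt2 <- numeric(0); mk_mz <- integer(0)
    guard <- 0L
    while (length(mk_rt1) < n_mk) {
      guard <- guard + 1L
      if (guard > 10000L) stop("could not place separated markers", call. = FALSE)
      r1 <- stats::runif(1, config$rt1_range[1], config$rt1_range[2])
      r2 <- stats::runif(1, config$rt2_range[1], config$rt2_range[2])
      mzc <- sample(seq(config$mz_range[1], config$mz_range[2]), 1L)
      sep <- !length(mk_rt1) ||
        all(abs(mk_rt1 - r1) > 10 | abs(mk_rt2 - r2) > 0.2)
      if (sep && !mzc %in% mk_mz) {
        mk_rt1 <- c(mk_rt1, r1); mk_rt2 <- c(mk_rt2, r2); mk_mz <- c(mk_mz, mzc)
      }
    }
    markers <- data.frame(
      voc_id = sprintf("MK%02d", seq_len(n_mk)),
      rt1 = mk_rt1, rt2 = mk_rt2, mz = mk_mz,
      log_mean = config$marker_log_mean + stats::rnorm(n_mk, 0, 0.3),
      is_marker = TRUE,
      is_contaminant = FALSE)
    catalog <- rbind(catalog, markers)
  }
  catalog
}

#' Simulate the peaks of one breath sample
#'
#' Draws one peak table from a subject state: each catalogued VOC is emitted
#' with independent lognormal abundance, Gaussian retention jitter and
#' lognormal signal-to-noise, subject to a per-sample dropout probability; a
#' spiked internal-standard peak is always present. For oxygen-group subjects
#' at times at or past the effect onset, planted-marker abundance is shifted
#' by the configured effect multiplier.
#'
#' Uses the current RNG state; callers wanting reproducibility seed the RNG
#' first (as [simulate_study()] does per subject).
#'
#' @param state Subject state: `list(catalog, group)` where `catalog` is the
#'   VOC catalog (as built inside [simulate_study()]) and `group` is `"air"`
#'   or `"oxygen"`.
#' @param time_h Collection time (hours relative to exposure start).
#' @param config A [sim_config()].
#' @return A list: `peaks` (peak table including the internal-standard peak),
#'   `background` (paired circuit-background peak table),
#'   `internal_standard_area`, and `true_abundance` (per-VOC latent areas
#'   before dropout/detection, named by `voc_id`).
#' @export
simulate_sample_peaks <- function(state, time_h, config) {
  cat_df <- state$catalog
  n <- nrow(cat_df)
  shift <- state$group == "oxygen" & cat_df$is_marker & time_h >= config$effect_onset_h
  mult <- if (config$effect_direction < 0) config$effect_multiplier
          else 1 / config$effect_multiplier
  mu <- cat_df$log_mean + ifelse(shift, log(mult), 0)
  true_area <- stats::rlnorm(n, mu, config$abundance_log_sd)
  names(true_area) <- cat_df$voc_id
  detected <- stats::runif(n) >= config$dropout_prob
  rt1 <- cat_df$rt1 + stats::rnorm(n, 0, config$rt1_jitter_sd)
  rt2 <- pmax(cat_df$rt2 + stats::rnorm(n, 0, config$rt2_jitter_sd), 1e-6)
  snr <- stats::rlnorm(n, config$snr_log_mean, config$snr_log_sd)
  is_area <- stats::rlnorm(1, log(config$is_area_nominal), config$is_area_cv)
  is_snr <- stats::rlnorm(1, config$snr_log_mean, config$snr_log_sd)
  peaks <- data.frame(
    row.names = NULL,
    rt1 = c(rt1[detected], config$is_rt1),
    rt2 = c(rt2[detected], config$is_rt2),
    mz = as.integer(c(cat_df$mz[detected], config$is_mz)),
    area = c(true_area[detected], is_area),
    snr = c(snr[detected], is_snr))

  # Paired breathing-circuit sample: contaminant VOCs at attenuated abundance.
  cont <- which(cat_df$is_contaminant)
  ncb <- length(cont)
  if (ncb) {
    bg_area <- stats::rlnorm(ncb, cat_df$log_mean[cont] +
                               log(config$contaminant_attenuation),
                             config$abundance_log_sd)
    bg_keep <- stats::runif(ncb) >= config$dropout_prob
    background <- data.frame(
      row.names = NULL,
      rt1 = (cat_df$rt1[cont] + stats::rnorm(ncb, 0, config$rt1_jitter_sd))[bg_keep],
      rt2 = pmax(cat_df$rt2[cont] + stats::rnorm(ncb, 0, config$rt2_jitter_sd),
                 1e-6)[bg_keep],
      mz = as.integer(cat_df$mz[cont][bg_keep]),
      area = bg_area[bg_keep],
      snr = stats::rlnorm(ncb, config$snr_log_mean, config$snr_log_sd)[bg_keep])
  } else {
    background <- peak_table()
  }
  list(peaks = peaks, background = background,
       internal_standard_area = is_area, true_abundance = true_area)
}

#' Simulate per-timepoint physiology for one subject
#'
#' Arterial blood gases are drawn after a 100% oxygen pre-breathe, so FiO2 is
#' recorded as 1.0 and PaO2 directly carries the target P/F ratio plus noise.
#' The air group is stationary around `pf_air_mean`; the oxygen group follows
#' the configured declining trajectory. PaCO2, pH, heart rate and respiratory
#' rate receive group-typical levels (mild hypercapnia, late acidaemia and
#' relative bradycardia under oxygen) with Gaussian noise.
#'
#' Uses the current RNG state (see [simulate_sample_peaks()]).
#'
#' @param config A [sim_config()].
#' @param group `"air"` or `"oxygen"`.
#' @param subject_id Subject label recorded on each row.
#' @return A physiology `data.frame` (see [read_physiology()]) with one row
#'   per configured collection time.
#' @export
simulate_physiology <- function(config, group, subject_id = "s01") {
  times <- c(config$baseline_times_h, config$exposure_times_h)
  n <- length(times)
  pf <- .pf_target(config, group, times) + stats::rnorm(n, 0, config$pf_noise_sd)
  oxy_on <- group == "oxygen" & times > 0
  paco2 <- ifelse(oxy_on & times >= 12, 48, 40) + stats::rnorm(n, 0, 2)
  ph <- ifelse(oxy_on, 7.45 - pmax(times - 36, 0) / 36 * 0.10, 7.45) +
    stats::rnorm(n, 0, 0.02)
  hr <- ifelse(group == "oxygen" & times > 0, 85, 95) + stats::rnorm(n, 0, 8)
  rr <- 25 + stats::rnorm(n, 0, 3)
  data.frame(subject_id = subject_id, time_h = times,
             pao2 = pmax(pf, 1), fio2 = 1.0, paco2 = paco2, ph = ph,
             hr = pmax(hr, 30), rr = pmax(rr, 5))
}

#' Simulate a complete longitudinal breath study
#'
#' Generates a full synthetic study under the configured conditions: every
#' subject contributes one breath sample (peak table, paired circuit
#' background, internal-standard area) at each of the nine collection times,
#' plus per-timepoint physiology, and the ground-truth planted-marker list
#' used by parameter-recovery tests. The study is fully reproducible from
#' `config$seed`; per-subject RNG substreams are derived by stable hashing of
#' the subject id.
#'
#' @param config A [sim_config()].
#' @return A `voc_study` object (see [read_study()]) with components
#'   `manifest`, `samples`, `physio`, `truth` (`$markers`: the planted-marker
#'   catalog; `$abundance`: latent per-sample marker areas) and `config`.
#' @examples
#' \donttest{
#' study <- simulate_study(sim_config(n_air = 2, n_oxygen = 2,
#'                                    n_background_voc = 50))
#' study
#' }
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    catalog <- .build_catalog(config)
    subjects <- data.frame(
      subject_id = c(sprintf("air%02d", seq_len(config$n_air)),
                     sprintf("oxy%02d", seq_len(config$n_oxygen))),
      group = rep(c("air", "oxygen"), c(config$n_air, config$n_oxygen)))
    times <- c(config$baseline_times_h, config$exposure_times_h)
    samples <- list()
    manifest <- list()
    physio <- list()
    truth_ab <- list()
    for (i in seq_len(nrow(subjects))) {
      sid <- subjects$subject_id[i]
      grp <- subjects$group[i]
      set.seed((as.numeric(config$seed) + .stable_hash(sid)) %% 2147483647)
      state <- list(catalog = catalog, group = grp)
      for (t in times) {
        sim <- simulate_sample_peaks(state, t, config)
        key <- sprintf("%s_%s%03d", sid, if (t < 0) "m" else "p", abs(t))
        samples[[key]] <- list(
          subject_id = sid, group = grp,
          phase = if (t <= 0) "baseline" else "exposure",
          time_h = t, peaks = sim$peaks, background = sim$background,
          internal_standard_area = sim$internal_standard_area)
        manifest[[key]] <- data.frame(
          subject_id = sid, group = grp,
          phase = if (t <= 0) "baseline" else "exposure", time_h = t,
          peaks_file = sprintf("peaks/%s.csv", key),
          background_file = sprintf("peaks/%s_bg.csv", key),
          internal_standard_area = sim$internal_standard_area)
        mk <- catalog$is_marker
        if (any(mk)) {
          truth_ab[[key]] <- data.frame(
            subject_id = sid, group = grp, time_h = t,
            voc_id = catalog$voc_id[mk],
            true_area = unname(sim$true_abundance[catalog$voc_id[mk]]))
        }
      }
      physio[[sid]] <- simulate_physiology(config, grp, sid)
    }
    truth <- list(
      markers = data.frame(
        voc_id = catalog$voc_id[catalog$is_marker],
        rt1 = catalog$rt1[catalog$is_marker],
        rt2 = catalog$rt2[catalog$is_marker],
        mz = catalog$mz[catalog$is_marker],
        log_mean = catalog$log_mean[catalog$is_marker],
        onset_h = config$effect_onset_h,
        effect_multiplier = config$effect_multiplier,
        direction = config$effect_direction),
      abundance = if (length(truth_ab)) {
        do.call(rbind, c(truth_ab, list(make.row.names = FALSE)))
      })
    structure(list(manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE))),
                   samples = samples,
                   physio = do.call(rbind, c(physio, list(make.row.names = FALSE))),
                   truth = truth, config = config),
              class = "voc_study")
  })
}
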