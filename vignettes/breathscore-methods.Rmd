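---
title: "Methods: weighted digital analysis of exhaled VOC panels"
author: "breathscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted digital analysis of exhaled VOC panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(breathscore)
```

## Scope and data model

`breathscore` analyses longitudinal breath-volatilomics exposure studies. The
unit of observation is a *breath sample*: one GC×GC-TOF-MS peak table (first-
and second-dimension retention times in seconds, quant-ion m/z, integrated
area, signal-to-noise ratio) collected from one subject at one timepoint,
paired with a breathing-circuit background sample and a spiked
internal-standard (2 ppm bromofluorobenzene) peak. A study follows two
treatment groups — air controls and hyperoxia-exposed subjects — through three
baseline samples (−24, −12, 0 h) and six exposure samples (12…72 h, 12-h
spacing), with arterial blood gases and vital signs recorded at the same
times. The physiological outcome is the P/F ratio PaO₂/FiO₂; values below
350 mmHg mark mild hypoxemia, the operational pulmonary-oxygen-toxicity
endpoint, chosen above the 300 mmHg ARDS criterion so that the outcome
precedes frank respiratory failure.

The pipeline starts at vendor-exported peak tables; instrument control,
feature detection, spectral deconvolution and library identification are out
of scope, and compound names are labels only.

## Feature alignment and normalization

Two peaks are treated as the same VOC species when their retention times agree
within 5 s (first dimension) and 0.1 s (second dimension) and their quant m/z
is identical. Both tolerances are read inclusively ("within 5 s" = ≤ 5 s); m/z
matching can be disabled. Peaks below signal-to-noise 400 are discarded, again
inclusively (a peak exactly at 400 is kept, reading "threshold" as the minimum
acceptable value).

Alignment across samples is a deterministic greedy pass rather than a
chromatogram-warping algorithm: all surviving peaks are pooled and visited in
order of decreasing area (ties: increasing RT1, RT2, then sample order); each
peak joins the earliest-created cluster whose running-mean centroid it matches
and that lacks a member from its sample, else it seeds a new cluster. Largest
peaks anchor the clusters, so centroid drift is dominated by well-measured
peaks; the unit tests verify the greedy pass against a naive independent
re-derivation and check that assignments respect the tolerance rule and the
one-member-per-sample constraint. Clustering is performed globally across all
subjects: aligning per animal first and bridging across animals afterwards
would need a second, unspecified matching step, and the global pass is the
simplest rule consistent with per-animal alignment.

Whether circuit-background abundances should be subtracted or only inspected
is genuinely open; the package defaults to alveolar-gradient-style subtraction
(breath area minus the nearest matching background area, floored at zero,
background-only peaks dropped) and offers `background = "ignore"`. Member
areas are divided by the sample's internal-standard area — a scale-invariant
correction for run-to-run sensitivity drift — and a feature absent from a
sample is recorded as abundance 0, since absence of a peak at fixed detection
settings is informative. Features present in fewer than 10% of samples are
dropped; rare features carry mostly detection noise, and the screening
statistics below are unstable for them.

## Candidate screening

Every feature is scored on two ROC axes with the Mann–Whitney AUC (pair
counting with ties as ½, identical to the trapezoidal area under the empirical
ROC curve):

* `auc_x`: oxygen-group baseline samples (t ≤ 0) versus oxygen-group exposure
  samples (t ≥ 12 h);
* `auc_y`: oxygen-group versus air-group exposure samples.

Both are folded two-sided, `max(AUC, 1 − AUC)`, because a marker may shift in
either direction; the raw direction is retained separately and later becomes
the marker's sign. A feature is a candidate when `auc_x ≥ 0.625` and
`auc_y ≥ 0.60`, thresholds inclusive. AUCs are computed over pooled samples,
ignoring within-animal pairing, since per-feature ROC screening has no natural
pairing construction. Both thresholds are configurable; 0.625/0.60 are the
defaults.

## The WDA model

Weighted digital analysis digitizes each marker by a cutoff crossing and sums
weights of active markers:

$$Q_{ij} = \sum_k w_k \, \mathbf{1}\!\left[\,s_k\,(A_{ijk} - c_k) > 0\,\right].$$

With sign $s_k = -1$ a marker contributes exactly when its normalized
abundance falls strictly below the cutoff — the natural encoding for
compounds depleted under exposure, and the one that makes an all-negative-sign
panel produce a score that *rises* under oxygen. The boundary is strict by
default (`boundary = "inclusive"` is available); the score is bounded by
$[0, \sum_k w_k]$.

Three fitting rules complete the model, each deliberately simple and
deterministic:

* **Cutoffs** maximize the Youden index of the digitized marker over the
  midpoints between adjacent distinct pooled values. Ties are broken toward
  the smaller cutoff, and the ranking uses exact integer cross-multiplied
  counts so that true ties are not perturbed by floating-point noise. If all
  values are equal the common value is returned with a warning.
* **Weights** transform the marker's two-sided C-statistic by
  $w = c/(1-c)$: monotone, equal to 1 for an uninformative marker, and mapping
  C-statistics slightly above 0.5 into the 1.2–1.5 range typical of printed
  panels. `identity` and `youden` ($2c-1$) transforms are selectable.
  Fold-level C-statistics reaching 1.0 under perfect separation are clamped to
  $1 - 1/(2 n_1 n_2)$ so the transform stays finite.
* **Subset selection** is greedy forward selection over the screening
  candidates, maximizing the leave-one-subject-out (LOSO) cross-validated AUC
  of the combined score against the exposure labels (oxygen-group samples at
  t > 0 versus everything else). Whole subjects are held out so repeated
  measures of one animal never straddle a fold; within each fold every
  marker's direction, cutoff and weight are refit on the training subjects
  only. Selection stops when no candidate improves the LOSO AUC by more than
  1e-9, or at `max_markers`; ties are broken by screening `auc_y`, then name.

Because a marker's fold-level fit does not depend on which other markers are
in the panel, the per-fold contributions are precomputed once per candidate,
making selection cost linear in candidates × subjects.

## Evaluation

The fitted score is evaluated sample-per-sample: each breath score is paired
with the concurrent (same subject, same timepoint) P/F measurement for the
outcome ROC, P/F < 350 mmHg read strictly. Per-timepoint inference replaces
repeated-measures ANOVA with the decisions actually consumed downstream:
paired t-tests of subject scores against their own baseline means, and Welch
t-tests between groups, both Bonferroni-corrected across the six exposure
timepoints at two-sided α = 0.05. The latency report is the gap between the
first exposure timepoint with a significant score elevation and the first
timepoint at which the group mean P/F drops below threshold; either side may
be "not reached". Subject-level bootstrap percentile intervals are available
for any AUC.

## The synthetic-study generator

No public per-animal dataset accompanies this design, so the generator is a
first-class, tested module that emulates the study conditions: 12 air and 10
oxygen subjects, 9 samples each, ~700 background VOC species per subject's
breath plus the internal standard, and 6 planted marker compounds whose
abundance in the oxygen group is multiplied by 0.25 from 24 h of exposure
onward (direction −1, matching an all-negative-sign panel). The oxygen group's
mean P/F trajectory declines piecewise-linearly from 450 mmHg at exposure
start through 334 mmHg at 60 h to 300 mmHg at 72 h — so the planted structure
has its first sub-350 group mean at 60 h and a 36-h gap to the 24-h marker
onset — while the air group stays at 450 mmHg. Blood gases are drawn after a
100% oxygen pre-breathe, so FiO₂ is recorded as 1.0.

Distributional choices, made once and recorded in `sim_config()`:

* Per-sample abundances are lognormal around each species' own level
  (`abundance_log_sd = 0.4`, a ~42% coefficient of variation for
  internal-standard-normalized abundances); species levels spread with SD 1.0
  on the log scale. Nothing in the study design identifies these
  distributions; lognormal is an assumption of the generator, not an
  inference.
* One S/N lognormal is shared by **all** species, planted markers included
  (meanlog 6.9, sdlog 0.9: median ≈ 1000 with ~16% of peaks below the 400
  threshold). A marker-specific detection stream would make planted markers
  distinguishable from background species even under a null effect, breaking
  the null calibration, and would make the panel informationally redundant by
  guaranteeing every marker is always detected.
* Retention jitter SDs (1 s / 0.02 s) sit strictly below half the matching
  tolerances, so jitter alone cannot defeat alignment; each species also has
  a 5% per-sample dropout probability.
* 10% of background species are circuit contaminants, present in the paired
  background sample at half abundance; the internal-standard area has 10%
  lognormal jitter so normalization is non-trivial.
* P/F noise is 10 mmHg per measurement — small against clinical
  between-animal variability, deliberately so: the generator plants a group
  *mean* trajectory, and the latency structure is a property of group means
  on a 12-h grid.

All randomness flows from one master seed; per-subject substreams are derived
by stable hashing of the subject id, so a subject's data do not depend on
generation order. Identical seeds reproduce a study byte-for-byte through the
write/read round trip.

What the generator does **not** emulate: chromatographic co-elution physics,
mass spectra, S/N–area correlation (S/N is drawn independently of abundance),
between-animal baseline offsets (samples are exchangeable within a species
and stratum), or drift in retention calibration. Passing tests therefore
demonstrate the pipeline's statistical behavior under a clean longitudinal
design, not robustness to instrument pathology.

## Problem sizes and test design

The unit suites run on reduced studies (typically 6 subjects × 60 species);
replication suites run the full default conditions (22 subjects, ~700
species) across 20 fixed seeds, memoizing each seeded study so several suites
share one computation. The full default pipeline completes in well under a
minute on one CPU, and the oracle-equivalence suites (pair-counting AUC,
naive clustering re-derivation, brute-force score summation, trapezoidal ROC)
run in seconds.

## Known limitations

* **Screening-then-CV optimism.** Candidates are screened on the full data
  and only then cross-validated during forward selection. Features that pass
  the screening gates by chance therefore carry realized label correlation
  that LOSO cannot remove, and greedy maximization compounds it. The null
  calibration suite quantifies this: with the planted effect disabled, the
  per-feature screening AUCs center on 0.5 as they should, but the *fitted*
  panel's LOSO AUC averages well above 0.5 (≈ 0.65–0.7 across its 20 null
  replicates). The LOSO AUC of a fitted panel should be read as an internal
  selection criterion, not an unbiased estimate of out-of-study performance;
  honest external performance requires a held-out study or fold-nested
  screening, both outside the present design.
* **Panel recall under redundancy.** The planted markers share one activation
  pattern (all shift at onset, same direction), so after three or four of
  them the panel is informationally redundant: adding the remaining true
  markers no longer improves the LOSO AUC and the stop rule halts — typically
  before the full planted panel is recovered, while the chance candidates
  above occasionally enter instead. In particular, markers that fire on the
  pre-onset 12-h oxygen samples — which the exposure labels count as positive
  although no planted effect exists yet — are rewarded by the selection
  objective, and in a minority of seeds they make the scored 12-h timepoint
  significantly elevated, so the first flagged elevation moves from the true
  24-h onset to 12 h and the reported latency inflates from 36 h to a spurious
  48 h. Both behaviors are properties of the screen-then-select architecture
  under these study conditions, not of any particular tuning.
* Vendor peak areas are taken as given (no baseline-correction model), and
  incomplete subjects are retained with a warning rather than dropped, since
  screening and scoring are defined per available sample.
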