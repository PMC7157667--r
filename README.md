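# avthresh

Analysis toolkit for 2AFC visual detection experiments with auditory
co-stimulation. The target experiment measures visual contrast thresholds
while an amplitude-modulated sound plays either in phase (IP) or out of
phase (OP) with the visual contrast modulation, at five auditory saliences
(31.5–55.0 dB), next to a no-sound baseline (BL). The package is written
for researchers in multisensory psychophysics who need the complete chain
from trial tables to inference — and for anyone who wants to *stress-test*
that chain against simulated observers with known ground truth.

## What it computes

At its core is a Weibull 2AFC psychometric model fitted by maximum
likelihood (`psychfit()`):

P(x) = γ + (1 − γ − λ)·[1 − exp(−(x/α)^β)],  γ = 0.5 fixed, λ ∈ [0, 0.05]

from which the 75% contrast threshold (full performance scale) and the
slope dP/d(log10 x) at threshold are derived. Around it:

* **Design** — enumeration of the 11-condition × 5-contrast session
  (1100 trials, 10 blocks of 110), practice block, practice-driven
  contrast-range adaptation, CSV trial-table IO with validation
  (`build_design()`, `select_contrast_range()`, `read_trials()`).
* **Effects** — log10-threshold difference measures BL−IP, OP−BL, OP−IP
  per salience; slope and trimmed-RT differences; two-step 2-SD outlier
  exclusion; enhancement/suppression grouping by the mid-salience BL−IP
  sign; alignment of every observer's effects to their *optimal salience*
  (the argmax of BL−IP) with ±1/±2-bin averaging
  (`threshold_differences()`, `exclude_participants()`,
  `align_to_optimal()`).
* **Inference** — one-sample t-tests with Benjamini–Hochberg FDR per
  comparison panel, Hedges' g with CI, one-way repeated-measures ANOVA
  with generalized eta squared and FDR-adjusted paired post-hocs, Pearson
  correlation, and noncentral-F power analysis for within-subject designs
  (`one_sample_t_fdr()`, `rm_anova()`, `rm_anova_power()`).
* **Simulation & diagnostics** — a generative observer model (Gaussian
  salience tuning of the audiovisual effect, Bernoulli trial outcomes,
  log-normal RTs) plus end-to-end orchestration, parameter-recovery
  scoring and a max-statistic selection-bias diagnostic
  (`simulate_cohort()`, `run_pipeline()`, `recovery_experiment()`,
  `selection_bias_experiment()`).

## Worked example

Simulate a cohort of 18 observers at the study's scale (20 trials per
cell, in-phase amplitude 0.135 log10 units, enhancement and suppression
equally likely) and run the full pipeline:

```r
library(avthresh)
cfg <- cohort_config(n_participants = 18, seed = 42)
sim <- simulate_cohort(cfg)
report <- run_pipeline(sim$trials)
print(report)
```

```
Audiovisual threshold pipeline report
  participants: 18 enrolled, 1 excluded, 17 analyzed
  exclusions: S018 (baseline_threshold, z = -2.21)
  groups at 39.5 dB: enhancement 7, suppression 10
  optimal-salience counts (dB):

31.5 35.5 39.5 47.5   55
   1    4    3    4    5
  bl_ip aligned: optimal bin mean = 0.1751, t(16) = 4.715, FDR p = 0.0007011; ANOVA F(2, 32) = 32.58, ges = 0.4085
  op_bl aligned: optimal bin mean = 0.008746, t(16) = 0.2037, FDR p = 0.8412; ANOVA F(2, 32) = 1.231, ges = 0.01952
  op_ip aligned: optimal bin mean = 0.1839, t(16) = 3.128, FDR p = 0.01946; ANOVA F(2, 32) = 7.486, ges = 0.2104
```

Reading this: one observer was excluded for an outlying baseline
threshold; the kept cohort splits into enhancement/suppression groups by
the sign of the mid-salience BL−IP difference; the optimal-salience counts
tabulate where each observer's in-phase benefit peaked. The aligned BL−IP
optimal-bin mean (0.175) exceeds the generating amplitude (0.135): the
optimal bin is chosen as an argmax, so its estimate is inflated by
selection. That inflation is exactly what the bias diagnostic quantifies —

```r
selection_bias_experiment(n_observers = 200, seed = 1)$ratio   # ~1.16 under the null
expected_max_normal(5)                                         # 1.16296, the theory
```

— under the null the aligned optimal-bin mean is about 1.163 × the SD of
the per-salience estimation noise, so aligned values need this diagnostic
(or far larger trial counts) before being read as effect sizes.

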