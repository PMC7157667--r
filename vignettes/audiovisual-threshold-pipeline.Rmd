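---
title: "Methods: audiovisual modulation of visual contrast thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: audiovisual modulation of visual contrast thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avthresh)
```

## The experimental question

In a two-alternative forced-choice (2AFC) detection task, an observer
reports which of two intervals or locations contained a low-contrast visual
target (a Gabor patch whose contrast is modulated over time). On most
trials an amplitude-modulated noise sound is played, either *in phase* (IP)
with the visual contrast modulation or *out of phase* (OP), at one of five
maximum sound levels ("auditory saliences": 31.5, 35.5, 39.5, 47.5 or
55.0 dB); a no-sound *baseline* (BL) completes the 11 auditory conditions.
The scientific questions are whether a temporally coherent sound lowers the
visual contrast threshold, whether that benefit depends on auditory
salience (the *inverse effectiveness* idea predicts larger multisensory
gain for weaker stimuli), and how to handle the large individual
differences in both the direction of the effect and the salience at which
it peaks.

## Design enumeration

`design_config()` encodes the session structure: 5 saliences x 2 phase
conditions + baseline = 11 auditory conditions, each crossed with 5 maximum
visual contrasts drawn from a 7-entry menu (0.08, 0.16, 0.31, 0.63, 1.25,
2.5, 5 percent), 20 trials per cell, for 1100 trials split into 10 blocks
of 110 with exactly two repeats of each of the 55 cells per block
(`build_design()` randomizes the within-block order from a seed). A
30-trial practice block (`build_practice_design()`) probes the lowest,
middle and highest contrast of the medium range; `select_contrast_range()`
then keeps the medium range, or shifts one step harder or easier. The shift
rule is a design choice of this package: the procedure targets roughly 50%
correct at the lowest contrast and 90-100% at the highest, so we shift
harder when accuracy at the lowest practice contrast exceeds 0.65 and
easier when accuracy at the highest falls below 0.85 — symmetric margins
around those targets, one step only, judged per contrast (the natural
reading of a per-level performance target).

## The psychometric model

Performance as a function of maximum contrast $x$ is modelled with a
Weibull psychometric function,

$$P(x) = \gamma + (1 - \gamma - \lambda)\left[1 - e^{-(x/\alpha)^\beta}\right],$$

with guess rate $\gamma = 0.5$ fixed (2AFC), lapse rate
$\lambda \in [0, 0.05]$, scale $\alpha > 0$ and shape
$\beta \in [0.5, 10]$. `psychfit()` maximizes the Bernoulli log-likelihood
of per-contrast correct/total counts. Two conventions needed fixing
because the literature uses both:

* **The "75% threshold" is on the full performance scale** ($P = 0.75$),
  not 75% of the unscaled Weibull; for 2AFC this is the standard reading
  (halfway between chance and perfect), inverted in closed form by
  `weibull_quantile()`.
* **The slope is $dP/d(\log_{10} x)$ at that threshold** — probability per
  decade of contrast — since a slope measure must name its abscissa;
  log-contrast is the axis on which psychometric functions are commonly
  displayed and compared.

Estimation is deterministic maximum likelihood, not Bayesian: it is
reproducible without priors, fast enough for thousands of cell fits, and
testable against an exhaustive grid-search oracle (the test suite requires
the fit to match a 200 x 100 x 6 grid over $\alpha, \beta, \lambda$ within
0.01 nats). Numerically, the likelihood surface for a 5-point dataset can
be *bimodal in* $\beta$ (a shallow and a steep mode) when the observed
proportions are non-monotone, so the optimizer is seeded from five
$\alpha$ values log-spaced across the tested contrasts *plus* the argmax
of a coarse 40 x 25 x 6 grid scan, then polished at tight tolerance.
Contrasts are internally rescaled by their geometric mean so the fit is
invariant to the contrast unit; ties are broken toward the smallest
$\alpha$. Data that are all-correct or all-incorrect are unidentifiable
and return a boundary estimate with `converged = FALSE` and a warning.

## Difference measures, exclusion, grouping, alignment

Thresholds are compared on the $\log_{10}$ scale: for each salience $s$,
`threshold_differences()` computes BL-IP $= \log_{10}\theta_{BL} -
\log_{10}\theta_{IP}(s)$ (positive = the in-phase sound improves the
threshold), OP-BL and OP-IP, with OP-IP composed as (BL-IP) + (OP-BL) so
the algebraic identity holds exactly in floating point. Base 10 is used
because the effect magnitudes this pipeline is designed around (a baseline
mean of -0.352 for sub-1% thresholds, effects of order 0.1) live naturally
on that scale. Slope and reaction-time differences use the same
orientations on the raw scale; RTs are first trimmed one-sidedly, dropping
trials slower than the cell mean + 2 SD (`rt_trim_and_mean()`; fast
outliers are never trimmed, matching the asymmetry of attention lapses).

`exclude_participants()` applies two sequential 2-SD criteria — baseline
log-threshold first, then the BL-IP difference at the grouping salience
(39.5 dB) with statistics recomputed on the survivors. Sequential
recomputation is a choice (the alternative, simultaneous criteria on the
full cohort, differs only when exclusions interact); a second pass can in
principle remove further participants because the group SD shrinks, so
only the "second pass removes no more than the first" relation is
guaranteed and tested.

`classify_groups()` splits observers into *enhancement* (positive
mid-salience BL-IP) and *suppression* groups; an exact zero is assigned to
enhancement with a warning (a zero difference is "no harm", and silent
dropping would bias the group sizes).

`align_to_optimal()` re-indexes each observer's five per-salience values
to the salience with the *maximum* BL-IP difference (ties toward the
lowest salience, warned), averaging the levels one bin away and two bins
away; near an edge a bin may contain a single level. OP-BL and OP-IP (and
slope/RT tables) are aligned by the BL-IP-derived optimum, so all
comparisons share one anchor per observer.

**The alignment is a max-statistic and is biased under the null.** If an
observer's five per-salience estimates were independent zero-mean noise
with SD $\sigma$, the aligned optimal-bin value would average
$\sigma\,E[\max \text{ of } 5\ N(0,1)] \approx 1.163\,\sigma$.
`selection_bias_experiment()` measures exactly this inflation through the
full estimation path (simulate null observers, fit, difference, align),
using the *within-observer* SD across saliences as $\sigma$ so that noise
shared through the common BL fit cancels. The package deliberately ships
the diagnostic rather than a corrected estimator (e.g. split-half
alignment): the published alignment procedure is what the pipeline
implements, and the diagnostic quantifies what the aligned numbers can and
cannot show.

## Inference

`one_sample_t_fdr()` runs two-sided one-sample t-tests per panel level
with Benjamini-Hochberg adjustment *within one comparison panel* (the five
saliences of one group x comparison, or the three aligned bins) — matching
how such panels are presented, rather than pooling all comparisons into a
single family. Effect sizes are Hedges' g, $g = J\,\bar x/s$ with
$J = 1 - 3/(4(n-1)-1)$, and a normal-approximation CI
($SE^2 = 1/n + g^2/(2(n-1))$); a zero-variance sample of exact zeros
reports $t = 0, p = 1$ (no evidence against zero), while zero variance
around a nonzero mean is flagged undefined.

`rm_anova()` is the one-way within-subject decomposition
($SS_{total} = SS_{subjects} + SS_{effect} + SS_{error}$), reporting
$F = MS_{effect}/MS_{error}$ on $(k-1, (k-1)(n-1))$ df and generalized eta
squared $SS_{effect}/(SS_{effect} + SS_{subjects} + SS_{error})$; post-hoc
pairwise *paired* t-tests are BH-adjusted (the conventional reading of an
FDR-adjusted post-hoc on within-subject levels). No sphericity correction
is estimated from the data; the power calculator instead exposes a fixed
nonsphericity $\epsilon$. Degenerate inputs are guarded: zero effect sum
of squares gives $F = 0, p = 1$; zero error with nonzero effect gives
$F = \infty$.

`rm_anova_power()` uses the classical noncentral-F convention
$\lambda = f^2 N m \epsilon/(1-\rho)$ with
$df = ((m-1)\epsilon, (N-1)(m-1)\epsilon)$ — the convention under which
$f = 0.3$, five measurements, $\alpha = 0.05$, $\rho = 0.5$ yields a
required sample of 17 for power 0.85:

```{r power}
rm_anova_power(n = 17, f = 0.3, m = 5)
required_n(f = 0.3, m = 5, power = 0.85)
```

## The synthetic observer model

`cohort_config()` / `simulate_cohort()` generate ground-truthed cohorts.
Each observer has a baseline $\log_{10}$ threshold drawn from
$N(-0.352, 0.188)$ (the distribution this pipeline's exclusion rules are
calibrated for), a uniformly drawn optimal salience bin $s^* \in 1..5$, an
effect direction (+1 enhancement / -1 suppression, enhancement probability
0.5 by default), and an IP amplitude $A_{IP}$ with mean 0.135
$\log_{10}$-threshold units (SD 0.05, truncated at zero — the mean is the
observed aligned effect magnitude; the SD is a modelling choice giving
realistic between-observer spread without sign flips). The condition
thresholds follow

$$\log_{10}\theta(c, s) = \text{baseline} - d\,A_c\,
  e^{-(s - s^*)^2 / (2\sigma_s^2)},$$

Gaussian tuning in salience *bins* (width $\sigma_s = 1$ by default),
because the downstream alignment operates on bins, not dB. The OP
amplitude defaults to zero but is a free parameter: the generator must be
able to produce OP benefit as well as no OP effect. Trial outcomes are
Bernoulli draws from the Weibull model with the generating threshold as
scale ($\beta = 2$, $\lambda = 0.02$); reaction times are log-normal
(median 500 ms, log-SD 0.2) and exist only to exercise the trimming rule.
The Gaussian-tuning law itself is a modelling stand-in — nothing in the
analyses assumes it — and the simulator makes no attempt to model block
fatigue, eye movements or stimulus rendering, so passing recovery tests
certify the *estimation pipeline*, not the biology.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations as
follows, as the package's own balance of Monte-Carlo error against
runtime: parameter-recovery uses 50 replicate cohorts of 18 observers at
20 trials per cell (the design's own cell size); the null selection-bias
experiment uses 800 observers, putting the Monte-Carlo SE of the measured
inflation ratio near 0.04 against the theoretical 1.163; argmax-recovery
checks use 200 trials per cell and amplitudes at or above 0.2, where the
optimum is identifiable. Grid-oracle equivalence for the MLE is asserted
within 0.01 nats; the RM-ANOVA is asserted against `stats::aov` with an
`Error(subject)` stratum at 1e-8 relative.

## Known limitations

* The aligned optimal-bin estimates are selection-biased by construction;
  use `selection_bias_experiment()` to quantify the inflation before
  interpreting aligned nulls.
* The MLE reports no interval estimates for $\alpha, \beta, \lambda$;
  downstream inference operates on derived thresholds across observers,
  where between-subject variance dominates.
* Exact numeric parity with Bayesian psychometric toolboxes is a
  non-goal; conventions (full-scale 75% threshold, bounded lapse, fixed
  guess rate) are documented above and in `?psychfit`.
* `threshold_differences()` requires BL and IP cells; OP comparisons are
  filled only when OP cells are present.
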