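Package: avthresh
Title: Audiovisual Modulation of Visual Contrast Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-alternative forced-choice (2AFC) visual
    psychophysics with auditory co-stimulation. Fits Weibull psychometric
    functions by maximum likelihood with a fixed guess rate and a bounded
    lapse rate, derives 75% contrast thresholds and slopes, and implements a
    complete analysis pipeline for studies of audiovisual phase coherence:
    log-threshold difference measures between baseline, in-phase and
    out-of-phase sound conditions, outlier exclusion, enhancement/suppression
    observer grouping, alignment of effects to each observer's optimal
    auditory salience, one-sample t-tests with false-discovery-rate
    correction, Hedges' g, one-way repeated-measures ANOVA with generalized
    eta squared, and noncentral-F power analysis. A synthetic-observer
    simulator with Gaussian salience tuning provides ground truth for
    parameter-recovery and selection-bias diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
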