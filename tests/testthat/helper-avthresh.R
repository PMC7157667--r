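# Shared fixtures and independent oracles for the test suite.

medium_contrasts <- c(0.16, 0.31, 0.63, 1.25, 2.5)

# Binomial counts drawn from a known Weibull observer at the medium contrasts.
random_weibull_counts <- function(n_per_level = 20L, alpha = 0.6, beta = 2,
                                  lapse = 0.02, contrasts = medium_contrasts) {
  p <- weibull_p(contrasts, alpha, beta, gamma = 0.5, lapse = lapse)
  data.frame(contrast = contrasts,
             n_correct = rbinom(length(contrasts), n_per_level, p),
             n_total = n_per_level)
}

# Exhaustive grid-search oracle for the Weibull MLE: best log-likelihood over
# a 200 x 100 x 6 (alpha x beta x lapse) grid spanning the fit's bounds.
grid_oracle_loglik <- function(contrast, n_correct, n_total,
                               n_alpha = 200L, n_beta = 100L) {
  alphas <- exp(seq(log(min(contrast) / 10), log(max(contrast) * 10),
                    length.out = n_alpha))
  betas <- exp(seq(log(0.5), log(10), length.out = n_beta))
  lapses <- seq(0, 0.05, by = 0.01)
  g <- expand.grid(alpha = alphas, beta = betas, lapse = lapses)
  ll <- numeric(nrow(g))
  for (i in seq_along(contrast)) {
    p <- 0.5 + (0.5 - g$lapse) * (1 - exp(-(contrast[i] / g$alpha)^g$beta))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- ll + n_correct[i] * log(p) + (n_total[i] - n_correct[i]) * log1p(-p)
  }
  max(ll)
}

# Independent RM-ANOVA oracle via stats::aov with an Error(subject) stratum.
aov_oracle <- function(y) {
  n <- nrow(y); k <- ncol(y)
  d <- data.frame(value = as.vector(y),
                  subject = factor(rep(seq_len(n), k)),
                  level = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(value ~ level + Error(subject), data = d)
  s <- summary(fit)
  within <- s[["Error: Within"]][[1]]
  subj <- s[["Error: subject"]][[1]]
  list(ss_effect = within["level", "Sum Sq"],
       ss_error = within["Residuals", "Sum Sq"],
       ss_subjects = subj["Residuals", "Sum Sq"],
       F = within["level", "F value"],
       p = within["level", "Pr(>F)"])
}

# Small simulated cohort: per-participant BL + IP (and optionally OP) fits
# turned into a threshold-difference table. Used by effect/alignment tests.
simulate_blip_cohort <- function(config, seed = 1L) {
  sim <- simulate_cohort(config, design_config(), conditions = c("BL", "IP"))
  fits <- suppressWarnings(fit_cohort(sim$trials))
  list(effects = threshold_differences(fits), truth = sim$truth)
}
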