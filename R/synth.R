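#' Synthetic cohort configuration
#'
#' Parameters of the generative observer model used for recovery and
#' calibration experiments. Each synthetic observer has a baseline
#' log10 contrast threshold drawn from a normal distribution, an optimal
#' auditory salience index (1-5) at which audiovisual modulation is
#' strongest, an effect direction (enhancement or suppression), and
#' in-phase / out-of-phase effect amplitudes on the log10-threshold scale
#' with Gaussian tuning across salience bins.
#'
#' The defaults emulate the cohort this package's analyses are designed for:
#' baseline log10 thresholds with mean -0.352 and SD 0.188, an in-phase
#' amplitude of 0.135 log10 units, enhancement and suppression equally
#' likely, and Gaussian tuning with width one salience bin.
#'
#' @param n_participants cohort size; default 18.
#' @param baseline_mean_log10,baseline_sd_log10 distribution of baseline
#'   log10 thresholds (% contrast); defaults -0.352 and 0.188.
#' @param p_enhancement probability an observer's effect direction is
#'   enhancement (+1) rather than suppression (-1); default 0.5.
#' @param ip_amplitude_mean,ip_amplitude_sd in-phase effect amplitude
#'   distribution (log10-threshold units, truncated at 0);
#'   defaults 0.135 and 0.05.
#' @param op_amplitude_mean,op_amplitude_sd out-of-phase amplitude
#'   distribution; defaults 0 and 0 (no OP effect).
#' @param tuning_width_bins Gaussian tuning width across salience bins.
#' @param lapse lapse rate; default 0.02.
#' @param weibull_shape psychometric shape beta; default 2.
#' @param rt_location_ms,rt_scale log-normal reaction-time model: median RT
#'   in ms and log-scale SD.
#' @param seed integer seed.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_participants = 18L,
                          baseline_mean_log10 = -0.352,
                          baseline_sd_log10 = 0.188,
                          p_enhancement = 0.5,
                          ip_amplitude_mean = 0.135,
                          ip_amplitude_sd = 0.05,
                          op_amplitude_mean = 0,
                          op_amplitude_sd = 0,
                          tuning_width_bins = 1.0,
                          lapse = 0.02,
                          weibull_shape = 2.0,
                          rt_location_ms = 500,
                          rt_scale = 0.2,
                          seed = 1L) {
  if (n_participants < 1L) stop("'n_participants' must be >= 1")
  if (baseline_sd_log10 < 0) stop("'baseline_sd_log10' must be >= 0")
  if (p_enhancement < 0 || p_enhancement > 1)
    stop("'p_enhancement' must be in [0, 1]")
  if (ip_amplitude_mean < 0) stop("'ip_amplitude_mean' must be >= 0")
  if (tuning_width_bins <= 0) stop("'tuning_width_bins' must be > 0")
  if (lapse < 0 || lapse > 0.05) stop("'lapse' must be in [0, 0.05]")
  if (weibull_shape <= 0) stop("'weibull_shape' must be > 0")
  structure(as.list(environment()), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic observer cohort\n")
  cat(sprintf("  n = %d; baseline log10 threshold ~ N(%.3f, %.3f)\n",
              x$n_participants, x$baseline_mean_log10, x$baseline_sd_log10))
  cat(sprintf("  P(enhancement) = %.2f; A_IP ~ %.3f (SD %.3f), A_OP ~ %.3f (SD %.3f)\n",
              x$p_enhancement, x$ip_amplitude_mean, x$ip_amplitude_sd,
              x$op_amplitude_mean, x$op_amplitude_sd))
  cat(sprintf("  tuning width %.2f bins; beta = %.2f, lapse = %.3f\n",
              x$tuning_width_bins, x$weibull_shape, x$lapse))
  invisible(x)
}

#' Draw a cohort of synthetic observers
#'
#' @param config a [cohort_config()].
#' @return A data frame of generative observer parameters, one row per
#'   participant: `baseline_log10_threshold`, `weibull_shape`, `lapse`,
#'   `optimal_salience_index` (1-5), `effect_direction` (+1 enhancement,
#'   -1 suppression), `ip_amplitude`, `op_amplitude`, `tuning_width_bins`,
#'   `rt_location_ms`, `rt_scale`.
#' @export
sample_observers <- function(config = cohort_config()) {
  set.seed(config$seed)
  n <- config$n_participants
  obs <- data.frame(
    participant_id = sprintf("S%03d", seq_len(n)),
    baseline_log10_threshold = stats::rnorm(n, config$baseline_mean_log10,
                                            config$baseline_sd_log10),
    weibull_shape = config$weibull_shape,
    lapse = config$lapse,
    optimal_salience_index = sample.int(5L, n, replace = TRUE),
    effect_direction = ifelse(stats::runif(n) < config$p_enhancement, 1, -1),
    ip_amplitude = pmax(0, stats::rnorm(n, config$ip_amplitude_mean,
                                        config$ip_amplitude_sd)),
    op_amplitude = pmax(0, stats::rnorm(n, config$op_amplitude_mean,
                                        config$op_amplitude_sd)),
    tuning_width_bins = config$tuning_width_bins,
    rt_location_ms = config$rt_location_ms,
    rt_scale = config$rt_scale,
    stringsAsFactors = FALSE
  )
  thr <- 10^obs$baseline_log10_threshold
  if (any(thr <= 0 | thr > 100))
    stop("sampled baseline thresholds fall outside (0, 100]% contrast")
  obs
}

#' Generating contrast threshold of a synthetic observer
#'
#' The generative scale of the observer's psychometric function in a given
#' condition. On the log10 scale, BL equals the baseline; IP and OP are the
#' baseline shifted by `direction * amplitude * exp(-(s - s*)^2 / (2 sigma^2))`
#' where `s` is the salience index, `s*` the observer's optimal salience and
#' `sigma` the tuning width in bins. Positive direction (enhancement) lowers
#' the IP threshold most at the optimal salience.
#'
#' @param observer a one-row data frame (or list) of observer parameters as
#'   produced by [sample_observers()].
#' @param condition `"BL"`, `"IP"` or `"OP"`.
#' @param salience_index salience bin 1-5 (required for IP/OP).
#' @return Threshold in percent contrast.
#' @export
true_threshold <- function(observer, condition, salience_index = NULL) {
  condition <- match.arg(condition, c("BL", "IP", "OP"))
  if (condition == "BL") return(10^observer$baseline_log10_threshold)
  if (is.null(salience_index) || any(!salience_index %in% 1:5))
    stop("'salience_index' must be an integer in 1..5")
  amp <- if (condition == "IP") observer$ip_amplitude else observer$op_amplitude
  tune <- exp(-(salience_index - observer$optimal_salience_index)^2 /
                (2 * observer$tuning_width_bins^2))
  10^(observer$baseline_log10_threshold - observer$effect_direction * amp * tune)
}

#' Simulate Bernoulli trial outcomes for one observer
#'
#' Each planned trial is correct with probability given by the Weibull
#' psychometric function evaluated at the trial's contrast, with scale equal
#' to the observer's generating threshold in that condition and salience,
#' the observer's shape and lapse, and guess rate 0.5. Reaction times are
#' drawn from a log-normal distribution.
#'
#' @param design planned trials from [build_design()].
#' @param observer one row of [sample_observers()].
#' @param seed integer seed.
#' @param salience_levels_db the design's salience levels, used to map
#'   salience in dB to bins 1-5.
#' @return A trial table (see [read_trials()] for the column contract).
#' @export
simulate_trials <- function(design, observer, seed = 1L,
                            salience_levels_db = c(31.5, 35.5, 39.5, 47.5, 55.0)) {
  if (any(design$max_contrast_pct <= 0)) stop("contrasts must be positive")
  set.seed(seed)
  s_idx <- match(design$salience_db, salience_levels_db)
  if (any(is.na(s_idx) & design$condition != "BL"))
    stop("design contains saliences outside 'salience_levels_db'")
  tune <- exp(-(s_idx - observer$optimal_salience_index)^2 /
                (2 * observer$tuning_width_bins^2))
  amp <- ifelse(design$condition == "IP", observer$ip_amplitude,
                ifelse(design$condition == "OP", observer$op_amplitude, 0))
  shift <- ifelse(design$condition == "BL", 0,
                  observer$effect_direction * amp * tune)
  alpha <- 10^(observer$baseline_log10_threshold - shift)
  p <- weibull_p(design$max_contrast_pct, alpha, observer$weibull_shape,
                 gamma = 0.5, lapse = observer$lapse)
  data.frame(
    participant_id = observer$participant_id,
    block = design$block,
    trial_index = design$trial_index,
    condition = design$condition,
    salience_db = design$salience_db,
    max_contrast_pct = design$max_contrast_pct,
    correct = stats::rbinom(nrow(design), 1L, p),
    rt_ms = stats::rlnorm(nrow(design), log(observer$rt_location_ms),
                          observer$rt_scale),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full cohort
#'
#' Draws observers from the generative model, builds one randomized design
#' per participant and simulates all trial outcomes. Per-participant seeds
#' are derived deterministically from the cohort seed.
#'
#' @param config a [cohort_config()].
#' @param design_config a [design_config()].
#' @param conditions optional subset of `c("BL","IP","OP")` to simulate;
#'   `NULL` keeps all.
#' @return A list with `trials` (trial table for the whole cohort) and
#'   `truth` (the generating observer parameters).
#' @export
simulate_cohort <- function(config = cohort_config(),
                            design_config = avthresh::design_config(),
                            conditions = NULL) {
  obs <- sample_observers(config)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * config$n_participants)
  trials <- vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    d <- build_design(design_config, seed = seeds[2L * i - 1L])
    if (!is.null(conditions)) d <- d[d$condition %in% conditions, , drop = FALSE]
    trials[[i]] <- simulate_trials(d, obs[i, ], seed = seeds[2L * i],
                                   salience_levels_db = design_config$salience_levels_db)
  }
  list(trials = do.call(rbind, trials), truth = obs)
}
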