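#' Hedges' g for a one-sample design
#'
#' Standardized mean difference from zero with the small-sample bias
#' correction `J = 1 - 3 / (4(n-1) - 1)` applied to Cohen's d, and a 95%
#' confidence interval from the normal approximation
#' `SE^2 = 1/n + g^2 / (2(n-1))`.
#'
#' @param x numeric vector.
#' @return A list with `g`, `ci_low`, `ci_high`, `J` and `n`; `g` is `NA`
#'   (flagged) when the sample SD is zero with a nonzero mean.
#' @export
hedges_g <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  J <- 1 - 3 / (4 * (n - 1) - 1)
  s <- stats::sd(x)
  if (s == 0) {
    g <- if (mean(x) == 0) 0 else NA_real_
    if (is.na(g))
      return(list(g = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  J = J, n = n, flag = "zero_variance"))
    return(list(g = 0, ci_low = 0, ci_high = 0, J = J, n = n, flag = NA_character_))
  }
  g <- J * mean(x) / s
  se <- sqrt(1 / n + g^2 / (2 * (n - 1)))
  z <- stats::qnorm(0.975)
  list(g = g, ci_low = g - z * se, ci_high = g + z * se, J = J, n = n,
       flag = NA_character_)
}

#' One-sample t-tests with FDR correction across a comparison panel
#'
#' For each column of `values` (one column per salience level or aligned
#' bin), a two-sided one-sample t-test of the mean against zero, with
#' Benjamini-Hochberg adjustment of the p-values across the columns of the
#' panel, a 95% t-based confidence interval of the mean, and Hedges' g with
#' its normal-approximation CI.
#'
#' Columns with zero variance are flagged: a column of exact zeros yields
#' `t = 0, p = 1` (no evidence against zero); a zero-variance column with a
#' nonzero mean yields `NA` statistics.
#'
#' @param values matrix or data frame, participants in rows, panel levels in
#'   columns.
#' @return A data frame with one row per level: `level`, `n`, `estimate`,
#'   `ci_low`, `ci_high`, `t`, `df`, `p_raw`, `p_fdr`, `hedges_g`,
#'   `g_ci_low`, `g_ci_high`, `flag`.
#' @export
one_sample_t_fdr <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("need at least 2 participants")
  levels_ <- colnames(values)
  if (is.null(levels_)) levels_ <- as.character(seq_len(ncol(values)))
  rows <- lapply(seq_len(ncol(values)), function(j) {
    x <- values[, j]; x <- x[!is.na(x)]
    n <- length(x)
    if (stats::sd(x) == 0) {
      zero <- mean(x) == 0
      gg <- hedges_g(x)
      return(data.frame(level = levels_[j], n = n, estimate = mean(x),
                        ci_low = if (zero) 0 else NA_real_,
                        ci_high = if (zero) 0 else NA_real_,
                        t = if (zero) 0 else NA_real_, df = n - 1L,
                        p_raw = if (zero) 1 else NA_real_,
                        hedges_g = gg$g, g_ci_low = gg$ci_low,
                        g_ci_high = gg$ci_high,
                        flag = "zero_variance", stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(x, mu = 0)
    gg <- hedges_g(x)
    data.frame(level = levels_[j], n = n, estimate = unname(tt$estimate),
               ci_low = tt$conf.int[1L], ci_high = tt$conf.int[2L],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, hedges_g = gg$g, g_ci_low = gg$ci_low,
               g_ci_high = gg$ci_high, flag = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p_raw, method = "BH")
  out[, c("level", "n", "estimate", "ci_low", "ci_high", "t", "df",
          "p_raw", "p_fdr", "hedges_g", "g_ci_low", "g_ci_high", "flag")]
}

#' One-way repeated-measures ANOVA with generalized eta squared
#'
#' Standard within-subject decomposition of a complete participants x levels
#' matrix: `SS_total = SS_subjects + SS_effect + SS_error`, `F = MS_effect /
#' MS_error` on `(k - 1, (k - 1)(n - 1))` degrees of freedom, and the
#' generalized effect size `ges = SS_effect / (SS_effect + SS_subjects +
#' SS_error)`. Post-hoc pairwise paired t-tests between levels are
#' Benjamini-Hochberg adjusted.
#'
#' @param values complete numeric matrix or data frame, participants in
#'   rows, within-subject levels in columns.
#' @return An object of class `"rm_anova"`: list with `F`, `df_effect`,
#'   `df_error`, `p`, `ges`, the sums of squares `ss`, and a `posthoc` data
#'   frame.
#' @export
rm_anova <- function(values) {
  y <- as.matrix(values)
  if (any(is.na(y))) stop("missing cells are not supported (no imputation)")
  n <- nrow(y); k <- ncol(y)
  if (n < 2L || k < 2L) stop("need at least 2 participants and 2 levels")
  grand <- mean(y)
  ss_subj <- k * sum((rowMeans(y) - grand)^2)
  ss_eff <- n * sum((colMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_eff
  df_eff <- k - 1L
  df_err <- (k - 1L) * (n - 1L)
  ms_err <- ss_err / df_err
  if (ss_eff <= 0) {
    Fv <- 0; p <- 1
  } else if (ms_err <= .Machine$double.eps * ss_tot) {
    Fv <- Inf; p <- 0
  } else {
    Fv <- (ss_eff / df_eff) / ms_err
    p <- stats::pf(Fv, df_eff, df_err, lower.tail = FALSE)
  }
  ges <- if (ss_eff + ss_subj + ss_err <= 0) 0
         else ss_eff / (ss_eff + ss_subj + ss_err)

  lv <- colnames(y)
  if (is.null(lv)) lv <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2L)
  ph <- lapply(seq_len(ncol(pairs)), function(m) {
    i <- pairs[1L, m]; j <- pairs[2L, m]
    d <- y[, i] - y[, j]
    if (stats::sd(d) == 0) {
      data.frame(level_1 = lv[i], level_2 = lv[j], estimate = mean(d),
                 t = if (mean(d) == 0) 0 else NA_real_, df = n - 1L,
                 p_raw = if (mean(d) == 0) 1 else NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(d, mu = 0)
      data.frame(level_1 = lv[i], level_2 = lv[j],
                 estimate = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p_raw = tt$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  posthoc <- do.call(rbind, ph)
  posthoc$p_fdr <- stats::p.adjust(posthoc$p_raw, method = "BH")

  structure(list(F = Fv, df_effect = df_eff, df_error = df_err, p = p,
                 ges = ges,
                 ss = c(effect = ss_eff, subjects = ss_subj,
                        error = ss_err, total = ss_tot),
                 n = n, k = k, posthoc = posthoc),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, digits = 4, ...) {
  cat(sprintf("One-way repeated-measures ANOVA: F(%d, %d) = %.*g, p = %.*g, ges = %.*g\n",
              x$df_effect, x$df_error, digits, x$F, digits, x$p, digits, x$ges))
  cat("Post-hoc paired t-tests (BH-adjusted):\n")
  print(format(x$posthoc, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Pearson correlation with two-sided test
#'
#' Thin wrapper around [stats::cor.test()] that flags degenerate input
#' (zero variance) instead of erroring.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return A list with `r`, `p`, `n` and `flag`.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                flag = "zero_variance"))
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       flag = NA_character_)
}

#' Power of a one-way repeated-measures ANOVA
#'
#' Classical noncentral-F power: with `m` within-subject measurements,
#' `n` participants, effect size `f`, correlation `rho` between repeated
#' measures and nonsphericity `epsilon`, the main effect is tested on
#' `df1 = (m-1) epsilon` and `df2 = (n-1)(m-1) epsilon` degrees of freedom
#' with noncentrality `lambda = f^2 n m epsilon / (1 - rho)`; power is the
#' probability that a noncentral F with these parameters exceeds the central
#' critical value at level `alpha`.
#'
#' @param n number of participants.
#' @param f Cohen's effect size f (SD of level means / error SD).
#' @param m number of repeated measurements (levels).
#' @param alpha significance level; default 0.05.
#' @param rho assumed correlation between repeated measures; default 0.5.
#' @param epsilon nonsphericity correction in (0, 1]; default 1.
#' @return Power in \[alpha, 1\]. With `f = 0`, exactly `alpha`.
#' @examples
#' rm_anova_power(n = 17, f = 0.3, m = 5)
#' @export
rm_anova_power <- function(n, f, m, alpha = 0.05, rho = 0.5, epsilon = 1) {
  if (f < 0) stop("'f' must be >= 0")
  if (rho < 0 || rho >= 1) stop("'rho' must be in [0, 1)")
  if (epsilon <= 0 || epsilon > 1) stop("'epsilon' must be in (0, 1]")
  if (n < 2L || m < 2L) stop("need n >= 2 and m >= 2")
  df1 <- (m - 1) * epsilon
  df2 <- (n - 1) * (m - 1) * epsilon
  lambda <- f^2 * n * m * epsilon / (1 - rho)
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' @rdname rm_anova_power
#' @param power target power for `required_n`.
#' @param n_max search limit.
#' @return `required_n` returns the smallest `n` achieving the target power.
#' @examples
#' required_n(f = 0.3, m = 5, power = 0.85)
#' @export
required_n <- function(f, m, power = 0.85, alpha = 0.05, rho = 0.5,
                       epsilon = 1, n_max = 10000L) {
  if (f == 0 && power > alpha)
    stop("no finite sample size reaches the target power with f = 0")
  for (n in 2:n_max) {
    if (rm_anova_power(n, f, m, alpha = alpha, rho = rho,
                       epsilon = epsilon) >= power)
      return(n)
  }
  stop(sprintf("no n <= %d reaches power %.2f", n_max, power))
}
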