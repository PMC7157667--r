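#' Weibull psychometric function
#'
#' Probability of a correct response in a forced-choice detection task as a
#' function of stimulus contrast, under the scaled Weibull model
#' \deqn{P(x) = \gamma + (1 - \gamma - \lambda)\,[1 - e^{-(x/\alpha)^\beta}]}
#' where \eqn{\gamma} is the guess rate (0.5 for 2AFC), \eqn{\lambda} the
#' lapse rate, \eqn{\alpha} the scale and \eqn{\beta} the shape.
#'
#' @param contrast stimulus contrast (same units as `alpha`, e.g. percent);
#'   nonnegative, vectorized.
#' @param alpha Weibull scale parameter, > 0.
#' @param beta Weibull shape parameter, > 0.
#' @param gamma guess rate in \[0, 1); 0.5 for 2AFC.
#' @param lapse lapse rate in \[0, 1 - gamma).
#' @return Probability of a correct response, in \[gamma, 1 - lapse\].
#' @examples
#' weibull_p(0.6, alpha = 0.6, beta = 2)          # = 0.5 + 0.5 * (1 - exp(-1))
#' weibull_p(c(0, 100), alpha = 0.6, beta = 2, lapse = 0.02)
#' @export
weibull_p <- function(contrast, alpha, beta, gamma = 0.5, lapse = 0) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) stop("'alpha' must be > 0")
  if (any(!is.finite(beta)) || any(beta <= 0)) stop("'beta' must be > 0")
  if (gamma < 0 || gamma >= 1) stop("'gamma' must be in [0, 1)")
  if (lapse < 0 || lapse >= 1 - gamma) stop("'lapse' must be in [0, 1 - gamma)")
  if (any(contrast < 0)) stop("'contrast' must be nonnegative")
  gamma + (1 - gamma - lapse) * (1 - exp(-(contrast / alpha)^beta))
}

#' Invert the Weibull psychometric function
#'
#' Contrast at which performance reaches probability `p`; with `p = 0.75`
#' this is the conventional 2AFC "75% threshold" on the full performance
#' scale.
#'
#' @inheritParams weibull_p
#' @param p target probability correct; must satisfy `gamma < p < 1 - lapse`.
#' @return Contrast at which `weibull_p` equals `p`.
#' @examples
#' weibull_quantile(0.75, alpha = 1, beta = 1)    # log(2)
#' @export
weibull_quantile <- function(p, alpha, beta, gamma = 0.5, lapse = 0) {
  if (any(alpha <= 0) || any(beta <= 0)) stop("'alpha' and 'beta' must be > 0")
  if (any(p <= gamma) || any(p >= 1 - lapse))
    stop("'p' must lie strictly between gamma and 1 - lapse")
  alpha * (-log(1 - (p - gamma) / (1 - gamma - lapse)))^(1 / beta)
}

# dP/d(log10 contrast) at the contrast where performance = p.
# dP/dx * x * ln(10) with dP/dx = (1-g-l) * exp(-u) * beta * u / x, u=(x/a)^b.
weibull_log10_slope <- function(alpha, beta, gamma = 0.5, lapse = 0, p = 0.75) {
  u <- -log(1 - (p - gamma) / (1 - gamma - lapse))
  (1 - gamma - lapse) * exp(-u) * beta * u * log(10)
}

# Negative Bernoulli log-likelihood over per-contrast counts, parameterized
# as (log alpha, log beta, lapse) so L-BFGS-B box bounds stay well scaled.
.psy_nll <- function(par, x, k, n, gamma) {
  p <- gamma + (1 - gamma - par[3L]) * (1 - exp(-(x / exp(par[1L]))^exp(par[2L])))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log1p(-p))
}

# Coarse vectorized scan of the (alpha, beta, lapse) likelihood surface,
# used to seed the optimizer: the surface can be bimodal in beta (a shallow
# and a steep mode) when observed proportions are non-monotone, and
# alpha-only multi-starts can miss the steep basin.
.psy_grid_start <- function(x, k, n, gamma, alpha_bounds, beta_bounds,
                            lapse_max) {
  g <- expand.grid(
    la = seq(log(alpha_bounds[1L]), log(alpha_bounds[2L]), length.out = 40L),
    lb = seq(log(beta_bounds[1L]), log(beta_bounds[2L]), length.out = 25L),
    lapse = seq(0, lapse_max, length.out = 6L))
  ll <- 0
  for (i in seq_along(x)) {
    p <- gamma + (1 - gamma - g$lapse) * (1 - exp(-(x[i] / exp(g$la))^exp(g$lb)))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- ll + k[i] * log(p) + (n[i] - k[i]) * log1p(-p)
  }
  best <- which.max(ll)
  starts <- list(c(g$la[best], g$lb[best], g$lapse[best]))
  # also seed the runner-up beta basin when the surface is bimodal
  other <- abs(g$lb - g$lb[best]) > 0.5
  if (any(other)) {
    second <- which(other)[which.max(ll[other])]
    starts <- c(starts, list(c(g$la[second], g$lb[second], g$lapse[second])))
  }
  starts
}

# Shared fitting engine on per-contrast counts. Contrasts are normalized by
# their geometric mean during optimization (exact scale invariance of the
# fit), which is seeded from n_starts alpha values log-spaced across the
# tested contrasts plus a coarse grid scan, and finished with a tight polish
# from the best start; ties in log-likelihood broken toward smallest alpha.
.psyfit_engine <- function(x, k, n, gamma = 0.5, lapse_max = 0.05,
                           beta_bounds = c(0.5, 10), n_starts = 5L,
                           call = sys.call(-1L)) {
  stopifnot(length(x) == length(k), length(k) == length(n))
  keep <- n > 0
  x <- x[keep]; k <- k[keep]; n <- n[keep]
  if (any(x <= 0)) stop("contrasts must be positive")
  if (any(k < 0 | k > n)) stop("counts must satisfy 0 <= correct <= total")
  if (length(unique(x)) < 2L)
    stop("at least two distinct contrast levels are required to fit a psychometric function")
  o <- order(x)
  x <- x[o]; k <- k[o]; n <- n[o]

  # optimize in units of the geometric-mean contrast so the fit is invariant
  # to rescaling the contrast axis
  unit <- exp(mean(log(x)))
  xs <- x / unit
  alpha_bounds <- c(min(xs) / 10, max(xs) * 10)
  lower <- c(log(alpha_bounds[1L]), log(beta_bounds[1L]), 0)
  upper <- c(log(alpha_bounds[2L]), log(beta_bounds[2L]), lapse_max)

  degenerate <- sum(k) == sum(n) || sum(k) == 0
  if (degenerate) {
    at_ceiling <- sum(k) == sum(n)
    warning(sprintf(
      "all responses %s: psychometric function is unidentifiable; returning a boundary estimate (converged = FALSE)",
      if (at_ceiling) "correct" else "incorrect"))
    alpha <- unit * if (at_ceiling) alpha_bounds[1L] else alpha_bounds[2L]
    beta <- 2
    lapse <- 0
    ll <- -.psy_nll(c(log(alpha), log(beta), lapse), x, k, n, gamma)
    converged <- FALSE
  } else {
    starts <- lapply(exp(seq(log(min(xs)), log(max(xs)), length.out = n_starts)),
                     function(a0) c(log(a0), log(2), 0.01))
    starts <- c(starts, .psy_grid_start(xs, k, n, gamma, alpha_bounds,
                                        beta_bounds, lapse_max))
    best <- NULL
    for (p0 in starts) {
      opt <- try(stats::optim(p0, .psy_nll,
                              x = xs, k = k, n = n, gamma = gamma,
                              method = "L-BFGS-B", lower = lower, upper = upper),
                 silent = TRUE)
      if (inherits(opt, "try-error")) next
      if (is.null(best) || opt$value < best$value - 1e-6 ||
          (abs(opt$value - best$value) <= 1e-6 && opt$par[1L] < best$par[1L]))
        best <- opt
    }
    if (is.null(best)) stop("all optimizer starts failed")
    converged <- best$convergence == 0L
    # refine at beyond-default tolerance; the polish may stop on rounding
    # limits (line-search abort), so it contributes parameters when it
    # improves the likelihood but never overrides the convergence status
    polish <- try(stats::optim(best$par, .psy_nll,
                               x = xs, k = k, n = n, gamma = gamma,
                               method = "L-BFGS-B", lower = lower, upper = upper,
                               control = list(factr = 1e2, pgtol = 1e-10)),
                  silent = TRUE)
    if (!inherits(polish, "try-error") && polish$value <= best$value)
      best <- polish
    alpha <- unit * exp(best$par[1L]); beta <- exp(best$par[2L]); lapse <- best$par[3L]
    ll <- -best$value
    if (!converged)
      warning("optimizer did not report convergence; inspect the fit")
  }

  threshold75 <- weibull_quantile(0.75, alpha, beta, gamma, lapse)
  structure(list(
    coefficients = c(alpha = alpha, beta = beta, lapse = lapse),
    gamma = gamma,
    threshold75 = threshold75,
    slope = weibull_log10_slope(alpha, beta, gamma, lapse, p = 0.75),
    logLik = ll,
    converged = converged,
    n_trials = sum(n),
    data = data.frame(contrast = x, n_correct = k, n_total = n),
    bounds = list(alpha = alpha_bounds, beta = beta_bounds, lapse = c(0, lapse_max)),
    call = call
  ), class = "psychfit")
}

#' Fit a Weibull 2AFC psychometric function by maximum likelihood
#'
#' The central model fit of the package: a Weibull psychometric function with
#' fixed guess rate (`gamma`, 0.5 for 2AFC) and a lapse rate bounded above,
#' estimated by maximizing the Bernoulli log-likelihood of per-contrast
#' correct/total counts. The 75% contrast threshold (on the full performance
#' scale) and the slope dP/d(log10 contrast) at that threshold are derived
#' from the fit.
#'
#' Optimization uses box-constrained quasi-Newton iterations from several
#' deterministic starting points (scale starts log-spaced across the tested
#' contrasts); ties in log-likelihood are broken toward the smallest scale.
#' Data that are entirely correct or entirely incorrect are unidentifiable:
#' the fit returns a boundary estimate with `converged = FALSE` and a warning
#' rather than a silent number.
#'
#' @param formula a formula describing the response and the contrast
#'   covariate. The response may be a 0/1 (or logical) per-trial outcome, or
#'   a two-column matrix `cbind(n_correct, n_incorrect)` of aggregated
#'   counts. The right-hand side names the contrast variable.
#' @param data a data frame in which `formula` is evaluated.
#' @param gamma guess rate, fixed during fitting; default 0.5 (2AFC).
#' @param lapse_max upper bound on the fitted lapse rate; default 0.05.
#' @param beta_bounds bounds for the shape parameter; default `c(0.5, 10)`.
#' @param n_starts number of deterministic optimizer starts; default 5.
#' @return An object of class `"psychfit"`: a list with components
#'   `coefficients` (alpha, beta, lapse), `gamma`, `threshold75`, `slope`,
#'   `logLik`, `converged`, `n_trials` and the aggregated `data`.
#' @seealso [fit_psychometric()] for the count-vector interface,
#'   [threshold()], [weibull_p()], [weibull_quantile()].
#' @examples
#' contrasts <- c(0.16, 0.31, 0.63, 1.25, 2.5)
#' p <- weibull_p(contrasts, alpha = 0.6, beta = 2, lapse = 0.02)
#' set.seed(1)
#' d <- data.frame(contrast = contrasts, k = rbinom(5, 40, p), n = 40)
#' fit <- psychfit(cbind(k, n - k) ~ contrast, data = d)
#' coef(fit)
#' threshold(fit)
#' @export
psychfit <- function(formula, data, gamma = 0.5, lapse_max = 0.05,
                     beta_bounds = c(0.5, 10), n_starts = 5L) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (ncol(mf) < 2L) stop("formula must name a contrast covariate")
  x <- mf[[2L]]
  if (is.matrix(y)) {
    if (ncol(y) != 2L) stop("matrix response must have two columns: successes, failures")
    k <- y[, 1L]; n <- y[, 1L] + y[, 2L]
  } else {
    if (is.logical(y)) y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop("per-trial response must be 0/1 or logical")
    agg_k <- tapply(y, x, sum)
    agg_n <- tapply(y, x, length)
    x <- as.numeric(names(agg_k)); k <- as.vector(agg_k); n <- as.vector(agg_n)
  }
  fit <- .psyfit_engine(x, k, n, gamma = gamma, lapse_max = lapse_max,
                        beta_bounds = beta_bounds, n_starts = n_starts,
                        call = match.call())
  fit
}

#' Fit a psychometric function from count vectors
#'
#' Count-vector interface to the same maximum-likelihood engine as
#' [psychfit()], convenient when data are already aggregated per contrast.
#'
#' @param contrast vector of contrast levels.
#' @param n_correct number of correct responses at each level.
#' @param n_total number of trials at each level.
#' @inheritParams psychfit
#' @return An object of class `"psychfit"`; see [psychfit()].
#' @export
fit_psychometric <- function(contrast, n_correct, n_total, gamma = 0.5,
                             lapse_max = 0.05, beta_bounds = c(0.5, 10),
                             n_starts = 5L) {
  .psyfit_engine(contrast, n_correct, n_total, gamma = gamma,
                 lapse_max = lapse_max, beta_bounds = beta_bounds,
                 n_starts = n_starts, call = match.call())
}

#' Performance threshold of a fitted psychometric function
#'
#' @param object a fitted model.
#' @param ... passed to methods.
#' @export
threshold <- function(object, ...) UseMethod("threshold")

#' @rdname threshold
#' @param p performance level on the full probability-correct scale;
#'   default 0.75.
#' @export
threshold.psychfit <- function(object, p = 0.75, ...) {
  cf <- object$coefficients
  weibull_quantile(p, cf[["alpha"]], cf[["beta"]], object$gamma, cf[["lapse"]])
}

#' @export
coef.psychfit <- function(object, ...) object$coefficients

#' @export
logLik.psychfit <- function(object, ...) {
  structure(object$logLik, df = 3L, nobs = object$n_trials, class = "logLik")
}

#' @export
print.psychfit <- function(x, digits = 4, ...) {
  cat("Weibull 2AFC psychometric fit\n")
  cat(sprintf("  alpha = %.*g, beta = %.*g, lapse = %.*g (gamma fixed at %.2f)\n",
              digits, x$coefficients[["alpha"]], digits, x$coefficients[["beta"]],
              digits, x$coefficients[["lapse"]], x$gamma))
  cat(sprintf("  75%% threshold = %.*g, slope = %.*g per log10 unit\n",
              digits, x$threshold75, digits, x$slope))
  cat(sprintf("  logLik = %.*g on %d trials; converged: %s\n",
              digits, x$logLik, x$n_trials, x$converged))
  invisible(x)
}

#' @export
summary.psychfit <- function(object, ...) {
  d <- object$data
  d$p_obs <- d$n_correct / d$n_total
  d$p_fit <- weibull_p(d$contrast, object$coefficients[["alpha"]],
                       object$coefficients[["beta"]], object$gamma,
                       object$coefficients[["lapse"]])
  structure(list(fit = object, table = d,
                 deviance = -2 * (object$logLik - .saturated_ll(d))),
            class = "summary.psychfit")
}

.saturated_ll <- function(d) {
  p <- pmin(pmax(d$p_obs, 1e-12), 1 - 1e-12)
  sum(d$n_correct * log(p) + (d$n_total - d$n_correct) * log1p(-p))
}

#' @export
print.summary.psychfit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nPer-contrast performance:\n")
  print(format(x$table, digits = digits), row.names = FALSE)
  cat(sprintf("\nResidual deviance vs saturated model: %.*g\n", digits, x$deviance))
  invisible(x)
}

#' @export
predict.psychfit <- function(object, newdata = NULL,
                             type = c("prob", "quantile"), ...) {
  type <- match.arg(type)
  cf <- object$coefficients
  if (type == "quantile") {
    p <- if (is.null(newdata)) 0.75 else newdata
    return(weibull_quantile(p, cf[["alpha"]], cf[["beta"]], object$gamma, cf[["lapse"]]))
  }
  x <- if (is.null(newdata)) object$data$contrast
       else if (is.data.frame(newdata)) newdata[[1L]] else newdata
  weibull_p(x, cf[["alpha"]], cf[["beta"]], object$gamma, cf[["lapse"]])
}

#' @export
fitted.psychfit <- function(object, ...) predict(object)

#' @export
residuals.psychfit <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  d <- object$data
  phat <- predict(object)
  pobs <- d$n_correct / d$n_total
  if (type == "pearson")
    return((pobs - phat) / sqrt(phat * (1 - phat) / d$n_total))
  ll_term <- function(k, n, p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    k * log(p) + (n - k) * log1p(-p)
  }
  dev <- 2 * (ll_term(d$n_correct, d$n_total, pobs) -
                ll_term(d$n_correct, d$n_total, phat))
  sign(pobs - phat) * sqrt(pmax(dev, 0))
}

#' @export
simulate.psychfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  p <- predict(object)
  out <- lapply(seq_len(nsim), function(i) {
    data.frame(contrast = d$contrast,
               n_correct = stats::rbinom(nrow(d), d$n_total, p),
               n_total = d$n_total)
  })
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.psychfit <- function(x, xlab = "Contrast (%)",
                          ylab = "Proportion correct", ...) {
  d <- x$data
  cf <- x$coefficients
  xx <- exp(seq(log(min(d$contrast) / 2), log(max(d$contrast) * 2), length.out = 200))
  graphics::plot(d$contrast, d$n_correct / d$n_total, log = "x",
                 ylim = c(min(0.4, x$gamma), 1), xlab = xlab, ylab = ylab,
                 pch = 19, cex = 0.4 + sqrt(d$n_total) / 5, ...)
  graphics::lines(xx, weibull_p(xx, cf[["alpha"]], cf[["beta"]], x$gamma, cf[["lapse"]]))
  graphics::abline(h = 0.75, lty = 3)
  graphics::abline(v = x$threshold75, lty = 3)
  invisible(x)
}
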