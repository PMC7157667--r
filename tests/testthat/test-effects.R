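# Build a fit table directly from chosen thresholds/slopes, bypassing trial
# simulation, so effect algebra can be checked against closed forms.
fits_from_values <- function(thresholds, slopes = NULL) {
  # thresholds: list(participant_id -> list(BL = x, IP = c(5), OP = c(5)))
  sal <- c(31.5, 35.5, 39.5, 47.5, 55.0)
  rows <- list()
  for (pid in names(thresholds)) {
    th <- thresholds[[pid]]
    sl <- if (is.null(slopes)) NULL else slopes[[pid]]
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = pid, condition = "BL", salience_db = NA_real_,
      threshold75 = th$BL, slope = if (is.null(sl)) 1 else sl$BL)
    for (cond in intersect(c("IP", "OP"), names(th))) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, condition = cond, salience_db = sal,
        threshold75 = th[[cond]],
        slope = if (is.null(sl)) 1 else sl[[cond]])
    }
  }
  out <- do.call(rbind, rows)
  out$alpha <- out$threshold75; out$beta <- 2; out$lapse <- 0.02
  out$loglik <- 0; out$converged <- TRUE; out$n_trials <- 100L
  out
}

test_that("threshold differences follow their log10 closed forms and identity", {
  fits <- fits_from_values(list(
    A = list(BL = 0.5, IP = c(0.25, 0.5, 0.5, 0.5, 0.5), OP = c(0.7, 0.5, 0.4, 0.5, 0.5))))
  eff <- threshold_differences(fits)
  expect_equal(eff$bl_ip[eff$salience_db == 31.5], log10(2))
  expect_equal(eff$bl_ip[eff$salience_db == 39.5], 0)
  expect_equal(eff$op_bl[eff$salience_db == 31.5], log10(0.7 / 0.5))
  # algebraic identity BL-IP + OP-BL = OP-IP at every salience, exactly
  expect_identical(eff$bl_ip + eff$op_bl, eff$op_ip)
})

test_that("slope differences subtract raw slopes with the same orientation", {
  fits <- fits_from_values(
    list(A = list(BL = 0.5, IP = rep(0.5, 5), OP = rep(0.5, 5))),
    slopes = list(A = list(BL = 1.2, IP = rep(1.5, 5), OP = rep(1.1, 5))))
  sl <- slope_differences(fits)
  expect_equal(unique(sl$bl_ip), 1.2 - 1.5)
  expect_equal(unique(sl$op_bl), 1.1 - 1.2)
  expect_equal(sl$bl_ip + sl$op_bl, sl$op_ip)
})

test_that("a missing condition x salience cell is reported by name", {
  fits <- fits_from_values(list(
    A = list(BL = 0.5, IP = c(0.25, 0.5, 0.5, 0.5, 0.5)),
    B = list(BL = 0.4, IP = c(0.4, 0.4, 0.4, 0.4, 0.4))))
  fits <- fits[!(fits$condition == "IP" & fits$salience_db == 47.5 &
                   fits$participant_id == "A"), ]
  expect_error(threshold_differences(fits), "IP at 47.5 dB")
})

test_that("RT trimming is one-sided at mean + 2 SD", {
  expect_equal(rt_trim_and_mean(c(500, 510, 520)), 510)
  rts <- c(400, 410, 420, 430, 440, 450, 460, 470, 480, 2000)
  # oracle: compute the cutoff on all 10 values and check who survives
  cutoff <- mean(rts) + 2 * sd(rts)
  expect_true(all(rts[rts <= cutoff] == rts[1:9]))
  expect_equal(rt_trim_and_mean(rts), 440)
  # fast outliers are never trimmed (the rule is one-sided, "slower")
  expect_equal(rt_trim_and_mean(c(100, 500, 510, 520)), mean(c(100, 500, 510, 520)))
  expect_error(rt_trim_and_mean(1000), "at least 2")
})

test_that("two-step exclusion removes constructed outliers and only them", {
  set.seed(4)
  n <- 20L
  sal <- c(31.5, 35.5, 39.5, 47.5, 55.0)
  thr <- lapply(seq_len(n), function(i) {
    bl <- 10^rnorm(1, -0.352, 0.1)
    list(BL = bl, IP = bl * 10^rnorm(5, 0, 0.05))
  })
  names(thr) <- sprintf("P%02d", seq_len(n))
  fits <- fits_from_values(thr)
  eff <- threshold_differences(fits)
  base <- exclude_participants(fits, eff)
  expect_length(base$kept, n - nrow(base$excluded))

  # plant a baseline outlier at group mean + 3 group SD
  v <- log10(vapply(thr, function(t) t$BL, numeric(1)))
  thr_out <- thr
  thr_out[["P01"]]$BL <- 10^(mean(v) + 3 * sd(v))
  thr_out[["P01"]]$IP <- thr_out[["P01"]]$BL * 10^rnorm(5, 0, 0.05)
  fits_out <- fits_from_values(thr_out)
  eff_out <- threshold_differences(fits_out)
  res <- exclude_participants(fits_out, eff_out)
  expect_true("P01" %in% res$excluded$participant_id)
  expect_equal(res$excluded$step[res$excluded$participant_id == "P01"],
               "baseline_threshold")
  expect_gt(abs(res$excluded$z[res$excluded$participant_id == "P01"]), 2)

  # a second pass on the kept set never removes more than the first
  fits_kept <- fits_out[fits_out$participant_id %in% res$kept, ]
  eff_kept <- eff_out[eff_out$participant_id %in% res$kept, ]
  res2 <- exclude_participants(fits_kept, eff_kept)
  expect_lte(nrow(res2$excluded), nrow(res$excluded))
  expect_error(exclude_participants(fits_out[fits_out$participant_id %in%
                                               c("P01", "P02"), ], eff_out),
               "at least 3")
})

test_that("grouping follows the sign of the mid-salience BL-IP difference", {
  fits <- fits_from_values(list(
    Enh = list(BL = 0.5, IP = c(0.5, 0.5, 0.4, 0.5, 0.5)),   # BL-IP > 0 at 39.5
    Sup = list(BL = 0.5, IP = c(0.5, 0.5, 0.63, 0.5, 0.5)),  # BL-IP < 0
    Tie = list(BL = 0.5, IP = c(0.4, 0.5, 0.5, 0.5, 0.5))))  # exactly 0
  eff <- threshold_differences(fits)
  expect_warning(g <- classify_groups(eff), "exactly 0")
  expect_equal(g$group[g$participant_id == "Enh"], "enhancement")
  expect_equal(g$group[g$participant_id == "Sup"], "suppression")
  expect_equal(g$group[g$participant_id == "Tie"], "enhancement")
  expect_error(classify_groups(eff, grouping_salience_db = 42), "not in the design")
})

test_that("alignment to the optimal salience averages equidistant bins", {
  mk <- function(blip) {
    sal <- c(31.5, 35.5, 39.5, 47.5, 55.0)
    data.frame(participant_id = "A", salience_db = sal, bl_ip = blip,
               op_bl = NA_real_, op_ip = NA_real_)
  }
  a <- align_to_optimal(mk(c(0.0, 0.1, 0.3, 0.1, 0.0)))
  expect_equal(a$optimal_index, 3L)
  expect_equal(a$optimal, 0.3)
  expect_equal(a$pm1, 0.1)   # mean of levels 2 and 4
  expect_equal(a$pm2, 0.0)   # mean of levels 1 and 5

  # edge optimum: one-sided bins use the single existing level
  e <- align_to_optimal(mk(c(0.3, 0.1, 0.0, 0.0, 0.0)))
  expect_equal(e$optimal_index, 1L)
  expect_equal(e$pm1, 0.1)
  expect_equal(e$pm2, 0.0)

  # constant profile: tie broken toward the lowest salience, with a warning
  expect_warning(tie <- align_to_optimal(mk(rep(0.2, 5))), "tie")
  expect_equal(tie$optimal_index, 1L)
  expect_equal(unlist(tie[, c("optimal", "pm1", "pm2")]), rep(0.2, 3),
               ignore_attr = TRUE)
})

test_that("the optimal bin dominates the others by construction", {
  set.seed(9)
  sal <- c(31.5, 35.5, 39.5, 47.5, 55.0)
  for (i in 1:50) {
    eff <- data.frame(participant_id = "X", salience_db = sal,
                      bl_ip = rnorm(5), op_bl = NA_real_, op_ip = NA_real_)
    a <- suppressWarnings(align_to_optimal(eff))
    expect_gte(a$optimal, a$pm1)
    expect_gte(a$optimal, a$pm2)
  }
})

test_that("secondary tables are aligned by the anchor's optimal index", {
  sal <- c(31.5, 35.5, 39.5, 47.5, 55.0)
  anchor <- data.frame(participant_id = "A", salience_db = sal,
                       bl_ip = c(0, 0, 0, 1, 0), op_bl = NA_real_,
                       op_ip = NA_real_)
  slopes <- data.frame(participant_id = "A", salience_db = sal,
                       bl_ip = 1:5, op_bl = NA_real_, op_ip = NA_real_)
  a <- align_to_optimal(slopes, anchor = anchor)
  expect_equal(a$optimal_index, 4L)
  expect_equal(a$optimal, 4)
  expect_equal(a$pm1, mean(c(3, 5)))
  expect_equal(a$pm2, 2)
})

test_that("aligned null estimates reproduce the max-of-5-normals bias law", {
  # independent Monte-Carlo oracle for E[max of 5 standard normals]
  set.seed(10)
  oracle <- mean(apply(matrix(rnorm(5 * 1e5), ncol = 5), 1, max))
  expect_equal(oracle, 1.1630, tolerance = 0.01)
  expect_equal(expected_max_normal(5), 1.16296, tolerance = 1e-4)

  # the alignment operation applied to iid zero-mean estimates inherits it
  sal <- c(31.5, 35.5, 39.5, 47.5, 55.0)
  sigma <- 0.1
  n <- 4000L
  eff <- data.frame(participant_id = rep(sprintf("P%04d", 1:n), each = 5),
                    salience_db = rep(sal, n),
                    bl_ip = rnorm(5 * n, 0, sigma),
                    op_bl = NA_real_, op_ip = NA_real_)
  a <- suppressWarnings(align_to_optimal(eff))
  expect_equal(mean(a$optimal) / sigma, expected_max_normal(5), tolerance = 0.03)
})
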