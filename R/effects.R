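#' Fit psychometric functions for every cell of a cohort
#'
#' Aggregates a trial table to per-contrast counts within each participant x
#' condition x salience cell and fits a Weibull psychometric function to each
#' (see [psychfit()]).
#'
#' @param trials a trial table (see [read_trials()]).
#' @param conditions optional subset of conditions to fit; `NULL` fits all
#'   present.
#' @return A data frame with one row per fitted cell: `participant_id`,
#'   `condition`, `salience_db` (`NA` for BL), the fitted `alpha`, `beta`,
#'   `lapse`, the derived `threshold75` and `slope`, `loglik`, `converged`
#'   and `n_trials`.
#' @export
fit_cohort <- function(trials, conditions = NULL) {
  if (!is.null(conditions))
    trials <- trials[trials$condition %in% conditions, , drop = FALSE]
  if (nrow(trials) == 0L) stop("no trials to fit")
  key <- paste(trials$participant_id, trials$condition, trials$salience_db,
               sep = "\r")
  groups <- split(seq_len(nrow(trials)), key)
  rows <- lapply(groups, function(idx) {
    tt <- trials[idx, ]
    k <- tapply(tt$correct, tt$max_contrast_pct, sum)
    n <- tapply(tt$correct, tt$max_contrast_pct, length)
    fit <- fit_psychometric(as.numeric(names(k)), as.vector(k), as.vector(n))
    data.frame(participant_id = tt$participant_id[1L],
               condition = tt$condition[1L],
               salience_db = tt$salience_db[1L],
               alpha = fit$coefficients[["alpha"]],
               beta = fit$coefficients[["beta"]],
               lapse = fit$coefficients[["lapse"]],
               threshold75 = fit$threshold75,
               slope = fit$slope,
               loglik = fit$logLik,
               converged = fit$converged,
               n_trials = fit$n_trials,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$condition, out$salience_db,
                   na.last = FALSE), ]
  rownames(out) <- NULL
  out
}

# Reshape a cohort fit table into per-participant lists of BL value plus
# IP/OP-by-salience values for one measure column, erroring on missing cells.
.effects_frame <- function(fits, measure, transform = identity) {
  parts <- unique(fits$participant_id)
  sal <- sort(unique(fits$salience_db[!is.na(fits$salience_db)]))
  if (length(sal) == 0L) stop("no auditory (IP/OP) cells present")
  have_op <- any(fits$condition == "OP")
  pick <- function(pid, cond, s = NA) {
    i <- which(fits$participant_id == pid & fits$condition == cond &
                 (if (is.na(s)) is.na(fits$salience_db)
                  else !is.na(fits$salience_db) & fits$salience_db == s))
    if (length(i) != 1L)
      stop(sprintf("missing or duplicated cell: participant %s, %s%s",
                   pid, cond, if (is.na(s)) "" else sprintf(" at %.1f dB", s)))
    transform(fits[[measure]][i])
  }
  rows <- lapply(parts, function(pid) {
    bl <- pick(pid, "BL")
    ip <- vapply(sal, function(s) pick(pid, "IP", s), numeric(1L))
    op <- if (have_op) vapply(sal, function(s) pick(pid, "OP", s), numeric(1L))
          else rep(NA_real_, length(sal))
    bl_ip <- bl - ip
    op_bl <- if (have_op) op - bl else rep(NA_real_, length(sal))
    data.frame(participant_id = pid, salience_db = sal,
               bl_ip = bl_ip,
               op_bl = op_bl,
               # composed from the other two so the algebraic identity
               # bl_ip + op_bl = op_ip holds exactly, not just to rounding
               op_ip = bl_ip + op_bl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Threshold difference measures
#'
#' Per participant and auditory salience, the log10-threshold difference
#' measures between conditions: `bl_ip` = log10 BL threshold - log10 IP
#' threshold (positive = in-phase sound lowers, i.e. improves, the visual
#' threshold), `op_bl` = log10 OP - log10 BL, and `op_ip` = log10 OP -
#' log10 IP. The three satisfy `bl_ip + op_bl = op_ip` exactly.
#'
#' @param fits a cohort fit table from [fit_cohort()]. OP columns are `NA`
#'   when no OP cells were fitted.
#' @return A data frame with columns `participant_id`, `salience_db`,
#'   `bl_ip`, `op_bl`, `op_ip`.
#' @export
threshold_differences <- function(fits) {
  out <- .effects_frame(fits, "threshold75", transform = log10)
  attr(out, "measure") <- "log10_threshold"
  out
}

#' Slope difference measures
#'
#' As [threshold_differences()] but for the psychometric slope at threshold,
#' subtracted on the raw scale (no log), with the same comparison
#' orientations.
#'
#' @inheritParams threshold_differences
#' @return A data frame with columns `participant_id`, `salience_db`,
#'   `bl_ip`, `op_bl`, `op_ip`.
#' @export
slope_differences <- function(fits) {
  out <- .effects_frame(fits, "slope")
  attr(out, "measure") <- "slope"
  out
}

#' Trimmed mean reaction time
#'
#' Removes trials whose reaction time is more than 2 SD *slower* than the
#' cell mean (one-sided trim) and returns the mean of the survivors.
#'
#' @param rt_ms vector of reaction times (ms); at least 2 values.
#' @return Mean RT of the surviving trials.
#' @examples
#' rt_trim_and_mean(c(400, 410, 420, 430, 440, 450, 460, 470, 480, 2000))
#' @export
rt_trim_and_mean <- function(rt_ms) {
  rt_ms <- rt_ms[!is.na(rt_ms)]
  if (length(rt_ms) < 2L) stop("need at least 2 reaction times")
  keep <- rt_ms <= mean(rt_ms) + 2 * stats::sd(rt_ms)
  mean(rt_ms[keep])
}

#' Reaction-time difference measures
#'
#' Trims and averages reaction times within each participant x condition x
#' salience cell (see [rt_trim_and_mean()]; contrasts are pooled within the
#' cell) and forms the same comparison orientations as the threshold
#' measures, on the raw millisecond scale.
#'
#' @param trials a trial table with an `rt_ms` column.
#' @return A data frame with columns `participant_id`, `salience_db`,
#'   `bl_ip`, `op_bl`, `op_ip` (mean RT differences, ms).
#' @export
rt_differences <- function(trials) {
  trials <- trials[!is.na(trials$rt_ms), , drop = FALSE]
  key <- paste(trials$participant_id, trials$condition, trials$salience_db,
               sep = "\r")
  means <- vapply(split(trials$rt_ms, key), rt_trim_and_mean, numeric(1L))
  parts <- strsplit(names(means), "\r", fixed = TRUE)
  cells <- data.frame(participant_id = vapply(parts, `[`, "", 1L),
                      condition = vapply(parts, `[`, "", 2L),
                      salience_db = suppressWarnings(
                        as.numeric(vapply(parts, `[`, "", 3L))),
                      rt_mean = unname(means),
                      stringsAsFactors = FALSE)
  out <- .effects_frame(cells, "rt_mean")
  attr(out, "measure") <- "rt_ms"
  out
}

#' Exclude outlying participants
#'
#' Two sequential criteria, each removing participants more than 2 group SD
#' from the group mean: (1) baseline performance, on the log10 BL threshold,
#' with mean and SD computed on the input cohort; (2) multisensory effect,
#' on the BL-IP threshold difference at the grouping salience (default
#' 39.5 dB), with mean and SD recomputed on the survivors of step 1.
#'
#' @param fits a cohort fit table from [fit_cohort()] (provides BL
#'   thresholds).
#' @param effects a threshold-difference table from
#'   [threshold_differences()].
#' @param grouping_salience_db salience at which the BL-IP criterion is
#'   applied; default 39.5.
#' @param n_sd exclusion cutoff in group SD units; default 2.
#' @return A list with `kept` (participant ids) and `excluded` (data frame
#'   with the criterion, value, group mean/SD and z-score of each removal).
#' @export
exclude_participants <- function(fits, effects, grouping_salience_db = 39.5,
                                 n_sd = 2) {
  bl <- fits[fits$condition == "BL", ]
  if (nrow(bl) < 3L) stop("need at least 3 participants")
  excl <- list()

  # step 1: baseline threshold criterion
  v1 <- log10(bl$threshold75)
  m1 <- mean(v1); s1 <- stats::sd(v1)
  z1 <- (v1 - m1) / s1
  out1 <- abs(z1) > n_sd
  if (any(out1))
    excl[[1L]] <- data.frame(participant_id = bl$participant_id[out1],
                             step = "baseline_threshold",
                             value = v1[out1], group_mean = m1, group_sd = s1,
                             z = z1[out1], stringsAsFactors = FALSE)
  kept <- bl$participant_id[!out1]

  # step 2: mid-salience BL-IP criterion, statistics recomputed on survivors
  mid <- effects[effects$participant_id %in% kept &
                   effects$salience_db == grouping_salience_db, ]
  if (nrow(mid) != length(kept))
    stop(sprintf("BL-IP at %.1f dB missing for some participants",
                 grouping_salience_db))
  v2 <- mid$bl_ip
  m2 <- mean(v2); s2 <- stats::sd(v2)
  z2 <- (v2 - m2) / s2
  out2 <- abs(z2) > n_sd
  if (any(out2))
    excl[[2L]] <- data.frame(participant_id = mid$participant_id[out2],
                             step = "mid_salience_bl_ip",
                             value = v2[out2], group_mean = m2, group_sd = s2,
                             z = z2[out2], stringsAsFactors = FALSE)
  kept <- setdiff(kept, mid$participant_id[out2])

  excluded <- if (length(excl)) do.call(rbind, excl)
    else data.frame(participant_id = character(), step = character(),
                    value = numeric(), group_mean = numeric(),
                    group_sd = numeric(), z = numeric())
  list(kept = kept, excluded = excluded)
}

#' Classify observers into enhancement and suppression groups
#'
#' Grouping is by the sign of the BL-IP threshold difference at the
#' grouping salience (default mid-level, 39.5 dB): positive differences
#' (in-phase sound improves the threshold) define the enhancement group,
#' negative the suppression group. An exact zero is assigned to the
#' enhancement group with a warning.
#'
#' @inheritParams exclude_participants
#' @param effects a threshold-difference table.
#' @return A data frame with `participant_id` and `group`
#'   (`"enhancement"`/`"suppression"`).
#' @export
classify_groups <- function(effects, grouping_salience_db = 39.5) {
  mid <- effects[effects$salience_db == grouping_salience_db, ]
  if (nrow(mid) == 0L)
    stop(sprintf("grouping salience %.1f dB is not in the design",
                 grouping_salience_db))
  if (any(mid$bl_ip == 0))
    warning("BL-IP difference of exactly 0: assigned to the enhancement group")
  data.frame(participant_id = mid$participant_id,
             group = ifelse(mid$bl_ip >= 0, "enhancement", "suppression"),
             stringsAsFactors = FALSE)
}

#' Align effects to each observer's optimal salience
#'
#' The optimal salience of an observer is the salience with the largest
#' BL-IP threshold difference (argmax over the five levels; ties broken
#' toward the lowest salience, with a warning). Effects are re-indexed into
#' three bins: the optimal salience itself, the mean of the levels one bin
#' away, and the mean of the levels two bins away (a single level when the
#' optimum sits near an edge). All three comparisons — and any secondary
#' table passed as `table` (slopes, RTs) — are aligned using the optimal
#' index derived from the *anchor* table's BL-IP values.
#'
#' @param table an effects table ([threshold_differences()],
#'   [slope_differences()] or [rt_differences()]) to align.
#' @param anchor the threshold-difference table supplying the BL-IP values
#'   that define each observer's optimal salience; defaults to `table`
#'   itself.
#' @return A data frame with one row per participant x comparison:
#'   `participant_id`, `comparison` (`bl_ip`/`op_bl`/`op_ip`),
#'   `optimal_index`, `optimal_salience_db`, and the aligned values
#'   `optimal`, `pm1`, `pm2`.
#' @export
align_to_optimal <- function(table, anchor = table) {
  sal <- sort(unique(table$salience_db))
  k <- length(sal)
  parts <- unique(table$participant_id)
  tied <- character()
  rows <- lapply(parts, function(pid) {
    a <- anchor[anchor$participant_id == pid, ]
    a <- a[order(a$salience_db), ]
    if (nrow(a) != k) stop(sprintf("participant %s: incomplete salience grid", pid))
    v_anchor <- a$bl_ip
    if (sum(v_anchor == max(v_anchor)) > 1L) tied <<- c(tied, pid)
    opt <- which.max(v_anchor)
    tt <- table[table$participant_id == pid, ]
    tt <- tt[order(tt$salience_db), ]
    comp_rows <- lapply(c("bl_ip", "op_bl", "op_ip"), function(cmp) {
      v <- tt[[cmp]]
      if (all(is.na(v))) return(NULL)
      dist <- abs(seq_len(k) - opt)
      data.frame(participant_id = pid, comparison = cmp,
                 optimal_index = opt, optimal_salience_db = sal[opt],
                 optimal = v[opt],
                 pm1 = mean(v[dist == 1L]),
                 pm2 = mean(v[dist == 2L]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, comp_rows)
  })
  if (length(tied))
    warning("argmax tie(s) broken toward the lowest salience for: ",
            paste(tied, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
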