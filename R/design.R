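#' Experimental design configuration
#'
#' Describes the audiovisual 2AFC detection design: five maximum sound levels
#' (auditory saliences), a seven-entry menu of maximum visual contrasts from
#' which a five-level range is active, three auditory conditions (BL: no
#' sound; IP: sound amplitude-modulated in phase with the visual contrast
#' modulation; OP: out of phase), and block structure.
#'
#' The active contrast range selects five consecutive menu entries:
#' `"hard"` entries 1-5, `"medium"` entries 2-6, `"easy"` entries 3-7.
#'
#' @param salience_levels_db maximum sound levels in dB, ordered.
#' @param contrast_menu_pct seven maximum Michelson contrasts in percent,
#'   ordered (0.16 means 0.16%).
#' @param contrast_range one of `"hard"`, `"medium"`, `"easy"`.
#' @param trials_per_cell trials per condition-salience-contrast cell.
#' @param block_size trials per block.
#' @return An object of class `"design_config"`.
#' @examples
#' cfg <- design_config()
#' contrast_levels(cfg)
#' @export
design_config <- function(salience_levels_db = c(31.5, 35.5, 39.5, 47.5, 55.0),
                          contrast_menu_pct = c(0.08, 0.16, 0.31, 0.63, 1.25, 2.5, 5),
                          contrast_range = c("medium", "hard", "easy"),
                          trials_per_cell = 20L,
                          block_size = 110L) {
  contrast_range <- match.arg(contrast_range)
  if (length(contrast_menu_pct) != 7L || is.unsorted(contrast_menu_pct))
    stop("'contrast_menu_pct' must be 7 increasing contrast values")
  if (length(salience_levels_db) < 1L || is.unsorted(salience_levels_db))
    stop("'salience_levels_db' must be increasing")
  if (any(contrast_menu_pct <= 0)) stop("contrasts must be positive")
  if (trials_per_cell < 1L || block_size < 1L)
    stop("'trials_per_cell' and 'block_size' must be positive")
  structure(list(salience_levels_db = as.numeric(salience_levels_db),
                 contrast_menu_pct = as.numeric(contrast_menu_pct),
                 contrast_range = contrast_range,
                 trials_per_cell = as.integer(trials_per_cell),
                 block_size = as.integer(block_size),
                 conditions = c("BL", "IP", "OP")),
            class = "design_config")
}

#' @export
print.design_config <- function(x, ...) {
  cat("Audiovisual 2AFC design\n")
  cat("  saliences (dB):", paste(x$salience_levels_db, collapse = ", "), "\n")
  cat("  contrast menu (%):", paste(x$contrast_menu_pct, collapse = ", "), "\n")
  cat(sprintf("  active range: %s -> %s\n", x$contrast_range,
              paste(contrast_levels(x), collapse = ", ")))
  cat(sprintf("  %d trials/cell, blocks of %d\n", x$trials_per_cell, x$block_size))
  invisible(x)
}

#' Active contrast levels of a design
#'
#' @param config a [design_config()].
#' @return The five active contrast levels in percent.
#' @export
contrast_levels <- function(config) {
  idx <- switch(config$contrast_range, hard = 1:5, medium = 2:6, easy = 3:7)
  config$contrast_menu_pct[idx]
}

# The 55 condition x salience x contrast cells of the default design:
# BL has no salience; IP and OP cross all saliences.
.design_cells <- function(config) {
  lv <- contrast_levels(config)
  aud <- rbind(data.frame(condition = "BL", salience_db = NA_real_),
               expand.grid(condition = c("IP", "OP"),
                           salience_db = config$salience_levels_db,
                           stringsAsFactors = FALSE))
  cells <- merge(aud, data.frame(max_contrast_pct = lv), by = NULL)
  cells[order(cells$condition, cells$salience_db, cells$max_contrast_pct,
              na.last = FALSE), , drop = FALSE]
}

#' Enumerate the planned trials for one participant
#'
#' Every condition-salience-contrast cell appears `trials_per_cell` times in
#' total, with an equal number of repeats of each cell in every block and the
#' within-block order randomized by `seed`.
#'
#' @param config a [design_config()].
#' @param seed integer seed controlling the within-block trial order.
#' @return A data frame of planned trials with columns `block`,
#'   `trial_index`, `condition`, `salience_db`, `max_contrast_pct`.
#' @examples
#' d <- build_design(design_config(), seed = 1)
#' nrow(d)          # 1100
#' @export
build_design <- function(config = design_config(), seed = 1L) {
  cells <- .design_cells(config)
  n_cells <- nrow(cells)
  if (config$block_size %% n_cells != 0L)
    stop(sprintf("design error: block size %d is not a multiple of the %d cells",
                 config$block_size, n_cells))
  repeats_per_block <- config$block_size %/% n_cells
  if (config$trials_per_cell %% repeats_per_block != 0L)
    stop(sprintf(
      "design error: %d trials per cell cannot be split into blocks of %d repeats",
      config$trials_per_cell, repeats_per_block))
  n_blocks <- config$trials_per_cell %/% repeats_per_block

  set.seed(seed)
  blocks <- lapply(seq_len(n_blocks), function(b) {
    idx <- rep(seq_len(n_cells), repeats_per_block)
    out <- cells[sample(idx), , drop = FALSE]
    out$block <- b
    out
  })
  d <- do.call(rbind, blocks)
  d$trial_index <- seq_len(nrow(d))
  rownames(d) <- NULL
  d[, c("block", "trial_index", "condition", "salience_db", "max_contrast_pct")]
}

#' Enumerate the practice block
#'
#' Thirty visual-only (BL) trials: ten each at the lowest, middle and highest
#' contrast of the medium range (menu entries 2, 4 and 6).
#'
#' @param config a [design_config()].
#' @param seed optional seed to randomize trial order; `NULL` leaves the
#'   enumeration order.
#' @return A data frame with the same columns as [build_design()].
#' @export
build_practice_design <- function(config = design_config(), seed = NULL) {
  medium <- config$contrast_menu_pct[2:6]
  lv <- medium[c(1L, 3L, 5L)]
  d <- data.frame(block = 0L, trial_index = NA_integer_, condition = "BL",
                  salience_db = NA_real_,
                  max_contrast_pct = rep(lv, each = 10L))
  if (!is.null(seed)) {
    set.seed(seed)
    d <- d[sample.int(nrow(d)), , drop = FALSE]
  }
  d$trial_index <- seq_len(nrow(d))
  rownames(d) <- NULL
  d
}

#' Choose the contrast range from practice performance
#'
#' The main-session contrast range targets performance near 50% correct at
#' the lowest contrast and near 90-100% at the highest. Starting from the
#' medium range, the design is made harder when accuracy at the lowest
#' practice contrast exceeds 0.65 (floor performance too easy), and easier
#' when accuracy at the highest practice contrast falls below 0.85 (ceiling
#' not reached); otherwise the medium range is kept.
#'
#' @param practice a data frame of practice trials with columns
#'   `max_contrast_pct` and `correct`; must contain all three practice
#'   contrasts.
#' @param low_cutoff accuracy at the lowest contrast above which the range
#'   is made harder; default 0.65.
#' @param high_cutoff accuracy at the highest contrast below which the range
#'   is made easier; default 0.85.
#' @return `"hard"`, `"medium"` or `"easy"`.
#' @export
select_contrast_range <- function(practice, low_cutoff = 0.65, high_cutoff = 0.85) {
  if (!all(c("max_contrast_pct", "correct") %in% names(practice)))
    stop("'practice' needs columns 'max_contrast_pct' and 'correct'")
  acc <- tapply(practice$correct, practice$max_contrast_pct, mean)
  if (length(acc) < 3L)
    stop("practice data must contain trials at all three practice contrasts")
  lv <- as.numeric(names(acc))
  acc_low <- acc[[which.min(lv)]]
  acc_high <- acc[[which.max(lv)]]
  if (acc_low > low_cutoff) return("hard")
  if (acc_high < high_cutoff) return("easy")
  "medium"
}

.trial_columns <- c("participant_id", "block", "trial_index", "condition",
                    "salience_db", "max_contrast_pct", "correct", "rt_ms")

#' Read and validate a trial table
#'
#' Trial tables are plain CSV with columns
#' `participant_id, block, trial_index, condition, salience_db,
#' max_contrast_pct, correct, rt_ms`; absent values (salience on BL rows,
#' missing reaction times) are empty fields. Validation errors name the
#' offending data row.
#'
#' @param path path to a CSV file.
#' @param config a [design_config()] used to validate salience and contrast
#'   values.
#' @return A data frame of trials.
#' @export
read_trials <- function(path, config = design_config()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                       colClasses = c(participant_id = "character"))
  if (nrow(d) == 0L) {
    warning(sprintf("'%s' contains no trials", path))
    d <- data.frame(participant_id = character(), block = integer(),
                    trial_index = integer(), condition = character(),
                    salience_db = numeric(), max_contrast_pct = numeric(),
                    correct = integer(), rt_ms = numeric())
    return(d)
  }
  missing_cols <- setdiff(.trial_columns, names(d))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  d <- d[, .trial_columns]
  validate_trials(d, config)
  d
}

#' @rdname read_trials
#' @param trials a data frame of trials.
#' @export
validate_trials <- function(trials, config = design_config()) {
  bad_row <- function(test, msg) {
    i <- which(test)
    if (length(i))
      stop(sprintf("trial table row %d: %s", i[1L], msg), call. = FALSE)
  }
  bad_row(!trials$condition %in% c("BL", "IP", "OP"),
          "unknown condition label")
  bad_row(trials$condition == "BL" & !is.na(trials$salience_db),
          "BL trials must not carry an auditory salience")
  bad_row(trials$condition != "BL" & is.na(trials$salience_db),
          "IP/OP trials must carry an auditory salience")
  ok_sal <- is.na(trials$salience_db) |
    sapply(trials$salience_db, function(s)
      is.na(s) || any(abs(s - config$salience_levels_db) < 1e-9))
  bad_row(!ok_sal, "salience is not one of the design's sound levels")
  ok_con <- sapply(trials$max_contrast_pct, function(v)
    any(abs(v - config$contrast_menu_pct) < 1e-9))
  bad_row(!ok_con, "contrast is not on the design's contrast menu")
  bad_row(!trials$correct %in% c(0, 1), "'correct' must be 0 or 1")
  bad_row(!is.na(trials$rt_ms) & trials$rt_ms <= 0,
          "reaction times must be positive")
  invisible(trials)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  missing_cols <- setdiff(.trial_columns, names(trials))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(trials[, .trial_columns], path, row.names = FALSE, na = "")
  invisible(path)
}
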