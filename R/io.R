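# Trial-table format: CSV (comma, header, UTF-8), one row per trial, ordered
# by (participant_id, stage, trial). Columns: participant_id, stage (1-9),
# trial (1-based within stage), left_line, left_shape, right_line,
# right_shape (feature identifiers, empty for an absent dimension), choice
# (left|right), feedback (1 = correct, 0 = incorrect on disk; +1/-1 in
# memory).

TRIAL_COLUMNS <- c("participant_id", "stage", "trial", "left_line",
                   "left_shape", "right_line", "right_shape", "choice",
                   "feedback")

#' Write participant datasets to a trial table
#'
#' @param datasets list of `ied_dataset` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(datasets, path) {
  stopifnot(all(vapply(datasets, inherits, logical(1), "ied_dataset")))
  rows <- lapply(datasets, function(d) {
    tr <- d$trials
    data.frame(participant_id = d$participant_id, tr[, 1:7],
               feedback = ifelse(tr$feedback == 1, 1L, 0L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[is.na(out)] <- ""
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

validation_error <- function(msg) {
  stop(structure(class = c("ied_validation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Read a trial table into participant datasets
#'
#' Parses and validates a trial-table CSV. Validation checks, with row
#' numbers on failure: required columns; ordering by (participant, stage,
#' trial); feedback consistent with a single target feature per stage (a
#' stage must admit a feature that is in the chosen stimulus exactly when
#' feedback is positive); and the task termination invariants
#' (six-in-a-row completion, 50-trial cap, no stages after a failure). In
#' strict mode any violation is an error; in lenient mode the offending
#' participant is dropped with a warning.
#'
#' @param path CSV path.
#' @param initially_relevant `"line"` or `"shape"` task template.
#' @param strict if `FALSE`, drop-and-warn instead of erroring.
#' @return list of `ied_dataset` objects.
#' @export
read_trials <- function(path, initially_relevant = "line", strict = TRUE) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing_cols))
    validation_error(paste("missing columns:",
                           paste(missing_cols, collapse = ", ")))
  raw$stage <- as.integer(raw$stage)
  raw$trial <- as.integer(raw$trial)
  raw$feedback_disk <- as.integer(raw$feedback)
  if (!all(raw$feedback_disk %in% c(0L, 1L)))
    validation_error("feedback must be 0/1 on disk")
  for (col in c("left_line", "left_shape", "right_line", "right_shape"))
    raw[[col]][raw[[col]] == ""] <- NA_character_
  raw$row <- seq_len(nrow(raw)) + 1L  # header is row 1

  out <- list()
  for (pid in unique(raw$participant_id)) {
    sub <- raw[raw$participant_id == pid, , drop = FALSE]
    res <- tryCatch({
      if (is.unsorted(sub$stage))
        validation_error(sprintf(
          "participant %s: stages out of order near row %d", pid,
          sub$row[which(diff(sub$stage) < 0)[1] + 1]))
      trials <- data.frame(stage = sub$stage, trial = sub$trial,
                           left_line = sub$left_line,
                           left_shape = sub$left_shape,
                           right_line = sub$right_line,
                           right_shape = sub$right_shape,
                           choice = sub$choice,
                           feedback = ifelse(sub$feedback_disk == 1L, 1L, -1L),
                           stringsAsFactors = FALSE)
      if (!all(trials$choice %in% c("left", "right")))
        validation_error(sprintf(
          "participant %s: bad choice value at row %d", pid,
          sub$row[which(!trials$choice %in% c("left", "right"))[1]]))
      check_feedback_consistency(trials, sub$row, pid)
      ds <- tryCatch(
        ied_dataset(pid, trials, initially_relevant),
        error = function(e) validation_error(conditionMessage(e)))
      ds
    }, ied_validation_error = function(e) e)
    if (inherits(res, "ied_validation_error")) {
      if (strict) stop(res)
      warning("dropping participant ", pid, ": ", conditionMessage(res))
    } else out[[pid]] <- res
  }
  out
}

# A stage's feedback is consistent iff some feature is contained in the
# chosen stimulus exactly when feedback is +1 (deterministic scoring against
# one target).
check_feedback_consistency <- function(trials, rows, pid) {
  for (s in unique(trials$stage)) {
    sel <- trials$stage == s
    tr <- trials[sel, , drop = FALSE]
    feats <- unique(stats::na.omit(c(tr$left_line, tr$left_shape,
                                     tr$right_line, tr$right_shape)))
    chosen_has <- function(f) {
      left <- tr$choice == "left"
      lf <- ifelse(left, tr$left_line, tr$right_line)
      sf <- ifelse(left, tr$left_shape, tr$right_shape)
      (!is.na(lf) & lf == f) | (!is.na(sf) & sf == f)
    }
    ok <- vapply(feats, function(f)
      all(chosen_has(f) == (tr$feedback == 1L)), logical(1))
    if (!any(ok)) {
      mism <- vapply(feats, function(f)
        which(chosen_has(f) != (tr$feedback == 1L))[1], integer(1))
      validation_error(sprintf(
        "participant %s: stage %d feedback inconsistent with any target feature (first conflict at row %d)",
        pid, s, rows[sel][max(mism)]))  # conflict row of the best candidate
    }
  }
  invisible(TRUE)
}
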