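#' Build the nine-stage intra-extra dimensional set-shift task
#'
#' Constructs the canonical IED stage ladder: simple discrimination (1) and
#' its reversal (2) in the initially relevant dimension; compound stimuli with
#' the stage-2 target retained (3–4) and a compound reversal (5); an
#' intradimensional shift to novel exemplars in the same dimension (6) and its
#' reversal (7); an extradimensional shift to novel exemplars with the other
#' dimension now relevant (8) and its reversal (9). Stage pairs (1,2), (4,5),
#' (6,7), (8,9) share feature pools; stages 6 and 8 introduce fresh feature
#' identifiers. Stages are won by six correct choices in a row; a stage
#' reaching 50 trials without that run fails the whole task.
#'
#' @param initially_relevant_dimension `"line"` or `"shape"`: the dimension
#'   whose feature is rewarded on stages 1–7 (the other takes over at 8–9).
#' @param seed ignored; the task structure is deterministic. Kept so task
#'   construction has the same signature as the stochastic generators.
#' @return an object of class `ied_task`: stage specifications, the feature
#'   registry, the six-in-a-row criterion and the 50-trial cap.
#' @examples
#' task <- build_task("line")
#' task$stages[[8]]$relevant_dimension  # "shape": the extradimensional shift
#' @export
build_task <- function(initially_relevant_dimension = c("line", "shape"),
                       seed = NULL) {
  rel <- match.arg(initially_relevant_dimension)
  irr <- setdiff(c("line", "shape"), rel)
  features <- c(paste0("line", 1:6), paste0("shape", 1:6))

  rel_f <- function(i) paste0(rel, i)
  irr_f <- function(i) paste0(irr, i)

  # per stage: pools in the initially relevant / irrelevant dimension,
  # target feature, whether compound, whether exemplars are novel
  ladder <- list(
    list(rp = rel_f(1:2), ip = NULL,       target = rel_f(1), novel = FALSE),
    list(rp = rel_f(1:2), ip = NULL,       target = rel_f(2), novel = FALSE),
    list(rp = rel_f(1:2), ip = irr_f(1:2), target = rel_f(2), novel = FALSE),
    list(rp = rel_f(1:2), ip = irr_f(1:2), target = rel_f(2), novel = FALSE),
    list(rp = rel_f(1:2), ip = irr_f(1:2), target = rel_f(1), novel = FALSE),
    list(rp = rel_f(3:4), ip = irr_f(3:4), target = rel_f(3), novel = TRUE),
    list(rp = rel_f(3:4), ip = irr_f(3:4), target = rel_f(4), novel = FALSE),
    list(rp = rel_f(5:6), ip = irr_f(5:6), target = irr_f(5), novel = TRUE),
    list(rp = rel_f(5:6), ip = irr_f(5:6), target = irr_f(6), novel = FALSE))

  stages <- lapply(seq_along(ladder), function(s) {
    st <- ladder[[s]]
    list(stage_index = s,
         compound = !is.null(st$ip),
         line_pool = if (rel == "line") st$rp else st$ip,
         shape_pool = if (rel == "shape") st$rp else st$ip,
         target_feature = st$target,
         relevant_dimension = if (s <= 7) rel else irr,
         novel_exemplars = st$novel)
  })

  idx <- function(f) if (is.null(f)) c(0L, 0L) else match(f, features)
  encoding <- t(vapply(seq_along(ladder), function(s) {
    st <- ladder[[s]]
    c(as.integer(!is.null(st$ip)), idx(st$rp), idx(st$ip),
      match(st$target, features))
  }, integer(6)))
  colnames(encoding) <- c("compound", "rel1", "rel2", "irr1", "irr2", "target")

  structure(list(stages = stages,
                 features = features,
                 initially_relevant = rel,
                 criterion_run = 6L,
                 trial_cap = 50L,
                 encoding = encoding),
            class = "ied_task")
}

#' @export
print.ied_task <- function(x, ...) {
  cat(sprintf("IED task: 9 stages, %s dimension relevant first; %d-in-a-row criterion, %d-trial cap\n",
              x$initially_relevant, x$criterion_run, x$trial_cap))
  for (st in x$stages)
    cat(sprintf("  stage %d: target %-7s (%s)%s\n", st$stage_index,
                st$target_feature,
                if (st$compound) "compound" else "simple",
                if (st$novel_exemplars) " [novel exemplars]" else ""))
  invisible(x)
}

#' Draw the next trial of a stage
#'
#' On compound stages the pairing of relevant-dimension with
#' irrelevant-dimension features is drawn uniformly from the two possible
#' pairings, independently on every trial, and left/right placement is
#' uniform. Uses the R random number stream.
#'
#' @param task an [build_task()] object.
#' @param stage_index stage number 1–9.
#' @return list with `stage_index`, `left` and `right` stimuli (each a list
#'   with `line`/`shape` feature ids, `NA` for an absent dimension) and
#'   `correct_side`.
#' @export
next_trial <- function(task, stage_index) {
  stopifnot(inherits(task, "ied_task"), stage_index %in% 1:9)
  st <- task$stages[[stage_index]]
  rel <- task$initially_relevant
  rel_pool <- if (rel == "line") st$line_pool else st$shape_pool
  irr_pool <- if (rel == "line") st$shape_pool else st$line_pool
  if (st$compound && stats::runif(1) < 0.5) irr_pool <- rev(irr_pool)
  stim <- function(r, i) {
    s <- list(line = NA_character_, shape = NA_character_)
    s[[rel]] <- r
    if (st$compound) s[[setdiff(c("line", "shape"), rel)]] <- i
    s
  }
  a <- stim(rel_pool[1], irr_pool[1])
  b <- stim(rel_pool[2], irr_pool[2])
  if (stats::runif(1) < 0.5) { left <- a; right <- b } else { left <- b; right <- a }
  has_target <- function(s) isTRUE(s$line == st$target_feature) ||
    isTRUE(s$shape == st$target_feature)
  list(stage_index = stage_index, left = left, right = right,
       correct_side = if (has_target(left)) "left" else "right",
       target_feature = st$target_feature)
}

#' Deterministic feedback for a choice
#'
#' @param trial a trial from [next_trial()].
#' @param chosen_side `"left"` or `"right"`.
#' @return `+1` if the chosen stimulus contains the stage's target feature,
#'   else `-1`.
#' @export
score_choice <- function(trial, chosen_side) {
  chosen_side <- match.arg(chosen_side, c("left", "right"))
  if (identical(chosen_side, trial$correct_side)) 1L else -1L
}

#' Stage progress tracking
#'
#' `new_stage_progress()` starts a fresh counter; [advance()] consumes one
#' feedback value, incrementing the consecutive-correct run on `+1` and
#' resetting it on `-1`. The stage completes at a six-long run
#' (configurable) and the task fails if the trial cap is reached first.
#'
#' @param criterion_run correct choices in a row required to pass a stage.
#' @param trial_cap trials allowed per stage before the task is failed.
#' @return a list with `run`, `n_trials` and `status`
#'   (`"ongoing"`, `"complete"`, `"failed"`).
#' @export
new_stage_progress <- function(criterion_run = 6L, trial_cap = 50L) {
  stopifnot(criterion_run <= trial_cap)
  list(run = 0L, n_trials = 0L, criterion_run = as.integer(criterion_run),
       trial_cap = as.integer(trial_cap), status = "ongoing")
}

#' @rdname new_stage_progress
#' @param progress a stage-progress object.
#' @param feedback `+1` or `-1`.
#' @export
advance <- function(progress, feedback) {
  if (progress$status != "ongoing")
    stop("cannot advance a stage that is already ", progress$status)
  if (!feedback %in% c(-1, 1)) stop("feedback must be +1 or -1")
  progress$n_trials <- progress$n_trials + 1L
  progress$run <- if (feedback == 1) progress$run + 1L else 0L
  if (progress$run >= progress$criterion_run) progress$status <- "complete"
  else if (progress$n_trials >= progress$trial_cap) progress$status <- "failed"
  progress
}

# Build an ied_dataset from the raw C++ trial matrix (rel/irr columns).
dataset_from_matrix <- function(mat, task, participant_id,
                                stages_completed, failed) {
  rel_is_line <- task$initially_relevant == "line"
  fname <- function(i) {
    out <- rep(NA_character_, length(i))
    out[i > 0L] <- task$features[i[i > 0L]]
    out
  }
  trials <- data.frame(
    stage = mat[, 1], trial = mat[, 2],
    left_line  = fname(if (rel_is_line) mat[, 3] else mat[, 4]),
    left_shape = fname(if (rel_is_line) mat[, 4] else mat[, 3]),
    right_line  = fname(if (rel_is_line) mat[, 5] else mat[, 6]),
    right_shape = fname(if (rel_is_line) mat[, 6] else mat[, 5]),
    choice = c("left", "right")[mat[, 7]],
    feedback = mat[, 8],
    stringsAsFactors = FALSE)
  structure(list(participant_id = participant_id,
                 trials = trials,
                 stages_completed = stages_completed,
                 failed = failed,
                 initially_relevant = task$initially_relevant,
                 features = task$features,
                 encoded = mat),
            class = "ied_dataset")
}

# Encode a trials data.frame into the integer matrix layout the C++ core
# consumes. `features` may be extended if the data mention unseen identifiers.
encode_trials <- function(trials, initially_relevant, features) {
  seen <- unique(c(trials$left_line, trials$left_shape,
                   trials$right_line, trials$right_shape))
  seen <- seen[!is.na(seen)]
  features <- union(features, seen)
  rel_is_line <- initially_relevant == "line"
  idx <- function(f) { i <- match(f, features); ifelse(is.na(i), 0L, i) }
  mat <- cbind(
    stage = as.integer(trials$stage), trial = as.integer(trials$trial),
    left_rel  = idx(if (rel_is_line) trials$left_line else trials$left_shape),
    left_irr  = idx(if (rel_is_line) trials$left_shape else trials$left_line),
    right_rel = idx(if (rel_is_line) trials$right_line else trials$right_shape),
    right_irr = idx(if (rel_is_line) trials$right_shape else trials$right_line),
    choice = ifelse(trials$choice == "left", 1L, 2L),
    feedback = as.integer(trials$feedback))
  storage.mode(mat) <- "integer"
  list(encoded = mat, features = features)
}

#' Construct a participant dataset from a trials table
#'
#' Validates the session against the task termination rules (six-in-a-row
#' stage completion, 50-trial cap, non-decreasing stages, no stages after a
#' failure) and derives `stages_completed` and `failed`.
#'
#' @param participant_id identifier.
#' @param trials data frame with columns `stage`, `trial`, `left_line`,
#'   `left_shape`, `right_line`, `right_shape`, `choice`, `feedback` (+1/-1).
#' @param initially_relevant `"line"` or `"shape"`.
#' @param criterion_run,trial_cap termination rules.
#' @return an `ied_dataset`.
#' @export
ied_dataset <- function(participant_id, trials, initially_relevant = "line",
                        criterion_run = 6L, trial_cap = 50L) {
  initially_relevant <- match.arg(initially_relevant, c("line", "shape"))
  req <- c("stage", "trial", "left_line", "left_shape", "right_line",
           "right_shape", "choice", "feedback")
  missing_cols <- setdiff(req, names(trials))
  if (length(missing_cols))
    stop("trials table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(trials$feedback %in% c(-1, 1)))
    stop("feedback must be coded +1/-1 in memory")
  stages <- unique(trials$stage)
  if (is.unsorted(trials$stage)) stop("stage indices must be non-decreasing")
  if (!identical(as.integer(stages), seq_along(stages)))
    stop("stages must start at 1 and have no gaps")

  stages_completed <- 0L; failed <- FALSE
  for (s in stages) {
    fb <- trials$feedback[trials$stage == s]
    prog <- new_stage_progress(criterion_run, trial_cap)
    for (i in seq_along(fb)) {
      if (prog$status != "ongoing")
        stop(sprintf("participant %s: stage %d continues after completion/failure (trial %d)",
                     participant_id, s, i))
      prog <- advance(prog, fb[i])
    }
    if (prog$status == "complete") stages_completed <- stages_completed + 1L
    else if (prog$status == "failed") failed <- TRUE
    else if (s != max(stages) || !failed)
      stop(sprintf("participant %s: stage %d ends without completion or failure",
                   participant_id, s))
    if (failed && s != max(stages))
      stop(sprintf("participant %s: stages present after failed stage %d",
                   participant_id, s))
  }
  canonical <- c(paste0("line", 1:6), paste0("shape", 1:6))
  enc <- encode_trials(trials, initially_relevant, canonical)
  structure(list(participant_id = participant_id, trials = trials,
                 stages_completed = stages_completed, failed = failed,
                 initially_relevant = initially_relevant,
                 features = enc$features, encoded = enc$encoded),
            class = "ied_dataset")
}

#' @export
print.ied_dataset <- function(x, ...) {
  cat(sprintf("IED session %s: %d trials, %d/9 stages completed%s\n",
              x$participant_id, nrow(x$trials), x$stages_completed,
              if (x$failed) " (task failed)" else ""))
  invisible(x)
}

#' Simulate one participant performing the task
#'
#' An agent with the given model and parameters plays the full nine-stage
#' session, sampling choices from the model's softmax probabilities and
#' learning from the deterministic feedback, until all stages are passed or a
#' stage hits the 50-trial cap. Reproducible: one RNG stream per participant,
#' seeded from `seed`.
#'
#' @param model_id model identifier.
#' @param params named native parameter vector.
#' @param task an [build_task()] object.
#' @param seed integer seed for this participant's stream.
#' @param record_state if `TRUE`, also return the post-trial attention logit
#'   and feature-weight snapshots (`state` element: one row per trial, column
#'   1 theta, then the feature weights).
#' @param participant_id identifier stored in the dataset.
#' @return an `ied_dataset`; with `record_state`, the trace is attached as
#'   attribute `"state"` and `errors`/`present` per stage as attributes
#'   `"errors"`/`"present"`.
#' @export
simulate_participant <- function(model_id, params, task, seed,
                                 record_state = FALSE,
                                 participant_id = "sim") {
  model_id <- match.arg(model_id, MODEL_IDS)
  params <- validate_native_params(model_id, params)
  stopifnot(inherits(task, "ied_task"))
  set.seed(as.integer(seed))
  sim <- cpp_simulate(model_code(model_id), params, task$encoding,
                      length(task$features), task$criterion_run,
                      task$trial_cap, record_state)
  ds <- dataset_from_matrix(sim$trials, task, participant_id,
                            sim$stages_completed, sim$failed)
  attr(ds, "errors") <- ifelse(sim$present, sim$errors, NA_integer_)
  attr(ds, "present") <- sim$present
  if (record_state) {
    colnames(sim$state) <- c("theta", task$features)
    attr(ds, "state") <- sim$state
  }
  ds
}

#' Errors per stage
#'
#' Counts negative-feedback trials in each of the nine stages directly from
#' the trial records.
#'
#' @param dataset an `ied_dataset`.
#' @return list with `errors` (integer 9-vector, `NA` for unreached stages)
#'   and `present` (logical 9-vector).
#' @export
errors_per_stage <- function(dataset) {
  stopifnot(inherits(dataset, "ied_dataset"))
  errors <- rep(NA_integer_, 9)
  present <- rep(FALSE, 9)
  for (s in unique(dataset$trials$stage)) {
    present[s] <- TRUE
    errors[s] <- sum(dataset$trials$feedback[dataset$trials$stage == s] == -1)
  }
  list(errors = errors, present = present)
}
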