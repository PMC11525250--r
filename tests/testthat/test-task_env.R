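test_that("stage ladder follows the canonical structure for both templates", {
  task <- build_task("line")
  expect_length(task$stages, 9)
  expect_equal(vapply(task$stages[1:7], `[[`, character(1),
                      "relevant_dimension"), rep("line", 7))
  expect_equal(task$stages[[8]]$relevant_dimension, "shape")
  expect_equal(task$stages[[9]]$relevant_dimension, "shape")
  expect_false(task$stages[[1]]$compound)
  expect_false(task$stages[[2]]$compound)
  expect_true(all(vapply(task$stages[3:9], `[[`, logical(1), "compound")))
  expect_equal(which(vapply(task$stages, `[[`, logical(1), "novel_exemplars")),
               c(6, 8))
  # reversal pairs share pools, reversals flip the target within the pool
  expect_identical(task$stages[[1]]$line_pool, task$stages[[2]]$line_pool)
  expect_false(task$stages[[1]]$target_feature ==
                 task$stages[[2]]$target_feature)
  expect_identical(task$stages[[4]]$target_feature,
                   task$stages[[3]]$target_feature)  # stage-2 target retained
  # novel pools are disjoint from everything earlier
  pools_before <- unlist(lapply(task$stages[1:5], function(s)
    c(s$line_pool, s$shape_pool)))
  pool6 <- c(task$stages[[6]]$line_pool, task$stages[[6]]$shape_pool)
  pool8 <- c(task$stages[[8]]$line_pool, task$stages[[8]]$shape_pool)
  expect_length(intersect(pool6, pools_before), 0)
  expect_length(intersect(pool8, c(pools_before, pool6)), 0)
  # target always lives in the relevant dimension's pool
  for (st in task$stages) {
    pool <- if (st$relevant_dimension == "line") st$line_pool else st$shape_pool
    expect_true(st$target_feature %in% pool)
  }

  shape_first <- build_task("shape")
  expect_equal(vapply(shape_first$stages[1:7], `[[`, character(1),
                      "relevant_dimension"), rep("shape", 7))
  expect_equal(shape_first$stages[[8]]$relevant_dimension, "line")
  expect_error(build_task("colour"))
})

test_that("trials show every pool feature once, with uniform pairing and sides", {
  task <- build_task("line")
  set.seed(42)
  # compound stage: all four features exactly once per trial
  st <- task$stages[[3]]
  pool <- c(st$line_pool, st$shape_pool)
  pair_l1 <- 0; left_first <- 0; n <- 10000
  for (i in seq_len(n)) {
    tr <- next_trial(task, 3)
    shown <- c(tr$left$line, tr$left$shape, tr$right$line, tr$right$shape)
    expect_setequal(shown, pool)
    stim_with_l1 <- if (tr$left$line == st$line_pool[1]) tr$left else tr$right
    if (stim_with_l1$shape == st$shape_pool[1]) pair_l1 <- pair_l1 + 1
    if (tr$left$line == st$line_pool[1]) left_first <- left_first + 1
  }
  expect_gte(pair_l1 / n, 0.48)  # binomial CI at p = 0.5
  expect_lte(pair_l1 / n, 0.52)
  expect_gte(left_first / n, 0.48)
  expect_lte(left_first / n, 0.52)
  # simple stage: only the relevant dimension is populated
  tr1 <- next_trial(task, 1)
  expect_true(is.na(tr1$left$shape) && is.na(tr1$right$shape))
  expect_false(is.na(tr1$left$line))
})

test_that("scoring is deterministic and the correct side holds the target", {
  task <- build_task("line")
  set.seed(7)
  for (s in c(1, 3, 8)) {
    tr <- next_trial(task, s)
    correct <- tr[[tr$correct_side]]
    expect_true(isTRUE(correct$line == tr$target_feature) ||
                  isTRUE(correct$shape == tr$target_feature))
    expect_equal(score_choice(tr, tr$correct_side), 1L)
    other <- setdiff(c("left", "right"), tr$correct_side)
    expect_equal(score_choice(tr, other), -1L)
    expect_equal(score_choice(tr, other), score_choice(tr, other))
  }
})

test_that("stage progress implements the six-run criterion and 50-trial cap", {
  run_seq <- function(fb) {
    p <- new_stage_progress()
    for (f in fb) p <- advance(p, f)
    p
  }
  p <- run_seq(rep(1, 6))
  expect_equal(p$status, "complete")
  expect_equal(p$n_trials, 6)
  p <- run_seq(c(rep(1, 5), -1, rep(1, 6)))
  expect_equal(p$status, "complete")
  expect_equal(p$n_trials, 12)
  p <- run_seq(rep(c(1, -1), 25))   # 50 trials, run never reaches 6
  expect_equal(p$status, "failed")
  expect_error(advance(p, 1), "failed")
  expect_error(advance(run_seq(rep(1, 6)), 1), "complete")
})

test_that("near-greedy fRL agents solve the discrimination and its reversal", {
  task <- build_task("line")
  for (seed in 1:10) {
    ds <- simulate_participant("fRL", c(alpha = 1, beta = 1e4), task, seed)
    e <- errors_per_stage(ds)$errors
    expect_lte(e[1], 1)       # at most the first uninformed guess
    expect_equal(e[2], 1L)    # reversal: exactly one error, then corrected
  }
})

test_that("a beta = 0 agent matches the fair-coin run-length oracle", {
  task <- build_task("line")
  stage1 <- vapply(1:4000, function(i)
    errors_per_stage(simulate_participant("fRL", c(alpha = 0.5, beta = 0),
                                          task, i))$errors[1], numeric(1))
  set.seed(99)
  oracle <- coin_stage_errors(4000)
  # frozen from the oracle: mean 21.28 (20,000 draws), MC se 0.06
  expect_gt(mean(stage1), 20.4)
  expect_lt(mean(stage1), 22.2)
  expect_lt(abs(mean(stage1) - mean(oracle)), 0.6)  # ~4 MC sd
})

test_that("simulated sessions always satisfy the termination invariants", {
  task <- build_task("line")
  pr <- reference_prior("Ca-fRL")
  sim <- simulate_cohort_from_prior("Ca-fRL", pr, 40, task, seed = 5)
  for (ds in sim$datasets) {
    # re-validating through the constructor replays the run/cap rules
    rebuilt <- ied_dataset(ds$participant_id, ds$trials,
                           ds$initially_relevant)
    expect_equal(rebuilt$stages_completed, ds$stages_completed)
    expect_equal(rebuilt$failed, ds$failed)
    per_stage <- table(ds$trials$stage)
    expect_true(all(per_stage <= 50))
    if (ds$failed) expect_lt(ds$stages_completed, 9)
    else expect_equal(ds$stages_completed, 9)
  }
})

test_that("feedback re-scores deterministically from the stimuli", {
  task <- build_task("line")
  ds <- simulate_participant("Ca-fRL", c(alpha = 0.9, beta = 1.3,
                                         theta0 = 1.8), task, seed = 11)
  targets <- vapply(task$stages, `[[`, character(1), "target_feature")
  for (i in seq_len(nrow(ds$trials))) {
    row <- ds$trials[i, ]
    target <- targets[row$stage]
    chosen <- if (row$choice == "left")
      c(row$left_line, row$left_shape) else c(row$right_line, row$right_shape)
    expect_equal(row$feedback, if (target %in% chosen) 1L else -1L)
  }
})

test_that("errors_per_stage counts errors and flags unreached stages", {
  task <- build_task("line")
  ds <- simulate_participant("fRL", c(alpha = 1, beta = 1e4), task, seed = 42)
  e <- errors_per_stage(ds)
  expect_equal(which(!e$present), seq(ds$stages_completed + 2, 9))
  expect_true(all(is.na(e$errors[!e$present])))
  # hand-built record: 2, 0, 1 errors over three completed stages
  fb <- c(-1, -1, rep(1, 6), rep(1, 6), -1, rep(1, 6))
  stage <- rep(1:3, c(8, 6, 7))
  tpl <- simulate_participant("fRL", c(alpha = 0.3, beta = 0), task, 1)
  rows <- lapply(seq_along(fb), function(i) {
    set.seed(i)
    tr <- next_trial(task, stage[i])
    correct <- tr$correct_side
    side <- if (fb[i] == 1) correct else setdiff(c("left", "right"), correct)
    data.frame(stage = stage[i],
               trial = sum(stage[seq_len(i)] == stage[i]),
               left_line = tr$left$line, left_shape = tr$left$shape,
               right_line = tr$right$line, right_shape = tr$right$shape,
               choice = side, feedback = fb[i], stringsAsFactors = FALSE)
  })
  ds2 <- ied_dataset("hand", do.call(rbind, rows), "line")
  e2 <- errors_per_stage(ds2)
  expect_equal(e2$errors[1:3], c(2L, 0L, 1L))
  expect_equal(ds2$stages_completed, 3L)
})

test_that("state recording returns per-trial attention and weight snapshots", {
  task <- build_task("line")
  ds <- simulate_participant("Ca-fRL", c(alpha = 0.9, beta = 1.3, theta0 = 2),
                             task, seed = 3, record_state = TRUE)
  st <- attr(ds, "state")
  expect_equal(nrow(st), nrow(ds$trials))
  expect_equal(colnames(st)[1], "theta")
  # theta frozen through the single-dimension stages
  n12 <- sum(ds$trials$stage <= 2)
  expect_true(all(st[seq_len(n12), "theta"] == 2))
  # weights of never-shown stage-8 features stay zero until stage 8
  pre8 <- ds$trials$stage < 8
  expect_true(all(st[pre8, c("line5", "line6", "shape5", "shape6")] == 0))
})
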