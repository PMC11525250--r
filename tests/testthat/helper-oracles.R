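# Independent R oracles and small fixture builders shared across test files.

# Trial object (next_trial layout) from one row of an ied_dataset trials table
trial_from_row <- function(row) {
  na_chr <- function(x) if (is.na(x) || x == "") NA_character_ else x
  list(stage_index = row$stage,
       left = list(line = na_chr(row$left_line), shape = na_chr(row$left_shape)),
       right = list(line = na_chr(row$right_line), shape = na_chr(row$right_shape)))
}

# Brute-force replay of a dataset through the exported R-level model
# operations; the independent oracle for dataset_neg_loglik's compiled path.
replay_nll_r <- function(model_id, params, dataset) {
  state <- init_state(model_id, params)
  beta <- params[["beta"]]
  nll <- 0
  for (i in seq_len(nrow(dataset$trials))) {
    row <- dataset$trials[i, ]
    trial <- trial_from_row(row)
    v <- stimulus_values(model_id, state, trial, dataset$initially_relevant)
    p <- choice_probabilities(v, beta)
    nll <- nll - log(p[[row$choice]])
    state <- update_state(model_id, state, trial, row$choice, row$feedback,
                          params, dataset$initially_relevant)
  }
  nll
}

# Fair-coin chooser under the run/cap rule: direct simulation, no model code.
coin_stage_errors <- function(n_sims, criterion = 6, cap = 50) {
  vapply(seq_len(n_sims), function(i) {
    run <- 0; errs <- 0
    for (t in seq_len(cap)) {
      if (runif(1) < 0.5) run <- run + 1 else { run <- 0; errs <- errs + 1 }
      if (run >= criterion) break
    }
    errs
  }, numeric(1))
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# small cohort of simulated datasets at fixed native params
fixed_param_cohort <- function(model_id, params, n, task, seed0 = 1000) {
  lapply(seq_len(n), function(i)
    simulate_participant(model_id, params, task, seed0 + i,
                         participant_id = sprintf("p%03d", i)))
}

fast_settings <- function(seed = 1, n_starts = 2, max_iter = 8,
                          ibic_samples = 500)
  em_settings(n_starts = n_starts, max_iter = max_iter, tol = 1e-2,
              ibic_samples = ibic_samples, seed = seed)
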