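# Default questionnaire scales: plausible totals for an unselected online
# adult cohort (instrument ranges are fixed by the instruments themselves).
DEFAULT_QUESTIONNAIRES <- list(
  "OCI-R"  = list(mean = 15, sd = 11, min = 0,  max = 72),
  "SDRS"   = list(mean = 38, sd = 9,  min = 20, max = 80),
  "STAI-S" = list(mean = 39, sd = 11, min = 20, max = 80),
  "STAI-T" = list(mean = 41, sd = 11, min = 20, max = 80),
  "SSMS"   = list(mean = 10, sd = 6,  min = 0,  max = 43))

#' Configuration for a synthetic study cohort
#'
#' Describes a full synthetic study: a generating model and group prior, the
#' task template, questionnaire instruments, demographic distributions, and a
#' list of planted parameter-questionnaire associations (target Spearman
#' correlations realised through a Gaussian copula on the unconstrained
#' parameter values).
#'
#' @param n_participants cohort size (at least 2).
#' @param model_id generating model.
#' @param prior generating [group_prior()]; defaults to [reference_prior()].
#' @param initially_relevant task template dimension, `"line"` or `"shape"`.
#' @param planted list of `list(parameter=, questionnaire=, rho=)` entries,
#'   at most one per questionnaire, each `|rho| < 1`.
#' @param questionnaires named list of `list(mean, sd, min, max)` scales.
#' @param seed master seed.
#' @return object of class `ied_cohort_config`.
#' @export
cohort_config <- function(n_participants, model_id = "Ca-fRL", prior = NULL,
                          initially_relevant = "line", planted = list(),
                          questionnaires = DEFAULT_QUESTIONNAIRES, seed = 1) {
  model_id <- match.arg(model_id, MODEL_IDS)
  if (n_participants < 2) stop("need at least 2 participants")
  if (is.null(prior)) prior <- reference_prior(model_id)
  nm <- model_param_names(model_id)
  qs_with_effect <- character()
  for (pl in planted) {
    if (!pl$parameter %in% nm)
      stop("planted effect targets unknown parameter ", pl$parameter)
    if (!pl$questionnaire %in% names(questionnaires))
      stop("planted effect targets unknown questionnaire ", pl$questionnaire)
    if (abs(pl$rho) >= 1) stop("|target rho| must be below 1")
    if (pl$questionnaire %in% qs_with_effect)
      stop("at most one planted effect per questionnaire")
    qs_with_effect <- c(qs_with_effect, pl$questionnaire)
  }
  structure(list(n_participants = as.integer(n_participants),
                 model_id = model_id, prior = prior,
                 initially_relevant = match.arg(initially_relevant,
                                                c("line", "shape")),
                 planted = planted, questionnaires = questionnaires,
                 seed = as.integer(seed)),
            class = "ied_cohort_config")
}

# Spearman target -> Pearson latent correlation under a bivariate Gaussian
# copula: r = 2 sin(pi * rho_s / 6).
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Questionnaire and demographic table with planted correlations
#'
#' Builds questionnaire totals from a Gaussian copula on the standardised
#' unconstrained parameter values: a questionnaire with a planted effect
#' mixes the target parameter's z-score with independent noise at the latent
#' Pearson correlation that yields the target Spearman correlation; totals
#' are then scaled, rounded to integers, and clipped to the instrument range
#' (the clipping rate is recorded). Demographics: age truncated-normal
#' 18–77 (mean 38.8, sd 13.6), gender balanced, education levels 1–6.
#'
#' Uses the current RNG stream (seed upstream).
#'
#' @param params_unconstrained n x p matrix of generating values.
#' @param config an [cohort_config()].
#' @return data frame (`participant_id`, one column per questionnaire, `age`,
#'   `gender`, `education`), with attribute `"clipping_rate"`.
#' @export
plant_questionnaires <- function(params_unconstrained, config) {
  n <- nrow(params_unconstrained)
  ids <- sprintf("sim%04d", seq_len(n))
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  clip_rate <- setNames(numeric(length(config$questionnaires)),
                        names(config$questionnaires))
  planted_by_q <- setNames(vector("list", length(config$questionnaires)),
                           names(config$questionnaires))
  for (pl in config$planted) planted_by_q[[pl$questionnaire]] <- pl

  for (q in names(config$questionnaires)) {
    sc <- config$questionnaires[[q]]
    pl <- planted_by_q[[q]]
    if (is.null(pl)) {
      z <- rnorm(n)
    } else {
      zp <- scale(params_unconstrained[, pl$parameter])[, 1]
      r <- spearman_to_pearson(pl$rho)
      z <- r * zp + sqrt(1 - r^2) * rnorm(n)
    }
    raw <- round(sc$mean + sc$sd * z)
    clipped <- pmin(pmax(raw, sc$min), sc$max)
    clip_rate[q] <- mean(clipped != raw)
    out[[q]] <- as.integer(clipped)
  }
  out$age <- as.integer(pmin(pmax(round(rnorm(n, 38.8, 13.6)), 18), 77))
  out$gender <- sample(c("female", "male"), n, replace = TRUE)
  out$education <- sample(1:6, n, replace = TRUE,
                          prob = c(0.05, 0.15, 0.25, 0.30, 0.18, 0.07))
  attr(out, "clipping_rate") <- clip_rate
  out
}

#' Generate a full synthetic study
#'
#' Draws generating parameters from the prior, simulates every participant's
#' task session, and builds the questionnaire/demographic table with the
#' configured planted correlations. Byte-identical given the same config.
#'
#' @param config an [cohort_config()].
#' @return list with `params_unconstrained`, `params_native`, `datasets`,
#'   `symptoms` (see [plant_questionnaires()]) and `ground_truth` (the config
#'   plus generating values, for recovery tests).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ied_cohort_config"))
  task <- build_task(config$initially_relevant)
  sim <- simulate_cohort_from_prior(config$model_id, config$prior,
                                    config$n_participants, task, config$seed)
  set.seed((config$seed + 500003L) %% .Machine$integer.max)  # symptom sub-stream
  symptoms <- plant_questionnaires(sim$params_unconstrained, config)
  for (i in seq_along(sim$datasets))
    stopifnot(identical(sim$datasets[[i]]$participant_id,
                        symptoms$participant_id[i]))
  list(params_unconstrained = sim$params_unconstrained,
       params_native = sim$params_native,
       datasets = sim$datasets,
       symptoms = symptoms,
       ground_truth = list(config = config,
                           params_unconstrained = sim$params_unconstrained,
                           params_native = sim$params_native))
}
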