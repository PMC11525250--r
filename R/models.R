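#' @useDynLib iedrl, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats plogis qlogis rnorm optim integrate cor qt qnorm pnorm
#'   sd var kmeans lm confint pf runif rbinom ks.test quantile median
#'   complete.cases coef setNames t.test
#' @importFrom utils read.csv write.csv head
NULL

MODEL_IDS <- c("fRL", "Ca-fRL", "Sa-fRL")

#' Free parameters of a choice model
#'
#' Parameter names, in canonical order, for each of the three trial-by-trial
#' choice models: `fRL` (feature reinforcement learning), `Ca-fRL`
#' (attention-modulated, combined learning rate) and `Sa-fRL`
#' (attention-modulated, separate dimension learning rate).
#'
#' * `alpha` — feature learning rate, native range \[0, 1\]
#' * `eps` — dimension-attention learning rate (Sa-fRL only), \[0, 1\]
#' * `beta` — choice determinism (softmax inverse temperature), \[0, Inf)
#' * `theta0` — dimension primacy: initial attention logit toward the
#'   initially relevant dimension, unbounded
#'
#' @param model_id one of `"fRL"`, `"Ca-fRL"`, `"Sa-fRL"`.
#' @return character vector of parameter names.
#' @export
model_param_names <- function(model_id) {
  switch(match.arg(model_id, MODEL_IDS),
    "fRL"    = c("alpha", "beta"),
    "Ca-fRL" = c("alpha", "beta", "theta0"),
    "Sa-fRL" = c("alpha", "eps", "beta", "theta0"))
}

model_code <- function(model_id) {
  match(match.arg(model_id, MODEL_IDS), MODEL_IDS)
}

# pad a native parameter vector into the fixed 4-slot layout used by the C++
# core: (alpha, eps, beta, theta0) with unused slots ignored
pad_par <- function(model_id, params) {
  params <- as.numeric(params)
  n <- length(model_param_names(model_id))
  if (length(params) != n)
    stop(sprintf("model '%s' takes %d parameters, got %d", model_id, n,
                 length(params)))
  params
}

#' Map unconstrained parameters to their native ranges
#'
#' Learning rates are passed through the logistic sigmoid (range \[0, 1\]),
#' choice determinism through the exponential (range \[0, Inf)), and dimension
#' primacy is untouched. [untransform_params()] is the inverse; it is undefined
#' at the closed boundaries (0 or 1 for rates, 0 for beta).
#'
#' @param model_id model identifier.
#' @param x numeric vector in unconstrained space, canonical parameter order.
#' @return named numeric vector of native parameters.
#' @export
transform_params <- function(model_id, x) {
  nm <- model_param_names(model_id)
  x <- as.numeric(x)
  if (length(x) != length(nm))
    stop(sprintf("expected %d values for model '%s'", length(nm), model_id))
  if (any(!is.finite(x))) stop("non-finite unconstrained parameter")
  out <- x
  rate <- nm %in% c("alpha", "eps")
  out[rate] <- plogis(x[rate])
  out[nm == "beta"] <- exp(x[nm == "beta"])
  names(out) <- nm
  out
}

#' @rdname transform_params
#' @param p numeric vector of native parameters, canonical order.
#' @export
untransform_params <- function(model_id, p) {
  nm <- model_param_names(model_id)
  p <- as.numeric(p)
  if (length(p) != length(nm))
    stop(sprintf("expected %d values for model '%s'", length(nm), model_id))
  rate <- nm %in% c("alpha", "eps")
  if (any(p[rate] <= 0 | p[rate] >= 1))
    stop("learning rates must lie strictly inside (0, 1) to untransform")
  if (any(p[nm == "beta"] <= 0))
    stop("beta must be strictly positive to untransform")
  out <- p
  out[rate] <- qlogis(p[rate])
  out[nm == "beta"] <- log(p[nm == "beta"])
  names(out) <- nm
  out
}

validate_native_params <- function(model_id, params) {
  nm <- model_param_names(model_id)
  params <- pad_par(model_id, params)
  names(params) <- nm
  rate <- nm %in% c("alpha", "eps")
  if (any(params[rate] < 0 | params[rate] > 1))
    stop("learning rates must lie in [0, 1]")
  if (params["beta"] < 0) stop("beta must be non-negative")
  if (any(!is.finite(params))) stop("non-finite parameter")
  params
}

#' Initialise the latent model state
#'
#' All feature weights start at zero; for the attention models the dimension
#' attention logit starts at the dimension-primacy parameter `theta0`.
#'
#' @param model_id model identifier.
#' @param params named native parameter vector (see [model_param_names()]).
#' @return list with `weights` (named numeric, initially empty; absent
#'   features read as 0) and `theta` (attention logit; `NA` for fRL).
#' @export
init_state <- function(model_id, params) {
  params <- validate_native_params(model_id, params)
  theta <- if (model_id == "fRL") NA_real_ else unname(params["theta0"])
  list(weights = setNames(numeric(0), character(0)), theta = theta)
}

weight_of <- function(state, feature) {
  if (is.na(feature)) return(0)
  w <- state$weights[feature]
  if (is.na(w)) 0 else unname(w)
}

stimulus_value_one <- function(model_id, state, stimulus, rel_dim) {
  irr_dim <- setdiff(c("line", "shape"), rel_dim)
  f_rel <- stimulus[[rel_dim]]
  f_irr <- stimulus[[irr_dim]]
  if (is.null(f_irr) || is.na(f_irr)) return(weight_of(state, f_rel))
  wr <- weight_of(state, f_rel)
  wi <- weight_of(state, f_irr)
  if (model_id == "fRL") return(wr + wi)
  a <- plogis(state$theta)
  a * wr + (1 - a) * wi
}

#' Stimulus values on one trial
#'
#' fRL values a stimulus as the sum of its feature weights. The attention
#' models weight the two dimensions by sigma(theta) (initially relevant
#' dimension) and 1 - sigma(theta); on single-dimension stages the value is
#' simply the present feature's weight.
#'
#' @param model_id model identifier.
#' @param state model state from [init_state()] / [update_state()].
#' @param trial a trial as produced by [next_trial()].
#' @param initially_relevant `"line"` or `"shape"`: the dimension that is
#'   relevant on stages 1–7 (attention is indexed to it throughout).
#' @return numeric `c(left, right)` stimulus values.
#' @export
stimulus_values <- function(model_id, state, trial, initially_relevant = "line") {
  model_id <- match.arg(model_id, MODEL_IDS)
  rel <- match.arg(initially_relevant, c("line", "shape"))
  c(left  = stimulus_value_one(model_id, state, trial$left, rel),
    right = stimulus_value_one(model_id, state, trial$right, rel))
}

#' Softmax choice probabilities over two stimuli
#'
#' @param values numeric `c(left, right)` stimulus values.
#' @param beta inverse temperature, `>= 0`. Zero gives coin-flip choices.
#' @return numeric `c(left, right)` probabilities summing to 1.
#' @export
choice_probabilities <- function(values, beta) {
  if (any(!is.finite(values))) stop("non-finite stimulus values")
  if (beta < 0) stop("beta must be non-negative")
  p_left <- plogis(beta * (values[[1]] - values[[2]]))
  c(left = p_left, right = 1 - p_left)
}

update_pass_r <- function(model_id, state, stimulus, target, alpha, theta_lr, rel_dim) {
  irr_dim <- setdiff(c("line", "shape"), rel_dim)
  f_rel <- stimulus[[rel_dim]]
  f_irr <- stimulus[[irr_dim]]
  if (is.null(f_irr) || is.na(f_irr)) {
    # simple-discrimination stage: plain delta rule, attention frozen
    d <- target - weight_of(state, f_rel)
    state$weights[f_rel] <- weight_of(state, f_rel) + alpha * d
    return(state)
  }
  wr <- weight_of(state, f_rel)
  wi <- weight_of(state, f_irr)
  if (model_id == "fRL") {
    d <- target - (wr + wi)
    state$weights[f_rel] <- wr + alpha * d
    state$weights[f_irr] <- wi + alpha * d
  } else {
    a <- plogis(state$theta)
    d <- target - (a * wr + (1 - a) * wi)
    state$weights[f_rel] <- wr + alpha * d * a
    state$weights[f_irr] <- wi + alpha * d * (1 - a)
    state$theta <- state$theta + theta_lr * d * (wr - wi) * a * (1 - a)
  }
  state
}

#' Learning update after one trial
#'
#' Performs a factual gradient pass on the chosen stimulus (target = feedback)
#' followed by a counterfactual pass on the unchosen stimulus (target =
#' -feedback). Each pass takes a single simultaneous gradient step on the
#' squared-error loss L = (target - V)^2 / 2, reading weights and theta at
#' their pre-pass values; theta evolves through both passes.
#'
#' @inheritParams stimulus_values
#' @param chosen_side `"left"` or `"right"`.
#' @param feedback `+1` (correct) or `-1` (incorrect).
#' @param params named native parameter vector.
#' @return the updated state.
#' @export
update_state <- function(model_id, state, trial, chosen_side, feedback, params,
                         initially_relevant = "line") {
  model_id <- match.arg(model_id, MODEL_IDS)
  rel <- match.arg(initially_relevant, c("line", "shape"))
  chosen_side <- match.arg(chosen_side, c("left", "right"))
  if (!feedback %in% c(-1, 1)) stop("feedback must be +1 or -1")
  params <- validate_native_params(model_id, params)
  alpha <- unname(params["alpha"])
  theta_lr <- if (model_id == "Sa-fRL") unname(params["eps"]) else alpha
  chosen   <- trial[[chosen_side]]
  unchosen <- trial[[setdiff(c("left", "right"), chosen_side)]]
  state <- update_pass_r(model_id, state, chosen, feedback, alpha, theta_lr, rel)
  update_pass_r(model_id, state, unchosen, -feedback, alpha, theta_lr, rel)
}

#' Negative log-likelihood of one participant's choices
#'
#' Replays the recorded choices and feedback through the model's learning rule
#' and accumulates minus the log softmax probability of each recorded choice.
#' Failed (truncated) sessions contribute their observed trials only.
#'
#' @param model_id model identifier.
#' @param params named native parameter vector.
#' @param dataset an `ied_dataset` (see [simulate_participant()],
#'   [read_trials()]).
#' @return scalar negative log-likelihood.
#' @export
dataset_neg_loglik <- function(model_id, params, dataset) {
  model_id <- match.arg(model_id, MODEL_IDS)
  params <- validate_native_params(model_id, params)
  stopifnot(inherits(dataset, "ied_dataset"))
  cpp_nll(model_code(model_id), params, dataset$encoded,
          length(dataset$features))
}
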