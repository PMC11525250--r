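BETA_CAP <- 100  # native beta is capped here inside optimisation objectives

#' Group-level Gaussian prior
#'
#' Diagonal multivariate Gaussian over a model's parameters in unconstrained
#' space; the hierarchical prior that regularises per-participant estimates.
#'
#' @param model_id model identifier.
#' @param mean,variance numeric vectors in unconstrained space, canonical
#'   parameter order; variances must be positive.
#' @return an object of class `ied_prior`.
#' @export
group_prior <- function(model_id, mean, variance) {
  nm <- model_param_names(model_id)
  mean <- as.numeric(mean); variance <- as.numeric(variance)
  if (length(mean) != length(nm) || length(variance) != length(nm))
    stop(sprintf("prior for '%s' needs %d means and variances", model_id,
                 length(nm)))
  if (any(variance <= 0)) stop("prior variances must be positive")
  structure(list(model_id = model_id,
                 mean = setNames(mean, nm),
                 variance = setNames(variance, nm)),
            class = "ied_prior")
}

#' @export
print.ied_prior <- function(x, ...) {
  cat(sprintf("Group prior (%s), unconstrained space:\n", x$model_id))
  print(rbind(mean = x$mean, sd = sqrt(x$variance)))
  invisible(x)
}

# penalised objective in unconstrained space: nll + Gaussian neg log prior
make_map_objective <- function(model_id, dataset, prior) {
  code <- model_code(model_id)
  enc <- dataset$encoded
  nf <- length(dataset$features)
  nm <- model_param_names(model_id)
  is_beta <- nm == "beta"
  m <- unname(prior$mean); v <- unname(prior$variance)
  lconst <- 0.5 * sum(log(2 * pi * v))
  cap_hit <- FALSE
  obj <- function(x) {
    p <- transform_params(model_id, x)
    if (any(p[is_beta] > BETA_CAP)) {
      p[is_beta] <- pmin(p[is_beta], BETA_CAP)
      cap_hit <<- TRUE
    }
    cpp_nll(code, p, enc, nf) + 0.5 * sum((x - m)^2 / v) + lconst
  }
  list(fn = obj, cap_hit = function() cap_hit)
}

numeric_hessian_diag <- function(fn, x, h = 1e-3) {
  f0 <- fn(x)
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (fn(x + e) - 2 * f0 + fn(x - e)) / h^2
  }, numeric(1))
}

#' MAP fit of one participant
#'
#' Minimises the penalised negative log posterior (choice negative
#' log-likelihood plus Gaussian negative log prior) in unconstrained space
#' with Nelder-Mead searches from `n_starts` initial points: the prior mean
#' plus Gaussian perturbations with the prior's standard deviations. Native
#' beta is capped at 100 inside the objective to avoid softmax overflow; the
#' cap being hit is reported in the result.
#'
#' @param dataset an `ied_dataset`.
#' @param model_id model identifier.
#' @param prior a [group_prior()].
#' @param n_starts number of optimisation starts.
#' @param seed optional integer seed for the perturbed starts.
#' @return list with `participant_id`, `map_unconstrained`, `map_native`,
#'   `neg_log_posterior`, `hessian_diag` (central differences at the optimum;
#'   non-positive curvature is replaced by the prior precision and flagged via
#'   `hessian_flagged`), `converged` and `beta_capped`.
#' @export
map_fit_subject <- function(dataset, model_id, prior, n_starts = 5,
                            seed = NULL) {
  stopifnot(inherits(dataset, "ied_dataset"), inherits(prior, "ied_prior"))
  model_id <- match.arg(model_id, MODEL_IDS)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ob <- make_map_objective(model_id, dataset, prior)
  m <- unname(prior$mean); s <- sqrt(unname(prior$variance))
  starts <- list(m)
  if (n_starts > 1)
    for (k in seq_len(n_starts - 1)) starts[[k + 1]] <- m + rnorm(length(m)) * s

  best <- NULL
  for (x0 in starts) {
    f0 <- ob$fn(x0)
    if (!is.finite(f0)) next
    fit <- optim(x0, ob$fn, method = "Nelder-Mead",
                 control = list(maxit = 800, reltol = 1e-9))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("objective non-finite at every start")

  hd <- numeric_hessian_diag(ob$fn, best$par)
  flagged <- any(hd <= 0)
  hd[hd <= 0] <- 1 / unname(prior$variance)[hd <= 0]
  list(participant_id = dataset$participant_id,
       map_unconstrained = setNames(best$par, model_param_names(model_id)),
       map_native = transform_params(model_id, best$par),
       neg_log_posterior = best$value,
       hessian_diag = hd,
       converged = best$convergence == 0,
       hessian_flagged = flagged,
       beta_capped = ob$cap_hit())
}

#' EM settings
#'
#' @param n_starts MAP optimisation restarts per subject per EM iteration.
#' @param max_iter maximum EM iterations.
#' @param tol convergence: max absolute change in prior means and variances.
#' @param var_floor lower bound on prior variances in the M-step.
#' @param init_mean,init_var starting prior (defaults: zero mean, variance 4 —
#'   broad on the sigmoid/exp scales).
#' @param ibic_samples prior draws for the integrated BIC.
#' @param seed integer seed for restarts and iBIC sampling.
#' @return a list of settings for [em_fit()].
#' @export
em_settings <- function(n_starts = 5, max_iter = 50, tol = 1e-3,
                        var_floor = 1e-6, init_mean = NULL, init_var = NULL,
                        ibic_samples = 2000, seed = 1) {
  list(n_starts = n_starts, max_iter = max_iter, tol = tol,
       var_floor = var_floor, init_mean = init_mean, init_var = init_var,
       ibic_samples = ibic_samples, seed = seed)
}

#' Hierarchical EM fit of a cohort
#'
#' Alternates an E-step — MAP estimation of every participant under the
#' current group prior ([map_fit_subject()]) — with an M-step that updates the
#' prior to the maximum-likelihood Gaussian given the individual estimates:
#' the mean is the mean of the MAP values, and the variance is the mean of
#' (MAP^2 + inverse-Hessian diagonal) minus the squared mean (a Laplace
#' correction for per-subject uncertainty), floored at `var_floor`. Iterates
#' until the prior moves less than `tol` or `max_iter` is reached
#' (non-convergence is flagged, not an error). The integrated BIC of the
#' final fit is attached.
#'
#' @param datasets list of at least two `ied_dataset` objects.
#' @param model_id model identifier.
#' @param settings see [em_settings()].
#' @return object of class `ied_fit`: `prior`, `subjects` (per-participant MAP
#'   fits), `ibic`, `em_trace` (per-iteration prior and total penalised
#'   posterior), `converged`, `n_choices`, `model_id`.
#' @export
em_fit <- function(datasets, model_id, settings = em_settings()) {
  model_id <- match.arg(model_id, MODEL_IDS)
  if (length(datasets) < 2) stop("em_fit needs at least two datasets")
  stopifnot(all(vapply(datasets, inherits, logical(1), "ied_dataset")))
  nm <- model_param_names(model_id)
  p <- length(nm)
  mean0 <- if (is.null(settings$init_mean)) rep(0, p) else settings$init_mean
  var0 <- if (is.null(settings$init_var)) rep(4, p) else settings$init_var
  prior <- group_prior(model_id, mean0, var0)

  n <- length(datasets)
  trace <- list()
  converged <- FALSE
  subjects <- NULL
  # fixed per-subject sub-seeds: the E-step restarts are identical across
  # iterations, so the map from prior to MAPs is deterministic and EM can
  # actually settle
  sub_seeds <- (as.integer(settings$seed) * 1009L + seq_len(n)) %%
    .Machine$integer.max
  for (iter in seq_len(settings$max_iter)) {
    subjects <- lapply(seq_len(n), function(i)
      map_fit_subject(datasets[[i]], model_id = model_id, prior = prior,
                      n_starts = settings$n_starts, seed = sub_seeds[i]))
    maps <- do.call(rbind, lapply(subjects, `[[`, "map_unconstrained"))
    inv_h <- do.call(rbind, lapply(subjects, function(s) 1 / s$hessian_diag))
    new_mean <- colMeans(maps)
    new_var <- pmax(colMeans(maps^2 + inv_h) - new_mean^2, settings$var_floor)
    total_nlp <- sum(vapply(subjects, `[[`, numeric(1), "neg_log_posterior"))
    trace[[iter]] <- c(iter = iter, setNames(prior$mean, paste0("mean_", nm)),
                       setNames(prior$variance, paste0("var_", nm)),
                       total_neg_log_posterior = total_nlp)
    delta <- max(abs(new_mean - prior$mean), abs(new_var - prior$variance))
    prior <- group_prior(model_id, new_mean, new_var)
    if (delta < settings$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge within ", settings$max_iter, " iterations")

  fit <- structure(list(model_id = model_id, prior = prior,
                        subjects = subjects,
                        em_trace = as.data.frame(do.call(rbind, trace)),
                        converged = converged,
                        n_choices = sum(vapply(datasets, function(d)
                          nrow(d$trials), numeric(1))),
                        ibic = NA_real_),
                   class = "ied_fit")
  fit$ibic <- ibic(fit, datasets, n_prior_samples = settings$ibic_samples,
                   seed = settings$seed)
  fit
}

#' @export
print.ied_fit <- function(x, ...) {
  cat(sprintf("Hierarchical fit: %s, %d participants, iBIC %.1f%s\n",
              x$model_id, length(x$subjects), x$ibic,
              if (!x$converged) " (EM not converged)" else ""))
  print(x$prior)
  invisible(x)
}

#' Integrated BIC of a hierarchical fit
#'
#' Approximates each participant's marginal likelihood by averaging the
#' choice likelihood over `n_prior_samples` parameter draws from the fitted
#' group prior, sums the logs across participants, and subtracts half the
#' number of prior hyperparameters (two per model parameter) times the log of
#' the total number of choices. Less negative is better.
#'
#' @param fit an [em_fit()] result (or any list with `model_id` and `prior`).
#' @param datasets the datasets the fit was computed on.
#' @param n_prior_samples number of prior draws (at least 100).
#' @param seed integer seed for the draws.
#' @return scalar iBIC.
#' @export
ibic <- function(fit, datasets, n_prior_samples = 2000, seed = 1) {
  if (n_prior_samples < 100) stop("n_prior_samples must be at least 100")
  prior <- fit$prior
  model_id <- fit$model_id
  nm <- model_param_names(model_id)
  p <- length(nm)
  set.seed(as.integer(seed))
  draws_u <- matrix(rnorm(n_prior_samples * p), n_prior_samples, p)
  draws_u <- sweep(sweep(draws_u, 2, sqrt(unname(prior$variance)), `*`),
                   2, unname(prior$mean), `+`)
  draws_n <- t(apply(draws_u, 1, function(x) transform_params(model_id, x)))
  is_beta <- nm == "beta"
  draws_n[, is_beta] <- pmin(draws_n[, is_beta], BETA_CAP)

  code <- model_code(model_id)
  log_ml <- vapply(datasets, function(d) {
    nll <- cpp_nll_many(code, draws_n, d$encoded, length(d$features))
    m <- min(nll)
    log(mean(exp(-(nll - m)))) - m
  }, numeric(1))
  n_choices <- sum(vapply(datasets, function(d) nrow(d$trials), numeric(1)))
  sum(log_ml) - 0.5 * (2 * p) * log(n_choices)
}
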