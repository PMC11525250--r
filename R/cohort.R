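#' K-means clustering of error trajectories
#'
#' Clusters complete nine-stage error trajectories (one 9-vector per
#' participant, treated as a point in Euclidean space, unstandardised) with
#' Lloyd's algorithm, `restarts` random-point initialisations, keeping the
#' lowest-inertia run. Participants who failed before stage 9 must be
#' excluded upstream (see [assign_with_failures()]).
#'
#' @param trajectories numeric matrix, one row per participant, 9 columns of
#'   per-stage error counts (no missing values).
#' @param K number of clusters.
#' @param restarts random restarts.
#' @param seed integer seed.
#' @return object of class `ied_clusters`: `K`, `labels`, `centroids`
#'   (K x 9), `inertia` (total within-cluster sum of squares),
#'   `restarts_used`.
#' @export
fit_kmeans_trajectories <- function(trajectories, K, restarts = 10, seed = 1) {
  trajectories <- as.matrix(trajectories)
  if (ncol(trajectories) != 9) stop("trajectories must have 9 stage columns")
  if (anyNA(trajectories))
    stop("incomplete trajectory supplied; exclude participants who failed")
  if (K > nrow(trajectories)) stop("K exceeds the number of trajectories")
  set.seed(as.integer(seed))
  km <- suppressWarnings(
    kmeans(trajectories, centers = K, nstart = restarts,
           algorithm = "Lloyd", iter.max = 100))
  structure(list(K = as.integer(K), labels = km$cluster, centroids = km$centers,
                 inertia = km$tot.withinss, restarts_used = restarts),
            class = "ied_clusters")
}

#' Scree of K-means inertia over K
#'
#' @inheritParams fit_kmeans_trajectories
#' @param K_range integer vector of cluster counts to sweep.
#' @return data frame with `K` and `inertia`.
#' @export
scree <- function(trajectories, K_range = 1:8, restarts = 10, seed = 1) {
  inertia <- vapply(K_range, function(k)
    fit_kmeans_trajectories(trajectories, k, restarts, seed)$inertia,
    numeric(1))
  # best-so-far discipline: a rare unlucky restart set at larger K is
  # replaced by the better smaller-K solution, keeping the sweep monotone
  data.frame(K = K_range, inertia = cummin(inertia))
}

#' Assign all participants, including task failures, to clusters
#'
#' Complete participants go to the nearest centroid (ties to the
#' lowest-index centroid); participants who failed before stage 9 form an
#' additional cluster labelled `K + 1`.
#'
#' @param solution an [fit_kmeans_trajectories()] result.
#' @param trajectories numeric matrix, one row per participant, 9 columns;
#'   rows with any `NA` are treated as failures.
#' @return integer labels in `1..(K+1)`.
#' @export
assign_with_failures <- function(solution, trajectories) {
  stopifnot(inherits(solution, "ied_clusters"))
  trajectories <- as.matrix(trajectories)
  vapply(seq_len(nrow(trajectories)), function(i) {
    x <- trajectories[i, ]
    if (anyNA(x)) return(solution$K + 1L)
    d2 <- colSums((t(solution$centroids) - x)^2)
    which.min(d2)  # which.min takes the first minimum: lowest-index tie-break
  }, integer(1))
}

#' Cluster agreement between human and simulated labelings
#'
#' @param labels_human,labels_simulated integer label vectors over the same
#'   participants and the same label set.
#' @return column-stochastic matrix: entry (r, c) is the proportion of
#'   participants with human label c whose simulated data received label r.
#' @export
cluster_agreement <- function(labels_human, labels_simulated) {
  if (length(labels_human) != length(labels_simulated))
    stop("labelings cover different participants")
  lev <- sort(unique(c(labels_human, labels_simulated)))
  tab <- table(factor(labels_simulated, lev), factor(labels_human, lev))
  counts <- colSums(tab)
  if (any(counts == 0))
    stop("label sets mismatch: empty human cluster ",
         paste(lev[counts == 0], collapse = ", "))
  sweep(unclass(tab), 2, counts, `/`)
}

#' Permutation test for a Spearman correlation
#'
#' Computes the observed Spearman rank correlation, then re-pairs the two
#' series by shuffling one of them `n_iter` times without replacement and
#' recomputes the coefficient. The two-tailed p-value is the smoothed
#' proportion `(b + 1) / (n_iter + 1)` of shuffles whose absolute coefficient
#' meets or exceeds the observed absolute coefficient.
#'
#' @param x,y equal-length numeric vectors, length at least 5, non-constant.
#' @param n_iter number of shuffles.
#' @param seed integer seed.
#' @return list with `rho` and `p`.
#' @export
permutation_pvalue <- function(x, y, n_iter = 10000, seed = 1) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 5) stop("need at least 5 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant series")
  rx <- rank(x); ry <- rank(y)
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  denom <- sqrt(sum(cx^2) * sum(cy^2))   # permutation-invariant
  rho <- sum(cx * cy) / denom
  set.seed(as.integer(seed))
  b <- 0L
  for (i in seq_len(n_iter)) {
    r_star <- sum(cx * cy[sample.int(n)]) / denom
    if (abs(r_star) >= abs(rho) - 1e-12) b <- b + 1L
  }
  list(rho = rho, p = (b + 1) / (n_iter + 1))
}

#' Steiger's Z for two dependent correlations sharing a variable
#'
#' Tests whether the correlation of j with k differs from the correlation of
#' j with h, given the correlation between k and h (Steiger, 1980: Fisher-z
#' difference scaled by the dependent-correlation covariance, pooled-r form).
#' The one-tailed p-value tests the directional hypothesis `r_jk > r_jh`;
#' to compare correlation magnitudes, pass absolute values.
#'
#' @param r_jk,r_jh the two correlations being compared (shared variable j).
#' @param r_kh correlation between the two non-shared variables.
#' @param n sample size (greater than 3).
#' @return list with `Z` (signed as `z(r_jk) - z(r_jh)`) and `p_one_tailed`
#'   (`1 - pnorm(Z)`).
#' @export
steiger_z <- function(r_jk, r_jh, r_kh, n) {
  rs <- c(r_jk, r_jh, r_kh)
  if (any(abs(rs) >= 1)) stop("correlations must lie strictly inside (-1, 1)")
  if (n <= 3) stop("n must exceed 3")
  z1 <- atanh(r_jk); z2 <- atanh(r_jh)
  rbar <- (r_jk + r_jh) / 2
  psi <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)
  s <- psi / (1 - rbar^2)^2
  Z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * s))
  list(Z = Z, p_one_tailed = 1 - pnorm(Z))
}

#' Critical correlation boundary
#'
#' The smallest `|r|` that reaches two-tailed significance at `alpha` in a
#' sample of size `n`, via the t distribution of the correlation test:
#' `r = t / sqrt(t^2 + n - 2)` with `t` the critical value on `n - 2`
#' degrees of freedom.
#'
#' @param n sample size (greater than 3).
#' @param alpha two-tailed significance level.
#' @return scalar critical r.
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (n <= 3) stop("n must exceed 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  t <- qt(1 - alpha / 2, df = n - 2)
  t / sqrt(t^2 + n - 2)
}

#' Minimum reliably detectable correlation
#'
#' Fisher-z power approximation: the smallest population correlation a
#' two-tailed test at `alpha` detects with the given power in a sample of
#' size `n`: `tanh((z_{1-alpha/2} + z_{power}) / sqrt(n - 3))`.
#'
#' @param n sample size (greater than 3).
#' @param alpha two-tailed significance level.
#' @param power target power in (0, 1).
#' @return scalar correlation.
#' @export
min_detectable_r <- function(n, alpha = 0.05, power = 0.95) {
  if (n <= 3) stop("n must exceed 3")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  tanh((qnorm(1 - alpha / 2) + qnorm(power)) / sqrt(n - 3))
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level.
#' @param m number of comparisons (at least 1).
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (m < 1) stop("m must be at least 1")
  alpha / m
}

#' Covariate-adjusted association models
#'
#' Ordinary least squares predicting a symptom total from a model parameter
#' plus covariates, on complete cases (listwise deletion, with the dropped
#' count reported). For each two-level factor covariate a group-difference
#' t-test on the outcome with Cohen's d is attached.
#'
#' @param data data frame holding outcome, predictors and covariates.
#' @param outcome name of the outcome column.
#' @param predictors character vector of predictor column names.
#' @param covariates character vector of covariate column names.
#' @return list with `coefficients` (estimate, 95% CI, t, p), `F`,
#'   `df`, `R2`, `n_used`, `n_dropped`, and `group_tests`.
#' @export
covariate_models <- function(data, outcome, predictors, covariates = character()) {
  vars <- c(outcome, predictors, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  cc <- complete.cases(data[vars])
  d <- data[cc, vars, drop = FALSE]
  form <- stats::reformulate(c(predictors, covariates), response = outcome)
  fit <- lm(form, data = d)
  qrr <- qr(stats::model.matrix(fit))
  if (qrr$rank < ncol(stats::model.matrix(fit)))
    stop("rank-deficient design matrix")
  sm <- summary(fit)
  ci <- confint(fit)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, 1],
                      ci_lower = ci[, 1], ci_upper = ci[, 2],
                      t = sm$coefficients[, 3], p = sm$coefficients[, 4],
                      row.names = NULL)
  fstat <- sm$fstatistic
  group_tests <- list()
  for (cv in covariates) {
    g <- d[[cv]]
    if ((is.factor(g) || is.character(g)) && length(unique(g)) == 2) {
      g <- factor(g)
      tt <- t.test(d[[outcome]] ~ g, var.equal = TRUE)
      x1 <- d[[outcome]][g == levels(g)[1]]
      x2 <- d[[outcome]][g == levels(g)[2]]
      sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x2) - 1) * var(x2)) /
                   (length(x1) + length(x2) - 2))
      group_tests[[cv]] <- list(t = unname(tt$statistic),
                                df = unname(tt$parameter),
                                p = tt$p.value,
                                cohens_d = (mean(x1) - mean(x2)) / sp)
    }
  }
  list(coefficients = coefs,
       F = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
       df = if (is.null(fstat)) c(NA, NA) else unname(fstat[2:3]),
       R2 = sm$r.squared,
       n_used = nrow(d), n_dropped = sum(!cc),
       group_tests = group_tests)
}
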