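# planted three-group trajectory fixture with small within-group noise
planted_trajectories <- function(n_per = 20, noise = 0.3, seed = 5) {
  centers <- rbind(c(1, 1, 0, 0, 1, 0, 1, 0, 1),
                   c(2, 1, 1, 0, 1, 1, 1, 12, 2),
                   c(1, 2, 0, 1, 0, 1, 0, 14, 20))
  set.seed(seed)
  x <- centers[rep(1:3, each = n_per), ] +
    matrix(rnorm(3 * n_per * 9, sd = noise), ncol = 9)
  list(x = pmax(x, 0), truth = rep(1:3, each = n_per))
}

test_that("k-means recovers planted trajectory groups exactly", {
  fx <- planted_trajectories()
  sol <- fit_kmeans_trajectories(fx$x, 3, restarts = 10, seed = 1)
  expect_equal(adjusted_rand_index(sol$labels, fx$truth), 1)
  expect_equal(sol$restarts_used, 10)
  expect_error(fit_kmeans_trajectories(fx$x[, 1:5], 3), "9 stage")
  expect_error(fit_kmeans_trajectories(fx$x, nrow(fx$x) + 1), "exceeds")
  bad <- fx$x; bad[1, 4] <- NA
  expect_error(fit_kmeans_trajectories(bad, 3), "incomplete")
})

test_that("k-means inertia identities hold", {
  fx <- planted_trajectories()
  sol1 <- fit_kmeans_trajectories(fx$x, 1, restarts = 5, seed = 2)
  tss <- sum(scale(fx$x, scale = FALSE)^2)
  expect_equal(sol1$inertia, tss, tolerance = 1e-8)
  # duplicated points: same centroids, doubled inertia
  sol <- fit_kmeans_trajectories(fx$x, 3, restarts = 10, seed = 3)
  sol2 <- fit_kmeans_trajectories(rbind(fx$x, fx$x), 3, restarts = 10,
                                  seed = 3)
  ord <- function(m) m[order(m[, 1], m[, 9]), ]
  expect_equal(ord(sol2$centroids), ord(sol$centroids), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(sol2$inertia, 2 * sol$inertia, tolerance = 1e-6)
})

test_that("the scree is monotone with a sharp elbow at the planted K", {
  fx <- planted_trajectories()
  sc <- scree(fx$x, K_range = 1:8, restarts = 10, seed = 4)
  expect_true(all(diff(sc$inertia) <= 1e-9))
  elbow <- (sc$inertia[2] - sc$inertia[3]) / (sc$inertia[3] - sc$inertia[4])
  expect_gt(elbow, 3)
  scn <- scree(fx$x[1:10, ], K_range = c(2, 10), restarts = 5, seed = 1)
  expect_equal(scn$inertia[scn$K == 10], 0, tolerance = 1e-9)
})

test_that("failure assignment adds cluster K+1 and breaks ties low", {
  fx <- planted_trajectories()
  sol <- fit_kmeans_trajectories(fx$x, 3, restarts = 10, seed = 1)
  withfail <- rbind(fx$x, c(1, 2, 0, 1, 0, 1, 0, 14, NA))
  labs <- assign_with_failures(sol, withfail)
  expect_equal(labs[nrow(withfail)], 4L)
  # each centroid maps to its own cluster
  expect_equal(assign_with_failures(sol, sol$centroids), 1:3)
  # exactly equidistant point goes to the lowest centroid index
  two <- structure(list(K = 2L,
                        centroids = rbind(rep(0, 9), rep(2, 9)),
                        labels = NULL, inertia = 0, restarts_used = 1),
                   class = "ied_clusters")
  expect_equal(assign_with_failures(two, matrix(1, 1, 9)), 1L)
})

test_that("cluster agreement matrices are column-stochastic", {
  expect_equal(cluster_agreement(c(1, 2, 3), c(1, 2, 3)),
               diag(3), ignore_attr = TRUE)
  h <- c(1, 1, 1, 1, 2, 2, 3)
  s <- c(1, 1, 1, 2, 2, 2, 3)
  m <- cluster_agreement(h, s)
  expect_equal(unname(colSums(m)), rep(1, 3))
  expect_equal(unname(m[, 1]), c(0.75, 0.25, 0))
  set.seed(1)
  mr <- cluster_agreement(sample(1:3, 60, TRUE), sample(1:3, 60, TRUE))
  expect_equal(unname(colSums(mr)), rep(1, 3))
  expect_error(cluster_agreement(1:4, 1:3), "different participants")
})

test_that("permutation p-values detect perfect agreement and reject constants", {
  r <- permutation_pvalue(1:100, 1:100, n_iter = 10000, seed = 1)
  expect_equal(r$rho, 1)
  expect_lte(r$p, 0.001)
  expect_error(permutation_pvalue(rep(1, 10), 1:10), "constant")
  expect_error(permutation_pvalue(1:4, 1:4), "at least 5")
  expect_error(permutation_pvalue(1:10, 1:9), "equal length")
})

test_that("permutation p-values are calibrated and monotone-invariant", {
  set.seed(22)
  ps <- vapply(1:200, function(i)
    permutation_pvalue(rnorm(200), rnorm(200), n_iter = 199,
                       seed = i)$p, numeric(1))
  expect_gt(mean(ps), 0.45)
  expect_lt(mean(ps), 0.55)
  # Spearman is a rank statistic: strictly monotone transforms change nothing
  set.seed(8)
  x <- rnorm(40); y <- x + rnorm(40)
  a <- permutation_pvalue(x, y, n_iter = 500, seed = 3)
  b <- permutation_pvalue(exp(x), rank(y)^3, n_iter = 500, seed = 3)
  expect_identical(a, b)
})

test_that("Steiger's Z is zero at equality, antisymmetric, and calibrated", {
  expect_equal(steiger_z(0.4, 0.4, 0.3, 100)$Z, 0)
  a <- steiger_z(0.5, 0.2, 0.3, 150)
  b <- steiger_z(0.2, 0.5, 0.3, 150)
  expect_equal(a$Z, -b$Z)
  expect_equal(a$p_one_tailed, 1 - b$p_one_tailed)
  expect_error(steiger_z(1, 0.5, 0.2, 50), "inside")
  expect_error(steiger_z(0.5, 0.4, 0.2, 3), "exceed")
  # null calibration: equal true correlations in a trivariate normal
  set.seed(31)
  n <- 200
  rej <- 0
  for (i in 1:2000) {
    z <- rnorm(n)
    k <- 0.4 * z + sqrt(1 - 0.16) * rnorm(n)
    h <- 0.4 * z + sqrt(1 - 0.16) * rnorm(n)
    st <- steiger_z(cor(z, k), cor(z, h), cor(k, h), n)
    if (st$p_one_tailed < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 2000, 0.03)
  expect_lte(rej / 2000, 0.07)
})

test_that("critical and minimum-detectable correlations match their formulas", {
  expect_equal(round(critical_r(730, 0.05), 3), 0.073)
  expect_equal(critical_r(4, 0.05), 0.950, tolerance = 1e-3)
  n_grid <- c(10, 30, 100, 500, 2000)
  expect_true(all(diff(vapply(n_grid, critical_r, numeric(1),
                              alpha = 0.05)) < 0))
  expect_equal(round(min_detectable_r(730, 0.05, 0.95), 2), 0.13)
  expect_equal(min_detectable_r(50, 0.05, 0.95), 0.482, tolerance = 1e-3)
  expect_equal(min_detectable_r(100, 0.05, 0.5 + 1e-12),
               tanh(qnorm(0.975) / sqrt(97)), tolerance = 1e-6)
  expect_error(critical_r(3), "exceed")
  expect_error(min_detectable_r(100, 0.05, 1.2), "in \\(0, 1\\)")
})

test_that("the power boundaries agree with brute-force simulation", {
  # type-I error of the |r| > critical_r rule and power at min_detectable_r,
  # each within +/- 0.01 of nominal over 50,000 replicates
  n <- 200
  rc <- critical_r(n, 0.05)
  rm <- min_detectable_r(n, 0.05, 0.8)
  set.seed(77)
  B <- 50000
  x <- matrix(rnorm(B * n), n, B)
  y0 <- matrix(rnorm(B * n), n, B)
  colcor <- function(a, b) {
    a <- scale(a); b <- scale(b)
    colSums(a * b) / (n - 1)
  }
  type1 <- mean(abs(colcor(x, y0)) > rc)
  expect_lt(abs(type1 - 0.05), 0.01)
  y1 <- rm * scale(x) + sqrt(1 - rm^2) * matrix(rnorm(B * n), n, B)
  power <- mean(abs(colcor(x, y1)) > rc)
  expect_lt(abs(power - 0.8), 0.015)
})

test_that("bonferroni adjustment is plain division", {
  expect_equal(bonferroni_alpha(0.05, 15), 0.05 / 15)
  expect_equal(round(bonferroni_alpha(0.05, 15), 4), 0.0033)
  expect_equal(bonferroni_alpha(0.07, 1), 0.07)
  expect_equal(round(bonferroni_alpha(0.05, 9), 5), 0.00556)
  expect_error(bonferroni_alpha(0.05, 0), "at least 1")
})

test_that("covariate models solve the normal equations and report diagnostics", {
  # exact fit
  d <- data.frame(sym = 2 * c(1, 2, 3, 4, 5, 6), par = c(1, 2, 3, 4, 5, 6))
  m <- suppressWarnings(covariate_models(d, "sym", "par"))  # exact fit
  expect_equal(m$R2, 1)
  expect_equal(m$coefficients$estimate[2], 2, tolerance = 1e-10)
  # 6-row fixture against a hand solve of the normal equations
  set.seed(12)
  d2 <- data.frame(sym = rnorm(6), par = rnorm(6), age = rnorm(6))
  m2 <- covariate_models(d2, "sym", "par", "age")
  X <- cbind(1, d2$par, d2$age)
  beta_hat <- solve(t(X) %*% X, t(X) %*% d2$sym)
  expect_equal(m2$coefficients$estimate, as.vector(beta_hat),
               tolerance = 1e-10)
  # binary covariate: group t-test with Cohen's d
  set.seed(13)
  d3 <- data.frame(sym = rnorm(80), par = rnorm(80),
                   gender = rep(c("female", "male"), 40))
  m3 <- covariate_models(d3, "sym", "par", "gender")
  expect_true("gender" %in% names(m3$group_tests))
  expect_true(is.finite(m3$group_tests$gender$cohens_d))
  # listwise deletion is logged
  d3$par[3] <- NA
  m4 <- covariate_models(d3, "sym", "par", "gender")
  expect_equal(m4$n_dropped, 1)
  expect_equal(m4$n_used, 79)
  # rank deficiency rejected
  d5 <- data.frame(sym = rnorm(10), a = 1:10, b = 2 * (1:10))
  expect_error(covariate_models(d5, "sym", c("a", "b")), "rank-deficient")
})

test_that("null covariate models have calibrated coefficient p-values", {
  set.seed(44)
  ps <- vapply(1:200, function(i) {
    d <- data.frame(sym = rnorm(60), par = rnorm(60))
    covariate_models(d, "sym", "par")$coefficients$p[2]
  }, numeric(1))
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})
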