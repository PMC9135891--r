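test_that("cluster sandwich matches the brute-force oracle on a toy fixture", {
  y <- c(1.2, 0.7, -0.3, 2.1, 1.8, -0.9)
  x <- c(0.5, -0.2, 1.1, 0.4, -0.8, 0.9)
  cl <- c("a", "a", "b", "b", "c", "c")
  fit <- fit_clustered_ols(y, cbind(x = x), cl)
  oracle <- oracle_cluster_vcov(cbind(1, x), y, cl)
  expect_equal(fit$table$estimate, unname(oracle$beta), tolerance = 1e-10)
  expect_equal(fit$table$se, unname(sqrt(diag(oracle$vcov))),
               tolerance = 1e-10)
  expect_equal(fit$n_clusters, 3)
  tq <- qt(0.975, 2)
  expect_equal(fit$table$ci_low, fit$table$estimate - tq * fit$table$se,
               tolerance = 1e-12)
})

test_that("singleton clusters reduce to HC1 heteroskedasticity-robust SEs", {
  withr::local_seed(10)
  n <- 40
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n) * (1 + abs(x))
  fit <- fit_clustered_ols(y, cbind(x = x), cluster_ids = seq_len(n))
  X <- cbind(1, x)
  bread <- solve(t(X) %*% X)
  e <- drop(y - X %*% bread %*% t(X) %*% y)
  hc1 <- n / (n - 2) * bread %*% (t(X) %*% (e^2 * X)) %*% bread
  # the G/(G-1)*(N-1)/(N-k) factor equals HC1's N/(N-k) when G = N
  expect_equal(fit$table$se, unname(sqrt(diag(hc1))), tolerance = 1e-10)
})

test_that("duplicating every cluster leaves point estimates unchanged", {
  withr::local_seed(11)
  y <- rnorm(30)
  x <- rnorm(30)
  cl <- rep(1:15, each = 2)
  f1 <- fit_clustered_ols(y, cbind(x = x), cl)
  f2 <- fit_clustered_ols(c(y, y), cbind(x = c(x, x)), c(cl, cl + 100))
  expect_equal(f1$table$estimate, f2$table$estimate, tolerance = 1e-10)
})

test_that("rank-deficient designs and single clusters fail with named causes", {
  y <- rnorm(10)
  x <- rnorm(10)
  expect_error(fit_clustered_ols(y, cbind(a = x, b = 2 * x), rep(1:5, 2)),
               "collinear.*b")
  expect_error(fit_clustered_ols(y, cbind(x = x), rep(1, 10)),
               "at least 2 clusters")
})

test_that("cluster-robust SEs exceed classical SEs under within-pair correlation", {
  withr::local_seed(12)
  wider <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    cl <- rep(1:100, each = 2)
    u <- rnorm(100)[cl]          # shared pair effect
    x <- rnorm(100)[cl]          # cluster-constant predictor
    y <- 0.3 * x + u + rnorm(200, sd = 0.5)
    fit <- fit_clustered_ols(y, cbind(x = x), cl)
    cls <- summary(fit$fit)$coefficients["x", "Std. Error"]
    if (fit$table$se[fit$table$term == "x"] > cls) wider <- wider + 1
  }
  expect_gt(wider / reps, 0.95)
})

test_that("standardized associations are SD-per-SD and scale invariant", {
  cfg <- bivariate_config(a2 = 0.5, rA = 0.4, rE = 0.2,
                          n_mz_pairs = 400, n_dz_pairs = 400, seed = 20)
  co <- generate_cohort(cfg)
  # regressing a variable on itself is a legitimate degenerate case; the
  # perfect-fit warning from the sandwich machinery is expected
  self <- suppressWarnings(
    standardized_association(co, "trait1", "trait1", sex = "both")
  )
  expect_equal(self$standardized_beta, 1, tolerance = 1e-12)
  expect_gt(self$ci_low, 0)

  res <- standardized_association(co, "trait1", "trait2", sex = "male")
  co2 <- co
  co2$trait1 <- co2$trait1 * 37.2
  res2 <- standardized_association(co2, "trait1", "trait2", sex = "male")
  expect_equal(res$standardized_beta, res2$standardized_beta,
               tolerance = 1e-10)
  expect_equal(res$se, res2$se, tolerance = 1e-10)
})

test_that("fully baseline-mediated associations vanish after adjustment", {
  rho1 <- -0.28; rho2 <- 0.70
  R <- matrix(c(1, rho1, rho1 * rho2,
                rho1, 1, rho2,
                rho1 * rho2, rho2, 1), 3, byrow = TRUE)
  co <- generate_cohort(mediation_config(R, n_mz_pairs = 1000,
                                         n_dz_pairs = 1000, seed = 23))
  unadj <- standardized_association(co, "pa", "bmi18", sex = "both")
  adj <- standardized_association(co, "pa", "bmi18", adjust_for = "bmi16",
                                  sex = "both")
  expect_lt(abs(adj$standardized_beta), 0.03)
  expect_gt(abs(unadj$standardized_beta), 0.1)
})

test_that("a direct path survives baseline adjustment at its generating size", {
  rho1 <- -0.28; rho2 <- 0.70; direct <- 0.06
  r13 <- rho1 * rho2 + direct * (1 - rho1^2)
  R <- matrix(c(1, rho1, r13,
                rho1, 1, rho2,
                r13, rho2, 1), 3, byrow = TRUE)
  co <- generate_cohort(mediation_config(R, n_mz_pairs = 1000,
                                         n_dz_pairs = 1000, seed = 24))
  adj <- standardized_association(co, "pa", "bmi18", adjust_for = "bmi16",
                                  sex = "both")
  expect_lt(abs(adj$standardized_beta - direct), 0.03)
})

test_that("pgs_association validates principal-component columns", {
  pgs <- tibble::tibble(pgs = "wc", target = "trait1", r2 = 0.05)
  cfg <- bivariate_config(traits = "trait1", a2 = 0.5, c2 = 0, e2 = 0.5,
                          rA = 1, n_mz_pairs = 300, n_dz_pairs = 300,
                          pgs = pgs, n_pcs = 3, seed = 25)
  co <- generate_cohort(cfg)
  expect_error(pgs_association(co, "wc", "trait1", n_pcs = 10),
               "pc4")
  res <- pgs_association(co, "wc", "trait1", n_pcs = 3)
  expect_s3_class(res, "regression_result")
  expect_error(pgs_association(co, "nope", "trait1", n_pcs = 3),
               "pgs_nope")
})

test_that("pure-noise principal components barely move the PGS coefficient", {
  pgs <- tibble::tibble(pgs = "wc", target = "trait1", r2 = 0.04)
  cfg <- bivariate_config(traits = "trait1", a2 = 0.5, c2 = 0, e2 = 0.5,
                          rA = 1, n_mz_pairs = 1500, n_dz_pairs = 1500,
                          pgs = pgs, n_pcs = 10, seed = 26)
  co <- generate_cohort(cfg)
  with_pcs <- pgs_association(co, "wc", "trait1", n_pcs = 10)
  without <- pgs_association(co, "wc", "trait1", n_pcs = 0)
  expect_lt(abs(with_pcs$standardized_beta - without$standardized_beta), 0.01)
  expect_lt(abs(with_pcs$standardized_beta - 0.2), 0.05)
})
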