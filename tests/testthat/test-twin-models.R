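test_that("expected pair covariance follows the twin sharing coefficients", {
  p <- cholesky_params("AE", c("t1", "t2"), a = diag(2), e = diag(2))
  mz <- expected_pair_covariance(p, "MZ")
  expect_equal(mz[1:2, 1:2], 2 * diag(2))
  expect_equal(mz[1:2, 3:4], diag(2))
  dz <- expected_pair_covariance(p, "DZ")
  expect_equal(dz[1:2, 3:4], 0.5 * diag(2))

  # dominance shares 1.0 in MZ and 0.25 in DZ
  pd <- cholesky_params("ADE", c("t1", "t2"), a = 1e-8 * diag(2),
                        d = diag(2), e = diag(2))
  dzd <- expected_pair_covariance(pd, "DZ")
  expect_equal(dzd[1:2, 3:4], 0.25 * diag(2), tolerance = 1e-10)
  expect_error(expected_pair_covariance(p, "MZ", model = "ACE"),
               "does not match")
})

test_that("pair_loglik equals a dense multivariate-normal oracle", {
  withr::local_seed(100)
  for (i in 1:20) {
    model <- sample(c("ACE", "ADE", "AE"), 1)
    params <- random_params(model)
    zyg <- sample(c("MZ", "DZ"), 1)
    y <- rnorm(4)
    y[sample(4, sample(0:2, 1))] <- NA
    if (all(is.na(y))) y[1] <- rnorm(1)
    got <- pair_loglik(params, make_pair(zyg, y))
    want <- oracle_mvn_loglik(y, rep(params$means, 2),
                              expected_pair_covariance(params, zyg))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("a pair with one member missing contributes the observed marginal", {
  params <- cholesky_params("AE", c("t1", "t2"),
                            a = c(0.8, 0.3, 0.6), e = c(0.7, 0.1, 0.5),
                            means = c(0.2, -0.1))
  y <- c(0.5, -0.4, NA, NA)
  full <- pair_loglik(params, make_pair("MZ", y))
  V <- expected_pair_covariance(params, "MZ")[1:2, 1:2]
  marg <- oracle_mvn_loglik(c(0.5, -0.4), params$means, V)
  expect_equal(full, marg, tolerance = 1e-10)
})

test_that("inflating E lowers the density at the mode", {
  params <- cholesky_params("AE", c("t1", "t2"),
                            a = c(0.8, 0.2, 0.7), e = c(0.6, 0.1, 0.5))
  wide <- cholesky_params("AE", c("t1", "t2"),
                          a = c(0.8, 0.2, 0.7),
                          e = sqrt(2) * c(0.6, 0.1, 0.5))
  at_mode <- make_pair("MZ", rep(0, 4))
  expect_gt(pair_loglik(params, at_mode), pair_loglik(wide, at_mode))
})

test_that("the grouped FIML objective equals the per-pair likelihood sum", {
  cfg <- bivariate_config(a2 = 0.5, rA = 0.3, rE = 0.1,
                          n_mz_pairs = 60, n_dz_pairs = 60, seed = 4)
  co <- generate_cohort(cfg)
  # punch some holes so missingness patterns are exercised
  co$trait1[c(2, 15, 40)] <- NA
  co$trait2[c(5, 15, 77)] <- NA
  prep <- pubertwin:::prepare_pair_data(co, c("trait1", "trait2"))
  groups <- pubertwin:::build_groups(prep)
  tmpl <- pubertwin:::par_template("AE", 2)
  fns <- pubertwin:::make_fiml_objective(groups, tmpl)
  params <- random_params("AE")
  par <- pubertwin:::pack_params(params, tmpl)
  per_pair <- sum(vapply(seq_len(nrow(prep$Y)), function(i) {
    pair_loglik(params, make_pair(prep$zyg[i], prep$Y[i, ]))
  }, numeric(1)))
  expect_equal(-fns$objective(par), per_pair, tolerance = 1e-8)
})

test_that("the analytic FIML gradient matches finite differences", {
  cfg <- bivariate_config(a2 = 0.6, c2 = 0.1, rA = 0.4, rE = -0.1,
                          n_mz_pairs = 80, n_dz_pairs = 80, seed = 6)
  co <- generate_cohort(cfg)
  co$trait2[seq(1, 40, by = 3)] <- NA
  prep <- pubertwin:::prepare_pair_data(co, c("trait1", "trait2"))
  groups <- pubertwin:::build_groups(prep)
  for (model in c("ACE", "AE")) {
    tmpl <- pubertwin:::par_template(model, 2)
    fns <- pubertwin:::make_fiml_objective(groups, tmpl)
    par <- pubertwin:::pack_params(random_params(model), tmpl)
    g_num <- vapply(seq_along(par), function(i) {
      h <- 1e-6 * (abs(par[i]) + 1)
      pp <- par; pp[i] <- par[i] + h
      pm <- par; pm[i] <- par[i] - h
      (fns$objective(pp) - fns$objective(pm)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(fns$gradient(par) - g_num)) /
                max(1, max(abs(g_num))), 1e-5)
  }
})

test_that("component correlations are the scaled off-diagonals and scale-free", {
  p <- cholesky_params("AE", c("t1", "t2"), a = diag(2), e = diag(2))
  covs <- component_covariances(p)
  covs$A <- matrix(c(1, 0.49, 0.49, 1), 2)
  expect_equal(genetic_correlation(covs, "A"), 0.49)
  scaled <- covs
  s <- 3.7
  scaled$A <- covs$A * tcrossprod(c(1, s))
  expect_equal(genetic_correlation(scaled, "A"),
               genetic_correlation(covs, "A"), tolerance = 1e-12)
  covs$A <- matrix(c(0, 0, 0, 1), 2)
  expect_error(genetic_correlation(covs, "A"), "undefined")
})

test_that("trait-correlation decomposition closes to 100% with signed shares", {
  # components contributing +0.20 and -0.01 to r = 0.19
  p <- cholesky_params("AE", c("t1", "t2"), a = diag(2), e = diag(2))
  covs <- component_covariances(p)
  covs$V <- matrix(c(1, 0.19, 0.19, 1), 2)
  covs$A <- matrix(c(0.5, 0.20, 0.20, 0.5), 2)
  covs$E <- matrix(c(0.5, -0.01, -0.01, 0.5), 2)
  dec <- decompose_trait_correlation(covs)
  expect_equal(dec$percent[dec$component == "A"], 100 * 0.20 / 0.19)
  expect_equal(dec$percent[dec$component == "E"], -100 * 0.01 / 0.19)
  expect_equal(sum(dec$percent), 100, tolerance = 1e-10)

  covs$E <- matrix(c(0.5, 0, 0, 0.5), 2)
  covs$V <- covs$A + covs$E
  dec0 <- decompose_trait_correlation(covs)
  expect_equal(dec0$percent, c(100, 0))
})

test_that("shared variance fraction is the squared component correlation", {
  expect_equal(shared_variance_fraction(0), 0)
  expect_equal(shared_variance_fraction(c(-1, 1)), c(1, 1))
  expect_equal(shared_variance_fraction(0.5), 0.25)
})

test_that("bonferroni_threshold divides alpha by the test count", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
  expect_error(bonferroni_threshold(1.2, 4))
})

test_that("comparing a model with itself gives a null LRT", {
  cfg <- bivariate_config(a2 = 0.5, rA = 0.3, n_mz_pairs = 200,
                          n_dz_pairs = 200, seed = 22)
  co <- generate_cohort(cfg)
  ae <- fit_bivariate(co, "trait1", "trait2", model = "AE", se = FALSE)
  same <- ae
  same$n_params <- ae$n_params - 1  # pretend-nested copy of the same fit
  cmp <- compare_models(ae, same)
  expect_equal(cmp$lrt_statistic, 0, tolerance = 1e-8)
  expect_equal(cmp$p_value, 1)
  expect_error(compare_models(same, ae), "fewer parameters")
})

test_that("an E-only generating model is recovered as near-zero heritability", {
  cfg <- bivariate_config(a2 = 0, c2 = 0, e2 = 1, rA = 0, rE = 0.3,
                          n_mz_pairs = 1000, n_dz_pairs = 1000, seed = 33)
  co <- generate_cohort(cfg)
  fit <- fit_bivariate(co, "trait1", "trait2", model = "AE", se = FALSE)
  covs <- fit$component_covariances
  expect_lt(covs$A[1, 1] / covs$V[1, 1], 0.05)
  expect_lt(covs$A[2, 2] / covs$V[2, 2], 0.05)
})

test_that("fits are invariant to trait ordering", {
  cfg <- bivariate_config(a2 = c(0.5, 0.6), c2 = 0, e2 = c(0.5, 0.4),
                          rA = 0.5, rE = 0.15,
                          n_mz_pairs = 1500, n_dz_pairs = 1500, seed = 44)
  co <- generate_cohort(cfg)
  f12 <- fit_bivariate(co, "trait1", "trait2", model = "AE", se = FALSE)
  f21 <- fit_bivariate(co, "trait2", "trait1", model = "AE", se = FALSE)
  expect_equal(f12$loglik, f21$loglik, tolerance = 1e-6)
  expect_lt(abs(f12$correlations$rA$estimate -
                  f21$correlations$rA$estimate), 1e-5)
  expect_lt(abs(f12$correlations$rE$estimate -
                  f21$correlations$rE$estimate), 1e-5)
  perm <- c(2, 1)
  expect_lt(max(abs(f12$component_covariances$A -
                      f21$component_covariances$A[perm, perm])), 1e-4)
  expect_lt(max(abs(f12$component_covariances$E -
                      f21$component_covariances$E[perm, perm])), 1e-4)
})

test_that("the ML heritability agrees with the Falconer approximation", {
  cfg <- bivariate_config(traits = "trait1", a2 = 0.5, c2 = 0.2, e2 = 0.3,
                          rA = 1, n_mz_pairs = 5000, n_dz_pairs = 5000,
                          seed = 55)
  co <- generate_cohort(cfg)
  icc <- icc_by_zygosity(co, "trait1")
  falconer <- 2 * (icc["MZ"] - icc["DZ"])
  fit <- fit_univariate(co, "trait1", model = "ACE", se = FALSE)
  expect_lt(abs(fit$variance_fractions[["a2"]] - falconer), 0.05)
})

test_that("fitting fails informatively with too few pairs", {
  cfg <- bivariate_config(n_mz_pairs = 10, n_dz_pairs = 10, seed = 66)
  co <- generate_cohort(cfg)
  expect_error(fit_bivariate(co, "trait1", "trait2", model = "AE"),
               "fewer than 30 pairs")
})
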