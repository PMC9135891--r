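test_that("cohorts are deterministic in the seed and differ across seeds", {
  cfg <- bivariate_config(n_mz_pairs = 50, n_dz_pairs = 50, seed = 101)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  cfg2 <- bivariate_config(n_mz_pairs = 50, n_dz_pairs = 50, seed = 102)
  expect_false(identical(as.data.frame(a)$trait1,
                         as.data.frame(generate_cohort(cfg2))$trait1))
})

test_that("pair structure is consistent: shared zygosity, sex and ages", {
  co <- generate_cohort(twin_cohort_config(n_mz_pairs = 60, n_dz_pairs = 60,
                                           seed = 5))
  per_pair <- split(as.data.frame(co), co$pair_id)
  expect_true(all(vapply(per_pair, function(p) {
    nrow(p) == 2 && length(unique(p$zygosity)) == 1 &&
      length(unique(p$sex)) == 1 && all(p$age_12[1] == p$age_12)
  }, logical(1))))
  expect_false(anyDuplicated(co$pair_id[co$member == 1]) > 0)
})

test_that("a purely additive trait is identical within MZ pairs", {
  cfg <- bivariate_config(traits = "trait1", a2 = 1, c2 = 0, e2 = 0,
                          rA = 1, n_mz_pairs = 40, n_dz_pairs = 40, seed = 3)
  co <- generate_cohort(cfg)
  m1 <- co[co$member == 1 & co$zygosity == "MZ", ]
  m2 <- co[co$member == 2 & co$zygosity == "MZ", ]
  m2 <- m2[match(m1$pair_id, m2$pair_id), ]
  expect_equal(m1$trait1, m2$trait1, tolerance = 1e-12)
})

test_that("twin correlations track the ACE expectations", {
  cfg <- bivariate_config(traits = "trait1", a2 = 0.5, c2 = 0.1, e2 = 0.4,
                          rA = 1, n_mz_pairs = 4000, n_dz_pairs = 4000,
                          seed = 8)
  icc <- icc_by_zygosity(generate_cohort(cfg), "trait1")
  expect_lt(abs(icc[["MZ"]] - 0.6), 0.04)
  expect_lt(abs(icc[["DZ"]] - 0.35), 0.04)
})

test_that("cross-trait cross-twin covariance matches the component blocks", {
  cfg <- bivariate_config(a2 = 0.6, c2 = 0.2, e2 = 0.2, rA = 0.4, rC = 0.3,
                          rE = 0.1, n_mz_pairs = 8000, n_dz_pairs = 8000,
                          seed = 21)
  co <- generate_cohort(cfg)
  m1 <- co[co$member == 1, ]
  m2 <- co[co$member == 2, ]
  m2 <- m2[match(m1$pair_id, m2$pair_id), ]
  cross <- function(z) {
    idx <- m1$zygosity == z
    cov(m1$trait1[idx], m2$trait2[idx])
  }
  a12 <- 0.6 * 0.4
  c12 <- 0.2 * 0.3
  expect_lt(abs(cross("MZ") - (a12 + c12)), 0.03)
  expect_lt(abs(cross("DZ") - (0.5 * a12 + c12)), 0.03)
})

test_that("non-PSD cross-trait correlation structures are rejected with a named block", {
  R <- matrix(c(1, 0.9, 0.9,
                0.9, 1, -0.9,
                0.9, -0.9, 1), 3, byrow = TRUE)
  expect_error(
    bivariate_config(traits = c("t1", "t2", "t3"), a2 = 1, c2 = 0, e2 = 0,
                     rA = R),
    "positive semidefinite"
  )
})

test_that("apply_skew is the identity at lambda 0 and preserves moments", {
  x <- rnorm(500, mean = 20, sd = 3)
  expect_identical(apply_skew(x, 0), x)
  y <- apply_skew(x, 0.6)
  expect_lt(abs(mean(y) - mean(x)), 1e-6)
  expect_lt(abs(sd(y) - sd(x)), 1e-6)
  expect_gt(sample_skewness(y), 0.5)
  expect_true(all(diff(y[order(x)]) >= 0))  # monotone in the input
})

test_that("log transform reduces the skewness that the tilt induces", {
  withr::local_seed(42)
  x <- rnorm(5000, mean = 20, sd = 2.5)
  y <- apply_skew(x, 0.45)
  expect_lt(sample_skewness(log(y)), sample_skewness(y))
})

test_that("censor_pa implements right-censoring at the given age", {
  out <- censor_pa(c(12.5, 18.2), 17)
  expect_equal(out$pa, c(12.5, 17.0))
  expect_equal(out$censored, c(FALSE, TRUE))
  low <- censor_pa(c(10, 13, 16.9), 17)
  expect_equal(low$pa, c(10, 13, 16.9))
  expect_false(any(low$censored))
  nas <- censor_pa(c(NA, 18), 17)
  expect_true(is.na(nas$pa[1]) && nas$censored[2])
})

test_that("censoring fraction matches the normal upper-tail probability", {
  tr <- trait_defaults()[trait_defaults()$trait == "pa", ]
  tr$miss <- 0
  cfg <- twin_cohort_config(n_mz_pairs = 30000, n_dz_pairs = 30000,
                            sex_ratio = 0, traits = tr,
                            RA = diag(1), RC = diag(1), RE = diag(1),
                            pgs = pgs_defaults()[0, ], n_pcs = 0, seed = 77)
  co <- generate_cohort(cfg)
  frac <- mean(co$pa_censored)
  p_tail <- pnorm((17 - 12.8) / 1.18, lower.tail = FALSE)
  # binomial Monte-Carlo error at n = 120,000 individuals
  expect_lt(abs(frac - p_tail), 4 * sqrt(p_tail * (1 - p_tail) / nrow(co)) + 1e-4)
})

test_that("polygenic scores are genome-determined and hit their target R2", {
  pgs <- tibble::tibble(pgs = "bmi", target = "trait1", r2 = 0.10)
  cfg <- bivariate_config(traits = "trait1", a2 = 0.5, c2 = 0, e2 = 0.5,
                          rA = 1, n_mz_pairs = 2500, n_dz_pairs = 2500,
                          pgs = pgs, seed = 12)
  co <- generate_cohort(cfg)
  m1 <- co[co$member == 1 & co$zygosity == "MZ", ]
  m2 <- co[co$member == 2 & co$zygosity == "MZ", ]
  m2 <- m2[match(m1$pair_id, m2$pair_id), ]
  expect_identical(m1$pgs_bmi, m2$pgs_bmi)
  expect_lt(abs(cor(co$pgs_bmi, co$trait1)^2 - 0.10), 0.01)
  d1 <- co[co$member == 1 & co$zygosity == "DZ", ]
  d2 <- co[co$member == 2 & co$zygosity == "DZ", ]
  d2 <- d2[match(d1$pair_id, d2$pair_id), ]
  expect_lt(abs(cor(d1$pgs_bmi, d2$pgs_bmi) - 0.5), 0.05)
})

test_that("a null polygenic score is uncorrelated with its target", {
  pgs <- tibble::tibble(pgs = "whr", target = "trait1", r2 = 0)
  cfg <- bivariate_config(traits = "trait1", a2 = 0.5, c2 = 0, e2 = 0.5,
                          rA = 1, n_mz_pairs = 2500, n_dz_pairs = 2500,
                          pgs = pgs, seed = 13)
  co <- generate_cohort(cfg)
  expect_lt(abs(cor(co$pgs_whr, co$trait1)), 0.03)
})

test_that("default-scale cohorts reproduce the configured raw moments", {
  cfg <- twin_cohort_config(n_mz_pairs = 1250, n_dz_pairs = 1250,
                            sex_ratio = 0.5, seed = 31)
  co <- generate_cohort(cfg)
  male_bmi12 <- co$bmi12[co$sex == "male" & !is.na(co$bmi12)]
  expect_lt(abs(mean(male_bmi12) - 17.7), 0.2)
  expect_lt(abs(sd(male_bmi12) - 2.55), 0.2)
})
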