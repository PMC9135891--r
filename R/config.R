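#' Default trait panel for the simulated twin cohort
#'
#' One row per phenotype wave: puberty indices (PDS at 12 and 14 on the
#' 1--4 mean-item scale, retrospective pubertal age in years) and BMI
#' (kg/m^2) from early adolescence to mid-adulthood. Columns give the
#' variance-component fractions used on the standardized latent scale
#' (`a2` additive genetic, `c2` shared environment, `e2` unique
#' environment), sex-specific means and SDs on the raw scale, the nominal
#' age of the survey wave, a per-year age slope on the raw scale, and the
#' marginal probability that the measurement is missing (MCAR attrition).
#'
#' Means and SDs default to values typical of Finnish adolescent twin
#' cohorts (e.g. male BMI at 12 years: mean 17.7, SD 2.55); variance
#' components reflect the literature consensus of moderate-to-high BMI
#' heritability with shared environment fading after mid-adolescence.
#'
#' @return A tibble with columns `trait`, `type`, `wave_age`, `a2`, `c2`,
#'   `e2`, `mean_male`, `sd_male`, `mean_female`, `sd_female`,
#'   `age_slope`, `miss`.
#' @export
trait_defaults <- function() {
  tibble::tribble(
    ~trait,   ~type,  ~wave_age, ~a2,  ~c2,  ~e2,  ~mean_male, ~sd_male, ~mean_female, ~sd_female, ~age_slope, ~miss,
    "pds12",  "pds",  12,        0.55, 0.20, 0.25, 1.30,       0.26,     1.67,         0.44,       0.30,       0.03,
    "pds14",  "pds",  14,        0.55, 0.15, 0.30, 2.02,       0.48,     2.82,         0.53,       0.40,       0.12,
    "pa",     "pa",   17,        0.60, 0.00, 0.40, 13.9,       1.25,     12.8,         1.18,       0.00,       0.12,
    "bmi12",  "bmi",  12,        0.60, 0.20, 0.20, 17.7,       2.55,     17.5,         2.57,       0.80,       0.03,
    "bmi14",  "bmi",  14,        0.65, 0.15, 0.20, 19.3,       2.69,     19.4,         2.71,       0.80,       0.11,
    "bmi16",  "bmi",  16,        0.70, 0.10, 0.20, 20.4,       2.22,     20.3,         2.43,       0.60,       0.12,
    "bmi17",  "bmi",  17,        0.75, 0.00, 0.25, 21.1,       2.36,     20.5,         2.45,       0.60,       0.18,
    "bmi18",  "bmi",  18,        0.75, 0.00, 0.25, 21.8,       2.50,     20.9,         2.67,       0.50,       0.13,
    "bmi24",  "bmi",  24,        0.75, 0.00, 0.25, 24.3,       3.50,     22.8,         3.94,       0.30,       0.35,
    "bmi25",  "bmi",  25,        0.75, 0.00, 0.25, 23.8,       3.10,     22.2,         3.39,       0.30,       0.12,
    "bmi35",  "bmi",  35,        0.75, 0.00, 0.25, 25.7,       3.52,     23.9,         4.38,       0.20,       0.05
  )
}

# Two-domain factor structure (puberty vs adiposity) that yields positive
# semidefinite cross-trait component correlation matrices at the magnitudes
# reported for Finnish twin cohorts: within-domain genetic correlations around
# 0.5 for puberty indices, 0.2--0.3 (negative for pubertal age) between
# puberty and adolescent BMI.
default_component_correlations <- function(traits) {
  puberty <- c(pds12 = 0.70, pds14 = 0.78, pa = -0.75)
  stopifnot(all(traits %in% c(names(puberty),
                              paste0("bmi", c(12, 14, 16, 17, 18, 24, 25, 35)))))
  domain <- ifelse(traits %in% names(puberty), "pub", "adi")
  load_a <- ifelse(domain == "pub", puberty[traits],
                   c(bmi12 = 0.80, bmi14 = 0.85, bmi16 = 0.85, bmi17 = 0.85,
                     bmi18 = 0.85, bmi24 = 0.80, bmi25 = 0.80, bmi35 = 0.75)[traits])
  load_c <- ifelse(domain == "pub", sign(load_a) * 0.50, 0.60)
  load_e <- ifelse(domain == "pub", sign(load_a) * 0.35, 0.45)
  list(
    RA = factor_correlation(load_a, domain, rho = 0.40, traits),
    RC = factor_correlation(load_c, domain, rho = 0.30, traits),
    RE = factor_correlation(load_e, domain, rho = 0.25, traits)
  )
}

# One loading per trait on its domain factor; domains correlate rho.
# R = L Phi L' + diag(1 - diag(L Phi L')) is a valid correlation matrix
# whenever |loadings| < 1.
factor_correlation <- function(loadings, domain, rho, traits) {
  L <- matrix(0, length(loadings), 2,
              dimnames = list(traits, c("pub", "adi")))
  L[cbind(seq_along(loadings), match(domain, colnames(L)))] <- loadings
  Phi <- matrix(c(1, rho, rho, 1), 2)
  R <- L %*% Phi %*% t(L)
  diag(R) <- 1
  R
}

#' Default polygenic-score panel
#'
#' Three latent polygenic scores mirroring common obesity-index GWAS
#' instruments: BMI, waist circumference (WC), and waist-to-hip ratio
#' adjusted for BMI (WHR). Each score is tied to the additive-genetic
#' latent value of a target trait with a configurable in-sample R-squared;
#' the WHR score is a null instrument by default.
#'
#' @return A tibble with columns `pgs` (column suffix), `target` (trait
#'   whose additive-genetic latent the score tags) and `r2` (squared
#'   correlation between the score and the target trait).
#' @export
pgs_defaults <- function() {
  tibble::tibble(
    pgs = c("bmi", "wc", "whr"),
    target = c("bmi16", "bmi16", "bmi16"),
    r2 = c(0.10, 0.08, 0.00)
  )
}

#' Configure the synthetic twin-cohort generator
#'
#' Assembles and validates every quantity the simulator needs: pair counts,
#' the trait panel with variance components and raw-scale moments, the
#' cross-trait correlation matrices of the A, C (or D) and E components,
#' the BMI skew strength, pubertal-age censoring, attrition, and the
#' polygenic-score panel.
#'
#' @param n_mz_pairs,n_dz_pairs Numbers of monozygotic and (same-sex)
#'   dizygotic pairs.
#' @param sex_ratio Proportion of pairs that are male.
#' @param traits Trait panel as returned by [trait_defaults()]; any subset
#'   (rows) or modified copy is accepted.
#' @param RA,RC,RE Cross-trait correlation matrices of the additive genetic,
#'   shared (or dominance) and unique environmental components, with
#'   dimnames matching `traits$trait`. Defaults use a two-domain
#'   (puberty/adiposity) factor structure.
#' @param component_kind `"C"` for shared environment or `"D"` for dominance;
#'   controls the cross-twin correlation of the second component
#'   (1.0/1.0 for C, 1.0/0.25 for D).
#' @param skew_lambda Exponential-tilt strength applied to BMI-type traits
#'   (0 = symmetric); the default gives raw-scale skewness around 1.5.
#' @param pa_censor_age Right-censoring age (years) for pubertal age.
#' @param pgs Polygenic-score panel as from [pgs_defaults()].
#' @param genotyped_prob Probability that a pair is genotyped (polygenic
#'   scores and principal components observed).
#' @param n_pcs Number of genetic principal components to simulate.
#' @param pc_confound Optional list `list(trait =, beta =)` adding
#'   `beta * sd(trait) * PC1` to the named trait, for testing the
#'   principal-component adjustment; `NULL` simulates no stratification.
#' @param seed Integer seed; cohorts are byte-identical given the seed.
#'
#' @return An object of class `twin_cohort_config`.
#' @seealso [bivariate_config()] for a compact two-trait configuration.
#' @export
twin_cohort_config <- function(n_mz_pairs = 500,
                               n_dz_pairs = 700,
                               sex_ratio = 0.45,
                               traits = trait_defaults(),
                               RA = NULL, RC = NULL, RE = NULL,
                               component_kind = c("C", "D"),
                               skew_lambda = 0.45,
                               pa_censor_age = 17,
                               pgs = pgs_defaults(),
                               genotyped_prob = 0.30,
                               n_pcs = 10,
                               pc_confound = NULL,
                               seed = 20220405) {
  component_kind <- match.arg(component_kind)
  if (is.null(RA) || is.null(RC) || is.null(RE)) {
    defaults <- default_component_correlations(traits$trait)
    if (is.null(RA)) RA <- defaults$RA
    if (is.null(RC)) RC <- defaults$RC
    if (is.null(RE)) RE <- defaults$RE
  }
  cfg <- structure(
    list(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
         sex_ratio = sex_ratio, traits = traits,
         RA = RA, RC = RC, RE = RE, component_kind = component_kind,
         skew_lambda = skew_lambda, pa_censor_age = pa_censor_age,
         pgs = pgs, genotyped_prob = genotyped_prob, n_pcs = n_pcs,
         pc_confound = pc_confound, seed = as.integer(seed)),
    class = "twin_cohort_config"
  )
  validate_config(cfg)
  cfg
}

#' Compact configuration for a two-trait (or few-trait) simulation
#'
#' Convenience wrapper used heavily in simulation studies: standardized
#' traits (mean 0, SD 1, no skew, no censoring, no attrition) with explicit
#' variance components and cross-trait component correlations.
#'
#' @param traits Character vector of trait names.
#' @param a2,c2,e2 Variance-component fractions, recycled across traits;
#'   must sum to 1 per trait.
#' @param rA,rC,rE Scalar cross-trait component correlations (applied to
#'   every off-diagonal entry) or full correlation matrices.
#' @param n_mz_pairs,n_dz_pairs,sex_ratio,component_kind,seed,skew_lambda,
#'   pgs,genotyped_prob,n_pcs As in [twin_cohort_config()].
#' @return A `twin_cohort_config`.
#' @export
bivariate_config <- function(traits = c("trait1", "trait2"),
                             a2 = 0.5, c2 = 0, e2 = 1 - a2 - c2,
                             rA = 0, rC = 0, rE = 0,
                             n_mz_pairs = 1000, n_dz_pairs = 1000,
                             sex_ratio = 0.5,
                             component_kind = "C",
                             skew_lambda = 0,
                             pgs = pgs_defaults()[0, ],
                             genotyped_prob = if (nrow(pgs)) 1 else 0,
                             n_pcs = 0,
                             seed = 20220405) {
  k <- length(traits)
  tab <- tibble::tibble(
    trait = traits, type = "generic", wave_age = 14,
    a2 = rep_len(a2, k), c2 = rep_len(c2, k), e2 = rep_len(e2, k),
    mean_male = 0, sd_male = 1, mean_female = 0, sd_female = 1,
    age_slope = 0, miss = 0
  )
  as_corr <- function(r) {
    if (is.matrix(r)) {
      dimnames(r) <- list(traits, traits)
      return(r)
    }
    R <- matrix(r, k, k, dimnames = list(traits, traits))
    diag(R) <- 1
    R
  }
  twin_cohort_config(
    n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs, sex_ratio = sex_ratio,
    traits = tab, RA = as_corr(rA), RC = as_corr(rC), RE = as_corr(rE),
    component_kind = component_kind, skew_lambda = skew_lambda,
    pgs = pgs, genotyped_prob = genotyped_prob, n_pcs = n_pcs,
    seed = seed
  )
}

validate_config <- function(cfg) {
  tr <- cfg$traits
  stopifnot(nrow(tr) >= 1, !anyDuplicated(tr$trait))
  comp_sum <- tr$a2 + tr$c2 + tr$e2
  if (any(abs(comp_sum - 1) > 1e-12)) {
    stop("variance components must sum to 1 per trait; offending trait(s): ",
         paste(tr$trait[abs(comp_sum - 1) > 1e-12], collapse = ", "))
  }
  if (any(tr$a2 < 0 | tr$c2 < 0 | tr$e2 < 0)) {
    stop("variance components must be nonnegative")
  }
  for (nm in c("RA", "RC", "RE")) {
    R <- cfg[[nm]]
    if (!is.matrix(R) || !identical(dim(R), c(nrow(tr), nrow(tr)))) {
      stop(nm, " must be a ", nrow(tr), "x", nrow(tr), " matrix")
    }
    if (any(abs(R) > 1 + 1e-12) || any(abs(diag(R) - 1) > 1e-12)) {
      stop(nm, " must be a correlation matrix (unit diagonal, entries in [-1, 1])")
    }
    if (max(abs(R - t(R))) > 1e-10) stop(nm, " must be symmetric")
  }
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1) stop("sex_ratio must be in [0, 1]")
  if (any(tr$miss < 0 | tr$miss > 1)) stop("missingness probabilities must be in [0, 1]")
  if (cfg$skew_lambda < 0) stop("skew_lambda must be nonnegative")
  if (cfg$pa_censor_age <= 0) stop("pa_censor_age must be positive")
  if (nrow(cfg$pgs)) {
    if (any(cfg$pgs$r2 < 0 | cfg$pgs$r2 > 1)) stop("pgs r2 must be in [0, 1]")
    bad <- !(cfg$pgs$target %in% tr$trait)
    if (any(bad)) {
      stop("pgs target trait(s) not in trait panel: ",
           paste(cfg$pgs$target[bad], collapse = ", "))
    }
    a2t <- tr$a2[match(cfg$pgs$target, tr$trait)]
    if (any(cfg$pgs$r2 > a2t + 1e-12)) {
      stop("pgs r2 cannot exceed the additive-genetic fraction of its target trait")
    }
  }
  # The assembled cross-twin covariance blocks must be PSD for both
  # zygosities; checked here so generation fails early with a named block.
  for (zyg in c("MZ", "DZ")) {
    sigma <- assemble_pair_covariance(cfg, zyg)
    ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) {
      stop("implied ", zyg, " pair covariance is not positive semidefinite ",
           "(min eigenvalue ", signif(ev, 3), "); check the cross-trait ",
           "component correlation matrices")
    }
  }
  invisible(cfg)
}

# Standardized-scale component covariance blocks implied by the config:
# A = D_a RA D_a etc., with D_a = diag(sqrt(a2)).
config_component_blocks <- function(cfg) {
  tr <- cfg$traits
  blk <- function(frac, R) {
    D <- diag(sqrt(frac), nrow(tr))
    out <- D %*% R %*% D
    dimnames(out) <- list(tr$trait, tr$trait)
    out
  }
  list(A = blk(tr$a2, cfg$RA),
       C = blk(tr$c2, cfg$RC),
       E = blk(tr$e2, cfg$RE))
}

# Full 2k x 2k pair covariance on the standardized scale for one zygosity,
# using the same cross-twin sharing coefficients as the likelihood code.
assemble_pair_covariance <- function(cfg, zygosity) {
  blocks <- config_component_blocks(cfg)
  coefA <- cross_twin_coef("A", zygosity)
  coefC <- cross_twin_coef(cfg$component_kind, zygosity)
  V <- blocks$A + blocks$C + blocks$E
  K <- coefA * blocks$A + coefC * blocks$C
  rbind(cbind(V, K), cbind(K, V))
}

#' @export
print.twin_cohort_config <- function(x, ...) {
  cat("<twin_cohort_config>\n")
  cat("  pairs: ", x$n_mz_pairs, " MZ + ", x$n_dz_pairs, " DZ (",
      round(100 * x$sex_ratio), "% male)\n", sep = "")
  cat("  traits:", paste(x$traits$trait, collapse = ", "), "\n")
  cat("  second component:", x$component_kind,
      "| skew_lambda:", x$skew_lambda,
      "| PA censored at:", x$pa_censor_age, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
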