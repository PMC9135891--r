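#' Induce positive skew with a monotone exponential tilt
#'
#' Standardizes the input, applies the monotone map
#' \eqn{z \mapsto (e^{\lambda z} - 1)/\lambda}, and rescales the result back
#' to the sample mean and SD of the input. `lambda = 0` is the identity.
#' For standard-normal input the transform has the skewness of a log-normal
#' with sigma = lambda, so the default generator value (0.45) produces
#' raw-BMI-like skewness around 1.5.
#'
#' @param values Numeric vector (NAs pass through).
#' @param skew_lambda Nonnegative tilt strength.
#' @return Numeric vector with the same sample mean and SD as `values`.
#' @export
apply_skew <- function(values, skew_lambda) {
  stopifnot(skew_lambda >= 0)
  if (skew_lambda == 0) return(values)
  ok <- !is.na(values)
  if (sum(ok) < 2) return(values)
  m <- mean(values[ok])
  s <- sd(values[ok])
  if (s == 0) return(values)
  z <- (values - m) / s
  y <- expm1(skew_lambda * z) / skew_lambda
  my <- mean(y[ok])
  sy <- sd(y[ok])
  m + s * (y - my) / sy
}

#' Right-censor pubertal age
#'
#' Ages above the censoring age are replaced by it and flagged, emulating
#' respondents who had not yet experienced menarche/voice break at the
#' retrospective survey and are coded at the survey age.
#'
#' @param pa_true Numeric vector of latent pubertal ages (years).
#' @param censor_age Positive censoring age (years).
#' @return A list with `pa` (censored values) and `censored` (logical flags;
#'   NA where the input is NA).
#' @export
censor_pa <- function(pa_true, censor_age) {
  stopifnot(censor_age > 0)
  flag <- pa_true > censor_age
  list(pa = ifelse(!is.na(flag) & flag, censor_age, pa_true),
       censored = flag)
}

#' Generate a synthetic same-sex twin cohort
#'
#' Draws, for every pair, latent additive genetic (A), shared/dominance
#' (C or D) and unique environmental (E) component vectors whose cross-twin
#' covariance blocks follow the classical twin design (A: correlation 1.0 in
#' MZ, 0.5 in DZ; C: 1.0/1.0; D: 1.0/0.25; E: independent), sums them into
#' standardized phenotypes, then applies the raw-scale decoration: the BMI
#' skew tilt, sex-specific means/SDs, a per-pair survey-age jitter with
#' trait-specific age slopes, pubertal-age right-censoring, wave-specific
#' MCAR attrition, and latent polygenic scores with principal components
#' for a genotyped subset.
#'
#' @param config A [twin_cohort_config()].
#' @return A tibble of class `twin_cohort`, one row per twin individual
#'   (long format), with attributes `config`, `seed` and `config_hash`.
#'   Columns: `pair_id`, `member`, `zygosity`, `sex`, one `age_<wave>`
#'   column per distinct survey wave, the trait columns, `pa_censored`,
#'   `pgs_<name>` scores, and `pc1..pcN`.
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  tr <- cfg$traits
  k <- nrow(tr)
  n_male_mz <- round(cfg$sex_ratio * cfg$n_mz_pairs)
  n_male_dz <- round(cfg$sex_ratio * cfg$n_dz_pairs)
  plan <- data.frame(
    zygosity = c("MZ", "MZ", "DZ", "DZ"),
    sex = c("male", "female", "male", "female"),
    n = c(n_male_mz, cfg$n_mz_pairs - n_male_mz,
          n_male_dz, cfg$n_dz_pairs - n_male_dz)
  )
  plan <- plan[plan$n > 0, , drop = FALSE]
  blocks <- config_component_blocks(cfg)

  pieces <- vector("list", nrow(plan))
  offset <- 0L
  for (i in seq_len(nrow(plan))) {
    zyg <- plan$zygosity[i]
    n <- plan$n[i]
    A <- draw_component_pairs(n, blocks$A, cross_twin_coef("A", zyg))
    C <- draw_component_pairs(n, blocks$C, cross_twin_coef(cfg$component_kind, zyg))
    E <- draw_component_pairs(n, blocks$E, 0)
    z1 <- A$m1 + C$m1 + E$m1     # n x k, member 1, standardized scale
    z2 <- A$m2 + C$m2 + E$m2
    pieces[[i]] <- list(
      zygosity = zyg, sex = plan$sex[i],
      pair_id = offset + seq_len(n),
      z1 = z1, z2 = z2, a1 = A$m1, a2 = A$m2
    )
    offset <- offset + n
  }

  # Long layout: one row per individual; latent standardized phenotypes.
  z <- do.call(rbind, lapply(pieces, function(p) rbind(p$z1, p$z2)))
  a_lat <- do.call(rbind, lapply(pieces, function(p) rbind(p$a1, p$a2)))
  meta <- do.call(rbind, lapply(pieces, function(p) {
    data.frame(pair_id = rep(p$pair_id, 2),
               member = rep(1:2, each = length(p$pair_id)),
               zygosity = p$zygosity, sex = p$sex)
  }))
  colnames(z) <- tr$trait
  colnames(a_lat) <- tr$trait
  n_pairs <- offset
  n_ind <- nrow(meta)

  # Per-pair survey-age jitter, shared by co-twins, one column per wave.
  waves <- sort(unique(tr$wave_age))
  age_pair <- vapply(waves, function(w) w + runif(n_pairs, -0.5, 0.5),
                     numeric(n_pairs))
  colnames(age_pair) <- paste0("age_", waves)
  ages <- age_pair[meta$pair_id, , drop = FALSE]

  # Skew tilt on standardized BMI values, then raw-scale location/scale.
  raw <- z
  for (j in seq_len(k)) {
    v <- raw[, j]
    if (tr$type[j] == "bmi" && cfg$skew_lambda > 0) {
      v <- apply_skew(v, cfg$skew_lambda)
    }
    mu <- ifelse(meta$sex == "male", tr$mean_male[j], tr$mean_female[j])
    sdv <- ifelse(meta$sex == "male", tr$sd_male[j], tr$sd_female[j])
    age_dev <- ages[, paste0("age_", tr$wave_age[j])] - tr$wave_age[j]
    raw[, j] <- mu + sdv * v + tr$age_slope[j] * age_dev
  }

  if (!is.null(cfg$pc_confound) || cfg$n_pcs > 0) {
    pcs <- matrix(rnorm(n_ind * max(cfg$n_pcs, 1)), n_ind)
  } else {
    pcs <- NULL
  }
  if (!is.null(cfg$pc_confound)) {
    j <- match(cfg$pc_confound$trait, tr$trait)
    sdv <- ifelse(meta$sex == "male", tr$sd_male[j], tr$sd_female[j])
    raw[, j] <- raw[, j] + cfg$pc_confound$beta * sdv * pcs[, 1]
  }

  out <- tibble::as_tibble(cbind(meta, as.data.frame(ages)))
  for (j in seq_len(k)) out[[tr$trait[j]]] <- raw[, j]

  if ("pa" %in% tr$trait) {
    cens <- censor_pa(out$pa, cfg$pa_censor_age)
    out$pa <- cens$pa
    out$pa_censored <- cens$censored
  }

  out <- simulate_pgs_impl(out, cfg, a_lat)
  if (cfg$n_pcs > 0) {
    # PCs observed only for genotyped individuals, like the scores.
    geno <- attr(out, "genotyped")
    for (p in seq_len(cfg$n_pcs)) {
      pc <- pcs[, p]
      if (nrow(cfg$pgs)) pc[!geno] <- NA
      out[[paste0("pc", p)]] <- pc
    }
  }

  # Wave-specific MCAR attrition, applied last (phenotype level only).
  for (j in seq_len(k)) {
    if (tr$miss[j] > 0) {
      drop <- runif(n_ind) < tr$miss[j]
      out[[tr$trait[j]]][drop] <- NA
      if (tr$trait[j] == "pa") out$pa_censored[drop] <- NA
    }
  }

  attr(out, "genotyped") <- NULL
  attr(out, "config") <- cfg
  attr(out, "seed") <- cfg$seed
  attr(out, "config_hash") <- rlang::hash(cfg)
  class(out) <- c("twin_cohort", class(out))
  out
}

# Draw n pairs of k-dimensional component vectors with within-twin
# covariance `block` and cross-twin covariance `coef * block`. coef = 1
# copies one draw to both twins (exact sharing); coef = 0 draws
# independently; otherwise the stacked 2k covariance is used.
draw_component_pairs <- function(n, block, coef) {
  k <- ncol(block)
  if (all(block == 0)) {
    zero <- matrix(0, n, k)
    return(list(m1 = zero, m2 = zero))
  }
  if (coef == 1) {
    m <- mvn_draw(n, block)
    list(m1 = m, m2 = m)
  } else if (coef == 0) {
    list(m1 = mvn_draw(n, block), m2 = mvn_draw(n, block))
  } else {
    sigma <- rbind(cbind(block, coef * block), cbind(coef * block, block))
    m <- mvn_draw(n, sigma)
    list(m1 = m[, seq_len(k), drop = FALSE],
         m2 = m[, k + seq_len(k), drop = FALSE])
  }
}

# MVN draw via eigendecomposition so that PSD (rank-deficient) covariance
# blocks are accepted; negative eigenvalues beyond tolerance are an error.
mvn_draw <- function(n, sigma) {
  k <- ncol(sigma)
  es <- eigen(sigma, symmetric = TRUE)
  if (min(es$values) < -1e-8 * max(abs(es$values), 1)) {
    stop("component covariance block is not positive semidefinite")
  }
  lam <- pmax(es$values, 0)
  root <- es$vectors %*% (sqrt(lam) * t(es$vectors))
  matrix(rnorm(n * k), n) %*% root
}

#' Attach latent polygenic scores and principal components to a cohort
#'
#' Each configured score is a linear combination of the target trait's
#' additive-genetic latent value and an independent genetic noise latent
#' (shared exactly within MZ pairs, correlated 0.5 within DZ pairs), scaled
#' so the squared correlation with the standardized target trait equals the
#' configured `r2`. Scores are observed only for the genotyped subset.
#' Principal components are independent standard normals (no population
#' structure) unless a confound is configured.
#'
#' @param cohort A `twin_cohort` (must carry its generating config with
#'   stored additive latents; i.e. be freshly generated).
#' @param config The generating [twin_cohort_config()].
#' @return The cohort with `pgs_*` columns (re)drawn under the config seed.
#' @export
simulate_pgs <- function(cohort, config) {
  a_lat <- attr(cohort, "additive_latents")
  if (is.null(a_lat)) {
    stop("cohort does not carry additive-genetic latents; ",
         "polygenic scores are simulated during generate_cohort()")
  }
  withr::with_seed(config$seed + 1L, simulate_pgs_impl(cohort, config, a_lat))
}

simulate_pgs_impl <- function(out, cfg, a_lat) {
  tr <- cfg$traits
  if (!nrow(cfg$pgs)) {
    attr(out, "genotyped") <- rep(TRUE, nrow(out))
    attr(out, "additive_latents") <- a_lat
    return(out)
  }
  n_ind <- nrow(out)
  pair_ids <- unique(out$pair_id)
  geno_pair <- runif(length(pair_ids)) < cfg$genotyped_prob
  genotyped <- geno_pair[match(out$pair_id, pair_ids)]

  # Family-structured genetic noise latent per score: identical within MZ,
  # correlated 0.5 within DZ.
  first <- match(pair_ids, out$pair_id)
  zyg_pair <- out$zygosity[first]
  for (s in seq_len(nrow(cfg$pgs))) {
    target <- cfg$pgs$target[s]
    r2 <- cfg$pgs$r2[s]
    a2t <- tr$a2[match(target, tr$trait)]
    a_std <- a_lat[, target] / sqrt(a2t)   # unit-variance additive latent
    g1 <- rnorm(length(pair_ids))
    g2 <- ifelse(zyg_pair == "MZ", g1,
                 0.5 * g1 + sqrt(0.75) * rnorm(length(pair_ids)))
    g <- ifelse(out$member == 1, g1[match(out$pair_id, pair_ids)],
                g2[match(out$pair_id, pair_ids)])
    alpha <- sqrt(r2 / a2t)
    score <- alpha * a_std + sqrt(pmax(1 - alpha^2, 0)) * g
    score[!genotyped] <- NA
    out[[paste0("pgs_", cfg$pgs$pgs[s])]] <- score
  }
  attr(out, "genotyped") <- genotyped
  attr(out, "additive_latents") <- a_lat
  out
}

#' Published-magnitude component correlations the generator defaults emulate
#'
#' Reference table of trait correlations (r), additive genetic correlations
#' (rA) and unique environmental correlations (rE) between puberty indices
#' and BMI at successive ages, by sex, at the magnitudes reported for
#' Finnish adolescent twin cohorts. These values anchor the generator's
#' default cross-trait correlation structure and are the inputs for
#' shared-variance summaries such as [shared_variance_fraction()].
#'
#' `adolescent` flags the rows pairing a puberty index with same-age
#' (adolescent) BMI.
#'
#' @return A tibble with columns `sex`, `trait1`, `trait2`, `r`, `r_a`,
#'   `r_e`, `adolescent`.
#' @export
cohort_target_correlations <- function() {
  tibble::tribble(
    ~sex,     ~trait1, ~trait2, ~r,    ~r_a,  ~r_e,  ~adolescent,
    "male",   "pds12", "pds14",  0.36,  0.49,  0.05, FALSE,
    "male",   "pds12", "bmi12",  0.14,  0.17,  0.03, TRUE,
    "male",   "pds14", "bmi14",  0.17,  0.21,  0.03, TRUE,
    "male",   "pds12", "bmi17",  0.09,  0.09,  0.10, FALSE,
    "male",   "pds12", "bmi22",  0.10,  0.09,  0.12, FALSE,
    "male",   "pds14", "bmi17",  0.13,  0.19, -0.04, FALSE,
    "male",   "pds14", "bmi24",  0.12,  0.15,  0.05, FALSE,
    "male",   "pa",    "bmi16", -0.15, -0.23,  0.06, TRUE,
    "male",   "pa",    "bmi17", -0.11, -0.12, -0.08, FALSE,
    "male",   "pa",    "bmi18", -0.08, -0.09, -0.07, FALSE,
    "male",   "pa",    "bmi25", -0.06, -0.06, -0.07, FALSE,
    "male",   "pa",    "bmi35", -0.06, -0.06, -0.05, FALSE,
    "female", "pds12", "pds14",  0.51,  0.62,  0.15, FALSE,
    "female", "pds12", "bmi12",  0.24,  0.25,  0.21, TRUE,
    "female", "pds14", "bmi14",  0.28,  0.33,  0.12, TRUE,
    "female", "pds12", "bmi17",  0.13,  0.17,  0.03, FALSE,
    "female", "pds12", "bmi22",  0.13,  0.15,  0.04, FALSE,
    "female", "pds14", "bmi17",  0.14,  0.18,  0.05, FALSE,
    "female", "pds14", "bmi24",  0.13,  0.20, -0.03, FALSE,
    "female", "pa",    "bmi16", -0.28, -0.30, -0.18, TRUE,
    "female", "pa",    "bmi17", -0.22, -0.25, -0.06, FALSE,
    "female", "pa",    "bmi18", -0.19, -0.21, -0.09, FALSE,
    "female", "pa",    "bmi25", -0.18, -0.20, -0.08, FALSE,
    "female", "pa",    "bmi35", -0.17, -0.17, -0.19, FALSE
  )
}
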