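#' Natural-log transform of BMI
#'
#' @param bmi Numeric vector of BMI values (kg/m^2); NAs propagate.
#' @return `log(bmi)`.
#' @export
log_bmi <- function(bmi) {
  bad <- which(!is.na(bmi) & bmi <= 0)
  if (length(bad)) {
    stop("nonpositive BMI value(s) at row(s): ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ...")
  }
  log(bmi)
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' The standardized third central moment with the small-sample correction
#' `sqrt(n(n-1))/(n-2)` used by most statistics packages.
#'
#' @param values Numeric vector; NAs are dropped.
#' @return Scalar skewness.
#' @export
sample_skewness <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 3) stop("skewness requires at least 3 non-missing values")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) stop("skewness is undefined for a constant sample")
  g1 <- mean((x - m)^3) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Residualize a trait on survey age, separately by sex
#'
#' Within each sex stratum, fits an ordinary least-squares regression of
#' the trait on intercept + age and returns the z-standardized residuals
#' (mean 0, SD 1 per stratum), so that downstream twin models operate on a
#' common scale and regression coefficients are standardized. Complete
#' cases per stratum; incomplete rows get NA. A stratum with (near-)
#' constant age falls back to intercept-only residualization with a
#' warning.
#'
#' @param trait,age,sex Equal-length vectors (sex a label vector).
#' @return An object of class `adjusted_trait`: a list with `values`
#'   (z-scored residuals, same length/order as the input),
#'   `adjustment_spec`, and `n_used` per stratum.
#' @export
residualize_by_sex <- function(trait, age, sex) {
  stopifnot(length(trait) == length(age), length(trait) == length(sex))
  out <- rep(NA_real_, length(trait))
  n_used <- c()
  for (s in unique(sex[!is.na(sex)])) {
    idx <- which(sex == s & !is.na(trait) & !is.na(age))
    if (length(idx) < 3) {
      stop("fewer than 3 complete observations in stratum '", s, "'")
    }
    if (sd(age[idx]) < 1e-12) {
      warning("age is constant in stratum '", s,
              "'; falling back to intercept-only adjustment")
      res <- trait[idx] - mean(trait[idx])
    } else {
      fit <- lm(trait[idx] ~ age[idx])
      res <- unname(fit$residuals)
    }
    s_res <- sd(res)
    # a numerically zero residual vector stays zero instead of being blown
    # up by standardization
    degenerate <- s_res <= 1e-10 * max(sd(trait[idx]), 1)
    out[idx] <- if (degenerate) res * 0 else res / s_res
    n_used[s] <- length(idx)
  }
  structure(
    list(values = out,
         adjustment_spec = list(covariates = "age", strata = "sex",
                                standardized = TRUE),
         n_used = n_used),
    class = "adjusted_trait"
  )
}

#' Preprocess a twin cohort for modeling
#'
#' Applies the standard phenotype preparation: BMI traits are
#' log-transformed, then every trait is residualized on its survey-wave age
#' separately by sex and z-standardized ([residualize_by_sex()]). Censored
#' pubertal-age values enter as-is (at the censoring age). Adjusted columns
#' are appended with an `_adj` suffix.
#'
#' @param cohort A `twin_cohort` (or compatible long-format table carrying
#'   a generating config attribute, used to map traits to age columns).
#' @return The cohort with `<trait>_adj` columns appended.
#' @export
preprocess_cohort <- function(cohort) {
  cfg <- attr(cohort, "config")
  if (is.null(cfg)) stop("cohort does not carry its generating config")
  tr <- cfg$traits
  for (j in seq_len(nrow(tr))) {
    trait <- tr$trait[j]
    v <- cohort[[trait]]
    if (tr$type[j] == "bmi") v <- log_bmi(v)
    age <- cohort[[paste0("age_", tr$wave_age[j])]]
    adj <- residualize_by_sex(v, age, cohort$sex)
    cohort[[paste0(trait, "_adj")]] <- adj$values
  }
  cohort
}

#' Descriptive statistics by trait and sex
#'
#' N, mean and SD of each raw trait per sex, with the sex difference tested
#' by a cluster-robust regression of the trait on sex (twin pairs as
#' clusters). Traits absent in one sex yield empty cells rather than an
#' error.
#'
#' @param cohort A twin cohort table.
#' @param traits Trait columns to describe; defaults to the config panel.
#' @return A tibble with one row per trait: `n_male`, `mean_male`,
#'   `sd_male`, `n_female`, `mean_female`, `sd_female`, `p_sex_diff`.
#' @export
describe_cohort <- function(cohort, traits = NULL) {
  stopifnot(nrow(cohort) > 0)
  if (is.null(traits)) {
    cfg <- attr(cohort, "config")
    traits <- if (!is.null(cfg)) cfg$traits$trait else
      setdiff(names(cohort),
              c("pair_id", "member", "zygosity", "sex", "pa_censored",
                grep("^(age_|pgs_|pc)", names(cohort), value = TRUE)))
  }
  rows <- lapply(traits, function(trait) {
    v <- cohort[[trait]]
    cell <- function(s) {
      x <- v[cohort$sex == s]
      x <- x[!is.na(x)]
      if (!length(x)) c(n = 0, mean = NA_real_, sd = NA_real_)
      else c(n = length(x), mean = mean(x), sd = sd(x))
    }
    m <- cell("male"); f <- cell("female")
    p <- NA_real_
    if (m["n"] >= 2 && f["n"] >= 2) {
      ok <- !is.na(v)
      fit <- fit_clustered_ols(
        outcome = v[ok],
        design = cbind(sex_male = as.numeric(cohort$sex[ok] == "male")),
        cluster_ids = cohort$pair_id[ok]
      )
      p <- fit$table$p_value[fit$table$term == "sex_male"]
    }
    tibble::tibble(trait = trait,
                   n_male = m[["n"]], mean_male = m[["mean"]], sd_male = m[["sd"]],
                   n_female = f[["n"]], mean_female = f[["mean"]], sd_female = f[["sd"]],
                   p_sex_diff = p)
  })
  dplyr::bind_rows(rows)
}
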