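# Cluster-robust regression layer. Point estimates are ordinary least
# squares; the covariance is the clustered sandwich estimator with the
# Stata-style small-sample factor G/(G-1) * (N-1)/(N-k) and a t reference
# distribution with G-1 degrees of freedom, G the number of clusters
# (Williams-type correction for twins sampled as pairs).

#' Ordinary least squares with cluster-robust (sandwich) inference
#'
#' @param outcome Numeric response vector.
#' @param design Numeric covariate matrix (no intercept column; one is
#'   prepended). Column names become coefficient names.
#' @param cluster_ids Cluster identifier per observation (e.g. twin pair
#'   id). With every observation its own cluster the standard errors reduce
#'   to heteroskedasticity-robust HC1 standard errors.
#' @param conf_level Confidence level.
#' @return An object of class `clustered_fit`: a coefficient `table`
#'   (term, estimate, se, ci_low, ci_high, p_value), `n_individuals`,
#'   `n_clusters`, `df`, and the underlying `lm` fit.
#' @export
fit_clustered_ols <- function(outcome, design, cluster_ids,
                              conf_level = 0.95) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  stopifnot(length(outcome) == nrow(design),
            length(cluster_ids) == nrow(design))
  ok <- !is.na(outcome) & complete.cases(design) & !is.na(cluster_ids)
  y <- outcome[ok]
  X <- cbind(`(Intercept)` = 1, design[ok, , drop = FALSE])
  cl <- cluster_ids[ok]
  G <- length(unique(cl))
  if (G < 2) stop("cluster-robust inference requires at least 2 clusters")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  df_mod <- data.frame(y = y, X[, -1, drop = FALSE], check.names = FALSE)
  fit <- lm(y ~ ., data = df_mod)
  V <- sandwich::vcovCL(fit, cluster = cl, type = "HC1", cadjust = TRUE)
  est <- coef(fit)
  se <- sqrt(diag(V))
  df <- G - 1
  tq <- qt(1 - (1 - conf_level) / 2, df)
  tstat <- est / se
  table <- tibble::tibble(
    term = names(est), estimate = unname(est), se = unname(se),
    ci_low = unname(est - tq * se), ci_high = unname(est + tq * se),
    p_value = unname(2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
  )
  structure(
    list(table = table, n_individuals = length(y), n_clusters = G,
         df = df, conf_level = conf_level, fit = fit, vcov = V),
    class = "clustered_fit"
  )
}

#' @export
print.clustered_fit <- function(x, ...) {
  cat("Cluster-robust OLS (", x$n_individuals, " obs, ", x$n_clusters,
      " clusters, t(", x$df, "))\n", sep = "")
  print(as.data.frame(x$table), digits = 3, row.names = FALSE)
  invisible(x)
}

z_std <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) stop("cannot standardize a constant variable")
  (x - mean(x, na.rm = TRUE)) / s
}

#' Standardized association between two traits with optional baseline adjustment
#'
#' Within one sex stratum, z-standardizes predictor and outcome (so the
#' coefficient reads as outcome SDs per predictor SD), enters the adjusters
#' on their original scale, and fits [fit_clustered_ols()] with twin pairs
#' as clusters. The canonical use is regressing post-puberty BMI on a
#' puberty index adjusted for baseline (pre/peri-pubertal) BMI.
#'
#' @param cohort A twin cohort table.
#' @param predictor,outcome Column names of the standardized variables.
#' @param adjust_for Character vector of adjuster columns (may be empty).
#' @param sex `"male"`, `"female"` or `"both"`.
#' @param min_n Minimum complete observations required.
#' @param conf_level Confidence level.
#' @return A `regression_result`: `outcome`, `predictor`,
#'   `standardized_beta`, `se`, `ci_low`, `ci_high`, `p_value`,
#'   `n_individuals`, `n_clusters`, and the full `clustered_fit`.
#' @export
standardized_association <- function(cohort, predictor, outcome,
                                     adjust_for = character(), sex = "both",
                                     min_n = 50, conf_level = 0.95) {
  df <- as.data.frame(cohort)
  if (!identical(sex, "both")) df <- df[df$sex == sex, , drop = FALSE]
  if (!nrow(df)) stop("no observations in stratum '", sex, "'")
  cols <- c(predictor, outcome, adjust_for)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop("column(s) not in cohort: ", paste(missing_cols, collapse = ", "))
  }
  ok <- complete.cases(df[, cols, drop = FALSE])
  if (sum(ok) < min_n) {
    stop("only ", sum(ok), " complete observations (< ", min_n, ")")
  }
  df <- df[ok, , drop = FALSE]
  design <- cbind(z_std(df[[predictor]]),
                  as.matrix(df[, adjust_for, drop = FALSE]))
  colnames(design) <- c(predictor, adjust_for)
  cf <- fit_clustered_ols(z_std(df[[outcome]]), design, df$pair_id,
                          conf_level)
  row <- cf$table[cf$table$term == predictor, ]
  structure(
    list(outcome = outcome, predictor = predictor, adjust_for = adjust_for,
         sex = sex, standardized_beta = row$estimate, se = row$se,
         ci_low = row$ci_low, ci_high = row$ci_high, p_value = row$p_value,
         n_individuals = cf$n_individuals, n_clusters = cf$n_clusters,
         fit = cf),
    class = "regression_result"
  )
}

#' Polygenic-score association with principal-component adjustment
#'
#' Standardized coefficient of a puberty index (or any outcome) on a
#' polygenic score, adjusted for the leading genetic principal components,
#' with cluster-robust standard errors by twin pair.
#'
#' @param cohort A twin cohort table with `pgs_<name>` and `pc1..pcN`
#'   columns.
#' @param pgs_name Score suffix, e.g. `"wc"` for column `pgs_wc` (a full
#'   column name is also accepted).
#' @param outcome Outcome column name.
#' @param n_pcs Number of principal components to adjust for.
#' @param sex `"male"`, `"female"` or `"both"`.
#' @param min_n,conf_level As in [standardized_association()].
#' @return A `regression_result`.
#' @export
pgs_association <- function(cohort, pgs_name, outcome, n_pcs = 10,
                            sex = "both", min_n = 50, conf_level = 0.95) {
  pgs_col <- if (pgs_name %in% names(cohort)) pgs_name else paste0("pgs_", pgs_name)
  if (!pgs_col %in% names(cohort)) {
    stop("polygenic score column not found: ", pgs_col)
  }
  pc_cols <- if (n_pcs > 0) paste0("pc", seq_len(n_pcs)) else character()
  absent <- setdiff(pc_cols, names(cohort))
  if (length(absent)) {
    stop("principal-component column(s) missing: ",
         paste(absent, collapse = ", "))
  }
  res <- standardized_association(cohort, predictor = pgs_col,
                                  outcome = outcome, adjust_for = pc_cols,
                                  sex = sex, min_n = min_n,
                                  conf_level = conf_level)
  res$predictor <- pgs_col
  res
}

#' @export
print.regression_result <- function(x, ...) {
  cat("Standardized association: ", x$outcome, " ~ ", x$predictor,
      if (length(x$adjust_for))
        paste0(" | adjusted for ", paste(x$adjust_for, collapse = ", ")),
      " (", x$sex, ")\n", sep = "")
  cat(sprintf("  beta = %.3f  [%.3f, %.3f], p = %.4g  (n = %d, clusters = %d)\n",
              x$standardized_beta, x$ci_low, x$ci_high, x$p_value,
              x$n_individuals, x$n_clusters))
  invisible(x)
}
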