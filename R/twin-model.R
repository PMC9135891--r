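#' Cholesky parameter set for a twin variance-component model
#'
#' Parameterizes each included component's covariance block as
#' \eqn{L L^\top} with \eqn{L} lower triangular, which keeps every block
#' positive semidefinite throughout optimization. Univariate models use a
#' single scalar loading per component; bivariate models use three
#' (`x11`, `x21`, `x22`).
#'
#' @param model `"ACE"`, `"ADE"` or `"AE"`.
#' @param traits Character vector of trait names (length 1 or 2).
#' @param a,c,d,e Lower-triangular loadings per component, given either as
#'   a vector in column-major lower-triangular order or as a full matrix.
#'   `c` is used by ACE, `d` by ADE; AE takes neither.
#' @param means Trait means (recycled to the number of traits).
#' @return An object of class `cholesky_params`.
#' @export
cholesky_params <- function(model = c("ACE", "ADE", "AE"),
                            traits, a, c = NULL, d = NULL, e,
                            means = 0) {
  model <- match.arg(model)
  k <- length(traits)
  loads <- list(A = as_lower_tri(a, k), E = as_lower_tri(e, k))
  kind <- model_second_component(model)
  if (!is.na(kind)) {
    second <- if (kind == "C") c else d
    if (is.null(second)) stop("model ", model, " requires ", kind, " loadings")
    loads[[kind]] <- as_lower_tri(second, k)
  }
  structure(
    list(model = model, traits = traits, loads = loads,
         means = rep_len(means, k)),
    class = "cholesky_params"
  )
}

model_second_component <- function(model) {
  switch(model, ACE = "C", ADE = "D", AE = NA_character_,
         stop("unknown model: ", model))
}

as_lower_tri <- function(x, k) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) == k, ncol(x) == k)
    x[upper.tri(x)] <- 0
    return(x)
  }
  stopifnot(length(x) == k * (k + 1) / 2)
  L <- matrix(0, k, k)
  L[lower.tri(L, diag = TRUE)] <- x
  L
}

# Cross-twin sharing coefficient of each component: additive genetic 1.0 in
# MZ / 0.5 in DZ; shared environment 1.0/1.0; dominance 1.0/0.25; unique
# environment uncorrelated across twins.
cross_twin_coef <- function(component, zygosity) {
  stopifnot(zygosity %in% c("MZ", "DZ"))
  coefs <- list(A = c(MZ = 1, DZ = 0.5),
                C = c(MZ = 1, DZ = 1),
                D = c(MZ = 1, DZ = 0.25),
                E = c(MZ = 0, DZ = 0))
  if (!component %in% names(coefs)) stop("unknown component: ", component)
  unname(coefs[[component]][zygosity])
}

#' Component covariance blocks implied by Cholesky loadings
#'
#' @param params A [cholesky_params()].
#' @return An object of class `component_covariances`: a list with symmetric
#'   PSD matrices `A`, `E`, optionally `C` or `D`, the `kind` of the second
#'   component (`NA` for AE) and the total phenotypic block `V`.
#' @export
component_covariances <- function(params) {
  stopifnot(inherits(params, "cholesky_params"))
  mats <- lapply(params$loads, function(L) tcrossprod(L))
  V <- Reduce(`+`, mats)
  structure(
    c(mats, list(kind = model_second_component(params$model), V = V,
                 traits = params$traits)),
    class = "component_covariances"
  )
}

#' Expected covariance of a twin pair's stacked phenotype vector
#'
#' Returns the 2k x 2k matrix `[[V, K], [K, V]]` where `V = A + C/D + E`
#' is the within-person block and the cross-twin block `K` weights each
#' component by its zygosity-specific sharing coefficient (A: 1.0 MZ /
#' 0.5 DZ; C: 1.0/1.0; D: 1.0/0.25; E: 0). Vector ordering is all traits of
#' member 1 followed by all traits of member 2.
#'
#' @param params A [cholesky_params()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param model Model label; defaults to the one stored in `params`.
#' @return A symmetric `2k x 2k` matrix.
#' @export
expected_pair_covariance <- function(params, zygosity, model = params$model) {
  if (!identical(model, params$model)) {
    stop("model label '", model, "' does not match the parameter set ('",
         params$model, "')")
  }
  mats <- lapply(params$loads, tcrossprod)
  V <- Reduce(`+`, mats)
  K <- Reduce(`+`, Map(function(m, comp) cross_twin_coef(comp, zygosity) * m,
                       mats, names(mats)))
  rbind(cbind(V, K), cbind(K, V))
}

#' Full-information log-likelihood contribution of one twin pair
#'
#' Evaluates the multivariate-normal log-density of the pair's observed
#' phenotype subvector under the model-implied mean and covariance,
#' marginalizing missing entries by row/column deletion. A pair with one
#' member entirely missing therefore contributes the marginal density of
#' the observed member.
#'
#' @param params A [cholesky_params()].
#' @param pair A list with `zygosity` (`"MZ"`/`"DZ"`) and `y`, the stacked
#'   phenotype vector of length `2k` (member 1's traits then member 2's),
#'   with `NA` for missing entries.
#' @param model Model label; defaults to the one stored in `params`.
#' @return The log-density (scalar); `-Inf` (with a warning) if the implied
#'   covariance of the observed subvector is not positive definite; `0` if
#'   nothing is observed.
#' @export
pair_loglik <- function(params, pair, model = params$model) {
  sigma <- expected_pair_covariance(params, pair$zygosity, model)
  mu <- rep(params$means, 2)
  obs <- which(!is.na(pair$y))
  if (!length(obs)) return(0)
  s <- sigma[obs, obs, drop = FALSE]
  r <- tryCatch(chol(s), error = function(e) NULL)
  if (is.null(r) || any(diag(r) < 1e-12)) {
    warning("implied covariance of the observed subvector is not positive definite")
    return(-Inf)
  }
  d <- pair$y[obs] - mu[obs]
  q <- sum(backsolve(r, d, transpose = TRUE)^2)
  -0.5 * (length(obs) * log(2 * pi) + 2 * sum(log(diag(r))) + q)
}

#' Correlation between two traits' latent component influences
#'
#' For the chosen component block this is the off-diagonal covariance
#' divided by the geometric mean of the diagonal variances, e.g. the
#' additive genetic correlation rA for component `"A"`.
#'
#' @param cov A [component_covariances()] object.
#' @param component `"A"`, `"C"`, `"D"` or `"E"`.
#' @return A scalar in `[-1, 1]`.
#' @export
genetic_correlation <- function(cov, component = "A") {
  stopifnot(inherits(cov, "component_covariances"))
  M <- cov[[component]]
  if (is.null(M)) stop("component ", component, " is not part of this model")
  if (nrow(M) < 2) stop("component correlation requires a bivariate model")
  if (any(diag(M) <= 0)) {
    stop("component ", component,
         " has a zero variance; its correlation is undefined")
  }
  M[1, 2] / sqrt(M[1, 1] * M[2, 2])
}

#' Fraction of one trait's component variance shared with another
#'
#' The square of a component correlation: rA = 0.49 means 24% of the
#' genetic variation of one trait is shared with the other.
#'
#' @param r_component A component correlation in `[-1, 1]`.
#' @return The squared correlation (a proportion in `[0, 1]`).
#' @export
shared_variance_fraction <- function(r_component) {
  stopifnot(all(abs(r_component) <= 1 + 1e-12))
  r_component^2
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Decompose a trait correlation into component contributions
#'
#' The phenotypic correlation between two traits splits additively into
#' per-component terms `X12 / sqrt(V11 * V22)`. Each term is also expressed
#' as a (signed) percentage of the trait correlation; percentages over the
#' included components sum to 100, and a negative percentage indicates a
#' component covariation working against the direction of the trait
#' correlation.
#'
#' @param fit A [fit_bivariate()] result (or a `component_covariances`
#'   object).
#' @return A tibble with columns `component`, `contribution`, `percent`.
#' @export
decompose_trait_correlation <- function(fit) {
  cov <- if (inherits(fit, "component_covariances")) fit else fit$component_covariances
  V <- cov$V
  denom <- sqrt(V[1, 1] * V[2, 2])
  comps <- intersect(c("A", "C", "D", "E"), names(cov))
  contribution <- vapply(comps, function(cp) cov[[cp]][1, 2] / denom, numeric(1))
  r <- sum(contribution)
  if (abs(r) < 1e-12) {
    stop("phenotypic correlation is zero; the decomposition is undefined")
  }
  tibble::tibble(component = comps,
                 contribution = unname(contribution),
                 percent = 100 * unname(contribution) / r)
}

#' Likelihood-ratio comparison of nested twin models
#'
#' @param full,nested Fits from [fit_bivariate()] or [fit_univariate()] on
#'   the same data, with the nested model's parameters a subset of the
#'   full model's (e.g. AE within ACE).
#' @param boundary `"naive"` uses a chi-square with df equal to the
#'   parameter-count difference (common practice in the twin literature);
#'   `"mixture"` uses an equal mixture of chi-squares with `df` and
#'   `df - 1` degrees of freedom, a conservative adjustment for variance
#'   components tested on the boundary of their space.
#' @return An object of class `model_comparison` with `lrt_statistic`,
#'   `df`, `p_value`, `aic_full`, `aic_nested`.
#' @export
compare_models <- function(full, nested, boundary = c("naive", "mixture")) {
  boundary <- match.arg(boundary)
  df <- full$n_params - nested$n_params
  if (df <= 0) stop("the nested model must have fewer parameters than the full model")
  lrt <- 2 * (full$loglik - nested$loglik)
  # tiny negative statistics are optimizer tolerance noise, not misordering
  if (lrt < -1e-3) {
    stop("nested log-likelihood exceeds the full model's; refit with more starts")
  }
  lrt <- max(lrt, 0)
  p <- if (boundary == "naive") {
    pchisq(lrt, df = df, lower.tail = FALSE)
  } else {
    0.5 * pchisq(lrt, df = df, lower.tail = FALSE) +
      0.5 * (if (df > 1) pchisq(lrt, df = df - 1, lower.tail = FALSE)
             else as.numeric(lrt == 0))
  }
  if (lrt == 0) p <- 1
  structure(
    list(lrt_statistic = lrt, df = df, p_value = p,
         aic_full = 2 * full$n_params - 2 * full$loglik,
         aic_nested = 2 * nested$n_params - 2 * nested$loglik,
         boundary = boundary),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Likelihood-ratio test: chi^2(", x$df, ") = ",
      formatC(x$lrt_statistic, digits = 3, format = "f"),
      ", p = ", formatC(x$p_value, digits = 4, format = "g"),
      if (x$boundary == "mixture") " (boundary mixture)", "\n", sep = "")
  cat("AIC full: ", round(x$aic_full, 1),
      " | AIC nested: ", round(x$aic_nested, 1), "\n", sep = "")
  invisible(x)
}
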