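# Full-information ML fitting of univariate/bivariate Cholesky twin models.
#
# The likelihood is evaluated on sufficient statistics grouped by zygosity
# and missingness pattern: for a group with n pairs, observed index set o,
# sample mean m and centered scatter S, the negative log-likelihood
# contribution is
#   n/2 [ |o| log 2pi + log det Sigma_o ] + 1/2 tr(Sigma_o^-1 S)
#     + n/2 (m - mu_o)' Sigma_o^-1 (m - mu_o),
# which makes each objective evaluation O(#patterns), independent of the
# number of pairs. The analytic gradient uses
#   d nll / d theta = 1/2 tr(W dSigma_o),
#   W = n Sigma_o^-1 - Sigma_o^-1 (S + n d d') Sigma_o^-1,
# with dSigma assembled from the Cholesky loading derivatives.

prepare_pair_data <- function(cohort, traits, sex = NULL,
                              complete_pairs_only = FALSE) {
  df <- as.data.frame(cohort)
  if (!is.null(sex) && !identical(sex, "both")) {
    df <- df[df$sex == sex, , drop = FALSE]
  }
  missing_cols <- setdiff(traits, names(df))
  if (length(missing_cols)) {
    stop("trait column(s) not in cohort: ", paste(missing_cols, collapse = ", "))
  }
  m1 <- df[df$member == 1, , drop = FALSE]
  m2 <- df[df$member == 2, , drop = FALSE]
  m2 <- m2[match(m1$pair_id, m2$pair_id), , drop = FALSE]
  Y <- cbind(as.matrix(m1[, traits, drop = FALSE]),
             as.matrix(m2[, traits, drop = FALSE]))
  zyg <- m1$zygosity
  keep <- rowSums(!is.na(Y)) > 0
  if (complete_pairs_only) keep <- keep & rowSums(is.na(Y)) == 0
  Y <- Y[keep, , drop = FALSE]
  zyg <- zyg[keep]
  list(Y = Y, zyg = zyg, traits = traits,
       n_pairs = c(MZ = sum(zyg == "MZ"), DZ = sum(zyg == "DZ")))
}

build_groups <- function(prep) {
  Y <- prep$Y
  obs <- !is.na(Y)
  key <- paste(prep$zyg, apply(obs, 1, function(r) paste(which(r), collapse = ",")))
  idx_list <- split(seq_len(nrow(Y)), key)
  lapply(idx_list, function(rows) {
    o <- which(obs[rows[1], ])
    sub <- Y[rows, o, drop = FALSE]
    m <- colMeans(sub)
    S <- if (length(rows) > 1) crossprod(sweep(sub, 2, m)) else
      matrix(0, length(o), length(o))
    list(zyg = prep$zyg[rows[1]], obs = o, n = length(rows), m = m, S = S)
  })
}

# --- parameter packing ------------------------------------------------------

model_components <- function(model) {
  second <- model_second_component(model)
  c("A", if (!is.na(second)) second, "E")
}

n_load <- function(k) k * (k + 1) / 2

par_template <- function(model, k) {
  comps <- model_components(model)
  list(model = model, k = k, comps = comps,
       n_params = length(comps) * n_load(k) + k)
}

unpack_par <- function(par, tmpl) {
  k <- tmpl$k
  nl <- n_load(k)
  loads <- list()
  pos <- 0
  for (cp in tmpl$comps) {
    loads[[cp]] <- as_lower_tri(par[pos + seq_len(nl)], k)
    pos <- pos + nl
  }
  list(loads = loads, means = par[pos + seq_len(k)])
}

pack_params <- function(params, tmpl) {
  k <- tmpl$k
  lt <- function(L) L[lower.tri(L, diag = TRUE)]
  c(unlist(lapply(tmpl$comps, function(cp) lt(params$loads[[cp]]))),
    params$means)
}

params_from_par <- function(par, tmpl, traits) {
  up <- unpack_par(par, tmpl)
  second <- model_second_component(tmpl$model)
  cholesky_params(
    model = tmpl$model, traits = traits,
    a = up$loads$A,
    c = if (identical(second, "C")) up$loads$C,
    d = if (identical(second, "D")) up$loads$D,
    e = up$loads$E,
    means = up$means
  )
}

# Per-zygosity full covariance and per-parameter derivative blocks.
sigma_and_derivs <- function(up, tmpl, want_derivs = FALSE) {
  k <- tmpl$k
  mats <- lapply(up$loads, tcrossprod)
  out <- list()
  for (zyg in c("MZ", "DZ")) {
    V <- Reduce(`+`, mats)
    K <- Reduce(`+`, Map(function(m, cp) cross_twin_coef(cp, zyg) * m,
                         mats, names(mats)))
    out[[zyg]] <- list(sigma = rbind(cbind(V, K), cbind(K, V)))
  }
  if (want_derivs) {
    lt_idx <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
    for (zyg in c("MZ", "DZ")) {
      derivs <- vector("list", length(tmpl$comps) * n_load(k))
      p <- 0
      for (cp in tmpl$comps) {
        L <- up$loads[[cp]]
        coef <- cross_twin_coef(cp, zyg)
        for (r in seq_len(nrow(lt_idx))) {
          Eij <- matrix(0, k, k)
          Eij[lt_idx[r, 1], lt_idx[r, 2]] <- 1
          dX <- Eij %*% t(L)
          dX <- dX + t(dX)
          p <- p + 1
          derivs[[p]] <- rbind(cbind(dX, coef * dX), cbind(coef * dX, dX))
        }
      }
      out[[zyg]]$derivs <- derivs
    }
  }
  out
}

make_fiml_objective <- function(groups, tmpl) {
  k <- tmpl$k
  n_cov <- length(tmpl$comps) * n_load(k)
  const <- 0.5 * log(2 * pi)

  objective <- function(par) {
    up <- unpack_par(par, tmpl)
    sig <- sigma_and_derivs(up, tmpl)
    mu <- rep(up$means, 2)
    nll <- 0
    for (g in groups) {
      s <- sig[[g$zyg]]$sigma[g$obs, g$obs, drop = FALSE]
      r <- tryCatch(chol(s), error = function(e) NULL)
      if (is.null(r)) return(1e10)
      d <- g$m - mu[g$obs]
      sinv_d <- backsolve(r, backsolve(r, d, transpose = TRUE))
      sinv_S_tr <- sum(chol2inv(r) * g$S)
      nll <- nll + g$n * (length(g$obs) * const + sum(log(diag(r)))) +
        0.5 * sinv_S_tr + 0.5 * g$n * sum(d * sinv_d)
    }
    nll
  }

  gradient <- function(par) {
    up <- unpack_par(par, tmpl)
    sig <- sigma_and_derivs(up, tmpl, want_derivs = TRUE)
    mu <- rep(up$means, 2)
    gcov <- numeric(n_cov)
    gmu_full <- numeric(2 * k)
    for (g in groups) {
      s <- sig[[g$zyg]]$sigma[g$obs, g$obs, drop = FALSE]
      r <- tryCatch(chol(s), error = function(e) NULL)
      if (is.null(r)) return(numeric(tmpl$n_params))
      sinv <- chol2inv(r)
      d <- g$m - mu[g$obs]
      sinv_d <- sinv %*% d
      W <- g$n * sinv - sinv %*% (g$S + g$n * tcrossprod(d)) %*% sinv
      derivs <- sig[[g$zyg]]$derivs
      for (p in seq_len(n_cov)) {
        gcov[p] <- gcov[p] +
          0.5 * sum(W * derivs[[p]][g$obs, g$obs, drop = FALSE])
      }
      gmu_full[g$obs] <- gmu_full[g$obs] - g$n * sinv_d
    }
    gmu <- gmu_full[seq_len(k)] + gmu_full[k + seq_len(k)]
    c(gcov, gmu)
  }

  list(objective = objective, gradient = gradient)
}

# --- starting values --------------------------------------------------------

pd_project <- function(M, floor_frac = 0.02) {
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  floor_val <- floor_frac * mean(pmax(diag(M), 0.1))
  lam <- pmax(es$values, floor_val)
  es$vectors %*% (lam * t(es$vectors))
}

lower_chol <- function(M) t(chol(pd_project(M)))

moment_component_estimates <- function(prep, model) {
  k <- length(prep$traits)
  stack <- rbind(prep$Y[, seq_len(k), drop = FALSE],
                 prep$Y[, k + seq_len(k), drop = FALSE])
  V <- cov(stack, use = "pairwise.complete.obs")
  cross_cov <- function(z) {
    Yz <- prep$Y[prep$zyg == z, , drop = FALSE]
    K <- cov(Yz[, seq_len(k), drop = FALSE], Yz[, k + seq_len(k), drop = FALSE],
             use = "pairwise.complete.obs")
    (K + t(K)) / 2
  }
  Kmz <- cross_cov("MZ")
  Kdz <- cross_cov("DZ")
  if (anyNA(V) || anyNA(Kmz) || anyNA(Kdz)) return(NULL)
  if (model == "ADE") {
    A <- 4 * Kdz - Kmz
    S2 <- Kmz - A
  } else {
    A <- 2 * (Kmz - Kdz)
    S2 <- if (model == "ACE") 2 * Kdz - Kmz else matrix(0, k, k)
  }
  E <- V - A - S2
  list(V = V, A = A, second = S2, E = E)
}

build_starts <- function(prep, tmpl, n_starts) {
  k <- tmpl$k
  comps <- tmpl$comps
  stack <- rbind(prep$Y[, seq_len(k), drop = FALSE],
                 prep$Y[, k + seq_len(k), drop = FALSE])
  means <- colMeans(stack, na.rm = TRUE)
  vars <- pmax(apply(stack, 2, var, na.rm = TRUE), 1e-4)

  split_start <- function(rho) {
    frac <- if (length(comps) == 3) c(0.4, 0.2, 0.4) else c(0.5, 0.5)
    R <- matrix(rho, k, k); diag(R) <- 1
    D <- diag(sqrt(vars), k)
    loads <- lapply(frac, function(f) lower_chol(f * (D %*% R %*% D)))
    c(unlist(lapply(loads, function(L) L[lower.tri(L, diag = TRUE)])), means)
  }

  starts <- list()
  mom <- moment_component_estimates(prep, tmpl$model)
  if (!is.null(mom)) {
    to_par <- function(A, S2, E) {
      loads <- list(A = lower_chol(A))
      if (length(comps) == 3) loads[[comps[2]]] <- lower_chol(S2)
      loads$E <- lower_chol(E)
      c(unlist(lapply(comps, function(cp)
        loads[[cp]][lower.tri(loads[[cp]], diag = TRUE)])), means)
    }
    starts$moment <- to_par(mom$A, mom$second, mom$E)
    starts$moment_half_a <- to_par(mom$A / 2, mom$second,
                                   mom$E + diag(diag(mom$A) / 2, k))
  }
  starts$split_r0 <- split_start(0)
  starts$split_rpos <- split_start(0.3)
  starts$split_rneg <- split_start(-0.3)
  starts[seq_len(min(n_starts, length(starts)))]
}

# --- main fitting routine ---------------------------------------------------

fit_twin_ml <- function(cohort, traits, model, sex = NULL,
                        n_starts = 5, complete_pairs_only = FALSE,
                        min_pairs = 30, se = TRUE, conf_level = 0.95) {
  model <- match.arg(model, c("ACE", "ADE", "AE"))
  prep <- prepare_pair_data(cohort, traits, sex, complete_pairs_only)
  if (any(prep$n_pairs < min_pairs)) {
    stop("fewer than ", min_pairs, " pairs per zygosity (MZ: ",
         prep$n_pairs["MZ"], ", DZ: ", prep$n_pairs["DZ"], ")")
  }
  groups <- build_groups(prep)
  tmpl <- par_template(model, length(traits))
  fns <- make_fiml_objective(groups, tmpl)
  starts <- build_starts(prep, tmpl, n_starts)

  runs <- lapply(starts, function(st) {
    tryCatch(
      nlminb(st, fns$objective, fns$gradient,
             control = list(iter.max = 1000, eval.max = 2000)),
      error = function(e) NULL
    )
  })
  runs <- Filter(Negate(is.null), runs)
  runs <- Filter(function(r) is.finite(r$objective) && r$objective < 1e9, runs)
  if (!length(runs)) stop("twin-model optimization failed from every start")
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  gnorms <- vapply(runs, function(r) max(abs(fns$gradient(r$par))), numeric(1))
  conv <- vapply(runs, function(r) r$convergence == 0, logical(1))
  ord <- order(!conv, objs, gnorms)
  best <- runs[[ord[1]]]
  if (!any(conv)) {
    warning("optimizer did not report convergence; best gradient norm ",
            signif(min(gnorms), 3))
  }

  par <- best$par
  params <- params_from_par(par, tmpl, traits)
  covs <- component_covariances(params)
  vcov <- NULL
  if (se) {
    H <- numeric_jacobian(fns$gradient, par)
    H <- (H + t(H)) / 2
    vcov <- tryCatch(solve(H), error = function(e) NULL)
  }
  list(prep = prep, tmpl = tmpl, fns = fns, par = par, params = params,
       component_covariances = covs, loglik = -best$objective,
       n_params = tmpl$n_params, n_pairs = prep$n_pairs, vcov = vcov,
       convergence = list(code = best$convergence,
                          message = best$message,
                          gradient_norm = max(abs(fns$gradient(par))),
                          n_starts_used = length(starts)),
       conf_level = conf_level)
}

numeric_jacobian <- function(fn, x, h_rel = 1e-5) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h <- h_rel * (abs(x[i]) + 1)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    J[, i] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

# Delta-method CI for a scalar smooth function of the parameter vector,
# on the Fisher-z scale when the quantity is a correlation.
delta_ci <- function(fn, par, vcov, conf_level, correlation = TRUE) {
  est <- fn(par)
  if (is.null(vcov)) {
    return(list(estimate = est, se = NA_real_, lower = NA_real_,
                upper = NA_real_))
  }
  g <- vapply(seq_along(par), function(i) {
    h <- 1e-6 * (abs(par[i]) + 1)
    xp <- par; xp[i] <- par[i] + h
    xm <- par; xm[i] <- par[i] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(1))
  v <- drop(t(g) %*% vcov %*% g)
  se <- sqrt(max(v, 0))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  if (correlation && abs(est) < 0.9999) {
    zeta <- atanh(est)
    se_z <- se / (1 - est^2)
    list(estimate = est, se = se,
         lower = tanh(zeta - zq * se_z), upper = tanh(zeta + zq * se_z))
  } else {
    list(estimate = est, se = se, lower = est - zq * se, upper = est + zq * se)
  }
}

#' Fit a bivariate Cholesky twin model by full-information ML
#'
#' Maximizes the sum of per-pair multivariate-normal log-likelihoods over
#' MZ and same-sex DZ pairs (see [pair_loglik()]) using a quasi-Newton
#' optimizer with analytic gradients from several deterministic starting
#' points (a moment-based start from the observed twin covariances plus
#' even variance splits with cross-trait correlations 0 and +/-0.3).
#' Returns component correlations with delta-method confidence intervals
#' computed on the Fisher-z scale, and the decomposition of the phenotypic
#' correlation into component contributions.
#'
#' @param cohort A twin cohort table (one row per individual) with columns
#'   `pair_id`, `member`, `zygosity`, `sex` and the trait columns.
#' @param trait1,trait2 Trait column names.
#' @param model `"ACE"`, `"ADE"` or `"AE"`.
#' @param sex `"male"`, `"female"` or `"both"`.
#' @param n_starts Number of deterministic starting points (1--5).
#' @param complete_pairs_only Drop pairs with any missing trait value
#'   instead of using their observed subvector.
#' @param min_pairs Minimum pairs required per zygosity.
#' @param se Compute the observed-information covariance matrix and CIs.
#' @param conf_level Confidence level for intervals.
#' @return An object of class `bivariate_fit`: estimates, component
#'   covariance blocks, log-likelihood, phenotypic/component correlations
#'   with CIs, percent-of-correlation decomposition, convergence
#'   diagnostics.
#' @export
fit_bivariate <- function(cohort, trait1, trait2,
                          model = c("ACE", "ADE", "AE"),
                          sex = "both", n_starts = 5,
                          complete_pairs_only = FALSE,
                          min_pairs = 30, se = TRUE, conf_level = 0.95) {
  model <- match.arg(model)
  traits <- c(trait1, trait2)
  base <- fit_twin_ml(cohort, traits, model, sex, n_starts,
                      complete_pairs_only, min_pairs, se, conf_level)
  tmpl <- base$tmpl
  second <- model_second_component(model)

  corr_fn <- function(component) {
    function(par) {
      up <- unpack_par(par, tmpl)
      M <- tcrossprod(up$loads[[component]])
      M[1, 2] / sqrt(M[1, 1] * M[2, 2])
    }
  }
  pheno_fn <- function(par) {
    up <- unpack_par(par, tmpl)
    V <- Reduce(`+`, lapply(up$loads, tcrossprod))
    V[1, 2] / sqrt(V[1, 1] * V[2, 2])
  }

  cis <- list(
    r_phenotypic = delta_ci(pheno_fn, base$par, base$vcov, conf_level),
    rA = delta_ci(corr_fn("A"), base$par, base$vcov, conf_level),
    rE = delta_ci(corr_fn("E"), base$par, base$vcov, conf_level)
  )
  if (!is.na(second)) {
    cis[[paste0("r", second)]] <-
      delta_ci(corr_fn(second), base$par, base$vcov, conf_level)
  }

  decomposition <- decompose_trait_correlation(base$component_covariances)
  boundary <- abs(cis$rA$estimate) > 0.98 ||
    (!is.na(second) && abs(cis[[paste0("r", second)]]$estimate) > 0.98)

  structure(
    c(base[c("params", "component_covariances", "loglik", "n_params",
             "n_pairs", "vcov", "convergence", "conf_level")],
      list(model = model, traits = traits, sex = sex,
           correlations = cis, decomposition = decomposition,
           boundary = boundary,
           par = base$par, tmpl = base$tmpl)),
    class = "bivariate_fit"
  )
}

#' Fit a univariate twin variance-component model by full-information ML
#'
#' Same machinery as [fit_bivariate()] for a single trait; reports
#' standardized variance components (e.g. heritability `a2 = A / V`).
#'
#' @inheritParams fit_bivariate
#' @param trait Trait column name.
#' @return An object of class `univariate_fit` with standardized variance
#'   fractions, log-likelihood and convergence diagnostics.
#' @export
fit_univariate <- function(cohort, trait, model = c("ACE", "ADE", "AE"),
                           sex = "both", n_starts = 5,
                           complete_pairs_only = FALSE,
                           min_pairs = 30, se = TRUE, conf_level = 0.95) {
  model <- match.arg(model)
  base <- fit_twin_ml(cohort, trait, model, sex, n_starts,
                      complete_pairs_only, min_pairs, se, conf_level)
  covs <- base$component_covariances
  V <- covs$V[1, 1]
  fracs <- c(a2 = covs$A[1, 1] / V,
             if (model == "ACE") c(c2 = covs$C[1, 1] / V),
             if (model == "ADE") c(d2 = covs$D[1, 1] / V),
             e2 = covs$E[1, 1] / V)
  structure(
    c(base[c("params", "component_covariances", "loglik", "n_params",
             "n_pairs", "vcov", "convergence", "conf_level")],
      list(model = model, trait = trait, sex = sex,
           variance_fractions = fracs,
           par = base$par, tmpl = base$tmpl)),
    class = "univariate_fit"
  )
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat("Bivariate ", x$model, " twin model: ", paste(x$traits, collapse = " ~ "),
      " (", x$sex, ")\n", sep = "")
  cat("  pairs: ", x$n_pairs["MZ"], " MZ + ", x$n_pairs["DZ"],
      " DZ | loglik: ", formatC(x$loglik, format = "f", digits = 2),
      " | params: ", x$n_params, "\n", sep = "")
  for (nm in names(x$correlations)) {
    ci <- x$correlations[[nm]]
    cat(sprintf("  %-13s %6.3f  [%6.3f, %6.3f]\n", nm,
                ci$estimate, ci$lower, ci$upper))
  }
  dec <- x$decomposition
  cat("  % of r explained:",
      paste(sprintf("%s %.0f%%", dec$component, dec$percent), collapse = ", "),
      "\n")
  if (x$boundary) cat("  note: boundary solution (|component correlation| near 1)\n")
  invisible(x)
}

#' @export
print.univariate_fit <- function(x, ...) {
  cat("Univariate ", x$model, " twin model: ", x$trait,
      " (", x$sex, ")\n", sep = "")
  cat("  pairs: ", x$n_pairs["MZ"], " MZ + ", x$n_pairs["DZ"],
      " DZ | loglik: ", formatC(x$loglik, format = "f", digits = 2), "\n",
      sep = "")
  fr <- x$variance_fractions
  cat(" ", paste(sprintf("%s = %.3f", names(fr), fr), collapse = ", "), "\n")
  invisible(x)
}
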