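# Independent oracles, deliberately coded with naive dense linear algebra
# (explicit solve() / det()) so they share no code path with the package.

# Multivariate-normal log-density of the observed subvector of y.
oracle_mvn_loglik <- function(y, mu, sigma) {
  obs <- which(!is.na(y))
  if (!length(obs)) return(0)
  s <- sigma[obs, obs, drop = FALSE]
  d <- y[obs] - mu[obs]
  -0.5 * (length(obs) * log(2 * pi) + log(det(s)) +
            drop(t(d) %*% solve(s) %*% d))
}

# Brute-force cluster sandwich covariance with the Stata-style small-sample
# factor G/(G-1) * (N-1)/(N-k) (X includes the intercept column).
oracle_cluster_vcov <- function(X, y, cluster) {
  n <- nrow(X); k <- ncol(X)
  bread <- solve(t(X) %*% X)
  beta <- bread %*% t(X) %*% y
  e <- drop(y - X %*% beta)
  meat <- matrix(0, k, k)
  for (g in unique(cluster)) {
    idx <- which(cluster == g)
    sg <- t(X[idx, , drop = FALSE]) %*% e[idx]
    meat <- meat + sg %*% t(sg)
  }
  G <- length(unique(cluster))
  adj <- G / (G - 1) * (n - 1) / (n - k)
  list(beta = drop(beta), vcov = adj * bread %*% meat %*% bread)
}

# Direct adjusted Fisher-Pearson skewness from raw moments.
oracle_skewness <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s3 <- (sum((x - m)^2) / n)^(3 / 2)
  (sum((x - m)^3) / n) / s3 * sqrt(n * (n - 1)) / (n - 2)
}

# Random Cholesky parameter set for likelihood oracle checks.
random_params <- function(model, k = 2) {
  lt <- function() {
    L <- matrix(0, k, k)
    L[lower.tri(L, diag = TRUE)] <- rnorm(k * (k + 1) / 2, sd = 0.6)
    diag(L) <- abs(diag(L)) + 0.3
    L
  }
  cholesky_params(
    model = model,
    traits = paste0("t", seq_len(k)),
    a = lt(),
    c = if (model == "ACE") lt(),
    d = if (model == "ADE") lt(),
    e = lt(),
    means = rnorm(k, sd = 0.5)
  )
}

make_pair <- function(zygosity, y) list(zygosity = zygosity, y = y)

# Intraclass correlations of one trait by zygosity, computed directly.
icc_by_zygosity <- function(cohort, trait) {
  m1 <- cohort[cohort$member == 1, ]
  m2 <- cohort[cohort$member == 2, ]
  m2 <- m2[match(m1$pair_id, m2$pair_id), ]
  vapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
    idx <- m1$zygosity == z
    cor(m1[[trait]][idx], m2[[trait]][idx], use = "complete.obs")
  }, numeric(1))
}

# Three standardized traits whose phenotypic correlation matrix equals R:
# identical variance fractions per trait with every component sharing R.
mediation_config <- function(R, traits = c("pa", "bmi16", "bmi18"),
                             n_mz_pairs = 1000, n_dz_pairs = 1000, seed = 1) {
  bivariate_config(traits = traits, a2 = 0.5, c2 = 0, e2 = 0.5,
                   rA = R, rC = diag(3), rE = R,
                   n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
                   seed = seed)
}
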