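# Independent oracles used across the suite. These deliberately avoid the
# package's own computation paths: brute-force simulation, direct
# joint-covariance algebra and explicit eigen-clipping.

# Random symmetric PSD matrix via crossproduct of a Gaussian factor.
rand_psd <- function(p, seed, rank = p) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(p * rank), p, rank)
    tcrossprod(A) / rank + diag(1e-8, p)
  })
}

# Brute-force variance-explained measures: simulate GE effects at large v
# with G = I and compute every statistic empirically from the effects.
empirical_decomposition <- function(Ge, v = 1e5, seed = 1) {
  p <- nrow(Ge)
  u <- withr::with_seed(seed, {
    root <- with(eigen(Ge, symmetric = TRUE),
                 vectors %*% (sqrt(pmax(values, 0)) * t(vectors)))
    matrix(rnorm(v * p), v, p) %*% root
  })
  mains <- rowMeans(u)
  env_var <- apply(u, 2, var)
  rho_star <- apply(u, 2, function(col) cor(col, mains))
  list(sigma2_g = var(mains),
       total = mean(env_var),
       sigma2_ge = mean(env_var) - var(mains),
       sigma2_ge_h = mean(env_var) - mean(sqrt(env_var))^2,
       sigma2_n = mean(rho_star^2 * env_var))
}

# Direct joint-covariance BLUP on plot-level data:
#   V = Z1 (s2g K) Z1' + s2ge Z2 Z2' + s2e I,  tau_hat by GLS,
#   g_hat = s2g K Z1' V^{-1} (y - X tau_hat).
blup_oracle <- function(dataset, sigma2_g, sigma2_ge, sigma2_eps, K = NULL) {
  geno <- factor(as.character(dataset$genotype))
  env <- factor(as.character(dataset$env))
  v <- nlevels(geno)
  n <- nrow(dataset)
  if (is.null(K)) K <- diag(v)
  Z1 <- matrix(0, n, v)
  Z1[cbind(seq_len(n), as.integer(geno))] <- 1
  cell <- interaction(geno, env, drop = TRUE)
  Z2 <- matrix(0, n, nlevels(cell))
  Z2[cbind(seq_len(n), as.integer(cell))] <- 1
  X <- if (nlevels(env) < 2) matrix(1, n, 1) else model.matrix(~env)
  V <- Z1 %*% (sigma2_g * K) %*% t(Z1) + sigma2_ge * tcrossprod(Z2) +
    diag(sigma2_eps, n)
  Vi <- solve(V)
  y <- dataset$phenotype
  tau_hat <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  resid <- y - X %*% tau_hat
  g_hat <- drop(sigma2_g * K %*% t(Z1) %*% Vi %*% resid)
  setNames(g_hat, levels(geno))
}

# Tiny multiplicative-terms object for direct construction in tests.
terms_from_matrix <- function(m, k = nrow(m)) decompose_covariance(m, k = k)

# Row-subset of a population without relying on package internals.
pop_subset_for_test <- function(pop, idx) {
  pop$h1 <- pop$h1[idx, , drop = FALSE]
  pop$h2 <- pop$h2[idx, , drop = FALSE]
  pop$ids <- pop$ids[idx]
  pop
}

numerical_rank <- function(m, tol = 1e-10) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  sum(ev > tol * max(ev))
}
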