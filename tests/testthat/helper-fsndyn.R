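# Shared fixtures and independent oracles, all built in code.

# small panel with known truth, reused across sampler tests
tiny_panel <- function(n = 4, T_ = 3, p = 1, seed = 11,
                       nugget = 0.3, sill = 0.2, decay = 0.002,
                       innovation_sd = 0.2) {
  co <- simulate_coords(n, seed = seed)
  tr <- simulate_truth(co, n_years = T_, p = p, seed = seed + 1,
                       beta0 = rep(1, p),
                       innovation_cov = diag(innovation_sd^2, p),
                       nugget_var = nugget, sill_var = sill, decay = decay)
  simulate_panel(tr, seed = seed + 2)
}

# a valid state at the truth of a panel (for conditioning in block tests)
truth_state <- function(panel) {
  tr <- panel$truth
  list(beta = tr$beta_path, beta0 = tr$beta0,
       spatial = tr$spatial_effects,
       nugget_var = pmax(tr$nugget_var_path, 1e-8),
       sill_var = pmax(tr$sill_var_path, 1e-8),
       decay = tr$decay_path,
       innovation_cov = tr$innovation_cov)
}

# batch-means Monte-Carlo standard error (accounts for chain autocorrelation)
mcse_batch <- function(x, n_batches = 30) {
  n <- length(x)
  b <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches), function(i)
    mean(x[((i - 1) * b + 1):(i * b)]), numeric(1))
  sd(means) / sqrt(n_batches)
}

# --- brute-force joint-Gaussian posterior oracles ---------------------------

# stacked prior covariance of beta_{1:T} (p = 1): Sigma0 + min(s,t) * q
beta_prior_cov <- function(T_, Sigma0, q) {
  outer(seq_len(T_), seq_len(T_), function(s, t) Sigma0 + pmin(s, t) * q)
}

# stacked prior covariance of the spatial field (column-major by time):
# cov(aleph_s, aleph_t) = sum_{u <= min(s,t)} sill_u * C_u
spatial_prior_cov <- function(C_list, sill) {
  T_ <- length(C_list); n <- nrow(C_list[[1]])
  blocks <- lapply(seq_len(T_), function(u) sill[u] * C_list[[u]])
  V <- matrix(0, n * T_, n * T_)
  for (s in seq_len(T_)) for (t in seq_len(T_)) {
    acc <- matrix(0, n, n)
    for (u in seq_len(min(s, t))) acc <- acc + blocks[[u]]
    V[((s - 1) * n + 1):(s * n), ((t - 1) * n + 1):(t * n)] <- acc
  }
  V
}

# Gaussian posterior (mean, cov) for z ~ N(m0, V0), y = A z + e, e ~ N(0, diag(v))
gaussian_posterior <- function(m0, V0, A, y, v) {
  P <- solve(V0) + t(A) %*% diag(1 / v, length(v)) %*% A
  S <- solve(P)
  mu <- S %*% (solve(V0, m0) + t(A) %*% (y / v))
  list(mean = drop(mu), cov = (S + t(S)) / 2)
}

# textbook log-density oracles (independent of the package internals)
oracle_dnorm <- function(x, m, v) -0.5 * log(2 * pi * v) - (x - m)^2 / (2 * v)
oracle_dmvnorm <- function(x, m, S) {
  k <- length(x)
  -0.5 * (k * log(2 * pi) + determinant(S)$modulus[1] +
            drop(t(x - m) %*% solve(S) %*% (x - m)))
}
oracle_dgamma <- function(x, a, b) a * log(b) - lgamma(a) + (a - 1) * log(x) - b * x
oracle_dinvwish_1d <- function(x, df, s) {
  # p = 1 inverse-Wishart == inverse-gamma(df/2, s/2)
  (df / 2) * log(s / 2) - lgamma(df / 2) - (df / 2 + 1) * log(x) - s / (2 * x)
}
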