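# Conjugate-oracle and brute-force checks of the individual Gibbs blocks.
# Acceptance-scale versions (larger draw counts) live in test-acceptance.R.

test_that("nugget update matches its conjugate Gamma full conditional", {
  co <- tibble::tibble(site_id = c("A", "B"), lon = c(0, 10), lat = c(0, 5))
  X <- array(1, dim = c(2, 2, 1), dimnames = list(NULL, NULL, "intercept"))
  pan <- fsndyn:::new_panel(Y = matrix(c(1, -1, 1, -1), 2, 2), X = X,
                            coords = as.matrix(co[, 2:3]),
                            site_ids = co$site_id, years = 1:2,
                            mask = matrix(TRUE, 2, 2), transform = "identity")
  st <- list(beta = matrix(0, 2, 1), spatial = matrix(0, 2, 2),
             nugget_var = c(1, 1), sill_var = c(1, 1),
             decay = c(0.01, 0.01), innovation_cov = diag(1))
  pr <- prior_spec(1, a_eps = 2, b_eps = 1, decay_bounds = c(1e-3, 1))
  # residuals (1, -1) at each t: posterior Gamma(2 + 1, 1 + 1) on the precision
  set.seed(1)
  M <- 20000
  prec <- replicate(M, 1 / sample_nugget_variances(pan, st, pr)[1])
  se <- sd(prec) / sqrt(M)
  expect_lt(abs(mean(prec) - 1.5), 3 * se)
  expect_equal(var(prec), 3 / 4, tolerance = 0.05)
  # zero residuals: posterior Gamma(a + k/2, b), precision stochastically larger
  pan0 <- pan; pan0$Y[] <- 0
  prec0 <- replicate(5000, 1 / sample_nugget_variances(pan0, st, pr)[1])
  expect_equal(mean(prec0), 3 / 1, tolerance = 3 * sd(prec0) / sqrt(5000) / 3 + 0.05)
  expect_gt(mean(prec0), mean(prec))
})

test_that("sill update matches the 2x2 closed-form full conditional", {
  # two sites at distance d with decay = log(2)/d -> correlation exactly 0.5
  co <- tibble::tibble(site_id = c("A", "B"), lon = c(0, 0),
                       lat = c(0, 100 / 111.3194908))
  d <- great_circle_km(co)[1, 2]
  th <- log(2) / d
  X <- array(1, dim = c(2, 2, 1))
  pan <- fsndyn:::new_panel(Y = matrix(0, 2, 2), X = X,
                            coords = as.matrix(co[, 2:3]),
                            site_ids = co$site_id, years = 1:2,
                            mask = matrix(TRUE, 2, 2), transform = "identity")
  # omega_1 = (1, 1); omega_2 = 0 (field constant after t = 1)
  st <- list(beta = matrix(0, 2, 1),
             spatial = matrix(c(1, 1, 1, 1), 2, 2),
             nugget_var = c(1, 1), sill_var = c(1, 1),
             decay = c(th, th), innovation_cov = diag(1))
  pr <- prior_spec(1, a_w = 2, b_w = 1, decay_bounds = c(th / 10, th * 10))
  # quadratic form (1,1) C^-1 (1,1)' = 2 / 1.5 = 4/3
  set.seed(2)
  M <- 20000
  draws <- replicate(M, 1 / sample_sill_variances(pan, st, pr))
  prec1 <- draws[1, ]; prec2 <- draws[2, ]
  m1 <- (2 + 1) / (1 + 2 / 3)     # Gamma(a + n/2, b + quad/2) mean
  expect_lt(abs(mean(prec1) - m1), 3 * sd(prec1) / sqrt(M))
  # omega = 0 at t = 2: posterior rate equals the prior rate
  m2 <- (2 + 1) / 1
  expect_lt(abs(mean(prec2) - m2), 3 * sd(prec2) / sqrt(M))
})

test_that("sill update with identity correlation reduces to the nugget-style form", {
  co <- simulate_coords(3, seed = 4)
  X <- array(1, dim = c(3, 2, 1))
  pan <- fsndyn:::new_panel(Y = matrix(0, 3, 2), X = X,
                            coords = fsndyn:::coords_matrix(co),
                            site_ids = co$site_id, years = 1:2,
                            mask = matrix(TRUE, 3, 2), transform = "identity")
  om <- c(0.5, -1, 2)
  st <- list(beta = matrix(0, 2, 1), spatial = cbind(om, om),
             nugget_var = c(1, 1), sill_var = c(1, 1),
             decay = c(50, 50), innovation_cov = diag(1))  # C ~ identity
  pr <- prior_spec(1, a_w = 2, b_w = 1, decay_bounds = c(1, 100))
  set.seed(5)
  M <- 20000
  prec <- replicate(M, 1 / sample_sill_variances(pan, st, pr)[1])
  m <- (2 + 1.5) / (1 + sum(om^2) / 2)
  expect_lt(abs(mean(prec) - m), 3 * sd(prec) / sqrt(M))
})

test_that("innovation covariance update matches the scalar conjugate oracle", {
  # p = 1: inverse-Wishart(df + T, scale + S) == inverse-gamma
  st <- list(beta = matrix(c(1.2, 0.8, 1.5), 3, 1), beta0 = 1)
  pr <- prior_spec(1, wishart_df = 5, wishart_scale = diag(2, 1),
                   decay_bounds = c(0.001, 0.1))
  S <- sum(diff(c(1, 1.2, 0.8, 1.5))^2)
  df_post <- 5 + 3
  scale_post <- 2 + S
  set.seed(6)
  M <- 20000
  draws <- replicate(M, sample_innovation_cov(st, pr)[1, 1])
  m_true <- scale_post / (df_post - 2)
  expect_lt(abs(mean(draws) - m_true), 3 * sd(draws) / sqrt(M))
  # T zero innovations: posterior IW(df + T, scale)
  st0 <- list(beta = matrix(1, 3, 1), beta0 = 1)
  draws0 <- replicate(M, sample_innovation_cov(st0, pr)[1, 1])
  expect_lt(abs(mean(draws0) - 2 / (8 - 2)), 3 * sd(draws0) / sqrt(M))
})

test_that("innovation covariance draws are symmetric positive definite (p = 2)", {
  st <- list(beta = matrix(rnorm(8), 4, 2), beta0 = c(0, 0))
  pr <- prior_spec(2, decay_bounds = c(0.001, 0.1))
  set.seed(7)
  for (i in 1:200) {
    S <- sample_innovation_cov(st, pr)
    expect_equal(S, t(S), tolerance = 1e-12)
    expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("FFBS at T = 1 reproduces the conjugate Bayesian-regression posterior", {
  set.seed(8)
  n <- 6; p <- 2
  X <- cbind(1, rnorm(n))
  ytrue <- drop(X %*% c(1, -0.5)) + rnorm(n, 0, 0.5)
  sig2 <- 0.25
  d0 <- c(0, 0); Sigma0 <- diag(2, p); Seta <- diag(0.5, p)
  Sstar <- Sigma0 + Seta       # prior covariance of beta_1
  Prec <- crossprod(X) / sig2 + solve(Sstar)
  Vpost <- solve(Prec)
  mpost <- drop(Vpost %*% (crossprod(X, ytrue) / sig2 + solve(Sstar, d0)))
  M <- 8000
  draws <- t(replicate(M, fsndyn:::ffbs_draw(
    list(ytrue), list(X), sig2, list(Seta), d0, Sigma0)[, 2]))
  for (j in 1:p) {
    se <- sd(draws[, j]) / sqrt(M)
    expect_lt(abs(mean(draws[, j]) - mpost[j]), 3 * se)
  }
  expect_equal(cov(draws), Vpost, tolerance = 0.08)
})

test_that("FFBS with vanishing innovation covariance yields a constant path", {
  pan <- tiny_panel(n = 4, T_ = 3, p = 1, seed = 81)
  st <- truth_state(pan)
  st$innovation_cov <- diag(1e-18, 1)
  pr <- prior_spec(1, coords = pan$coords)
  set.seed(9)
  b <- ffbs_beta(pan, st, pr)$beta
  expect_lt(max(abs(diff(b))), 1e-6)
})

test_that("FFBS matches the brute-force joint Gaussian posterior (n=4, T=3, p=1)", {
  pan <- tiny_panel(n = 4, T_ = 3, p = 1, seed = 91)
  st <- truth_state(pan)
  pr <- prior_spec(1, coords = pan$coords, Sigma0 = diag(1.5, 1),
                   decay_bounds = c(1e-4, 1))
  q <- st$innovation_cov[1, 1]
  V0 <- beta_prior_cov(3, pr$Sigma0[1, 1], q)
  # A maps stacked beta_{1:3} to stacked observations (time-major)
  A <- matrix(0, 12, 3)
  y <- v <- numeric(12)
  for (t in 1:3) {
    rows <- (t - 1) * 4 + 1:4
    A[rows, t] <- pan$X[, t, 1]
    y[rows] <- pan$Y[, t] - st$spatial[, t]
    v[rows] <- st$nugget_var[t]
  }
  oracle <- gaussian_posterior(rep(pr$d0, 3), V0, A, y, v)
  cache <- fsndyn:::panel_cache(pan)
  set.seed(10)
  M <- 6000
  draws <- t(replicate(M, drop(ffbs_beta(pan, st, pr, cache)$beta)))
  for (t in 1:3) {
    se <- sd(draws[, t]) / sqrt(M)
    expect_lt(abs(mean(draws[, t]) - oracle$mean[t]), 3 * se)
  }
  expect_equal(cov(draws), oracle$cov, tolerance = 0.1)
})

test_that("spatial-field draw matches the brute-force joint Gaussian posterior (n=4, T=3)", {
  pan <- tiny_panel(n = 4, T_ = 3, p = 1, seed = 101)
  st <- truth_state(pan)
  pr <- prior_spec(1, coords = pan$coords, decay_bounds = c(1e-4, 1))
  C_list <- lapply(st$decay, function(th) build_correlation(pan$coords, th))
  V0 <- spatial_prior_cov(C_list, st$sill_var)
  y <- v <- numeric(12)
  for (t in 1:3) {
    rows <- (t - 1) * 4 + 1:4
    y[rows] <- pan$Y[, t] - drop(matrix(pan$X[, t, ], 4, 1) %*% st$beta[t, ])
    v[rows] <- st$nugget_var[t]
  }
  oracle <- gaussian_posterior(rep(0, 12), V0, diag(12), y, v)
  cache <- fsndyn:::panel_cache(pan)
  set.seed(11)
  M <- 5000
  draws <- t(replicate(M, as.vector(
    sample_spatial_effects(pan, st, pr, C_list, cache))))
  for (j in 1:12) {
    se <- sd(draws[, j]) / sqrt(M)
    expect_lt(abs(mean(draws[, j]) - oracle$mean[j]), 3.5 * se)
  }
  expect_equal(cov(draws), oracle$cov, tolerance = 0.12)
})

test_that("spatial-field draw reverts to the prior random walk when data are uninformative", {
  pan <- tiny_panel(n = 3, T_ = 2, p = 1, seed = 111)
  st <- truth_state(pan)
  st$nugget_var <- rep(1e12, 2)     # observation variance -> infinity
  pr <- prior_spec(1, coords = pan$coords, decay_bounds = c(1e-4, 1))
  C_list <- lapply(st$decay, function(th) build_correlation(pan$coords, th))
  cache <- fsndyn:::panel_cache(pan)
  set.seed(12)
  M <- 5000
  draws <- t(replicate(M, as.vector(
    sample_spatial_effects(pan, st, pr, C_list, cache))))
  # prior moments: mean 0; var(aleph_1) = sill_1, var(aleph_2) = sill_1 + sill_2
  expect_lt(max(abs(colMeans(draws))), 4 * max(apply(draws, 2, sd)) / sqrt(M))
  v1 <- st$sill_var[1]; v2 <- st$sill_var[1] + st$sill_var[2]
  expect_equal(unname(apply(draws[, 1:3], 2, var)), rep(v1, 3), tolerance = 0.1)
  expect_equal(unname(apply(draws[, 4:6], 2, var)), rep(v2, 3), tolerance = 0.1)
})

test_that("spatial field collapses to zero when the sill vanishes", {
  pan <- tiny_panel(n = 3, T_ = 2, p = 1, seed = 121)
  st <- truth_state(pan)
  st$sill_var <- rep(1e-300, 2)
  pr <- prior_spec(1, coords = pan$coords, decay_bounds = c(1e-4, 1))
  set.seed(13)
  sp <- sample_spatial_effects(pan, st, pr)
  expect_lt(max(abs(sp)), 1e-10)
})

test_that("a decay proposal equal to the current value is always accepted", {
  pan <- tiny_panel(n = 3, T_ = 2, p = 1, seed = 131)
  st <- truth_state(pan)
  pr <- prior_spec(1, coords = pan$coords, decay_bounds = c(1e-4, 1))
  set.seed(14)
  md <- metropolis_decay(pan, st, pr, step = 0)
  expect_true(all(md$accepted))
  expect_equal(md$decay, st$decay)
})

test_that("metropolis decay recovers its uniform prior when the field is re-drawn each scan", {
  # mini-Gibbs on (omega, decay) with no data: the stationary marginal of the
  # decay is exactly its uniform prior
  co <- simulate_coords(3, seed = 15)
  cm <- fsndyn:::coords_matrix(co)
  X <- array(1, dim = c(3, 2, 1))
  pan <- fsndyn:::new_panel(Y = matrix(0, 3, 2), X = X, coords = cm,
                            site_ids = co$site_id, years = 1:2,
                            mask = matrix(TRUE, 3, 2), transform = "identity")
  D <- great_circle_km(cm)
  pr <- prior_spec(1, coords = co)
  lo <- pr$decay_bounds[1]; hi <- pr$decay_bounds[2]
  st <- list(beta = matrix(0, 2, 1), spatial = matrix(0, 3, 2),
             nugget_var = c(1, 1), sill_var = c(0.5, 0.5),
             decay = rep(sqrt(lo * hi), 2), innovation_cov = diag(1))
  set.seed(16)
  n_scan <- 20000
  kept <- numeric(n_scan)
  for (i in seq_len(n_scan)) {
    # redraw the field from its prior given the current decay
    om <- vapply(1:2, function(t) {
      C <- exp(-st$decay[t] * D); diag(C) <- 1
      drop(crossprod(chol(C + diag(1e-8, 3)), rnorm(3))) *
        sqrt(st$sill_var[t])
    }, numeric(3))
    st$spatial <- cbind(om[, 1], om[, 1] + om[, 2])
    md <- metropolis_decay(pan, st, pr, step = 1.2, dist_km = D)
    st$decay <- md$decay
    kept[i] <- st$decay[1]
  }
  thinned <- kept[seq(10, n_scan, by = 10)]
  ks <- suppressWarnings(stats::ks.test(thinned, "punif", lo, hi))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(thinned) - (lo + hi) / 2), 0.05 * (hi - lo))
})

test_that("log_joint differences reproduce the Metropolis log-ratio", {
  pan <- tiny_panel(n = 3, T_ = 2, p = 1, seed = 141)
  st <- truth_state(pan)
  pr <- prior_spec(1, coords = pan$coords, decay_bounds = c(1e-4, 1))
  st2 <- st
  st2$decay[1] <- st$decay[1] * 1.5
  delta <- as.numeric(log_joint(pan, st2, pr)) - as.numeric(log_joint(pan, st, pr))
  # only the t = 1 spatial innovation term changes (uniform prior is flat)
  D <- great_circle_km(pan$coords)
  C1 <- exp(-st$decay[1] * D); diag(C1) <- 1
  C2 <- exp(-st2$decay[1] * D); diag(C2) <- 1
  om <- st$spatial[, 1]
  manual <- oracle_dmvnorm(om, rep(0, 3), st$sill_var[1] * C2) -
    oracle_dmvnorm(om, rep(0, 3), st$sill_var[1] * C1)
  expect_equal(delta, manual, tolerance = 1e-6)
})
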