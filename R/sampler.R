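#' One exact draw of the coefficient path by FFBS
#'
#' Samples the full path `beta_{0:T}` from its Gaussian full conditional given
#' the spatial field, variance paths and innovation covariance, via a Kalman
#' forward filter (identity evolution, evolution covariance the innovation
#' covariance, observation matrices the covariate rows of the observed cells,
#' observation variance the nugget) followed by backward sampling. The t = 0
#' state (prior `N(d0, Sigma0)`) is backward-sampled too and returned as
#' `beta0`; marginally `beta_1` has the `N(d0, Sigma0 + innovation_cov)` prior.
#'
#' @param panel an `fsn_panel`.
#' @param state current `fsn_state` (uses `spatial`, `nugget_var`,
#'   `innovation_cov`).
#' @param priors an `fsn_priors`.
#' @param cache optional precomputed internal panel cache (advanced use).
#' @return list with `beta` (T x p) and `beta0` (length p).
#' @export
ffbs_beta <- function(panel, state, priors, cache = NULL) {
  T_ <- panel$n_times; n <- panel$n_sites; p <- panel$p
  cache <- cache %||% panel_cache(panel)
  y <- Fm <- vector("list", T_)
  for (t in seq_len(T_)) {
    o <- cache$obs[[t]]
    y[[t]] <- panel$Y[o, t] - state$spatial[o, t]
    Fm[[t]] <- cache$Xobs[[t]]
  }
  path <- ffbs_draw(y, Fm, state$nugget_var,
                    rep(list(state$innovation_cov), T_),
                    priors$d0, priors$Sigma0)
  list(beta = t(path[, -1, drop = FALSE]), beta0 = path[, 1])
}

#' One exact joint draw of the spatial random-effect field
#'
#' Samples the whole `n_sites x T` field from its Gaussian full conditional
#' given the coefficients and variance/decay paths, exploiting the random-walk
#' structure: a forward filter over time with state the length-n field,
#' identity evolution, evolution covariance `sill_var[t] * C_t`, selection
#' observations at the observed cells with nugget variance, started from the
#' degenerate zero field at t = 0; then backward sampling.
#'
#' @inheritParams ffbs_beta
#' @param C_list optional precomputed list of per-time correlation matrices.
#' @param cache optional precomputed internal panel cache.
#' @return n_sites x T matrix.
#' @export
sample_spatial_effects <- function(panel, state, priors, C_list = NULL,
                                   cache = NULL) {
  T_ <- panel$n_times; n <- panel$n_sites; p <- panel$p
  cache <- cache %||% panel_cache(panel)
  C_list <- C_list %||% correlation_list(panel, state$decay,
                                         dist_km = cache$D)
  y <- Fm <- Q <- vector("list", T_)
  for (t in seq_len(T_)) {
    o <- cache$obs[[t]]
    mu <- drop(cache$Xobs[[t]] %*% state$beta[t, ])
    y[[t]] <- panel$Y[o, t] - mu
    Fm[[t]] <- o
    Q[[t]] <- state$sill_var[t] * C_list[[t]]
  }
  path <- ffbs_draw(y, Fm, state$nugget_var, Q,
                    rep(0, n), matrix(0, n, n))
  path[, -1, drop = FALSE]
}

#' Conjugate update of the nugget (micro-scale) variance path
#'
#' Per time point, draws the precision `1/sigma2_eps_t` from
#' `Gamma(a_eps + k_t/2, b_eps + sum(r^2)/2)` where `r` are the residuals
#' `Y - X beta_t - spatial` over the `k_t` observed cells. A time point with
#' no observed cells falls back to the prior.
#'
#' @inheritParams ffbs_beta
#' @return length-T vector of variances.
#' @export
sample_nugget_variances <- function(panel, state, priors, cache = NULL) {
  T_ <- panel$n_times
  cache <- cache %||% panel_cache(panel)
  out <- numeric(T_)
  for (t in seq_len(T_)) {
    o <- cache$obs[[t]]
    k <- length(o)
    ss <- if (k > 0) {
      mu <- drop(cache$Xobs[[t]] %*% state$beta[t, ]) + state$spatial[o, t]
      sum((panel$Y[o, t] - mu)^2)
    } else 0
    out[t] <- 1 / rgamma(1, priors$a_eps + k / 2, rate = priors$b_eps + ss / 2)
  }
  out
}

#' Conjugate update of the spatial innovation (partial sill) variance path
#'
#' Per time point, with innovation `omega_t = spatial_t - spatial_{t-1}`
#' (`spatial_0 = 0`) and unit-sill correlation `C_t`, draws the precision from
#' `Gamma(a_w + n/2, b_w + t(omega) C_t^{-1} omega / 2)`.
#'
#' @inheritParams sample_spatial_effects
#' @param chol_list optional upper-Cholesky factors of `C_list`.
#' @return length-T vector of variances.
#' @export
sample_sill_variances <- function(panel, state, priors, C_list = NULL,
                                  chol_list = NULL) {
  T_ <- panel$n_times; n <- panel$n_sites
  C_list <- C_list %||% correlation_list(panel, state$decay)
  chol_list <- chol_list %||% lapply(C_list, safe_chol)
  out <- numeric(T_)
  prev <- rep(0, n)
  for (t in seq_len(T_)) {
    omega <- state$spatial[, t] - prev
    prev <- state$spatial[, t]
    z <- backsolve(chol_list[[t]], omega, transpose = TRUE)
    out[t] <- 1 / rgamma(1, priors$a_w + n / 2, rate = priors$b_w + sum(z^2) / 2)
  }
  out
}

#' Conjugate inverse-Wishart update of the coefficient innovation covariance
#'
#' Given the sampled path including the t = 0 state, draws
#' `inverse-Wishart(df + T, scale + sum_t d_t d_t')` with
#' `d_t = beta_t - beta_{t-1}`.
#'
#' @inheritParams ffbs_beta
#' @return p x p positive-definite matrix.
#' @export
sample_innovation_cov <- function(state, priors) {
  B <- rbind(state$beta0 %||% priors$d0, state$beta)
  dB <- diff(B)
  S_post <- priors$wishart_scale + crossprod(dB)
  rinvwishart1(priors$wishart_df + nrow(dB), S_post)
}

#' Random-walk Metropolis update of the correlation decay path
#'
#' Per time point, proposes `decay' = decay * exp(step * z)` (log-scale
#' Gaussian random walk), rejects proposals outside the uniform prior support
#' outright, and otherwise accepts with probability
#' `min(1, exp(dloglik + log(decay'/decay)))` — the log-Jacobian of the
#' log-scale proposal — where the log-likelihood is the Gaussian-process
#' density of the innovation `omega_t` under `sill_var[t] * C(decay)`.
#'
#' @inheritParams sample_spatial_effects
#' @param step length-T (or scalar) log-scale proposal standard deviation.
#' @param dist_km optional precomputed distance matrix.
#' @param chol_list optional upper-Cholesky factors of `C_list`.
#' @return list with `decay` (length T), `accepted` (logical length T), and
#'   `C_list` (correlations at the returned decays).
#' @export
metropolis_decay <- function(panel, state, priors, step = 0.3,
                             C_list = NULL, dist_km = NULL,
                             chol_list = NULL) {
  T_ <- panel$n_times; n <- panel$n_sites
  D <- dist_km %||% great_circle_km(panel$coords)
  C_list <- C_list %||% correlation_list(panel, state$decay, dist_km = D)
  chol_list <- chol_list %||% lapply(C_list, safe_chol)
  step <- rep_len(step, T_)
  decay <- state$decay
  accepted <- logical(T_)
  prev <- rep(0, n)
  for (t in seq_len(T_)) {
    omega <- state$spatial[, t] - prev
    prev <- state$spatial[, t]
    prop <- decay[t] * exp(step[t] * rnorm(1))
    if (prop >= priors$decay_bounds[1] && prop <= priors$decay_bounds[2]) {
      Cp <- exp(-prop * D); diag(Cp) <- 1
      Up <- safe_chol(Cp)
      ll_cur <- dmvnorm0_chol(omega, chol_list[[t]], state$sill_var[t])
      ll_prop <- dmvnorm0_chol(omega, Up, state$sill_var[t])
      if (log(runif(1)) < ll_prop - ll_cur + log(prop) - log(decay[t])) {
        decay[t] <- prop
        C_list[[t]] <- Cp
        chol_list[[t]] <- Up
        accepted[t] <- TRUE
      }
    }
  }
  list(decay = decay, accepted = accepted, C_list = C_list,
       chol_list = chol_list)
}

correlation_list <- function(panel, decay, dist_km = NULL) {
  D <- dist_km %||% great_circle_km(panel$coords)
  lapply(decay, function(th) { C <- exp(-th * D); diag(C) <- 1; C })
}

# per-panel precomputations shared across the Gibbs blocks
panel_cache <- function(panel) {
  T_ <- panel$n_times; n <- panel$n_sites; p <- panel$p
  obs <- lapply(seq_len(T_), function(t) which(panel$mask[, t]))
  Xobs <- lapply(seq_len(T_), function(t)
    matrix(panel$X[, t, ], n, p)[obs[[t]], , drop = FALSE])
  list(D = great_circle_km(panel$coords), obs = obs, Xobs = Xobs)
}

# log N(x; 0, scale * C) with U = chol(C)
dmvnorm0_chol <- function(x, U, scale) {
  n <- length(x)
  z <- backsolve(U, x, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + n * log(scale) + 2 * sum(log(diag(U))) +
            sum(z^2) / scale)
}

#' Fit the dynamic spatio-temporal model by MCMC
#'
#' Systematic-scan MCMC cycling six blocks: FFBS for the coefficient path,
#' an exact joint draw of the spatial field, conjugate Gamma updates of the
#' nugget and sill variance paths, an inverse-Wishart update of the
#' coefficient innovation covariance, and per-time random-walk Metropolis for
#' the correlation decay. Initial state: zero coefficient path and spatial
#' field, variances at their prior means, decay at the midpoint of its
#' support. Deterministic given `seed`.
#'
#' @param panel an `fsn_panel` (cells with `mask = FALSE` are ignored by the
#'   likelihood — the training mask of a [split_panel()] goes here).
#' @param priors an [prior_spec()]; default derived from the panel.
#' @param n_iter total MCMC iterations (default 5000).
#' @param burn_in discarded initial iterations (default 1000).
#' @param thin keep every `thin`-th post-burn-in draw (default 1).
#' @param seed integer seed.
#' @param metropolis_step initial log-scale random-walk sd for the decay
#'   proposals (default 0.3).
#' @param adapt adapt the Metropolis step during burn-in only, targeting
#'   20-45% acceptance (default TRUE).
#' @param verbose print progress every 500 iterations.
#' @return an object of class `fsn_fit` holding the kept draws of every
#'   block, per-time decay acceptance rates (post burn-in), the log joint
#'   density trace at kept iterations, the configuration, and the panel
#'   (plus the generative truth when the panel carries one).
#' @export
fit_dynamic_st <- function(panel, priors = NULL, n_iter = 5000,
                           burn_in = 1000, thin = 1, seed = NULL,
                           metropolis_step = 0.3, adapt = TRUE,
                           verbose = FALSE) {
  stopifnot(inherits(panel, "fsn_panel"))
  priors <- priors %||% prior_spec(panel$p, coords = panel$coords)
  if (!is_count(n_iter) || !is_count(thin) ||
      !(is_count(burn_in) || burn_in == 0) || burn_in >= n_iter)
    abort_config("Need integer n_iter > burn_in >= 0 and thin >= 1.")
  n <- panel$n_sites; T_ <- panel$n_times; p <- panel$p
  if (priors$p != p) abort_config("Prior dimension does not match the panel.")
  D <- great_circle_km(panel$coords)
  n_kept <- floor((n_iter - burn_in) / thin)
  draws <- list(
    beta = array(NA_real_, c(n_kept, T_, p),
                 dimnames = list(NULL, NULL, panel$covariate_names)),
    beta0 = matrix(NA_real_, n_kept, p),
    spatial = array(NA_real_, c(n_kept, n, T_)),
    nugget_var = matrix(NA_real_, n_kept, T_),
    sill_var = matrix(NA_real_, n_kept, T_),
    decay = matrix(NA_real_, n_kept, T_),
    innovation_cov = array(NA_real_, c(n_kept, p, p))
  )
  log_joint_trace <- numeric(n_kept)
  var_init <- function(a, b) if (a > 1) b / (a - 1) else b / a
  state <- list(
    beta = matrix(0, T_, p), beta0 = priors$d0,
    spatial = matrix(0, n, T_),
    nugget_var = rep(var_init(priors$a_eps, priors$b_eps), T_),
    sill_var = rep(var_init(priors$a_w, priors$b_w), T_),
    decay = rep(mean(priors$decay_bounds), T_),
    innovation_cov = if (priors$wishart_df > p + 1)
      priors$wishart_scale / (priors$wishart_df - p - 1) else priors$wishart_scale
  )
  steps <- rep(metropolis_step, T_)
  accept_post <- integer(T_)
  accept_batch <- integer(T_)
  t_start <- Sys.time()
  cache <- panel_cache(panel)
  with_seed_if(seed, {
    C_list <- correlation_list(panel, state$decay, dist_km = D)
    chol_list <- lapply(C_list, safe_chol)
    for (it in seq_len(n_iter)) {
      bb <- ffbs_beta(panel, state, priors, cache)
      state$beta <- bb$beta
      state$beta0 <- bb$beta0
      state$spatial <- sample_spatial_effects(panel, state, priors, C_list,
                                              cache)
      state$nugget_var <- sample_nugget_variances(panel, state, priors, cache)
      state$sill_var <- sample_sill_variances(panel, state, priors, C_list,
                                              chol_list)
      state$innovation_cov <- sample_innovation_cov(state, priors)
      md <- metropolis_decay(panel, state, priors, step = steps,
                             C_list = C_list, dist_km = D,
                             chol_list = chol_list)
      state$decay <- md$decay
      C_list <- md$C_list
      chol_list <- md$chol_list
      if (it > burn_in) {
        accept_post <- accept_post + md$accepted
      } else if (adapt) {
        accept_batch <- accept_batch + md$accepted
        if (it %% 50 == 0) {
          rate <- accept_batch / 50
          steps <- pmin(10, pmax(1e-3,
            steps * ifelse(rate > 0.45, 1.25, ifelse(rate < 0.2, 0.8, 1))))
          accept_batch <- integer(T_)
        }
      }
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        j <- (it - burn_in) %/% thin
        if (j <= n_kept) {
          check_state_mid_chain(state, it)
          draws$beta[j, , ] <- state$beta
          draws$beta0[j, ] <- state$beta0
          draws$spatial[j, , ] <- state$spatial
          draws$nugget_var[j, ] <- state$nugget_var
          draws$sill_var[j, ] <- state$sill_var
          draws$decay[j, ] <- state$decay
          draws$innovation_cov[j, , ] <- state$innovation_cov
          log_joint_trace[j] <- log_joint_fast(panel, state, priors,
                                               chol_list, cache)
        }
      }
      if (verbose && it %% 500 == 0)
        message(sprintf("iteration %d / %d (%.1fs)", it, n_iter,
                        as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
    }
  })
  structure(list(
    draws = draws,
    acceptance_rates = accept_post / max(1, n_iter - burn_in),
    log_joint_trace = log_joint_trace,
    config = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                  seed = seed, metropolis_step = metropolis_step,
                  adapt = adapt, n_kept = n_kept,
                  elapsed_secs = as.numeric(difftime(Sys.time(), t_start,
                                                     units = "secs"))),
    priors = priors, panel = panel, truth = panel$truth,
    covariate_names = panel$covariate_names, years = panel$years
  ), class = "fsn_fit")
}

check_state_mid_chain <- function(state, it) {
  bad <- NULL
  if (any(!is.finite(state$beta))) bad <- "beta"
  else if (any(!is.finite(state$spatial))) bad <- "spatial"
  else if (any(state$nugget_var <= 0)) bad <- "nugget_var"
  else if (any(state$sill_var <= 0)) bad <- "sill_var"
  else if (any(state$decay <= 0)) bad <- "decay"
  if (!is.null(bad))
    abort_numeric(sprintf("State invariant violated at iteration %d in block `%s`.",
                          it, bad))
  invisible(TRUE)
}

# log joint reusing cached correlation factors (kept-iteration trace)
log_joint_fast <- function(panel, state, priors, chol_list, cache) {
  n <- panel$n_sites; T_ <- panel$n_times
  obs <- 0; sterm <- 0
  prev <- rep(0, n)
  for (t in seq_len(T_)) {
    o <- cache$obs[[t]]
    mu <- drop(cache$Xobs[[t]] %*% state$beta[t, ]) + state$spatial[o, t]
    if (length(o))
      obs <- obs + sum(dnorm(panel$Y[o, t], mu, sqrt(state$nugget_var[t]),
                             log = TRUE))
    sterm <- sterm + dmvnorm0_chol(state$spatial[, t] - prev,
                                   chol_list[[t]], state$sill_var[t])
    prev <- state$spatial[, t]
  }
  bterm <- dmvnorm_log(state$beta0, priors$d0, priors$Sigma0) +
    sum(vapply(seq_len(T_), function(t) {
      from <- if (t == 1) state$beta0 else state$beta[t - 1, ]
      dmvnorm_log(state$beta[t, ], from, state$innovation_cov)
    }, numeric(1)))
  pterm <-
    sum(dgamma(1 / state$nugget_var, priors$a_eps, rate = priors$b_eps, log = TRUE)) +
    sum(dgamma(1 / state$sill_var, priors$a_w, rate = priors$b_w, log = TRUE)) +
    ldinvwishart(state$innovation_cov, priors$wishart_df, priors$wishart_scale) +
    sum(dunif(state$decay, priors$decay_bounds[1], priors$decay_bounds[2],
              log = TRUE))
  obs + sterm + bterm + pterm
}

#' @export
print.fsn_fit <- function(x, ...) {
  cat(sprintf(
    "<fsn_fit> %d kept draws (n_iter %d, burn-in %d, thin %d)\n  %d sites x %d years, %d coefficients\n  decay acceptance: %.2f (mean over time)\n",
    x$config$n_kept, x$config$n_iter, x$config$burn_in, x$config$thin,
    x$panel$n_sites, x$panel$n_times, x$panel$p, mean(x$acceptance_rates)))
  invisible(x)
}

#' Posterior medians and equal-tailed credible intervals
#'
#' Per-parameter summaries of the kept draws: posterior median and the
#' `(alpha/2, 1 - alpha/2)` quantiles. A coefficient at a given year is
#' flagged `significant` when its interval excludes zero.
#'
#' @param fit an `fsn_fit`.
#' @param level credibility level (default 0.95).
#' @return tibble with `parameter`, `component`, `year`, `median`, `lower`,
#'   `upper`, `significant`.
#' @export
posterior_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "fsn_fit"))
  if (fit$config$n_kept < 10)
    abort_validation("Need at least 10 kept draws to summarize.")
  if (!is.numeric(level) || level <= 0 || level >= 1)
    abort_validation("`level` must be in (0, 1).")
  a <- (1 - level) / 2
  qs <- function(x) unname(quantile(x, c(0.5, a, 1 - a), type = 7))
  T_ <- length(fit$years); p <- dim(fit$draws$beta)[3]
  rows <- list()
  for (j in seq_len(p)) for (t in seq_len(T_)) {
    q <- qs(fit$draws$beta[, t, j])
    rows[[length(rows) + 1]] <- tibble(
      parameter = "beta", component = fit$covariate_names[j],
      year = fit$years[t], median = q[1], lower = q[2], upper = q[3])
  }
  paths <- list(sigma2 = fit$draws$sill_var, tau2 = fit$draws$nugget_var,
                decay = fit$draws$decay)
  for (nm in names(paths)) for (t in seq_len(T_)) {
    q <- qs(paths[[nm]][, t])
    rows[[length(rows) + 1]] <- tibble(
      parameter = nm, component = NA_character_, year = fit$years[t],
      median = q[1], lower = q[2], upper = q[3])
  }
  for (i in seq_len(p)) for (j in seq_len(i)) {
    q <- qs(fit$draws$innovation_cov[, i, j])
    rows[[length(rows) + 1]] <- tibble(
      parameter = "innovation_cov",
      component = paste(fit$covariate_names[i], fit$covariate_names[j], sep = ":"),
      year = NA_integer_, median = q[1], lower = q[2], upper = q[3])
  }
  out <- dplyr::bind_rows(rows)
  out$significant <- ifelse(out$parameter == "beta",
                            out$lower > 0 | out$upper < 0, NA)
  out
}

#' @method tidy fsn_fit
#' @export
tidy.fsn_fit <- function(x, level = 0.95, ...) posterior_summary(x, level)

#' @method glance fsn_fit
#' @export
glance.fsn_fit <- function(x, ...) {
  tibble(n_iter = x$config$n_iter, burn_in = x$config$burn_in,
         thin = x$config$thin, n_kept = x$config$n_kept,
         n_sites = x$panel$n_sites, n_years = x$panel$n_times,
         p = x$panel$p,
         mean_decay_acceptance = mean(x$acceptance_rates),
         final_log_joint = x$log_joint_trace[x$config$n_kept])
}
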