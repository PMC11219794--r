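#' Prior specification for the dynamic spatio-temporal model
#'
#' Hyper-parameters of the hierarchical model: a normal prior `N(d0, Sigma0)`
#' on the initial coefficient vector, Gamma priors on the observation
#' (nugget) and spatial-innovation (partial sill) precisions, an
#' inverse-Wishart prior on the coefficient innovation covariance, and a
#' uniform prior on the exponential correlation decay.
#'
#' Defaults follow common weakly-informative practice: `d0 = 0` and
#' `Sigma0 = 1e4 * I` (vague), `Gamma(2, 1)` on both precisions (proper, prior
#' mean 2), `inverse-Wishart(p + 2, I)`, and, when coordinates are supplied,
#' decay bounds `(3 / max_distance, 3 / min_distance)` — the effective-range
#' heuristic under which the correlation at the largest (smallest) intersite
#' distance is about 0.05.
#'
#' @param p number of regression coefficients.
#' @param coords optional site coordinates used to derive `decay_bounds`.
#' @param d0,Sigma0 initial-coefficient prior mean and covariance.
#' @param a_eps,b_eps Gamma shape/rate on the nugget precision `1/sigma2_eps`.
#' @param a_w,b_w Gamma shape/rate on the sill precision `1/sigma2_omega`.
#' @param wishart_df,wishart_scale inverse-Wishart degrees of freedom
#'   (`> p - 1`) and p x p scale.
#' @param decay_bounds length-2 positive vector, support of the uniform decay
#'   prior (1/km).
#' @return a list of class `fsn_priors`.
#' @export
prior_spec <- function(p, coords = NULL, d0 = rep(0, p),
                       Sigma0 = diag(1e4, p),
                       a_eps = 2, b_eps = 1, a_w = 2, b_w = 1,
                       wishart_df = p + 2, wishart_scale = diag(1, p),
                       decay_bounds = NULL) {
  if (!is_count(p)) abort_config("`p` must be a positive integer.")
  Sigma0 <- sym_mat(as.matrix(Sigma0))
  wishart_scale <- sym_mat(as.matrix(wishart_scale))
  if (length(d0) != p || !all(dim(Sigma0) == p) || !all(dim(wishart_scale) == p))
    abort_config("Prior dimensions must match `p`.")
  for (nm in c("a_eps", "b_eps", "a_w", "b_w"))
    if (get(nm) <= 0) abort_config(sprintf("`%s` must be strictly positive.", nm))
  if (wishart_df <= p - 1) abort_config("`wishart_df` must exceed p - 1.")
  if (min(eigen(Sigma0, symmetric = TRUE, only.values = TRUE)$values) <= 0 ||
      min(eigen(wishart_scale, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    abort_config("Sigma0 and wishart_scale must be positive definite.")
  if (is.null(decay_bounds)) {
    if (is.null(coords))
      abort_config("Supply `decay_bounds` or `coords` to derive them from.")
    D <- great_circle_km(coords_matrix(coords))
    dd <- D[upper.tri(D)]
    decay_bounds <- c(3 / max(dd), 3 / min(dd))
  }
  if (length(decay_bounds) != 2 || decay_bounds[1] <= 0 ||
      decay_bounds[2] <= decay_bounds[1])
    abort_config("`decay_bounds` must be positive and increasing.")
  structure(list(p = as.integer(p), d0 = as.numeric(d0), Sigma0 = Sigma0,
                 a_eps = a_eps, b_eps = b_eps, a_w = a_w, b_w = b_w,
                 wishart_df = wishart_df, wishart_scale = wishart_scale,
                 decay_bounds = as.numeric(decay_bounds)),
            class = "fsn_priors")
}

#' Read a prior specification from a YAML or JSON config
#'
#' Expects a `priors` block whose entries mirror the [prior_spec()] argument
#' names; missing entries fall back to the defaults.
#'
#' @param path YAML or JSON file.
#' @param p number of coefficients.
#' @param coords optional coordinates for default decay bounds.
#' @return an `fsn_priors` object.
#' @export
read_prior_config <- function(path, p, coords = NULL) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  pr <- cfg$priors %||% cfg
  args <- pr[intersect(names(pr), names(formals(prior_spec)))]
  for (nm in c("Sigma0", "wishart_scale"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.matrix(args[[nm]])
  do.call(prior_spec, c(list(p = p, coords = coords), args))
}

#' Exponential spatial correlation matrix
#'
#' `C[i, j] = exp(-decay * d_ij)` with `d_ij` the great-circle distance in km
#' between sites i and j; unit diagonal, symmetric. This is the correlation
#' family of the Gaussian-process innovations of the spatial random effect.
#' Factorizations downstream add a 1e-8 diagonal jitter.
#'
#' @param coords site coordinates (lon/lat degrees) or a precomputed distance
#'   matrix passed via `dist_km`.
#' @param decay positive decay rate in 1/km.
#' @param dist_km optional precomputed distance matrix in km.
#' @return n x n correlation matrix.
#' @export
build_correlation <- function(coords, decay, dist_km = NULL) {
  if (!is.numeric(decay) || length(decay) != 1 || decay <= 0)
    abort_validation("`decay` must be a single positive number.")
  D <- dist_km %||% great_circle_km(coords_matrix(coords))
  if (any(D[upper.tri(D)] == 0))
    abort_validation("Duplicate coordinates: zero off-diagonal distance.")
  C <- exp(-decay * D)
  diag(C) <- 1
  C
}

#' Model state constructor
#'
#' Bundles one full set of latent quantities of the hierarchical model: the
#' coefficient path, spatial field, variance paths, decay path and coefficient
#' innovation covariance. Invariants (positive variances, decay within its
#' prior support, positive-definite innovation covariance) are checked.
#'
#' @param beta T x p coefficient matrix (`beta[t, ]` is the coefficient at
#'   time t).
#' @param spatial n_sites x T spatial random-effect matrix.
#' @param nugget_var,sill_var,decay length-T paths.
#' @param innovation_cov p x p coefficient innovation covariance.
#' @param beta0 optional length-p initial coefficient (sampled state at t=0).
#' @param priors optional `fsn_priors` used to validate the decay support.
#' @return a list of class `fsn_state`.
#' @export
model_state <- function(beta, spatial, nugget_var, sill_var, decay,
                        innovation_cov, beta0 = NULL, priors = NULL) {
  beta <- as.matrix(beta)
  spatial <- as.matrix(spatial)
  T_ <- nrow(beta)
  if (ncol(spatial) != T_ ||
      length(nugget_var) != T_ || length(sill_var) != T_ || length(decay) != T_)
    abort_validation("State path lengths disagree.")
  if (any(nugget_var <= 0) || any(sill_var <= 0))
    abort_validation("Variance paths must be strictly positive.")
  if (any(decay <= 0)) abort_validation("`decay` must be strictly positive.")
  if (!is.null(priors) &&
      (any(decay < priors$decay_bounds[1] - 1e-12) ||
       any(decay > priors$decay_bounds[2] + 1e-12)))
    abort_validation("`decay` outside its prior support.")
  innovation_cov <- sym_mat(as.matrix(innovation_cov))
  if (min(eigen(innovation_cov, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    abort_validation("`innovation_cov` must be positive definite.")
  structure(list(beta = beta, beta0 = beta0, spatial = spatial,
                 nugget_var = as.numeric(nugget_var),
                 sill_var = as.numeric(sill_var), decay = as.numeric(decay),
                 innovation_cov = innovation_cov),
            class = "fsn_state")
}

#' Full hierarchical log joint density
#'
#' Sum of the four blocks of the hierarchy at a given state: (i) Gaussian
#' observation terms over observed cells, (ii) the coefficient random walk
#' (when `state$beta0` is present, `N(beta0; d0, Sigma0)` plus T innovation
#' terms; otherwise the t=0 state is marginalized and the first term is
#' `N(beta_1; d0, Sigma0 + innovation_cov)`), (iii) the spatial random walk
#' with GP innovations starting from zero, and (iv) the parameter priors. The
#' variance priors are evaluated as Gamma log-densities of the *precisions*
#' at `1/variance` (the scale the priors are stated on). The result carries a
#' `"terms"` attribute with the per-block decomposition.
#'
#' @param panel an `fsn_panel`.
#' @param state an `fsn_state` (or compatible list).
#' @param priors an `fsn_priors`.
#' @return the log joint density (numeric scalar) with attribute `terms`.
#' @export
log_joint <- function(panel, state, priors) {
  n <- panel$n_sites; T_ <- panel$n_times; p <- panel$p
  D <- great_circle_km(panel$coords)
  for (block in c("beta", "spatial", "nugget_var", "sill_var", "decay")) {
    if (!all(is.finite(state[[block]])))
      abort_numeric(sprintf("Non-finite values in state block `%s`.", block))
  }
  obs <- 0
  for (t in seq_len(T_)) {
    o <- panel$mask[, t]
    if (!any(o)) next
    mu <- drop(matrix(panel$X[, t, ], n, p) %*% state$beta[t, ]) + state$spatial[, t]
    obs <- obs + sum(dnorm(panel$Y[o, t], mu[o], sqrt(state$nugget_var[t]), log = TRUE))
  }
  if (!is.finite(obs)) abort_numeric("Non-finite observation block.")
  bterm <- if (!is.null(state$beta0)) {
    v <- dmvnorm_log(state$beta0, priors$d0, priors$Sigma0) +
      dmvnorm_log(state$beta[1, ], state$beta0, state$innovation_cov)
    if (T_ > 1) for (t in 2:T_)
      v <- v + dmvnorm_log(state$beta[t, ], state$beta[t - 1, ], state$innovation_cov)
    v
  } else {
    v <- dmvnorm_log(state$beta[1, ], priors$d0,
                     priors$Sigma0 + state$innovation_cov)
    if (T_ > 1) for (t in 2:T_)
      v <- v + dmvnorm_log(state$beta[t, ], state$beta[t - 1, ], state$innovation_cov)
    v
  }
  sterm <- 0
  prev <- rep(0, n)
  for (t in seq_len(T_)) {
    Ct <- build_correlation(decay = state$decay[t], dist_km = D)
    sterm <- sterm + dmvnorm_log(state$spatial[, t], prev,
                                 state$sill_var[t] * Ct)
    prev <- state$spatial[, t]
  }
  prior_term <-
    sum(dgamma(1 / state$nugget_var, priors$a_eps, rate = priors$b_eps, log = TRUE)) +
    sum(dgamma(1 / state$sill_var, priors$a_w, rate = priors$b_w, log = TRUE)) +
    ldinvwishart(state$innovation_cov, priors$wishart_df, priors$wishart_scale) +
    sum(dunif(state$decay, priors$decay_bounds[1], priors$decay_bounds[2],
              log = TRUE))
  total <- obs + bterm + sterm + prior_term
  attr(total, "terms") <- c(observation = obs, beta_walk = bterm,
                            spatial_walk = sterm, priors = prior_term)
  total
}
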