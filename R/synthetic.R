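#' Specification of a synthetic indicator table
#'
#' Describes a block-factor generator for a wide table of food-security
#' indicators on a site-by-year grid. Indicators are partitioned into
#' `n_blocks` groups; indicators in a group share one latent site-year factor,
#' so the sample correlation matrix has `n_blocks` dominant eigenvalues and an
#' eigenvalue-greater-than-one retention rule recovers the planted block count.
#'
#' With `noise_sd = 1` the expected within-block correlation equals
#' `within_block_correlation`; `noise_sd` rescales the idiosyncratic part, so
#' `noise_sd -> 0` makes the indicators in a block exact affine copies of the
#' latent factor.
#'
#' @param n_sites number of spatial units (default 54).
#' @param n_years number of annual time points (default 20).
#' @param n_indicators number of indicator columns (default 40).
#' @param n_blocks number of latent blocks (default 10).
#' @param within_block_correlation block correlation in (0, 1).
#' @param noise_sd positive scale of the idiosyncratic noise.
#' @param seed integer seed; the whole table is a deterministic function of it.
#' @return a list of class `fsn_indicator_spec`.
#' @export
#' @examples
#' spec <- indicator_spec(n_sites = 6, n_years = 4, n_indicators = 8, n_blocks = 2)
#' simulate_indicators(spec)
indicator_spec <- function(n_sites = 54, n_years = 20, n_indicators = 40,
                           n_blocks = 10, within_block_correlation = 0.7,
                           noise_sd = 1, seed = 1) {
  for (nm in c("n_sites", "n_years", "n_indicators", "n_blocks")) {
    if (!is_count(get(nm))) abort_config(sprintf("`%s` must be a positive integer.", nm))
  }
  if (n_blocks > n_indicators)
    abort_config("`n_blocks` must not exceed `n_indicators`.")
  if (!is.numeric(within_block_correlation) ||
      within_block_correlation <= 0 || within_block_correlation >= 1)
    abort_config("`within_block_correlation` must lie strictly in (0, 1).")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    abort_config("`noise_sd` must be a non-negative real.")
  structure(list(
    n_sites = as.integer(n_sites), n_years = as.integer(n_years),
    n_indicators = as.integer(n_indicators), n_blocks = as.integer(n_blocks),
    within_block_correlation = within_block_correlation,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "fsn_indicator_spec")
}

#' Simulate a wide indicator table with planted correlated blocks
#'
#' Generates `x_j = sqrt(rho) * f_b(j) + sqrt(1 - rho) * noise_sd * e_j` per
#' site-year row, then shifts and rescales each indicator column to an
#' arbitrary measurement scale (deterministic given the seed). The table is
#' complete by construction. The latent factors are attached as attribute
#' `"latent_factors"` (a tibble keyed by site and year) and the block
#' membership of each indicator as attribute `"block_of"`, for recovery tests.
#'
#' @param spec an [indicator_spec()].
#' @return a tibble with columns `site_id`, `year`, and
#'   `ind_01 ... ind_<n_indicators>`; `n_sites * n_years` rows.
#' @export
simulate_indicators <- function(spec) {
  if (!inherits(spec, "fsn_indicator_spec"))
    abort_config("`spec` must be created by indicator_spec().")
  with_seed_if(spec$seed, {
    n <- spec$n_sites * spec$n_years
    B <- spec$n_blocks
    J <- spec$n_indicators
    rho <- spec$within_block_correlation
    block_of <- rep(seq_len(B), length.out = J)
    f <- matrix(rnorm(n * B), n, B)
    e <- matrix(rnorm(n * J), n, J)
    z <- sqrt(rho) * f[, block_of, drop = FALSE] + sqrt(1 - rho) * spec$noise_sd * e
    shift <- runif(J, 10, 100)
    scale <- runif(J, 0.5, 5)
    vals <- sweep(sweep(z, 2, scale, `*`), 2, shift, `+`)
    site_id <- sprintf("S%03d", seq_len(spec$n_sites))
    years <- 2000L + seq_len(spec$n_years) - 1L
    keys <- tidyr::expand_grid(site_id = site_id, year = years)
    colnames(vals) <- sprintf("ind_%02d", seq_len(J))
    out <- dplyr::bind_cols(keys, tibble::as_tibble(vals))
    latent <- dplyr::bind_cols(keys, tibble::as_tibble(
      `colnames<-`(f, sprintf("factor_%02d", seq_len(B)))))
    attr(out, "latent_factors") <- latent
    attr(out, "block_of") <- block_of
    attr(out, "spec") <- spec
    out
  })
}

#' Draw distinct synthetic site coordinates
#'
#' Uniform longitude/latitude points in a rectangle spanning continental
#' Africa's bounding box (-20..55 E, -35..38 N) by default, as a stand-in for
#' real country centroids (which a user supplies as a CSV of `site_id`, `lon`,
#' `lat`). Points are redrawn until all pairwise distances are positive.
#'
#' @param n_sites number of sites (at least 2).
#' @param seed integer seed.
#' @param bbox numeric vector `c(lon_min, lon_max, lat_min, lat_max)`.
#' @return tibble with columns `site_id`, `lon`, `lat`.
#' @export
simulate_coords <- function(n_sites = 54, seed = 1,
                            bbox = c(-20, 55, -35, 38)) {
  if (!is_count(n_sites) || n_sites < 2)
    abort_config("`n_sites` must be an integer >= 2.")
  with_seed_if(seed, {
    repeat {
      lon <- runif(n_sites, bbox[1], bbox[2])
      lat <- runif(n_sites, bbox[3], bbox[4])
      if (!anyDuplicated(cbind(lon, lat))) break
    }
    tibble::tibble(site_id = sprintf("S%03d", seq_len(n_sites)),
                   lon = lon, lat = lat)
  })
}

#' Ground-truth parameters for the generative spatio-temporal model
#'
#' Draws and stores a full set of true parameters for the hierarchical model:
#' a random-walk coefficient path `beta_path` (T x p) with recorded innovations
#' `eta` drawn from `N(0, innovation_cov)`, a spatial random-effect field
#' `spatial_effects` (n_sites x T) built by accumulating Gaussian-process
#' innovations with exponential correlation `exp(-decay * d_km)` starting from
#' zero, and the variance/decay paths. Defaults are the package's reference
#' study conditions: a unit-scale response with observation (nugget) variance
#' 0.25, spatial innovation (partial sill) variance 0.16, coefficient
#' innovation standard deviation 0.1 and a 1500 km effective correlation range
#' (decay 0.002 per km).
#'
#' @param coords tibble/matrix of site coordinates (`lon`, `lat`, optionally
#'   `site_id`).
#' @param n_years number of annual time points T.
#' @param p number of regression coefficients (including any intercept).
#' @param seed integer seed.
#' @param beta0 length-p vector of true initial coefficients; default
#'   `c(2, 0.5, -0.5, 0.5, ...)`.
#' @param innovation_cov p x p innovation covariance of the coefficient random
#'   walk; default `0.01 * I`.
#' @param nugget_var observation variance path (scalar recycled to length T);
#'   entries may be 0 for noiseless limits.
#' @param sill_var spatial innovation variance path (scalar recycled); 0
#'   disables the spatial field.
#' @param decay exponential correlation decay path in 1/km (scalar recycled).
#' @return a list of class `fsn_truth`.
#' @export
simulate_truth <- function(coords, n_years = 20, p = 3, seed = 1,
                           beta0 = NULL, innovation_cov = NULL,
                           nugget_var = 0.25, sill_var = 0.16,
                           decay = 0.002) {
  cm <- coords_matrix(coords)
  n <- nrow(cm)
  if (!is_count(n_years) || n_years < 2) abort_config("`n_years` must be >= 2.")
  if (!is_count(p)) abort_config("`p` must be a positive integer.")
  beta0 <- beta0 %||% c(2, rep_len(c(0.5, -0.5), p - 1))[seq_len(p)]
  if (length(beta0) != p) abort_config("`beta0` must have length p.")
  innovation_cov <- innovation_cov %||% diag(0.01, p)
  innovation_cov <- sym_mat(as.matrix(innovation_cov))
  if (!all(dim(innovation_cov) == c(p, p)) ||
      min(eigen(innovation_cov, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    abort_config("`innovation_cov` must be a p x p symmetric positive-definite matrix.")
  nugget_var <- rep_len(nugget_var, n_years)
  sill_var <- rep_len(sill_var, n_years)
  decay <- rep_len(decay, n_years)
  if (any(nugget_var < 0) || any(sill_var < 0) || any(decay <= 0))
    abort_config("Variance paths must be non-negative and `decay` strictly positive.")
  with_seed_if(seed, {
    Ueta <- safe_chol(innovation_cov)
    eta <- t(crossprod(Ueta, matrix(rnorm(p * n_years), p, n_years)))  # T x p
    beta_path <- sweep(apply(eta, 2, cumsum), 2, beta0, `+`)
    beta_path <- matrix(beta_path, n_years, p)
    D <- great_circle_km(cm)
    omega <- matrix(0, n, n_years)
    for (t in seq_len(n_years)) {
      if (sill_var[t] > 0) {
        Ct <- exp(-decay[t] * D)
        omega[, t] <- drop(crossprod(safe_chol(sym_mat(Ct), jitter = 1e-8),
                                     rnorm(n))) * sqrt(sill_var[t])
      }
    }
    spatial <- t(apply(omega, 1, cumsum))
    spatial <- matrix(spatial, n, n_years)
    structure(list(
      beta0 = beta0, beta_path = beta_path, eta = eta,
      innovation_cov = innovation_cov,
      spatial_effects = spatial, spatial_innovations = omega,
      nugget_var_path = nugget_var, sill_var_path = sill_var,
      decay_path = decay, coords = cm,
      site_ids = coords_site_ids(coords), n_years = as.integer(n_years),
      p = p, seed = as.integer(seed)
    ), class = "fsn_truth")
  })
}

#' Simulate a covariate design panel
#'
#' A simple design for synthetic studies: an optional intercept column of ones
#' plus independent standard-normal covariates per site-year cell.
#'
#' @param n_sites,n_years grid dimensions.
#' @param p total number of design columns (including the intercept when
#'   `intercept = TRUE`).
#' @param seed integer seed.
#' @param intercept include a leading column of ones (default TRUE).
#' @return an `n_sites x n_years x p` array with covariate dimnames.
#' @export
simulate_design <- function(n_sites, n_years, p, seed = 1, intercept = TRUE) {
  X <- with_seed_if(seed, array(rnorm(n_sites * n_years * p),
                                dim = c(n_sites, n_years, p)))
  nms <- paste0("x", seq_len(p))
  if (intercept) {
    X[, , 1] <- 1
    nms[1] <- "intercept"
  }
  dimnames(X) <- list(NULL, NULL, nms)
  X
}

#' Simulate a response panel from the generative model
#'
#' Simulates `Y[s, t] = X[s, t, ] %*% beta_t + spatial[s, t] + eps` forward
#' from stored true parameters, with `eps ~ N(0, nugget_var[t])`. The truth
#' object is recorded on the returned panel for recovery tests.
#'
#' @param truth an [simulate_truth()] object.
#' @param design `n_sites x n_years x p` covariate array (e.g.
#'   [simulate_design()]), or `NULL` for a fresh default design drawn from the
#'   same seed.
#' @param seed integer seed for the observation noise.
#' @param include_spatial include the spatial random effect (default TRUE);
#'   `FALSE` gives the pure dynamic-regression limit.
#' @return an [fsn_panel] with the truth attached as `$truth`.
#' @export
simulate_panel <- function(truth, design = NULL, seed = 1,
                           include_spatial = TRUE) {
  if (!inherits(truth, "fsn_truth"))
    abort_config("`truth` must be created by simulate_truth().")
  n <- nrow(truth$coords)
  T_ <- truth$n_years
  p <- truth$p
  design <- design %||% simulate_design(n, T_, p, seed = seed)
  if (!is.array(design) || !all(dim(design) == c(n, T_, p)))
    abort_config(sprintf(
      "`design` must be an array of dimension %d x %d x %d to match the truth.",
      n, T_, p))
  Y <- with_seed_if(seed, {
    Y <- matrix(0, n, T_)
    for (t in seq_len(T_)) {
      mu <- drop(matrix(design[, t, ], n, p) %*% truth$beta_path[t, ])
      if (include_spatial) mu <- mu + truth$spatial_effects[, t]
      eps <- if (truth$nugget_var_path[t] > 0)
        rnorm(n, 0, sqrt(truth$nugget_var_path[t])) else 0
      Y[, t] <- mu + eps
    }
    Y
  })
  new_panel(Y = Y, X = design, coords = truth$coords,
            site_ids = truth$site_ids %||% sprintf("S%03d", seq_len(n)),
            years = 2000L + seq_len(T_) - 1L,
            mask = matrix(TRUE, n, T_), transform = "identity",
            truth = truth)
}

# ---- coordinate input helpers -----------------------------------------------

coords_matrix <- function(coords) {
  df <- as.data.frame(coords)
  if (all(c("lon", "lat") %in% names(df))) {
    m <- as.matrix(df[, c("lon", "lat")])
  } else {
    m <- as.matrix(df[, setdiff(names(df), "site_id")[1:2]])
  }
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, c("lon", "lat"))
  if (nrow(m) < 2) abort_config("Need at least 2 sites.")
  if (anyDuplicated(m)) abort_validation("Site coordinates must be distinct.")
  m
}

coords_site_ids <- function(coords) {
  df <- as.data.frame(coords)
  if ("site_id" %in% names(df)) as.character(df$site_id)
  else sprintf("S%03d", seq_len(nrow(df)))
}
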