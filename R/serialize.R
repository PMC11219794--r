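#' Serialize posterior samples to a directory of CSVs plus a manifest
#'
#' Writes the kept draws of every sampled block as long-format CSV arrays
#' (`beta.csv`, `beta0.csv`, `spatial.csv`, `variances.csv`, `decay.csv`,
#' `innovation_cov.csv`, `log_joint.csv`) and a `manifest.json` recording the
#' sampler configuration, seed, per-time decay acceptance rates and panel
#' geometry, so a fit can be archived or post-processed outside R.
#'
#' @param fit an `fsn_fit`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_posterior_csv <- function(fit, dir) {
  stopifnot(inherits(fit, "fsn_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  M <- fit$config$n_kept
  T_ <- fit$panel$n_times; p <- fit$panel$p; n <- fit$panel$n_sites
  idx <- tidyr::expand_grid(draw = seq_len(M), t = seq_len(T_))
  beta_long <- dplyr::bind_cols(
    tibble(draw = rep(seq_len(M), times = T_ * p),
           year = rep(rep(fit$years, each = M), times = p),
           component = rep(fit$covariate_names, each = M * T_),
           value = as.vector(fit$draws$beta)))
  readr::write_csv(beta_long, file.path(dir, "beta.csv"))
  readr::write_csv(tibble(draw = seq_len(M),
                          as_tibble(`colnames<-`(fit$draws$beta0,
                                                 fit$covariate_names))),
                   file.path(dir, "beta0.csv"))
  readr::write_csv(tibble(
    draw = rep(seq_len(M), times = n * T_),
    site_id = rep(rep(fit$panel$site_ids, each = M), times = T_),
    year = rep(fit$years, each = M * n),
    value = as.vector(fit$draws$spatial)), file.path(dir, "spatial.csv"))
  readr::write_csv(tibble(
    draw = rep(idx$draw, 2),
    year = rep(fit$years[idx$t], 2),
    series = rep(c("sigma2", "tau2"), each = nrow(idx)),
    value = c(as.vector(fit$draws$sill_var),
              as.vector(fit$draws$nugget_var))),
    file.path(dir, "variances.csv"))
  readr::write_csv(tibble(draw = idx$draw, year = fit$years[idx$t],
                          value = as.vector(fit$draws$decay)),
                   file.path(dir, "decay.csv"))
  readr::write_csv(tibble(
    draw = rep(seq_len(M), times = p * p),
    row = rep(rep(fit$covariate_names, each = M), times = p),
    col = rep(fit$covariate_names, each = M * p),
    value = as.vector(fit$draws$innovation_cov)),
    file.path(dir, "innovation_cov.csv"))
  readr::write_csv(tibble(draw = seq_len(M), log_joint = fit$log_joint_trace),
                   file.path(dir, "log_joint.csv"))
  jsonlite::write_json(list(
    config = fit$config[c("n_iter", "burn_in", "thin", "seed",
                          "metropolis_step", "adapt", "n_kept")],
    acceptance_rates = fit$acceptance_rates,
    panel = list(n_sites = n, n_times = T_, p = p,
                 covariates = fit$covariate_names,
                 transform = fit$panel$transform),
    note = "burn-in, thinning and single-chain defaults are artifact choices"
  ), file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  invisible(dir)
}
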