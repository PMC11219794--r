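#' Split a panel's observed cells into training and testing masks
#'
#' Implements the 70/30 out-of-sample protocol. Three strategies:
#' `"random_cells"` (default) samples cells stratified by year — per-year test
#' counts follow a largest-remainder allocation of `floor(test_fraction * K)`
#' cells (K the number of observed cells), capped so every year keeps at
#' least one training cell; `"by_site"` holds out all cells of
#' `floor(test_fraction * n_sites)` whole sites; `"by_year"` the analogue for
#' whole years.
#'
#' @param panel an `fsn_panel`.
#' @param test_fraction fraction of observed cells (or sites/years) held out,
#'   in (0, 1); default 0.3.
#' @param strategy `"random_cells"`, `"by_site"` or `"by_year"`.
#' @param seed integer seed.
#' @return list of class `fsn_split` with logical `train` and `test` masks
#'   (disjoint, union = observed cells), plus `strategy` and `seed`.
#' @export
split_panel <- function(panel, test_fraction = 0.3,
                        strategy = c("random_cells", "by_site", "by_year"),
                        seed = NULL) {
  stopifnot(inherits(panel, "fsn_panel"))
  strategy <- match.arg(strategy)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    abort_validation("`test_fraction` must lie strictly in (0, 1).")
  n <- panel$n_sites; T_ <- panel$n_times
  test <- matrix(FALSE, n, T_)
  with_seed_if(seed, {
    if (strategy == "random_cells") {
      k_t <- colSums(panel$mask)
      K <- sum(k_t)
      total <- floor(test_fraction * K)
      raw <- test_fraction * k_t
      alloc <- floor(raw)
      rem <- total - sum(alloc)
      if (rem > 0) {
        extra <- order(raw - alloc, decreasing = TRUE)[seq_len(rem)]
        alloc[extra] <- alloc[extra] + 1
      }
      alloc <- pmin(alloc, pmax(k_t - 1, 0))   # keep >= 1 training cell per year
      ok <- FALSE
      for (attempt in seq_len(100)) {
        test[] <- FALSE
        for (t in seq_len(T_)) {
          obs <- which(panel$mask[, t])
          if (alloc[t] > 0)
            test[sample(obs, alloc[t]), t] <- TRUE
        }
        if (all(colSums(panel$mask & !test) >= 1)) { ok <- TRUE; break }
      }
      if (!ok) abort_validation(
        "Could not build a split keeping a training cell in every year (100 attempts).")
    } else if (strategy == "by_site") {
      k <- floor(test_fraction * n)
      sites <- sample(seq_len(n), k)
      test[sites, ] <- TRUE
      test <- test & panel$mask
      if (any(colSums(panel$mask & !test) < 1))
        abort_validation("by_site split left a year with no training cells.")
    } else {
      k <- floor(test_fraction * T_)
      yrs <- sample(seq_len(T_), k)
      test[, yrs] <- TRUE
      test <- test & panel$mask
      # whole held-out years keep no training cells by design; the random
      # walk still bridges them
    }
  })
  structure(list(train = panel$mask & !test, test = test,
                 strategy = strategy, seed = seed,
                 test_fraction = test_fraction),
            class = "fsn_split")
}

#' Restrict a panel to a training mask
#'
#' Returns a copy of the panel whose likelihood mask is the training part of
#' a split; the held-out responses stay stored (for later assessment) but do
#' not enter the fit.
#'
#' @param panel an `fsn_panel`.
#' @param split an [split_panel()] result.
#' @return an `fsn_panel`.
#' @export
training_panel <- function(panel, split) {
  stopifnot(inherits(split, "fsn_split"))
  out <- panel
  out$mask <- split$train
  out
}

#' Posterior-predictive draws for panel cells
#'
#' For each kept posterior draw and requested cell (site s, time t), the
#' predictive value is `X[s,t,] beta_t + spatial[s,t] + N(0, nugget_var_t)`.
#' The latent spatial field is sampled at every site of the panel whether or
#' not the cell entered the likelihood, so for held-out cells this is the
#' conditional (kriging-style) draw given the observed data, not a marginal
#' prior draw.
#'
#' @param fit an `fsn_fit`.
#' @param cells data frame with `site_id` and `year` columns, or a two-column
#'   matrix of (site index, time index).
#' @param seed integer seed for the predictive noise.
#' @param include_noise add the observation noise (default TRUE; `FALSE`
#'   gives fitted-mean draws).
#' @return matrix of predictive draws, one row per cell, one column per kept
#'   draw; rows carry the cell indices as attributes `site` and `time`.
#' @export
posterior_predict <- function(fit, cells, seed = NULL, include_noise = TRUE) {
  stopifnot(inherits(fit, "fsn_fit"))
  idx <- resolve_cells(fit$panel, cells)
  M <- fit$config$n_kept
  n <- fit$panel$n_sites; p <- fit$panel$p
  out <- matrix(NA_real_, nrow(idx), M)
  with_seed_if(seed, {
    for (r in seq_len(nrow(idx))) {
      s <- idx[r, 1]; t <- idx[r, 2]
      x <- fit$panel$X[s, t, ]
      mu <- fit$draws$beta[, t, , drop = FALSE]
      mu <- matrix(mu, M, p) %*% x + fit$draws$spatial[, s, t]
      if (include_noise)
        mu <- mu + rnorm(M, 0, sqrt(fit$draws$nugget_var[, t]))
      out[r, ] <- mu
    }
  })
  attr(out, "site") <- idx[, 1]
  attr(out, "time") <- idx[, 2]
  out
}

resolve_cells <- function(panel, cells) {
  if (is.matrix(cells) && is.numeric(cells)) {
    idx <- cells[, 1:2, drop = FALSE]
  } else if (is.logical(cells) && is.matrix(cells)) {
    idx <- which(cells, arr.ind = TRUE)
  } else {
    df <- as.data.frame(cells)
    idx <- cbind(match(as.character(df$site_id), panel$site_ids),
                 match(df$year, panel$years))
  }
  if (anyNA(idx) || any(idx[, 1] < 1) || any(idx[, 1] > panel$n_sites) ||
      any(idx[, 2] < 1) || any(idx[, 2] > panel$n_times))
    abort_validation("Requested cells fall outside the panel grid.")
  idx <- matrix(as.integer(idx), ncol = 2)
  idx
}

#' Posterior-predictive draws at a new (off-grid) site
#'
#' Conditional simulation of the spatial field at an unobserved location: per
#' posterior draw and time step, the innovation at the new site is drawn from
#' its GP conditional given the sampled innovations at the panel sites
#' (`mean = c' C^{-1} omega_t`, `var = sill_var_t (1 - c' C^{-1} c)` with `c`
#' the cross-correlations), and accumulated through the random walk. As the
#' new site moves arbitrarily far away the spatial contribution vanishes and
#' the predictive mean reduces to the regression part.
#'
#' @param fit an `fsn_fit`.
#' @param lonlat length-2 numeric (longitude, latitude) of the new site.
#' @param x_new T x p covariate matrix for the new site.
#' @param draws indices of kept draws to use (default: all, capped at 500
#'   for tractability).
#' @param seed integer seed.
#' @param include_noise add observation noise (default TRUE).
#' @return T x length(draws) matrix of predictive draws.
#' @export
predict_offgrid <- function(fit, lonlat, x_new, draws = NULL, seed = NULL,
                            include_noise = TRUE) {
  stopifnot(inherits(fit, "fsn_fit"))
  panel <- fit$panel
  T_ <- panel$n_times; n <- panel$n_sites; p <- panel$p
  x_new <- matrix(x_new, T_, p)
  M_all <- fit$config$n_kept
  draws <- draws %||% seq_len(min(M_all, 500))
  d_new <- drop(geosphere::distHaversine(
    matrix(lonlat, 1, 2)[rep(1, n), ], panel$coords)) / 1000
  D <- great_circle_km(panel$coords)
  out <- matrix(NA_real_, T_, length(draws))
  with_seed_if(seed, {
    for (mi in seq_along(draws)) {
      m <- draws[mi]
      aleph_prev_new <- 0
      spat_prev <- rep(0, n)
      for (t in seq_len(T_)) {
        th <- fit$draws$decay[m, t]
        sv <- fit$draws$sill_var[m, t]
        omega <- fit$draws$spatial[m, , t] - spat_prev
        spat_prev <- fit$draws$spatial[m, , t]
        C <- exp(-th * D); diag(C) <- 1
        cc <- exp(-th * d_new)
        U <- safe_chol(C)
        Cinv_c <- backsolve(U, backsolve(U, cc, transpose = TRUE))
        w_mean <- sum(Cinv_c * omega)
        w_var <- max(0, sv * (1 - sum(cc * Cinv_c)))
        aleph_prev_new <- aleph_prev_new + w_mean + sqrt(w_var) * rnorm(1)
        mu <- sum(x_new[t, ] * fit$draws$beta[m, t, ]) + aleph_prev_new
        if (include_noise)
          mu <- mu + rnorm(1, 0, sqrt(fit$draws$nugget_var[m, t]))
        out[t, mi] <- mu
      }
    }
  })
  out
}

#' Coverage percentage of predictive intervals
#'
#' The coverage statistic `CP = 100 * mean(I(L_i <= y_i <= U_i))` over k
#' held-out observations, with non-strict inequalities, so a value exactly on
#' an interval endpoint counts as covered.
#'
#' @param y observed values (length k >= 1).
#' @param lower,upper interval endpoints (elementwise `lower <= upper`).
#' @param level nominal level of the intervals (recorded, default 0.95).
#' @param cells optional tibble of cell labels bound onto the result.
#' @return object of class `fsn_coverage`: a list with `table` (tibble of
#'   `y`, `lower`, `upper`, `inside`), `k`, `level`, `cp`.
#' @export
coverage_percentage <- function(y, lower, upper, level = 0.95, cells = NULL) {
  k <- length(y)
  if (k < 1) abort_validation("Need at least one held-out observation.")
  if (length(lower) != k || length(upper) != k)
    abort_validation("`y`, `lower`, `upper` must have equal length.")
  if (any(lower > upper))
    abort_validation("Every interval must satisfy lower <= upper.")
  inside <- lower <= y & y <= upper
  tab <- tibble(y = as.numeric(y), lower = as.numeric(lower),
                upper = as.numeric(upper), inside = inside)
  if (!is.null(cells)) tab <- dplyr::bind_cols(tibble::as_tibble(cells), tab)
  structure(list(table = tab, k = k, level = level,
                 cp = 100 * mean(inside)),
            class = "fsn_coverage")
}

#' @export
print.fsn_coverage <- function(x, ...) {
  cat(sprintf("<fsn_coverage> CP = %.1f%% (%d of %d cells inside %.0f%% intervals)\n",
              x$cp, sum(x$table$inside), x$k, 100 * x$level))
  invisible(x)
}

#' @method glance fsn_coverage
#' @export
glance.fsn_coverage <- function(x, ...) {
  tibble(k = x$k, level = x$level, cp = x$cp)
}

#' Hold-out predictive assessment of a fitted model
#'
#' Computes equal-tailed predictive intervals for every held-out cell of a
#' split from the posterior-predictive draws and applies
#' [coverage_percentage()].
#'
#' @param fit an `fsn_fit` (fitted on the training mask).
#' @param split the [split_panel()] used for the fit (its `test` mask defines
#'   the held-out cells); a logical mask matrix is also accepted.
#' @param level interval level (default 0.95).
#' @param seed integer seed for the predictive noise.
#' @return an `fsn_coverage` object whose table carries `site_id` and `year`.
#' @export
assess_coverage <- function(fit, split, level = 0.95, seed = NULL) {
  test <- if (inherits(split, "fsn_split")) split$test else split
  idx <- which(test, arr.ind = TRUE)
  if (nrow(idx) == 0) abort_validation("The test mask holds no cells.")
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  pred <- posterior_predict(fit, idx, seed = seed)
  a <- (1 - level) / 2
  lims <- t(apply(pred, 1, quantile, probs = c(a, 1 - a), type = 7))
  y <- fit$panel$Y[idx]
  cells <- tibble(site_id = fit$panel$site_ids[idx[, 1]],
                  year = fit$panel$years[idx[, 2]])
  coverage_percentage(y, lims[, 1], lims[, 2], level = level, cells = cells)
}
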