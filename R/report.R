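#' Dynamic-coefficient trajectory report
#'
#' Posterior median and equal-tailed interval of every regression coefficient
#' at every year, with a significance flag set when the interval excludes
#' zero — the time path of each food-security component's influence.
#'
#' @param fit an `fsn_fit`.
#' @param level credibility level (default 0.95).
#' @return tibble with `component`, `year`, `median`, `lower`, `upper`,
#'   `significant`.
#' @export
coefficient_trajectories <- function(fit, level = 0.95) {
  posterior_summary(fit, level) |>
    dplyr::filter(.data$parameter == "beta") |>
    dplyr::select("component", "year", "median", "lower", "upper", "significant")
}

#' Variance trajectory report (sigma2 and tau2)
#'
#' Posterior summaries per year of the spatial innovation variance (the
#' partial sill, labelled `sigma2` — the spatio-temporal dependence strength)
#' and the observation-level variance (the nugget, labelled `tau2` — the
#' micro-scale variation).
#'
#' @inheritParams coefficient_trajectories
#' @return tibble with `series` (`"sigma2"`/`"tau2"`), `year`, `median`,
#'   `lower`, `upper`.
#' @export
variance_trajectories <- function(fit, level = 0.95) {
  posterior_summary(fit, level) |>
    dplyr::filter(.data$parameter %in% c("sigma2", "tau2")) |>
    dplyr::rename(series = "parameter") |>
    dplyr::select("series", "year", "median", "lower", "upper")
}

#' Annual fitted-value layers
#'
#' Posterior mean of the fitted surface `X beta_t + spatial` per site and
#' year, back-transformed to the raw response scale when the panel uses a
#' transform — the per-year map layer.
#'
#' @param fit an `fsn_fit`.
#' @return tibble with `site_id`, `year`, `fitted`.
#' @export
annual_fitted_layers <- function(fit) {
  panel <- fit$panel
  n <- panel$n_sites; T_ <- panel$n_times; p <- panel$p
  M <- fit$config$n_kept
  fitted <- matrix(0, n, T_)
  for (t in seq_len(T_)) {
    Xt <- matrix(panel$X[, t, ], n, p)
    mu_beta <- Xt %*% colMeans(matrix(fit$draws$beta[, t, ], M, p))
    fitted[, t] <- drop(mu_beta) + colMeans(matrix(fit$draws$spatial[, , t], M, n))
  }
  tibble(site_id = rep(panel$site_ids, times = T_),
         year = rep(panel$years, each = n),
         fitted = inverse_transform(as.vector(fitted), panel$transform))
}

#' Period-aggregated percentile map layers
#'
#' Aggregates annual fitted layers over multi-year blocks (default the four
#' five-year periods 2000-2004, 2005-2009, 2010-2014, 2015-2019) with the
#' per-site median (resistant to outlying years; the mean is available via
#' `stat`), then classifies sites within each block into `n_bins` percentile
#' classes by rank: `class = ceiling(n_bins * rank / n)` with minimum-rank
#' ties, so equal aggregates share the lowest applicable class and the
#' classes are invariant under any strictly monotone transform of the
#' aggregates.
#'
#' @param layers tibble from [annual_fitted_layers()] (columns `site_id`,
#'   `year`, `fitted`).
#' @param blocks list of `c(first_year, last_year)` pairs.
#' @param n_bins number of percentile classes (default 5).
#' @param stat `"median"` (default) or `"mean"`.
#' @return tibble with `block`, `site_id`, `aggregate`, `percentile_class`.
#' @export
period_percentile_layers <- function(layers,
                                     blocks = list(c(2000, 2004), c(2005, 2009),
                                                   c(2010, 2014), c(2015, 2019)),
                                     n_bins = 5, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  agg_fun <- if (stat == "median") stats::median else mean
  if (!is_count(n_bins)) abort_validation("`n_bins` must be a positive integer.")
  purrr::map_dfr(blocks, function(b) {
    sub <- dplyr::filter(layers, .data$year >= b[1], .data$year <= b[2])
    if (nrow(sub) == 0)
      abort_validation(sprintf("Block %d-%d contains no panel years.", b[1], b[2]))
    sub |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(aggregate = agg_fun(.data$fitted), .groups = "drop") |>
      dplyr::mutate(
        block = sprintf("%d-%d", b[1], b[2]),
        percentile_class = as.integer(ceiling(
          n_bins * rank(.data$aggregate, ties.method = "min") /
            dplyr::n()))) |>
      dplyr::select("block", "site_id", "aggregate", "percentile_class")
  })
}

#' Write map layers as GeoJSON point features
#'
#' RFC 7946 FeatureCollection with one Point feature per row of `layers`,
#' joined to site coordinates; all non-coordinate columns become feature
#' properties. A thin export for mapping tools — no rendering here.
#'
#' @param layers tibble with a `site_id` column (annual or period layers).
#' @param coords tibble with `site_id`, `lon`, `lat`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_layers_geojson <- function(layers, coords, path) {
  co <- as.data.frame(coords)
  m <- match(layers$site_id, co$site_id)
  if (anyNA(m)) abort_validation("`layers` has site_ids missing from `coords`.")
  props <- as.data.frame(layers)
  features <- lapply(seq_len(nrow(props)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(co$lon[m[i]], co$lat[m[i]])),
         properties = as.list(props[i, , drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Plot coefficient trajectories
#'
#' Ribbon plot of the dynamic coefficients over time, one facet per
#' component, with the zero line for reading off significance.
#'
#' @param object an `fsn_fit`.
#' @param level credibility level.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fsn_fit
#' @export
autoplot.fsn_fit <- function(object, level = 0.95, ...) {
  df <- coefficient_trajectories(object, level)
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "Year", y = "Coefficient",
                  title = "Dynamic coefficients (posterior median, credible band)")
}

#' Plot the variance trajectories (sigma2 and tau2)
#'
#' @param fit an `fsn_fit`.
#' @param level credibility level.
#' @return a ggplot.
#' @export
plot_variance_trajectories <- function(fit, level = 0.95) {
  df <- variance_trajectories(fit, level)
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Year", y = "Variance",
                  title = "Spatio-temporal (sigma2) and micro-scale (tau2) variance")
}

#' Plot percentile map layers as a point map
#'
#' @param layers tibble from [period_percentile_layers()].
#' @param coords tibble with `site_id`, `lon`, `lat`.
#' @return a ggplot.
#' @export
plot_percentile_map <- function(layers, coords) {
  df <- dplyr::inner_join(layers, tibble::as_tibble(coords), by = "site_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   colour = factor(.data$percentile_class))) +
    ggplot2::geom_point(size = 3) +
    ggplot2::facet_wrap(~block) +
    ggplot2::scale_colour_viridis_d(name = "Percentile class") +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  title = "Period-aggregated percentile classes")
}
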