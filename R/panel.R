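#' Spatio-temporal panel container
#'
#' Packs a long site-year table into the matrix layout the sampler works on:
#' an `n_sites x T` response matrix `Y` (on the model scale), an
#' `n_sites x T x p` covariate array `X`, site coordinates, and an observation
#' mask. Cells with `mask = FALSE` (held out, or `NA` in the input) contribute
#' nothing to the likelihood but are still covered by the latent spatial
#' field, which is what makes hold-out prediction possible.
#'
#' @param data long-format data frame with columns `site_id`, `year`, the
#'   response, and covariate columns. One row per site-year cell.
#' @param coords data frame with `site_id`, `lon`, `lat` (decimal degrees).
#' @param response name of the response column (default `"y"`).
#' @param covariates character vector of covariate column names; default all
#'   numeric columns other than the response and `year`. An intercept column
#'   is *not* added automatically.
#' @param transform response transform: `"identity"` or `"log1p"`. The panel
#'   stores the transformed response; reporting back-transforms.
#' @param mask optional `n_sites x T` logical matrix of observed cells
#'   (default: non-missing response).
#' @return an object of class `fsn_panel`.
#' @export
as_panel <- function(data, coords, response = "y", covariates = NULL,
                     transform = c("identity", "log1p"), mask = NULL) {
  transform <- match.arg(transform)
  data <- as.data.frame(data)
  if (!all(c("site_id", "year", response) %in% names(data)))
    abort_validation("`data` must contain columns site_id, year and the response.")
  coords_df <- as.data.frame(coords)
  if (!all(c("site_id", "lon", "lat") %in% names(coords_df)))
    abort_validation("`coords` must contain site_id, lon, lat.")
  site_ids <- as.character(coords_df$site_id)
  years <- sort(unique(data$year))
  n <- length(site_ids); T_ <- length(years)
  covariates <- covariates %||% setdiff(
    names(data)[vapply(data, is.numeric, logical(1))], c(response, "year"))
  p <- length(covariates)
  if (p < 1) abort_validation("Need at least one covariate column.")
  si <- match(as.character(data$site_id), site_ids)
  ti <- match(data$year, years)
  if (anyNA(si)) abort_validation("`data` has site_ids missing from `coords`.")
  Y <- matrix(NA_real_, n, T_)
  Y[cbind(si, ti)] <- transform_response(data[[response]], transform)
  X <- array(NA_real_, dim = c(n, T_, p), dimnames = list(NULL, NULL, covariates))
  for (j in seq_len(p)) X[cbind(si, ti, j)] <- data[[covariates[j]]]
  if (anyNA(X)) abort_validation("Covariates must be complete on the full grid.")
  mask <- mask %||% !is.na(Y)
  Y[is.na(Y)] <- 0
  new_panel(Y = Y, X = X, coords = coords_matrix(coords_df),
            site_ids = site_ids, years = as.integer(years),
            mask = mask, transform = transform)
}

new_panel <- function(Y, X, coords, site_ids, years, mask, transform,
                      truth = NULL) {
  n <- nrow(Y); T_ <- ncol(Y); p <- dim(X)[3]
  if (n < 2 || T_ < 2 || p < 1)
    abort_validation("Panel needs n_sites >= 2, T >= 2, p >= 1.")
  if (!all(dim(X)[1:2] == c(n, T_)) || !all(dim(mask) == c(n, T_)))
    abort_validation("Y, X and mask dimensions disagree.")
  if (anyDuplicated(coords)) abort_validation("Site coordinates must be distinct.")
  if (any(colSums(mask) < 1))
    abort_validation("Every time point needs at least one observed cell.")
  structure(list(
    Y = Y, X = X, coords = coords, site_ids = site_ids,
    years = as.integer(years), mask = mask, transform = transform,
    truth = truth,
    n_sites = n, n_times = T_, p = p,
    covariate_names = dimnames(X)[[3]] %||% paste0("x", seq_len(p))
  ), class = "fsn_panel")
}

#' @export
print.fsn_panel <- function(x, ...) {
  cat(sprintf(
    "<fsn_panel> %d sites x %d years, %d covariates (%s)\n  response scale: %s; observed cells: %d / %d\n",
    x$n_sites, x$n_times, x$p, paste(x$covariate_names, collapse = ", "),
    x$transform, sum(x$mask), length(x$mask)))
  if (!is.null(x$truth)) cat("  generative truth attached\n")
  invisible(x)
}

#' Long tibble view of a panel
#'
#' @param x an `fsn_panel`.
#' @param ... unused.
#' @return tibble with `site_id`, `year`, `y` (model scale), `observed`, and
#'   one column per covariate.
#' @method as_tibble fsn_panel
#' @export
as_tibble.fsn_panel <- function(x, ...) {
  grid <- tidyr::expand_grid(site = seq_len(x$n_sites), t = seq_len(x$n_times))
  out <- tibble::tibble(
    site_id = x$site_ids[grid$site],
    year = x$years[grid$t],
    y = x$Y[cbind(grid$site, grid$t)],
    observed = x$mask[cbind(grid$site, grid$t)]
  )
  for (j in seq_len(x$p))
    out[[x$covariate_names[j]]] <- x$X[cbind(grid$site, grid$t, j)]
  out
}

#' Transform a raw response to the model scale (and back)
#'
#' `transform_response()` maps raw responses onto the scale the Gaussian model
#' works on; `inverse_transform()` undoes it exactly (round-trip error below
#' 1e-10). The available modes are the identity and `log1p` (for non-negative
#' counts such as numbers of severely food-insecure individuals).
#'
#' @param y numeric vector.
#' @param mode `"identity"` or `"log1p"`.
#' @return transformed numeric vector.
#' @export
transform_response <- function(y, mode = c("identity", "log1p")) {
  mode <- match.arg(mode)
  if (mode == "identity") return(as.numeric(y))
  if (any(y < 0, na.rm = TRUE))
    abort_validation("log1p transform requires a non-negative response.")
  log1p(as.numeric(y))
}

#' @rdname transform_response
#' @export
inverse_transform <- function(y, mode = c("identity", "log1p")) {
  mode <- match.arg(mode)
  if (mode == "identity") as.numeric(y) else expm1(as.numeric(y))
}

#' Write / read a panel as CSV
#'
#' The long-format CSV (`site_id`, `year`, `y`, covariates) plus a coordinate
#' CSV (`site_id`, `lon`, `lat`) round-trip through [as_panel()].
#'
#' @param panel an `fsn_panel`.
#' @param path CSV file path for the panel table.
#' @param coords_path optional CSV path for the coordinates.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path, coords_path = NULL) {
  tbl <- as_tibble.fsn_panel(panel)
  tbl$y <- inverse_transform(tbl$y, panel$transform)
  tbl$y[!tbl$observed] <- NA_real_
  readr::write_csv(dplyr::select(tbl, -"observed"), path)
  if (!is.null(coords_path)) {
    readr::write_csv(tibble::tibble(site_id = panel$site_ids,
                                    lon = panel$coords[, 1],
                                    lat = panel$coords[, 2]), coords_path)
  }
  invisible(path)
}

#' @rdname write_panel_csv
#' @param transform response transform passed to [as_panel()].
#' @export
read_panel_csv <- function(path, coords_path, transform = "identity") {
  data <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  coords <- readr::read_csv(coords_path, show_col_types = FALSE, comment = "#")
  as_panel(data, coords, transform = transform)
}
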