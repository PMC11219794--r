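#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' The overall KMO statistic
#' `sum(r_ij^2) / (sum(r_ij^2) + sum(q_ij^2))` over off-diagonal pairs, where
#' `q_ij` are the anti-image partial correlations obtained by scaling the
#' inverse correlation matrix. Values near 1 indicate that a factor model can
#' compress the indicators; 0.5 is the floor usually quoted as acceptable. For
#' any bivariate correlation matrix the partial correlation equals the
#' marginal one, so KMO is exactly 0.5.
#'
#' @param R correlation matrix (symmetric, unit diagonal, positive definite).
#' @return a single number in `[0, 1]`.
#' @export
#' @examples
#' kmo(matrix(c(1, 0.5, 0.5, 1), 2))  # 0.5
kmo <- function(R) {
  R <- check_corr(R)
  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(Rinv) || !all(is.finite(Rinv)))
    abort_numeric(sprintf(
      "Correlation matrix is numerically singular (condition number %.3g).",
      kappa(R)))
  s <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * tcrossprod(s)          # anti-image partial correlations
  off <- upper.tri(R)
  r2 <- sum(R[off]^2)
  q2 <- sum(Q[off]^2)
  r2 / (r2 + q2)
}

#' Bartlett's test of sphericity
#'
#' Tests the null that the correlation matrix is the identity (no common
#' structure worth extracting). The statistic is
#' `-(n - 1 - (2p + 5)/6) * log(det(R))` on `p(p-1)/2` degrees of freedom with
#' a chi-square upper-tail p-value.
#'
#' @param R correlation matrix.
#' @param n sample size used to estimate `R` (must exceed `ncol(R)`).
#' @return tibble with columns `statistic`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(R, n) {
  R <- check_corr(R)
  p <- ncol(R)
  if (!is_count(n) || n <= p) abort_validation("`n` must exceed ncol(R).")
  detR <- det(R)
  if (detR <= 0)
    abort_numeric("det(R) is non-positive; R is not positive definite.")
  stat <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  tibble(statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE))
}

check_corr <- function(R) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-8 ||
      max(abs(diag(R) - 1)) > 1e-8)
    abort_validation("`R` must be a symmetric correlation matrix with unit diagonal.")
  sym_mat(R)
}

#' Varimax rotation by pairwise planar rotations
#'
#' Maximizes the varimax criterion (the sum over factors of the variance of
#' squared loadings, computed on Kaiser row-normalized loadings when
#' `kaiser_normalize = TRUE`) over orthogonal rotations, by sweeping all
#' factor pairs with the closed-form optimal planar angle until the criterion
#' gain in a sweep drops below `tol`. The criterion is non-decreasing across
#' sweeps. Non-convergence sets a `converged = FALSE` flag (with a warning)
#' rather than failing.
#'
#' @param loadings p x k loading matrix, `k >= 1`.
#' @param kaiser_normalize scale rows to unit length before rotating and
#'   rescale after (default TRUE, the classic Kaiser procedure).
#' @param tol convergence tolerance on the criterion gain per sweep.
#' @param max_iter maximum number of sweeps.
#' @return list with `rotated_loadings`, `rotation` (k x k orthogonal),
#'   `criterion`, `iterations`, `converged`.
#' @export
varimax_rotate <- function(loadings, kaiser_normalize = TRUE, tol = 1e-10,
                           max_iter = 1000L) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  if (is.null(k) || k < 1) abort_validation("`loadings` must have at least one column.")
  if (k == 1L) {
    return(list(rotated_loadings = L, rotation = matrix(1, 1, 1),
                criterion = varimax_criterion(L, kaiser_normalize),
                iterations = 0L, converged = TRUE))
  }
  h <- if (kaiser_normalize) sqrt(rowSums(L^2)) else rep(1, nrow(L))
  h[h == 0] <- 1
  A <- L / h
  Rot <- diag(k)
  p <- nrow(A)
  crit_of <- function(M) sum(apply(M^2, 2, function(c2) mean(c2^2) - mean(c2)^2))
  crit <- crit_of(A)
  converged <- FALSE
  iterations <- 0L
  for (sweep in seq_len(max_iter)) {
    iterations <- sweep
    crit_before <- crit
    for (j in seq_len(k - 1)) {
      for (l in (j + 1):k) {
        x <- A[, j]; y <- A[, l]
        u <- x^2 - y^2
        v <- 2 * x * y
        a <- sum(u); b <- sum(v)
        c_ <- sum(u^2 - v^2); d_ <- sum(2 * u * v)
        num <- d_ - 2 * a * b / p
        den <- c_ - (a^2 - b^2) / p
        phi <- atan2(num, den) / 4
        if (abs(phi) < 1e-14) next
        # planar rotation x' = x cos + y sin, y' = -x sin + y cos
        G <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
        A[, c(j, l)] <- A[, c(j, l)] %*% G
        Rot[, c(j, l)] <- Rot[, c(j, l)] %*% G
      }
    }
    crit <- crit_of(A)
    if (crit - crit_before < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warn(sprintf("varimax did not converge in %d sweeps.", max_iter))
  rotated <- (A * h)
  list(rotated_loadings = rotated, rotation = Rot, criterion = crit,
       iterations = iterations, converged = converged)
}

#' Varimax simplicity criterion
#'
#' Sum over factors of the variance of squared loadings (rows Kaiser
#' normalized first when requested) — the objective [varimax_rotate()]
#' maximizes.
#'
#' @param loadings p x k loading matrix.
#' @param kaiser_normalize normalize rows to unit length first.
#' @return a single number.
#' @export
varimax_criterion <- function(loadings, kaiser_normalize = FALSE) {
  L <- as.matrix(loadings)
  if (kaiser_normalize) {
    h <- sqrt(rowSums(L^2)); h[h == 0] <- 1
    L <- L / h
  }
  sum(apply(L^2, 2, function(c2) mean(c2^2) - mean(c2)^2))
}

#' Principal-component factor model with eigenvalue-one retention
#'
#' The dimension-reduction stage applied to a wide indicator table:
#' standardize columns (population 1/n variance, so results are
#' bit-reproducible), eigendecompose the sample correlation matrix, retain
#' components with eigenvalue strictly greater than 1, scale eigenvectors by
#' the square-root eigenvalue into loadings, varimax-rotate, and compute
#' regression-method component scores `Z %*% solve(R) %*% rotated_loadings`.
#' Sampling-adequacy diagnostics (KMO, Bartlett sphericity) are computed on
#' the way. Loading signs are fixed so each component's largest-magnitude
#' loading is positive.
#'
#' @param data data frame or matrix of indicators; `site_id`/`year` key
#'   columns are carried through to the score panel when present.
#' @param kaiser_normalize passed to [varimax_rotate()].
#' @return an object of class `fsn_factor` with fields `correlation`,
#'   `eigenvalues`, `raw_loadings`, `rotated_loadings`, `rotation`, `scores`
#'   (long tibble), `kmo`, `bartlett`, `variance_explained` (pre-rotation, %
#'   of total), `variance_explained_rotated` (post-rotation sum-of-squares
#'   shares), `n_retained`.
#' @export
fit_pca <- function(data, kaiser_normalize = TRUE) {
  df <- as.data.frame(data)
  keys <- intersect(c("site_id", "year"), names(df))
  Xdf <- df[, setdiff(names(df), keys), drop = FALSE]
  if (!all(vapply(Xdf, is.numeric, logical(1))))
    abort_validation("All indicator columns must be numeric.")
  X <- as.matrix(Xdf)
  if (anyNA(X))
    abort_validation("Indicator table has missing cells; impute upstream before fitting.")
  n <- nrow(X); p <- ncol(X)
  if (p < 2 || n <= p)
    abort_validation("Need at least 2 indicator columns and more rows than columns.")
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(sweep(X, 2, mu)^2))
  if (any(sd_pop == 0))
    abort_validation(sprintf("Constant indicator column(s): %s.",
                             paste(colnames(X)[sd_pop == 0], collapse = ", ")))
  Z <- sweep(sweep(X, 2, mu), 2, sd_pop, `/`)
  R <- crossprod(Z) / n
  R <- sym_mat(R); diag(R) <- 1
  eig <- eigen(R, symmetric = TRUE)
  ev <- eig$values
  keep <- which(ev > 1)             # strict: ties at exactly 1 excluded
  k <- length(keep)
  raw <- if (k > 0) eig$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev[keep]), k)
         else matrix(0, p, 0)
  rownames(raw) <- colnames(X)
  raw <- fix_signs(raw)
  if (k > 0) {
    vr <- varimax_rotate(raw, kaiser_normalize = kaiser_normalize)
    rot <- vr$rotation
    # fold the sign convention into the rotation so rotated = raw %*% rotation
    sgn <- sign_flips(raw %*% rot)
    rot <- rot %*% diag(sgn, k)
    rotated <- raw %*% rot
    colnames(rotated) <- paste0("component_", seq_len(k))
    scores_mat <- Z %*% solve(R, rotated)
    colnames(scores_mat) <- colnames(rotated)
  } else {
    rot <- matrix(0, 0, 0); rotated <- matrix(0, p, 0)
    scores_mat <- matrix(0, n, 0)
    vr <- list(converged = TRUE, criterion = 0)
  }
  scores <- dplyr::bind_cols(
    if (length(keys)) tibble::as_tibble(df[, keys, drop = FALSE]) else NULL,
    tibble::as_tibble(scores_mat))
  structure(list(
    correlation = R, eigenvalues = ev,
    raw_loadings = raw, rotated_loadings = rotated, rotation = rot,
    scores = scores, n_retained = k,
    kmo = kmo(R), bartlett = bartlett_sphericity(R, n),
    variance_explained = 100 * ev[keep] / p,
    variance_explained_rotated = if (k > 0) 100 * colSums(rotated^2) / p else numeric(0),
    varimax_converged = vr$converged, varimax_criterion = vr$criterion,
    center = mu, scale = sd_pop, columns = colnames(X), keys = keys,
    n_rows = n
  ), class = "fsn_factor")
}

fix_signs <- function(L) {
  if (ncol(L) == 0) return(L)
  sweep(L, 2, sign_flips(L), `*`)
}

sign_flips <- function(L) {
  vapply(seq_len(ncol(L)), function(j) {
    s <- sign(L[which.max(abs(L[, j])), j])
    if (s == 0) 1 else s
  }, numeric(1))
}

#' @export
print.fsn_factor <- function(x, ...) {
  cat(sprintf(
    "<fsn_factor> %d indicators -> %d retained components (eigenvalue > 1)\n",
    length(x$columns), x$n_retained))
  cat(sprintf("  KMO %.3f | Bartlett chi^2 %.1f (df %d, p %.3g)\n",
              x$kmo, x$bartlett$statistic, x$bartlett$df, x$bartlett$p_value))
  cat(sprintf("  variance explained (pre-rotation): %.1f%%\n",
              sum(x$variance_explained)))
  invisible(x)
}

#' Component scores for new data
#'
#' Regression-method scores for a table with the same indicator columns as the
#' fitted one, standardized with the training means and (population) standard
#' deviations. Scores of the training table itself have exactly zero mean.
#'
#' @param model an [fit_pca()] object.
#' @param data indicator table with the fitted columns (plus optional
#'   `site_id`/`year` keys carried through).
#' @return long-format tibble of scores keyed by `site_id`, `year` when
#'   available.
#' @export
component_scores <- function(model, data) {
  stopifnot(inherits(model, "fsn_factor"))
  df <- as.data.frame(data)
  keys <- intersect(c("site_id", "year"), names(df))
  if (!all(model$columns %in% names(df)))
    abort_validation("`data` is missing fitted indicator columns.")
  X <- as.matrix(df[, model$columns, drop = FALSE])
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  S <- Z %*% solve(model$correlation, model$rotated_loadings)
  colnames(S) <- colnames(model$rotated_loadings)
  dplyr::bind_cols(
    if (length(keys)) tibble::as_tibble(df[, keys, drop = FALSE]) else NULL,
    tibble::as_tibble(S))
}

#' Pearson correlations between component scores and raw indicators
#'
#' A convenience report for naming components: the plain Pearson correlation
#' of each component score with each raw indicator, sorted descending (by
#' absolute value) within component, so a component's defining metrics float
#' to the top.
#'
#' @param model an [fit_pca()] object.
#' @param data the indicator table the scores refer to.
#' @return tibble with `component`, `indicator`, `correlation`.
#' @export
loading_correlation_report <- function(model, data) {
  scores <- component_scores(model, data)
  sc <- as.matrix(scores[, setdiff(names(scores), model$keys), drop = FALSE])
  X <- as.matrix(as.data.frame(data)[, model$columns, drop = FALSE])
  cc <- cor(sc, X)
  tibble(component = rep(rownames(cc), each = ncol(cc)),
         indicator = rep(colnames(cc), times = nrow(cc)),
         correlation = as.vector(t(cc))) |>
    dplyr::group_by(.data$component) |>
    dplyr::arrange(dplyr::desc(abs(.data$correlation)), .by_group = TRUE) |>
    dplyr::ungroup()
}

#' @method tidy fsn_factor
#' @export
tidy.fsn_factor <- function(x, ...) {
  if (x$n_retained == 0) {
    return(tibble(component = character(0), indicator = character(0),
                  loading = numeric(0)))
  }
  tibble(
    component = rep(colnames(x$rotated_loadings), each = nrow(x$rotated_loadings)),
    indicator = rep(rownames(x$raw_loadings), times = x$n_retained),
    loading = as.vector(x$rotated_loadings))
}

#' @method glance fsn_factor
#' @export
glance.fsn_factor <- function(x, ...) {
  tibble(n_indicators = length(x$columns), n_retained = x$n_retained,
         kmo = x$kmo, bartlett_statistic = x$bartlett$statistic,
         bartlett_df = x$bartlett$df, bartlett_p = x$bartlett$p_value,
         variance_explained_pct = sum(x$variance_explained))
}

#' Scree plot of a factor model
#'
#' @param object an [fit_pca()] object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fsn_factor
#' @export
autoplot.fsn_factor <- function(object, ...) {
  df <- tibble(component = seq_along(object$eigenvalues),
               eigenvalue = object$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$eigenvalue)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "Component", y = "Eigenvalue",
                  title = "Scree plot (eigenvalue > 1 retained)")
}
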