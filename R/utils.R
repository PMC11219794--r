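#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble as_tibble tibble
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom stats rnorm rgamma runif dnorm dgamma dunif pchisq quantile
#'   median cor sd rWishart setNames
#' @importFrom utils modifyList
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
tibble::as_tibble

abort_config <- function(msg) abort(msg, class = "fsndyn_error_config")
abort_validation <- function(msg) abort(msg, class = "fsndyn_error_validation")
abort_numeric <- function(msg) abort(msg, class = "fsndyn_error_numeric")

# run code under a temporary RNG state when seed is given, untouched otherwise
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == as.integer(x) && x >= 1

sym_mat <- function(S) (S + t(S)) / 2

#' Cholesky factorization with escalating diagonal jitter
#'
#' Upper-triangular factor of a symmetric positive (semi-)definite matrix.
#' A diagonal jitter starting at `jitter * mean(diag)` is added and escalated
#' tenfold (at most seven attempts) when plain `chol()` fails, which covers the
#' numerically semi-definite matrices arising in backward sampling.
#'
#' @param S symmetric matrix.
#' @param jitter relative starting jitter (default 1e-8).
#' @return upper-triangular matrix `U` with `t(U) %*% U ~ S`.
#' @keywords internal
safe_chol <- function(S, jitter = 1e-8) {
  d <- nrow(S)
  eps <- 0
  base <- max(mean(diag(S)), 1e-12)
  for (k in 0:7) {
    U <- tryCatch(chol(S + diag(rep(eps, d), d)), error = function(e) NULL)
    if (!is.null(U)) return(U)
    eps <- if (eps == 0) jitter * base else eps * 10
  }
  abort_numeric(sprintf(
    "Cholesky factorization failed even after jitter (condition number ~ %.3g).",
    kappa(S)))
}

# one multivariate normal draw; exact mean when the covariance is numerically zero
rmvnorm1 <- function(mean, cov) {
  d <- length(mean)
  if (d == 1L) {
    v <- as.numeric(cov)
    if (v <= 1e-300) return(as.numeric(mean))
    return(as.numeric(mean) + sqrt(v) * rnorm(1))
  }
  if (max(abs(cov)) < 1e-12 * max(1, max(abs(mean)))) return(as.numeric(mean))
  U <- safe_chol(sym_mat(cov))
  as.numeric(mean + drop(crossprod(U, rnorm(d))))
}

# log N(x; mean, cov) for a vector x
dmvnorm_log <- function(x, mean, cov) {
  d <- length(x)
  U <- safe_chol(sym_mat(cov))
  z <- backsolve(U, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(U))) - 0.5 * sum(z^2)
}

# log multivariate gamma function
lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# log density of the inverse-Wishart(df, scale) at X
ldinvwishart <- function(X, df, scale) {
  p <- nrow(X)
  Ux <- safe_chol(sym_mat(X))
  Us <- safe_chol(sym_mat(scale))
  ldetX <- 2 * sum(log(diag(Ux)))
  ldetS <- 2 * sum(log(diag(Us)))
  Xinv <- chol2inv(Ux)
  df / 2 * ldetS - df * p / 2 * log(2) - lmvgamma(df / 2, p) -
    (df + p + 1) / 2 * ldetX - 0.5 * sum(scale * Xinv)
}

# one inverse-Wishart(df, scale) draw
rinvwishart1 <- function(df, scale) {
  W <- rWishart(1, df, chol2inv(safe_chol(sym_mat(scale))))[, , 1]
  chol2inv(safe_chol(sym_mat(W)))
}

#' Great-circle distance matrix in kilometres
#'
#' Haversine distances between longitude/latitude points (WGS84 sphere).
#'
#' @param coords two-column matrix or data frame of longitude, latitude in
#'   decimal degrees.
#' @return symmetric matrix of distances in km with zero diagonal.
#' @export
great_circle_km <- function(coords) {
  if (is.data.frame(coords) && all(c("lon", "lat") %in% names(coords))) {
    m <- as.matrix(coords[, c("lon", "lat")])
  } else {
    m <- as.matrix(coords[, 1:2, drop = FALSE])
  }
  storage.mode(m) <- "double"
  D <- geosphere::distm(m, fun = geosphere::distHaversine) / 1000
  dimnames(D) <- NULL
  D
}
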