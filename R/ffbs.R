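# Forward-filtering backward-sampling for a linear-Gaussian state-space model
# with identity state evolution:
#   theta_t = theta_{t-1} + w_t,  w_t ~ N(0, Q[[t]]),  theta_0 ~ N(m0, P0)
#   y[[t]]  = F_t theta_t + e_t,  e_t ~ N(0, v[t] I)
# F_t is either a k_t x d matrix or an integer vector of state indices (a
# selection observation, used for the spatial field). Returns one exact joint
# draw of theta_{0:T} as a d x (T+1) matrix (column t+1 holds theta_t).
ffbs_draw <- function(y, Fm, v, Q, m0, P0) {
  T_ <- length(y)
  d <- length(m0)
  m <- matrix(0, d, T_ + 1)
  m[, 1] <- m0
  P <- vector("list", T_ + 1)
  P[[1]] <- sym_mat(as.matrix(P0))
  Rl <- vector("list", T_ + 1)
  for (t in seq_len(T_)) {
    Rt <- sym_mat(P[[t]] + Q[[t]])
    a <- m[, t]
    k <- length(y[[t]])
    if (k > 0) {
      Ft <- Fm[[t]]
      if (is.matrix(Ft)) {
        RF <- Rt %*% t(Ft)                 # d x k
        S <- Ft %*% RF
        pred <- drop(Ft %*% a)
      } else {                             # selection indices
        RF <- Rt[, Ft, drop = FALSE]
        S <- RF[Ft, , drop = FALSE]
        pred <- a[Ft]
      }
      diag(S) <- diag(S) + v[t]
      US <- tryCatch(chol(sym_mat(S)), error = function(e)
        abort_numeric(sprintf("Filter covariance not positive definite at time %d.", t)))
      K <- t(backsolve(US, backsolve(US, t(RF), transpose = TRUE)))
      m[, t + 1] <- a + drop(K %*% (y[[t]] - pred))
      P[[t + 1]] <- sym_mat(Rt - K %*% t(RF))
    } else {
      m[, t + 1] <- a
      P[[t + 1]] <- Rt
    }
    Rl[[t + 1]] <- Rt
  }
  x <- matrix(0, d, T_ + 1)
  x[, T_ + 1] <- rmvnorm1(m[, T_ + 1], P[[T_ + 1]])
  for (t in rev(seq_len(T_))) {
    Pf <- P[[t]]                           # filtered cov of theta_{t-1}
    if (max(abs(Pf)) < 1e-300) {           # degenerate: theta_{t-1} known
      x[, t] <- m[, t]
      next
    }
    Rt <- Rl[[t + 1]]                      # Pf + Q_t
    UR <- safe_chol(Rt)
    RinvP <- backsolve(UR, backsolve(UR, Pf, transpose = TRUE))
    J <- t(RinvP)                          # Pf %*% Rt^{-1}
    h <- m[, t] + drop(J %*% (x[, t + 1] - m[, t]))
    H <- sym_mat(Pf - J %*% Pf)
    x[, t] <- rmvnorm1(h, H)
  }
  x
}
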