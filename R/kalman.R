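# Kalman filter / RTS smoother for the DFA state-space form
#   x_t = x_{t-1} + w_t,  w_t ~ N(0, I_m)      (random-walk trends, Q = I)
#   y_t = Z x_t + a + D d_t + v_t, v_t ~ N(0, R)
# The initial state x_0 is a fixed parameter (zero prior variance), so
# x_1 ~ N(x0, I).  Missing observations are handled by reducing the
# observation vector to the observed rows at each time step.

.dfa_obs_index <- function(y) {
  lapply(seq_len(ncol(y)), function(t) which(!is.na(y[, t])))
}

# y: S x T (NA = missing); Z: S x m; R: S x S; x0: length m;
# a: length S offsets; Dd: S x T covariate effect matrix (or NULL).
# Returns prediction-error-decomposition log-likelihood and, when
# smooth = TRUE, smoothed means/covariances and lag-one covariances.
# Thin wrapper over the compiled filter; .dfa_kalman_r is the pure-R
# reference implementation kept for cross-checking.
.dfa_kalman <- function(y, Z, R, x0, a = NULL, Dd = NULL, smooth = TRUE,
                        obs = NULL) {
  if (is.null(a)) a <- numeric(nrow(y))
  .dfa_kalman_cpp(y, Z, R, x0, a,
                  if (is.null(Dd)) matrix(0, 0, 0) else Dd,
                  !is.null(Dd), smooth)
}

.dfa_kalman_r <- function(y, Z, R, x0, a = NULL, Dd = NULL, smooth = TRUE,
                        obs = NULL) {
  S <- nrow(y); T_ <- ncol(y); m <- ncol(Z)
  if (is.null(a)) a <- numeric(S)
  if (is.null(obs)) obs <- .dfa_obs_index(y)
  Im <- diag(m)
  xf <- matrix(0, m, T_); xp <- matrix(0, m, T_)
  Vf <- array(0, c(m, m, T_)); Vp <- array(0, c(m, m, T_))
  ll <- 0
  xprev <- x0; Vprev <- matrix(0, m, m)
  for (t in seq_len(T_)) {
    xpt <- xprev
    Vpt <- Vprev + Im
    o <- obs[[t]]; k <- length(o)
    if (k > 0L) {
      Zo <- Z[o, , drop = FALSE]
      yo <- y[o, t] - a[o]
      if (!is.null(Dd)) yo <- yo - Dd[o, t]
      PZ <- Vpt %*% t(Zo)                       # m x k
      Fm <- Zo %*% PZ + R[o, o, drop = FALSE]
      Fm <- (Fm + t(Fm)) / 2
      cF <- tryCatch(chol(Fm), error = function(e) NULL)
      if (is.null(cF)) return(list(loglik = -Inf, ok = FALSE))
      innov <- yo - drop(Zo %*% xpt)
      u <- backsolve(cF, innov, transpose = TRUE)
      ll <- ll - 0.5 * (k * log(2 * pi) + 2 * sum(log(diag(cF))) +
                          sum(u * u))
      K <- PZ %*% chol2inv(cF)                  # m x k
      xft <- xpt + drop(K %*% innov)
      Vft <- Vpt - K %*% t(PZ)
      Vft <- (Vft + t(Vft)) / 2
    } else {
      xft <- xpt; Vft <- Vpt
    }
    xp[, t] <- xpt; Vp[, , t] <- Vpt
    xf[, t] <- xft; Vf[, , t] <- Vft
    xprev <- xft; Vprev <- Vft
  }
  out <- list(loglik = ll, ok = TRUE)
  if (!smooth) return(out)

  xs <- xf; Vs <- Vf
  Cs <- array(0, c(m, m, T_))   # slot t (t >= 2): Cov(x_{t-1}, x_t | Y)
  if (T_ > 1L) {
    for (t in seq(T_ - 1L, 1L)) {
      Jt <- Vf[, , t] %*% solve(Vp[, , t + 1L])
      xs[, t] <- xf[, t] + drop(Jt %*% (xs[, t + 1L] - xp[, t + 1L]))
      Vt <- Vf[, , t] +
        Jt %*% (Vs[, , t + 1L] - Vp[, , t + 1L]) %*% t(Jt)
      Vs[, , t] <- (Vt + t(Vt)) / 2
      Cs[, , t + 1L] <- Jt %*% Vs[, , t + 1L]
    }
  }
  out$xs <- xs; out$Vs <- Vs; out$Cs <- Cs
  out$xf <- xf; out$Vf <- Vf
  out
}

#' Exact joint-normal log-likelihood (brute-force oracle)
#'
#' Evaluates the DFA log-likelihood directly from the model-implied joint
#' covariance of all non-missing observations, without a Kalman filter.
#' Under the random-walk trend model with unit innovation covariance and
#' a fixed initial state, `Cov(y_{it}, y_{ju}) = min(t, u) * z_i' z_j +
#' R_{ij} * 1(t = u)` and `E[y_{it}] = z_i' x0 + a_i + (D d_t)_i`.  Only
#' practical for small panels (the stacked vector is inverted densely);
#' intended as an independent check of the filter-based likelihood.
#'
#' @param panel a [length_panel()] or numeric matrix (rivers x years,
#'   `NA` for missing).
#' @param params a fitted [fit_dfa()] object, or a list with elements
#'   `Z`, `R` (full S x S matrix), `x0`, and optionally `a`, `D`, `d`
#'   (covariate series, years x p).
#' @return The log-likelihood (a scalar).
#' @export
loglik_exact <- function(panel, params) {
  y <- if (inherits(panel, "length_panel")) panel$values else as.matrix(panel)
  Z <- params$Z
  R <- if (is.matrix(params$R)) params$R else params$R_matrix
  x0 <- params$x0
  a <- if (is.null(params$a)) numeric(nrow(y)) else params$a
  Dd <- NULL
  if (!is.null(params$D) && !is.null(params$d)) {
    Dd <- params$D %*% t(as.matrix(params$d))
  }
  S <- nrow(y); T_ <- ncol(y)
  idx <- which(!is.na(y), arr.ind = TRUE)
  nobs <- nrow(idx)
  if (nobs > 400L) stop("panel too large for the brute-force oracle")
  i <- idx[, 1L]; t <- idx[, 2L]
  mu <- drop(Z[i, , drop = FALSE] %*% x0) + a[i]
  if (!is.null(Dd)) mu <- mu + Dd[cbind(i, t)]
  G <- Z %*% t(Z)                 # z_i' z_j
  Sig <- outer(t, t, pmin) * G[i, i, drop = FALSE]
  same_t <- outer(t, t, `==`)
  Rsub <- R[i, i, drop = FALSE]
  Sig[same_t] <- Sig[same_t] + Rsub[same_t]
  Sig <- (Sig + t(Sig)) / 2
  cS <- chol(Sig)
  v <- y[idx] - mu
  u <- backsolve(cS, v, transpose = TRUE)
  -0.5 * (nobs * log(2 * pi) + 2 * sum(log(diag(cS))) + sum(u * u))
}
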