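#' Control parameters for the DFA EM algorithm
#'
#' @param tol convergence tolerance: the EM stops when the absolute
#'   change in log-likelihood between iterations falls below `tol`.
#' @param max_iter maximum number of EM iterations.  The fit is returned
#'   (flagged non-converged) rather than erroring when the cap is hit.
#' @param aicc_n sample size used in the AICc correction: `"observed"`
#'   counts non-missing observations (default), `"total"` uses
#'   rivers x years.
#' @param d_se whether to compute covariate-coefficient standard errors
#'   from the observed information (numerical Hessian over the D block
#'   at the MLE).
#' @param verbose print the log-likelihood every 100 iterations.
#' @return A list of class `dfa_control`.
#' @export
dfa_control <- function(tol = 1e-6, max_iter = 50000L,
                        aicc_n = c("observed", "total"),
                        d_se = TRUE, verbose = FALSE) {
  stopifnot(tol > 0, max_iter >= 1L)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 aicc_n = match.arg(aicc_n), d_se = d_se,
                 verbose = verbose),
            class = "dfa_control")
}

.r_structures <- c("diagonal_equal", "equalvarcov", "diagonal_unequal")

# Build the S x S observation-error covariance from its parameters.
.build_R <- function(structure, pars, S) {
  switch(structure,
         diagonal_equal = diag(rep(pars[[1L]], S)),
         diagonal_unequal = diag(as.numeric(pars), S),
         equalvarcov = {
           v <- pars[[1L]]; cc <- pars[[2L]]
           M <- matrix(cc, S, S); diag(M) <- v; M
         })
}

.n_r_params <- function(structure, S) {
  switch(structure, diagonal_equal = 1L, equalvarcov = 2L,
         diagonal_unequal = S)
}

# Lower-trapezoidal start for Z from an SVD of the zero-imputed panel:
# the QR of t(Z0) gives an orthogonal rotation of the SVD loadings onto
# the zero-constrained (upper triangle) parameterization.
.init_Z <- function(y, m) {
  y0 <- y; y0[is.na(y0)] <- 0
  sv <- svd(y0, nu = m, nv = m)
  Z0 <- sv$u %*% diag(sv$d[seq_len(m)] / sqrt(ncol(y)), m)
  Z <- t(qr.R(qr(t(Z0))))                     # S x m, lower trapezoidal
  sgn <- sign(diag(Z[seq_len(m), seq_len(m), drop = FALSE]))
  sgn[sgn == 0] <- 1
  sweep(Z, 2L, sgn, `*`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a dynamic factor analysis by EM
#'
#' Estimates the state-space model
#' \deqn{y_t = Z x_t + a + D d_t + v_t, \quad v_t \sim N(0, R)}
#' \deqn{x_t = x_{t-1} + w_t, \quad w_t \sim N(0, I_m)}
#' by maximum likelihood using an (E)CM algorithm with a Kalman smoother
#' in the E-step.  Missing river-years are handled by reducing the
#' observation vector at each time step.  Identifiability follows the
#' standard DFA convention: the trend innovation covariance is fixed at
#' the identity and entries of `Z` above the diagonal are constrained to
#' zero during estimation (apply [varimax_rotate()] afterwards for
#' interpretation).  The initial state is treated as a fixed parameter
#' with zero prior variance, which makes the likelihood identical to the
#' dense joint-normal form checked by [loglik_exact()].
#'
#' @param panel a [length_panel()] (normally centered on river-specific
#'   means) or a plain numeric matrix, rivers x years, `NA` = missing.
#' @param m number of latent common trends (1 to one less than the
#'   number of rivers).
#' @param R observation-error structure: `"diagonal_equal"` (one shared
#'   variance), `"equalvarcov"` (shared variance and shared covariance),
#'   or `"diagonal_unequal"` (river-specific variances).
#' @param covariates optional year-indexed covariate matrix or data
#'   frame (years in rows matching the panel years, one column per
#'   covariate; a bare vector is taken as a single covariate).  Must be
#'   complete over the panel years and should be centered and scaled.
#'   One regression coefficient per river per covariate is estimated.
#' @param control a [dfa_control()] list.
#' @param offsets `"zero"` (default for centered panels) or
#'   `"estimate"` river-specific intercepts.
#' @return An object of class `dfa` with components `Z` (loadings),
#'   `x` (m x T smoothed trends), `x_var` (their smoothed covariance
#'   array), `a`, `D`, `D_se`, `R_params`, `R_matrix`, `x0`, `logLik`,
#'   `n_params`, `AICc`, `converged`, `n_iter`, `loglik_trace`, plus the
#'   panel metadata needed by the methods.
#' @seealso [varimax_rotate()], [fitted_ci()], [select_model()]
#' @examples
#' truth <- dfa_truth(S = 5, T = 30, m = 1, obs_sd = 5, seed = 1)
#' sim <- simulate_panel(truth)
#' fit <- fit_dfa(center_panel(sim$panel), m = 1,
#'                control = dfa_control(max_iter = 200))
#' fit
#' @export
fit_dfa <- function(panel, m = 1L, R = .r_structures, covariates = NULL,
                    control = dfa_control(), offsets = NULL) {
  r_structure <- match.arg(R, .r_structures)
  if (is.matrix(panel)) {
    yrs <- suppressWarnings(as.integer(colnames(panel)))
    if (anyNA(yrs)) yrs <- seq_len(ncol(panel))
    rn <- rownames(panel) %||% paste0("series", seq_len(nrow(panel)))
    cen <- all(abs(rowMeans(panel, na.rm = TRUE)) < 1e-9)
    panel <- length_panel(panel, yrs, rn, centered = cen)
  }
  stopifnot(inherits(panel, "length_panel"))
  y <- panel$values
  S <- nrow(y); T_ <- ncol(y); m <- as.integer(m)
  if (m >= S) stop("number of trends must be less than the number of rivers")
  if (m < 1L) stop("'m' must be at least 1")
  if (any(rowSums(!is.na(y)) == 0L)) {
    stop("panel contains an all-missing river")
  }
  if (is.null(offsets)) offsets <- if (panel$centered) "zero" else "estimate"
  offsets <- match.arg(offsets, c("zero", "estimate"))
  est_a <- offsets == "estimate"

  # covariates -> T x p matrix d, effects D d_t
  d <- NULL; p <- 0L
  if (!is.null(covariates)) {
    d <- as.matrix(covariates)
    if (nrow(d) != T_) stop("covariate rows must match the panel years")
    if (anyNA(d)) stop("covariates must be complete over the panel years")
    p <- ncol(d)
    if (is.null(colnames(d))) colnames(d) <- paste0("cov", seq_len(p))
    mx <- apply(d, 2L, function(z) abs(mean(z)))
    sx <- apply(d, 2L, sd)
    if (any(mx > 0.1) || any(abs(sx - 1) > 0.5)) {
      warning("covariates do not look centered and scaled")
    }
  }

  obs <- .dfa_obs_index(y)
  nobs <- sum(lengths(obs))

  # --- initial parameter values -------------------------------------
  Z <- .init_Z(y, m)
  vy <- var(y[!is.na(y)])
  R_pars <- switch(r_structure,
                   diagonal_equal = 0.5 * vy,
                   diagonal_unequal = pmax(
                     0.5 * apply(y, 1L, var, na.rm = TRUE), 1e-4 * vy),
                   equalvarcov = c(0.5 * vy, 0.05 * vy))
  x0 <- numeric(m)
  a <- numeric(S)
  D <- if (p > 0L) matrix(0, S, p) else NULL

  # free-entry bookkeeping for the joint (Z, a, D) CM step
  fz <- which(rep(seq_len(m), each = S) <= rep(seq_len(S), m)) # i >= j
  n_beta <- length(fz) + (if (est_a) S else 0L) + S * p
  ia <- if (est_a) length(fz) + seq_len(S) else integer(0)
  iD <- if (p > 0L) length(fz) + (if (est_a) S else 0L) + seq_len(S * p)
        else integer(0)

  pat_key <- vapply(obs, paste, "", collapse = ",")
  groups <- lapply(split(seq_len(T_), pat_key), function(ts) {
    list(o = obs[[ts[1L]]] - 1L, ts = ts - 1L)   # 0-based for C++
  })
  groups <- unname(groups[vapply(groups, function(gr) length(gr$o) > 0L,
                                 logical(1))])
  y0 <- y; y0[is.na(y0)] <- 0
  d_cpp <- if (p > 0L) d else matrix(0, 0, 0)

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  Rm <- .build_R(r_structure, R_pars, S)
  km <- NULL
  iter <- 0L

  while (iter < control$max_iter) {
    iter <- iter + 1L
    Dd <- if (p > 0L) D %*% t(d) else NULL
    km <- .dfa_kalman(y, Z, Rm, x0, a = a, Dd = Dd, obs = obs)
    if (!km$ok) stop("Kalman filter failed: implied covariance not PD")
    ll <- km$loglik
    ll_trace <- c(ll_trace, ll)
    if (control$verbose && iter %% 100L == 0L) {
      cat(sprintf("iter %d logLik %.6f\n", iter, ll))
    }
    if (is.finite(ll_prev) && abs(ll - ll_prev) < control$tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll

    xs <- km$xs; Vs <- km$Vs

    # CM step 1: initial state
    x0 <- xs[, 1L]

    # CM step 2: joint GLS update of (Z, a, D) given R
    beta <- .dfa_mstep_obs_cpp(y0, xs, Vs, Rm, groups, d_cpp, p > 0L,
                               est_a, fz - 1L)$beta
    Zv <- numeric(S * m); Zv[fz] <- beta[seq_along(fz)]
    Z <- matrix(Zv, S, m)
    if (est_a) a <- beta[ia]
    if (p > 0L) D <- matrix(beta[iD], S, p)

    # CM step 3: R given the new (Z, a, D)
    mu <- Z %*% xs + a
    if (p > 0L) mu <- mu + D %*% t(d)
    rs <- .dfa_rstats_cpp(y, mu, Z, Vs)
    if (r_structure == "diagonal_unequal") {
      R_pars <- pmax(drop(rs$row_rss) / drop(rs$row_n), 1e-12)
    } else if (r_structure == "diagonal_equal") {
      R_pars <- max(sum(rs$row_rss) / nobs, 1e-12)
    } else {
      # equalvarcov: numerical CM step on (v, c) via a positive
      # reparameterization of the two eigenvalue families
      nz <- rs$kk > 0
      trE <- rs$trE[nz]; sumE <- rs$sumE[nz]; kk <- rs$kk[nz]
      # barrier keeps both eigenvalue families of R away from 0 and
      # infinity (the profile likelihood is unbounded when the
      # within-year residuals collapse onto the constant vector)
      lo <- log(1e-8 * vy); hi <- log(1e8 * vy)
      objfun <- function(par) {
        if (any(par < lo) || any(par > hi)) {
          return(1e12 + sum(pmax(par - hi, 0) + pmax(lo - par, 0)))
        }
        e1 <- exp(par[1L]); e2 <- exp(par[2L])
        v <- (e1 * (S - 1) + e2) / S
        cc <- (e2 - e1) / S
        lam <- v + (kk - 1) * cc
        q <- -cc / (e1 * lam)
        sum((kk - 1) * log(e1) + log(lam) + trE / e1 + q * sumE)
      }
      e1_0 <- min(max(R_pars[1L] - R_pars[2L], 2e-8 * vy), 0.5e8 * vy)
      e2_0 <- min(max(R_pars[1L] + (S - 1) * R_pars[2L], 2e-8 * vy),
                  0.5e8 * vy)
      op <- optim(log(c(e1_0, e2_0)), objfun, method = "Nelder-Mead",
                  control = list(maxit = 200))
      e1 <- exp(op$par[1L]); e2 <- exp(op$par[2L])
      R_pars <- c((e1 * (S - 1) + e2) / S, (e2 - e1) / S)
    }
    Rm <- .build_R(r_structure, R_pars, S)
  }

  # final E-step at the converged parameters
  Dd <- if (p > 0L) D %*% t(d) else NULL
  km <- .dfa_kalman(y, Z, Rm, x0, a = a, Dd = Dd, obs = obs)
  ll <- km$loglik

  K <- (S * m - m * (m - 1L) / 2L) + .n_r_params(r_structure, S) + m +
    (if (est_a) S else 0L) + S * p
  n_aicc <- if (control$aicc_n == "observed") nobs else S * T_
  AICc <- if (n_aicc - K - 1 > 0) {
    -2 * ll + 2 * K * n_aicc / (n_aicc - K - 1)
  } else {
    warning("AICc undefined: n <= K + 1"); Inf
  }

  D_se <- NULL; D_ci <- NULL
  if (p > 0L && isTRUE(control$d_se)) {
    hess <- .d_block_hessian(y, Z, Rm, x0, a, D, d, obs)
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) > 0)) {
      D_se <- matrix(sqrt(diag(vc)), S, p)
    } else {
      D_se <- matrix(NA_real_, S, p)
    }
    zq <- qnorm(0.975)
    D_ci <- array(c(D - zq * D_se, D + zq * D_se), c(S, p, 2L),
                  dimnames = list(rownames(y), colnames(d),
                                  c("lower", "upper")))
  }

  rownames(Z) <- rownames(y)
  structure(list(
    Z = Z, x = km$xs, x_var = km$Vs, x0 = x0, a = a,
    D = D, D_se = D_se, D_ci = D_ci,
    covariates = d,
    R_params = R_pars, R_matrix = Rm, r_structure = r_structure,
    m = m, logLik = ll, n_params = K, n_obs = nobs, AICc = AICc,
    converged = converged, n_iter = iter, loglik_trace = ll_trace,
    rotated = FALSE, rotation = diag(m),
    panel = panel, offsets = offsets, control = control,
    call = match.call()
  ), class = "dfa")
}

# Observed information for the covariate coefficients: numerical Hessian
# of the negative Kalman log-likelihood over vec(D), other parameters
# held at their maximum-likelihood values.
.d_block_hessian <- function(y, Z, Rm, x0, a, D, d, obs, h = 1e-4) {
  theta0 <- as.vector(D)
  np <- length(theta0)
  f <- function(th) {
    Dm <- matrix(th, nrow(D), ncol(D))
    -.dfa_kalman(y, Z, Rm, x0, a = a, Dd = Dm %*% t(d),
                 smooth = FALSE, obs = obs)$loglik
  }
  H <- matrix(0, np, np)
  hh <- h * (1 + abs(theta0))
  f0 <- f(theta0)
  fp <- numeric(np); fm <- numeric(np)
  for (i in seq_len(np)) {
    ei <- numeric(np); ei[i] <- hh[i]
    fp[i] <- f(theta0 + ei); fm[i] <- f(theta0 - ei)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / hh[i]^2
  }
  if (np > 1L) {
    for (i in seq_len(np - 1L)) {
      for (j in seq(i + 1L, np)) {
        ei <- numeric(np); ei[i] <- hh[i]
        ej <- numeric(np); ej[j] <- hh[j]
        fpp <- f(theta0 + ei + ej)
        H[i, j] <- H[j, i] <-
          (fpp - fp[i] - fp[j] + f0) / (hh[i] * hh[j])
      }
    }
  }
  (H + t(H)) / 2
}
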