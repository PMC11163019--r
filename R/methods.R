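#' @export
print.dfa <- function(x, ...) {
  cat(sprintf(
    "Dynamic factor analysis: %d trends, R = %s%s\n",
    x$m, x$r_structure, if (x$rotated) " (varimax-rotated)" else ""))
  cat(sprintf("  %d rivers x %d years, %d observations\n",
              nrow(x$Z), ncol(x$x), x$n_obs))
  if (!is.null(x$D)) {
    cat(sprintf("  covariates: %s\n",
                paste(colnames(x$covariates), collapse = ", ")))
  }
  cat(sprintf("  logLik %.2f, K = %d, AICc %.2f, %s (%d iterations)\n",
              x$logLik, x$n_params, x$AICc,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @export
summary.dfa <- function(object, ...) {
  print(object)
  cat("\nLoadings (Z):\n")
  print(round(object$Z, 3))
  if (!is.null(object$D)) {
    cat("\nCovariate coefficients (D):\n")
    Dtab <- data.frame(river = rownames(object$Z), round(object$D, 3))
    if (!is.null(object$D_se)) {
      Dtab$se <- round(as.vector(object$D_se), 3)
      Dtab$significant <- apply(
        object$D_ci, 1L, function(ci) any(ci[, 1] > 0 | ci[, 2] < 0))
    }
    print(Dtab, row.names = FALSE)
  }
  invisible(object)
}

#' @export
logLik.dfa <- function(object, ...) {
  structure(object$logLik, df = object$n_params,
            nobs = object$n_obs, class = "logLik")
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2 K n / (n - K - 1)` with `K` the number of
#' estimated parameters and `n` the sample size (for a [fit_dfa()]
#' object, the number of non-missing observations by default).
#'
#' @param object a fitted model, or a log-likelihood value when using
#'   the default method.
#' @param ... for the default method: `k` (parameter count) and `n`
#'   (sample size).
#' @return The AICc value.
#' @export
AICc <- function(object, ...) UseMethod("AICc")

#' @rdname AICc
#' @export
AICc.dfa <- function(object, ...) object$AICc

#' @rdname AICc
#' @param k number of estimated parameters.
#' @param n sample size.
#' @export
AICc.default <- function(object, k, n, ...) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * as.numeric(object) + 2 * k * n / (n - k - 1)
}

#' @export
coef.dfa <- function(object, ...) {
  out <- list(Z = object$Z, x0 = object$x0, R = object$R_params)
  if (object$offsets == "estimate") out$a <- object$a
  if (!is.null(object$D)) out$D <- object$D
  out
}

#' @export
fitted.dfa <- function(object, ...) {
  fit <- object$Z %*% object$x + object$a
  if (!is.null(object$D)) fit <- fit + object$D %*% t(object$covariates)
  dimnames(fit) <- dimnames(object$panel$values)
  fit
}

#' @export
residuals.dfa <- function(object, ...) {
  object$panel$values - fitted(object)
}

#' @export
predict.dfa <- function(object, level = 0.95,
                        interval = c("confidence", "none"), ...) {
  interval <- match.arg(interval)
  if (interval == "none") return(fitted(object))
  fitted_ci(object, level = level)
}

#' Varimax rotation of loadings and trends
#'
#' Rotates the loading matrix to the varimax-optimal orthogonal basis
#' (`Z <- Z H`) and counter-rotates the trends (`x <- H' x`) and their
#' smoothed covariances, so fitted values are unchanged to machine
#' precision.  With one trend the rotation is the identity.
#'
#' @param fit a [fit_dfa()] object.
#' @return The fit with rotated `Z`, `x`, `x_var`, `x0`, the rotation
#'   matrix in `$rotation`, and `rotated = TRUE`.
#' @export
varimax_rotate <- function(fit) {
  stopifnot(inherits(fit, "dfa"))
  if (fit$m == 1L) {
    fit$rotated <- TRUE
    return(fit)
  }
  H <- stats::varimax(fit$Z, normalize = FALSE)$rotmat
  fit$Z <- fit$Z %*% H
  fit$x <- t(H) %*% fit$x
  fit$x0 <- drop(t(H) %*% fit$x0)
  for (t in seq_len(dim(fit$x_var)[3L])) {
    fit$x_var[, , t] <- t(H) %*% fit$x_var[, , t] %*% H
  }
  fit$rotation <- fit$rotation %*% H
  fit$rotated <- TRUE
  fit
}

#' Fitted river trajectories with confidence intervals
#'
#' For each river and year, the fitted value `Z_s x_t + a_s (+ D_s d_t)`
#' with a normal-approximation confidence interval propagated from the
#' smoothed state covariance through the river's loading row (delta
#' method); parameter uncertainty in `Z` is not included, matching the
#' usual DFA presentation of trend bands.
#'
#' @param fit a [fit_dfa()] object.
#' @param level confidence level (default 0.95).
#' @return A data frame with columns `river`, `year`, `fitted`, `se`,
#'   `lower`, `upper`, carrying attributes `centered`, `level` and
#'   `river_means` used by [significant_changes()].
#' @export
fitted_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "dfa"), level > 0, level < 1)
  S <- nrow(fit$Z); T_ <- ncol(fit$x)
  fv <- fitted(fit)
  se <- matrix(0, S, T_)
  for (t in seq_len(T_)) {
    ZV <- fit$Z %*% fit$x_var[, , t]
    se[, t] <- sqrt(pmax(rowSums(ZV * fit$Z), 0))
  }
  zq <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(
    river = rep(rownames(fit$panel$values), T_),
    year = rep(fit$panel$years, each = S),
    fitted = as.vector(fv),
    se = as.vector(se))
  out$lower <- out$fitted - zq * out$se
  out$upper <- out$fitted + zq * out$se
  attr(out, "centered") <- fit$panel$centered
  attr(out, "level") <- level
  attr(out, "river_means") <- fit$panel$river_means
  out
}

#' Simulate new panels from a fitted DFA
#'
#' Parametric simulation: new random-walk trends are drawn from the
#' fitted initial state and unit innovation covariance, observation
#' noise from the fitted `R`, and the fitted missingness pattern is
#' reapplied.
#'
#' @param object a [fit_dfa()] object.
#' @param nsim number of simulated panels.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `length_panel` objects (length `nsim`).
#' @export
simulate.dfa <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(object$Z); T_ <- ncol(object$x); m <- object$m
  cR <- chol(object$R_matrix)
  miss <- is.na(object$panel$values)
  lapply(seq_len(nsim), function(k) {
    w <- matrix(rnorm(m * T_), m, T_)
    x <- apply(w, 1L, cumsum)
    x <- if (m == 1L) matrix(x, 1L, T_) else t(x)
    x <- x + object$x0
    eps <- t(cR) %*% matrix(rnorm(S * T_), S, T_)
    yv <- object$Z %*% x + object$a + eps
    if (!is.null(object$D)) yv <- yv + object$D %*% t(object$covariates)
    yv[miss] <- NA_real_
    length_panel(yv, object$panel$years, object$panel$rivers,
                 centered = FALSE)
  })
}

#' @export
plot.dfa <- function(x, which = c("trends", "loadings"), ...) {
  which <- match.arg(which)
  if (which == "trends") {
    matplot(x$panel$years, t(x$x), type = "l", lty = 1,
            xlab = "Year", ylab = "Common trend",
            main = sprintf("DFA common trends (m = %d)", x$m), ...)
    abline(h = 0, col = "grey70", lty = 2)
  } else {
    barplot(t(x$Z), beside = TRUE, names.arg = rownames(x$Z),
            las = 2, ylab = "Loading",
            main = "DFA loadings by river", ...)
    abline(h = 0)
  }
  invisible(x)
}

#' Serialize a fitted DFA to JSON
#'
#' Writes the estimated quantities (loadings, trends, offsets,
#' covariate coefficients, error parameters, likelihood and convergence
#' metadata) to a JSON file; a convenience for downstream tooling, not
#' a full round-trip of the fit object.
#'
#' @param fit a [fit_dfa()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dfa <- function(fit, path) {
  stopifnot(inherits(fit, "dfa"))
  out <- list(
    m = fit$m, r_structure = fit$r_structure, rotated = fit$rotated,
    rivers = rownames(fit$Z), years = fit$panel$years,
    Z = fit$Z, x = fit$x, x0 = fit$x0, a = fit$a,
    D = fit$D, D_se = fit$D_se, R_params = fit$R_params,
    logLik = fit$logLik, n_params = fit$n_params, AICc = fit$AICc,
    converged = fit$converged, n_iter = fit$n_iter)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
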