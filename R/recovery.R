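#' Trend recovery against a simulation truth
#'
#' Compares estimated common trends with the generating trends of a
#' [dfa_truth()].  A DFA identifies the trend basis only up to sign and
#' rotation, so two matchings are offered: `"best_match"` correlates
#' each true trend with the most-correlated (varimax-rotated) estimated
#' trend, the conventional presentation; `"procrustes"` first aligns
#' the estimated trend set to the truth by the optimal orthogonal
#' rotation and then reads off per-trend correlations, which measures
#' recovery of the trend subspace without penalizing the arbitrary
#' basis.
#'
#' @param fit a [fit_dfa()] object (rotate with [varimax_rotate()]
#'   first for the conventional metric).
#' @param truth the [dfa_truth()] the panel was simulated from.
#' @param method `"best_match"` (default) or `"procrustes"`.
#' @return A list with `per_trend` (absolute correlations, one per true
#'   trend) and `mean`.
#' @export
trend_recovery <- function(fit, truth,
                           method = c("best_match", "procrustes")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "dfa"), inherits(truth, "dfa_truth"))
  X <- t(fit$x)            # T x m estimated
  Xt <- t(truth$trends)    # T x m true
  per <- if (method == "best_match") {
    apply(abs(cor(X, Xt)), 2L, max)
  } else {
    sv <- svd(crossprod(X, Xt))
    H <- sv$u %*% t(sv$v)
    abs(diag(cor(X %*% H, Xt)))
  }
  list(per_trend = as.numeric(per), mean = mean(per))
}
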