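#' Grid model selection over trends and error structures
#'
#' Fits every combination of 1-4 common trends (capped at one less than
#' the number of rivers) and the three observation-error structures,
#' drops non-converged fits, and ranks the rest by AICc.  When two or
#' more converged models fall within `tie_aicc` (default 2) of the best,
#' the tie is broken by first preferring models without an unimportant
#' trend — a trend whose largest absolute varimax-rotated loading,
#' expressed in units of the panel's pooled observation SD, is below
#' `loading_threshold` — and then by fewer parameters.  The winner is
#' returned varimax-rotated.
#'
#' @param panel a centered [length_panel()].
#' @param m_range trend counts to try (default `1:4`).
#' @param structures error structures to try (default all three).
#' @param control a [dfa_control()].
#' @param tie_aicc AICc window treated as a tie.
#' @param loading_threshold unimportant-trend screen (SD units).
#' @param keep_fits keep every fitted model in the result.
#' @return A list of class `dfa_selection`: `table` (one row per model:
#'   `m`, `r_structure`, `logLik`, `n_params`, `AICc`, `dAICc`,
#'   `weight`, `converged`), `fit` (the chosen, rotated model) and
#'   optionally `fits`.
#' @export
select_model <- function(panel, m_range = 1:4,
                         structures = .r_structures,
                         control = dfa_control(), tie_aicc = 2,
                         loading_threshold = 0.2, keep_fits = FALSE) {
  stopifnot(inherits(panel, "length_panel"))
  m_range <- m_range[m_range < nrow(panel$values)]
  grid <- expand.grid(m = m_range, r_structure = structures,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  tab <- data.frame(grid, logLik = NA_real_, n_params = NA_integer_,
                    AICc = NA_real_, converged = NA)
  for (k in seq_len(nrow(grid))) {
    fit <- fit_dfa(panel, m = grid$m[k], R = grid$r_structure[k],
                   control = control)
    fits[[k]] <- fit
    tab$logLik[k] <- fit$logLik
    tab$n_params[k] <- fit$n_params
    tab$AICc[k] <- fit$AICc
    tab$converged[k] <- fit$converged
  }
  conv <- which(tab$converged)
  if (!length(conv)) stop("no DFA model converged")
  best_aicc <- min(tab$AICc[conv])
  tab$dAICc <- tab$AICc - best_aicc
  w <- exp(-0.5 * tab$dAICc[conv])
  tab$weight <- NA_real_
  tab$weight[conv] <- w / sum(w)
  ord <- order(!tab$converged, tab$AICc)
  tab <- tab[ord, ]; fits <- fits[ord]
  rownames(tab) <- NULL

  # tie-break among converged fits within tie_aicc of the best
  cand <- which(tab$converged & tab$dAICc < tie_aicc)
  pooled_sd <- sd(panel$values[!is.na(panel$values)])
  if (length(cand) > 1L) {
    has_weak <- vapply(cand, function(k) {
      Zr <- varimax_rotate(fits[[k]])$Z / pooled_sd
      any(apply(abs(Zr), 2L, max) < loading_threshold)
    }, logical(1))
    if (any(!has_weak) && any(has_weak)) cand <- cand[!has_weak]
    if (length(cand) > 1L) {
      cand <- cand[order(tab$n_params[cand], tab$AICc[cand])]
    }
  }
  chosen <- cand[1L]
  out <- list(table = tab, fit = varimax_rotate(fits[[chosen]]),
              chosen = chosen)
  if (keep_fits) out$fits <- fits
  class(out) <- "dfa_selection"
  out
}

#' @export
print.dfa_selection <- function(x, ...) {
  cat("DFA model selection (AICc):\n")
  tb <- x$table
  tb$logLik <- round(tb$logLik, 2)
  tb$AICc <- round(tb$AICc, 2)
  tb$dAICc <- round(tb$dAICc, 2)
  tb$weight <- round(tb$weight, 3)
  print(tb, row.names = FALSE)
  cat(sprintf("\nchosen: m = %d, R = %s (row %d)\n",
              x$fit$m, x$fit$r_structure, x$chosen))
  invisible(x)
}

#' Significant river-level changes from confidence bands
#'
#' Scans each river's fitted trajectory for maximal runs of years in
#' which the confidence interval lies entirely above zero (the river's
#' long-term mean length) or entirely below it.  A river's change is
#' significant when runs of both signs exist — i.e. the river was
#' credibly below its mean in one period and credibly above it in
#' another (`require_both_signs = FALSE` relaxes this to any two
#' excluding-zero runs).  The change magnitude is the difference
#' between the maximum fitted value inside above-runs and the minimum
#' inside below-runs, with the percentage change referred to the
#' river's raw mean length when available.
#'
#' @param fc a [fitted_ci()] data frame on the centered scale.
#' @param require_both_signs logical (default `TRUE`).
#' @return A list of class `significance_report`: `summary` (data frame
#'   `river`, `significant`, `change_mm`, `change_pct`) and `runs`
#'   (data frame `river`, `start_year`, `end_year`, `direction`).
#' @export
significant_changes <- function(fc, require_both_signs = TRUE) {
  if (!isTRUE(attr(fc, "centered"))) {
    stop("significant_changes requires fitted values on the centered ",
         "scale (zero = river-specific mean)")
  }
  river_means <- attr(fc, "river_means")
  runs_all <- list(); summ <- list()
  for (rv in unique(fc$river)) {
    d <- fc[fc$river == rv, , drop = FALSE]
    d <- d[order(d$year), ]
    state <- ifelse(d$lower > 0, "above",
                    ifelse(d$upper < 0, "below", "none"))
    r <- rle(state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values != "none")
    runs <- data.frame(river = rep(rv, length(keep)),
                       start_year = d$year[starts[keep]],
                       end_year = d$year[ends[keep]],
                       direction = r$values[keep])
    runs_all[[rv]] <- runs
    has_above <- any(runs$direction == "above")
    has_below <- any(runs$direction == "below")
    sig <- if (require_both_signs) has_above && has_below
           else nrow(runs) >= 2L
    change_mm <- NA_real_
    if (has_above && has_below) {
      in_run <- function(dir) {
        sel <- rep(FALSE, nrow(d))
        for (k in which(runs$direction == dir)) {
          sel <- sel | (d$year >= runs$start_year[k] &
                          d$year <= runs$end_year[k])
        }
        sel
      }
      change_mm <- max(d$fitted[in_run("above")]) -
        min(d$fitted[in_run("below")])
    }
    change_pct <- if (!is.na(change_mm) && !is.null(river_means) &&
                        rv %in% names(river_means)) {
      100 * change_mm / river_means[[rv]]
    } else NA_real_
    summ[[rv]] <- data.frame(river = rv, significant = sig,
                             change_mm = change_mm,
                             change_pct = change_pct)
  }
  structure(list(summary = do.call(rbind, c(summ, make.row.names = FALSE)),
                 runs = do.call(rbind, c(runs_all, make.row.names = FALSE))),
            class = "significance_report")
}

#' @export
print.significance_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("significant change in %d of %d rivers\n",
              sum(s$significant), nrow(s)))
  s$change_mm <- round(s$change_mm, 1)
  s$change_pct <- round(s$change_pct, 1)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Hierarchical clustering of DFA loadings with the gap statistic
#'
#' Centers and scales the loading columns, builds a complete-linkage
#' dendrogram on Euclidean distances, and chooses the number of
#' clusters by the gap statistic (uniform reference, `B` bootstrap
#' draws) over `k = 1..k_max` with the standard one-SE rule.
#'
#' @param Z S x m loading matrix (m >= 2), or a rotated [fit_dfa()]
#'   object.
#' @param k_max largest number of clusters examined (default 6, capped
#'   at S - 1).
#' @param B reference draws for the gap statistic.
#' @param seed optional seed for the reference draws.
#' @return A list of class `loading_clusters`: `hclust`, `gap` (the
#'   `clusGap` table), `k` (optimal clusters), `newick` (dendrogram as
#'   a Newick string, when the ape package is available).
#' @export
cluster_loadings <- function(Z, k_max = 6L, B = 100L, seed = NULL) {
  if (inherits(Z, "dfa")) Z <- Z$Z
  Z <- as.matrix(Z)
  if (ncol(Z) < 2L) {
    stop("loading clustering needs at least two trends")
  }
  if (!is.null(seed)) set.seed(seed)
  Zs <- scale(Z)
  hc <- hclust(dist(Zs), method = "complete")
  hcut <- function(x, k) {
    list(cluster = cutree(hclust(dist(x), method = "complete"), k))
  }
  K <- min(k_max, nrow(Z) - 1L)
  gap <- cluster::clusGap(Zs, FUNcluster = hcut, K.max = K, B = B,
                          verbose = FALSE)
  k <- cluster::maxSE(gap$Tab[, "gap"], gap$Tab[, "SE.sim"],
                      method = "Tibs2001SEmax")
  nw <- NULL
  if (requireNamespace("ape", quietly = TRUE)) {
    nw <- ape::write.tree(ape::as.phylo(hc))
  }
  structure(list(hclust = hc, gap = gap$Tab, k = k, newick = nw),
            class = "loading_clusters")
}

#' @export
print.loading_clusters <- function(x, ...) {
  cat(sprintf("complete-linkage clustering of loadings: optimal k = %d\n",
              x$k))
  print(round(x$gap, 3))
  invisible(x)
}

#' Conventional AICc improvement threshold for covariate models
#'
#' A covariate adds one regression coefficient per time series, so a
#' single-covariate DFA is conventionally preferred only when its AICc
#' improves on the base model by more than twice the number of added
#' parameters: `2 * n_series`.
#'
#' @param n_series number of time series (rivers).
#' @return `2 * n_series`.
#' @examples
#' aicc_threshold(19)  # 38
#' aicc_threshold(8)   # 16
#' @export
aicc_threshold <- function(n_series) {
  stopifnot(n_series >= 1)
  2 * n_series
}

#' Evaluate annual covariates against a base DFA
#'
#' Refits the base model once per covariate (one at a time, since the
#' candidate covariates are strongly collinear) and reports the AICc
#' difference to the base (negative = improvement), the log-likelihood,
#' and per-river regression coefficients with 95% confidence intervals
#' and significance flags.  The conventional `2 * S` threshold is
#' attached for reference; covariates with any AICc improvement and a
#' higher log-likelihood are flagged as improving the base model.
#'
#' @param panel the centered [length_panel()] the base model was fit to.
#' @param base the selected base [fit_dfa()] object.
#' @param covariates a data frame with a `year` column and one column
#'   per (centered and scaled) covariate, covering all panel years.
#' @param control a [dfa_control()].
#' @return A list of class `covariate_evaluation`: `table` (per
#'   covariate: `covariate`, `dAICc`, `logLik`, `improves`,
#'   `n_significant`), `coefficients` (per covariate x river: estimate,
#'   `se`, `lower`, `upper`, `significant`), `threshold`.
#' @export
evaluate_covariates <- function(panel, base, covariates,
                                control = dfa_control()) {
  stopifnot(inherits(panel, "length_panel"), inherits(base, "dfa"))
  if (!"year" %in% names(covariates)) stop("covariates need a 'year' column")
  idx <- match(panel$years, covariates$year)
  if (anyNA(idx)) stop("covariates do not cover all panel years")
  vars <- setdiff(names(covariates), "year")
  S <- nrow(panel$values)
  rows <- list(); coefs <- list()
  for (v in vars) {
    d <- covariates[[v]][idx]
    if (anyNA(d)) stop("covariate '", v, "' has missing panel years")
    fit <- fit_dfa(panel, m = base$m, R = base$r_structure,
                   covariates = matrix(d, dimnames = list(NULL, v)),
                   control = control)
    dAICc <- fit$AICc - base$AICc
    sig <- if (!is.null(fit$D_ci)) {
      fit$D_ci[, 1L, "lower"] > 0 | fit$D_ci[, 1L, "upper"] < 0
    } else rep(NA, S)
    rows[[v]] <- data.frame(
      covariate = v, dAICc = dAICc, logLik = fit$logLik,
      converged = fit$converged,
      improves = fit$converged & dAICc < 0 & fit$logLik > base$logLik,
      n_significant = sum(sig, na.rm = TRUE))
    coefs[[v]] <- data.frame(
      covariate = v, river = rownames(panel$values),
      estimate = fit$D[, 1L],
      se = if (!is.null(fit$D_se)) fit$D_se[, 1L] else NA_real_,
      lower = if (!is.null(fit$D_ci)) fit$D_ci[, 1L, "lower"] else NA_real_,
      upper = if (!is.null(fit$D_ci)) fit$D_ci[, 1L, "upper"] else NA_real_,
      significant = sig)
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  tab <- tab[order(tab$dAICc), ]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 coefficients = do.call(rbind, c(coefs,
                                                 make.row.names = FALSE)),
                 threshold = aicc_threshold(S), base_AICc = base$AICc),
            class = "covariate_evaluation")
}

#' @export
print.covariate_evaluation <- function(x, ...) {
  cat(sprintf(
    "covariate evaluation vs base model (conventional threshold %g):\n",
    x$threshold))
  tb <- x$table
  tb$dAICc <- round(tb$dAICc, 2)
  tb$logLik <- round(tb$logLik, 2)
  print(tb, row.names = FALSE)
  invisible(x)
}
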