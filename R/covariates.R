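#' Annual means of monthly climate indices
#'
#' Two windows are supported: the calendar-year mean (`"Jan-Dec"`, e.g.
#' AMO) labelled by that year, and the winter mean (`"Dec-Mar"`, e.g.
#' NAO) over December of the previous year through March, labelled by
#' the January-March year.  Years with any window month missing are
#' dropped with an error, since a partial mean would silently change
#' the index definition.
#'
#' @param monthly data frame with columns `year`, `month`, `value`.
#' @param window `"Jan-Dec"` or `"Dec-Mar"`.
#' @return Data frame `year`, `value`.
#' @export
climate_means <- function(monthly, window = c("Jan-Dec", "Dec-Mar")) {
  window <- match.arg(window)
  stopifnot(all(c("year", "month", "value") %in% names(monthly)))
  if (anyNA(monthly$value)) stop("missing months in the climate series")
  if (window == "Jan-Dec") {
    agg <- tapply(monthly$value, monthly$year, mean)
    cnt <- tapply(monthly$value, monthly$year, length)
    if (any(cnt != 12L)) {
      agg <- agg[cnt == 12L]
    }
    return(data.frame(year = as.integer(names(agg)),
                      value = as.numeric(agg), row.names = NULL))
  }
  keep <- monthly$month %in% c(12L, 1L, 2L, 3L)
  sub <- monthly[keep, , drop = FALSE]
  lab <- sub$year + as.integer(sub$month == 12L)
  agg <- tapply(sub$value, lab, mean)
  cnt <- tapply(sub$value, lab, length)
  agg <- agg[cnt == 4L]
  data.frame(year = as.integer(names(agg)), value = as.numeric(agg),
             row.names = NULL)
}

#' Food-availability index from a PCA of prey biomass
#'
#' Combines annual zooplankton and Capelin biomass (and optionally
#' further series, e.g. the second-year prey field) into a single index:
#' the first principal component of the centered-and-scaled series over
#' their overlapping years.  The sign is fixed so that low biomass maps
#' to negative scores (positive loading sum on the inputs).
#'
#' @param zoop data frame `year`, `value`: zooplankton biomass.
#' @param capelin data frame `year`, `value`: Capelin biomass (already
#'   aligned, e.g. the subsequent year's biomass).
#' @param ... optional further `year`, `value` series.
#' @return A list with `scores` (data frame `year`, `pc1`),
#'   `var_explained` (fraction of total variance on PC1) and
#'   `loadings`.
#' @export
food_availability_index <- function(zoop, capelin, ...) {
  series <- c(list(zoop, capelin), list(...))
  if (length(series) < 2L) stop("need at least two biomass series")
  tabs <- lapply(seq_along(series), function(k) {
    s <- series[[k]]
    vcol <- setdiff(names(s), "year")[1L]
    setNames(data.frame(s$year, s[[vcol]]), c("year", paste0("s", k)))
  })
  merged <- Reduce(function(a, b) merge(a, b, by = "year"), tabs)
  merged <- merged[stats::complete.cases(merged), , drop = FALSE]
  if (nrow(merged) < 3L) stop("fewer than 3 overlapping years")
  X <- as.matrix(merged[, -1L, drop = FALSE])
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1L]
  load1 <- pc$rotation[, 1L]
  if (sum(load1) < 0) { scores <- -scores; load1 <- -load1 }
  list(scores = data.frame(year = merged$year, pc1 = as.numeric(scores)),
       var_explained = pc$sdev[1L]^2 / ncol(X),
       loadings = load1)
}

#' Back-adjust 1 August pre-fishery abundance to 1 January
#'
#' Applies the assumed natural mortality of 0.03 per month over the
#' seven months separating the two reference dates:
#' `PFA_jan = PFA_aug * exp(0.03 * 7)`.
#'
#' @param pfa_aug1 abundance as of 1 August (any non-negative scale).
#' @param mortality monthly instantaneous mortality rate.
#' @param months months between the reference dates.
#' @return The abundance adjusted back to 1 January.
#' @export
adjust_pfa_to_jan <- function(pfa_aug1, mortality = 0.03, months = 7) {
  if (any(pfa_aug1 < 0, na.rm = TRUE)) stop("PFA must be non-negative")
  pfa_aug1 * exp(mortality * months)
}

#' At-sea density index from pre-fishery abundance
#'
#' First sea year: the North American smolt cohort's maturing plus
#' non-maturing PFA (reported 1 August), back-adjusted to 1 January.
#' Second sea year: the North American non-maturing PFA (adjusted to
#' 1 January) plus the southern European (SNEAC) non-maturing PFA
#' (already reported 1 January).  A year with any required component
#' missing is missing in the output.
#'
#' @param pfa data frame with columns `year`, `nac_maturing`,
#'   `nac_nonmaturing`, `sneac_nonmaturing` (thousands of fish).
#' @param sea_year `"first"` or `"second"`.
#' @return Data frame `year`, `value`.
#' @export
density_index <- function(pfa, sea_year = c("first", "second")) {
  sea_year <- match.arg(sea_year)
  if (sea_year == "first") {
    val <- adjust_pfa_to_jan(pfa$nac_maturing + pfa$nac_nonmaturing)
  } else {
    val <- adjust_pfa_to_jan(pfa$nac_nonmaturing) + pfa$sneac_nonmaturing
  }
  data.frame(year = pfa$year, value = val)
}

#' Fishery exploitation rates
#'
#' `er_wg`: West Greenland catch relative to the North American
#' non-maturing 1SW pre-fishery abundance (1 August basis by default,
#' as reported by the assessment; `pfa_basis = "jan1"` applies the
#' mortality back-adjustment first).  `er_nac_small` / `er_nac_large`:
#' combined Newfoundland, Labrador and Saint-Pierre-et-Miquelon catches
#' relative to catches plus size-specific returns — the standard
#' exploitation rate `C / (C + returns)`, a proportion in \[0, 1\]
#' (`denominator = "returns"` gives the raw catch/returns ratio
#' instead).  Zero denominators give missing values with a warning.
#'
#' @param fishery data frame with columns `year`, `catch_nl`,
#'   `catch_lab`, `catch_spm`, `catch_wg`, `returns_nac_small`,
#'   `returns_nac_large` (fish counts).
#' @param nonmaturing_pfa data frame `year`, `value`: NAC non-maturing
#'   1SW PFA in the same units as `catch_wg`.
#' @param denominator `"catch_plus_returns"` (default) or `"returns"`.
#' @param pfa_basis `"aug1"` (default) or `"jan1"`.
#' @return Data frame `year`, `er_nac_small`, `er_nac_large`, `er_wg`.
#' @export
exploitation_rates <- function(fishery, nonmaturing_pfa,
                               denominator = c("catch_plus_returns",
                                               "returns"),
                               pfa_basis = c("aug1", "jan1")) {
  denominator <- match.arg(denominator)
  pfa_basis <- match.arg(pfa_basis)
  C <- fishery$catch_nl + fishery$catch_lab + fishery$catch_spm
  er_size <- function(returns) {
    den <- if (denominator == "returns") returns else C + returns
    out <- ifelse(den > 0, C / den, NA_real_)
    if (any(den <= 0, na.rm = TRUE)) {
      warning("zero denominator in NAC exploitation rate; set to NA")
    }
    out
  }
  pfa <- nonmaturing_pfa$value[match(fishery$year, nonmaturing_pfa$year)]
  if (pfa_basis == "jan1") pfa <- adjust_pfa_to_jan(pfa)
  er_wg <- ifelse(!is.na(pfa) & pfa > 0, fishery$catch_wg / pfa, NA_real_)
  if (any(!is.na(pfa) & pfa <= 0)) {
    warning("zero PFA denominator in West Greenland rate; set to NA")
  }
  data.frame(year = fishery$year,
             er_nac_small = er_size(fishery$returns_nac_small),
             er_nac_large = er_size(fishery$returns_nac_large),
             er_wg = er_wg)
}

#' Center and scale covariate series
#'
#' Per-series z-scores over the non-missing years (sample SD, n - 1
#' convention).  The original means and SDs are stored as attributes so
#' [uncenter_scale()] inverts the transformation; applying
#' `center_scale` to an already scaled table is a no-op.
#'
#' @param table data frame with a `year` column and one column per
#'   covariate.
#' @return The scaled table (attributes `scaled`, `centers`, `scales`).
#' @export
center_scale <- function(table) {
  if (isTRUE(attr(table, "scaled"))) return(table)
  vars <- setdiff(names(table), "year")
  centers <- numeric(0); scales <- numeric(0)
  for (v in vars) {
    x <- table[[v]]
    if (length(unique(na.omit(x))) < 2L) {
      stop("constant covariate series: ", v)
    }
    mu <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
    table[[v]] <- (x - mu) / s
    centers[v] <- mu; scales[v] <- s
  }
  attr(table, "scaled") <- TRUE
  attr(table, "centers") <- centers
  attr(table, "scales") <- scales
  table
}

#' @rdname center_scale
#' @export
uncenter_scale <- function(table) {
  if (!isTRUE(attr(table, "scaled"))) return(table)
  centers <- attr(table, "centers"); scales <- attr(table, "scales")
  for (v in names(centers)) {
    table[[v]] <- table[[v]] * scales[v] + centers[v]
  }
  attr(table, "scaled") <- NULL
  attr(table, "centers") <- NULL
  attr(table, "scales") <- NULL
  table
}
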