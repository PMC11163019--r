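#' Ground truth for a simulated fork-length panel
#'
#' Defines the data-generating DFA from which [simulate_panel()] draws:
#' latent random-walk trends with unit innovation variance (the same
#' identifiability convention used in estimation, so the loadings carry
#' the scale), river loadings, offsets, observation noise and a
#' missingness mask.  The defaults emulate the study system: 19 rivers
#' observed 1971-2021 (51 years) with 20-51 observed years per river,
#' gaps placed as contiguous head/tail blocks (the pattern monitoring
#' programmes produce, and the one that stresses the smoother most),
#' loadings uniform on (-2, 2) mm, offsets near the 543 mm mean 1SW
#' fork length, and 15 mm observation noise.
#'
#' @param S number of rivers.
#' @param T number of years.
#' @param m number of latent trends.
#' @param years calendar years (length `T`).
#' @param loadings S x m matrix; default drawn uniform on (-2, 2).
#' @param offsets length-S vector of river mean lengths (mm); default
#'   drawn around 543 mm.  Use 0 for a pre-centered truth.
#' @param obs_sd observation noise SD in mm (scalar or length S).
#' @param obs_cov common observation-error covariance between rivers
#'   (default 0, i.e. diagonal R).
#' @param missing `"blocks"` (contiguous head/tail gaps, default),
#'   `"random"` (scattered holes), or `"none"`.
#' @param obs_years_range for `"blocks"`/`"random"`: range the number of
#'   observed years per river is drawn from (default 20 to `T`).
#' @param missing_frac for `"random"`: fraction of cells removed.
#' @param seed integer seed; the truth is a pure function of its
#'   arguments and this seed.
#' @return A list of class `dfa_truth` with the trends, loadings, mask
#'   and all generator settings.
#' @export
dfa_truth <- function(S = 19L, T = 51L, m = 3L, years = NULL,
                      loadings = NULL, offsets = NULL,
                      obs_sd = 15, obs_cov = 0,
                      missing = c("blocks", "random", "none"),
                      obs_years_range = c(20L, T), missing_frac = 0.3,
                      seed = 1L) {
  missing <- match.arg(missing)
  if (is.null(years)) years <- seq(1971L, length.out = T)
  stopifnot(length(years) == T, m < S)
  set.seed(seed)
  w <- matrix(rnorm(m * T), m, T)
  trends <- t(apply(w, 1L, cumsum))
  if (m == 1L) trends <- matrix(cumsum(w[1L, ]), 1L, T)
  if (is.null(loadings)) loadings <- matrix(runif(S * m, -2, 2), S, m)
  loadings <- as.matrix(loadings)
  if (ncol(loadings) != m) stop("loadings must have m columns")
  if (is.null(offsets)) offsets <- rnorm(S, 543, 15)
  offsets <- rep_len(offsets, S)
  obs_sd <- rep_len(obs_sd, S)

  mask <- matrix(FALSE, S, T)       # TRUE = missing
  if (missing == "blocks") {
    n_obs <- sample(seq(obs_years_range[1L], obs_years_range[2L]), S,
                    replace = TRUE)
    for (i in seq_len(S)) {
      gap <- T - n_obs[i]
      head_gap <- if (gap > 0L) sample(0:gap, 1L) else 0L
      keep <- seq(head_gap + 1L, head_gap + n_obs[i])
      mask[i, -keep] <- TRUE
    }
  } else if (missing == "random") {
    mask[sample(S * T, round(missing_frac * S * T))] <- TRUE
    # never leave a river fully unobserved
    for (i in which(rowSums(!mask) == 0L)) mask[i, sample(T, 1L)] <- FALSE
  }
  frac <- mean(mask)
  if (frac > 0.8) stop("missing fraction exceeds 0.8")

  structure(list(S = S, T = T, m = m, years = as.integer(years),
                 trends = trends, loadings = loadings, offsets = offsets,
                 obs_sd = obs_sd, obs_cov = obs_cov,
                 missing_mask = mask, seed = seed),
            class = "dfa_truth")
}

#' Simulate a fork-length panel from a known DFA truth
#'
#' Draws `y = Z x + a + v` with `v ~ N(0, R)` where `R` has the truth's
#' observation SDs on the diagonal and `obs_cov` off the diagonal, then
#' blanks the cells of the missingness mask.  The same truth always
#' yields the same panel (noise is seeded from `truth$seed`).
#'
#' @param truth a [dfa_truth()].
#' @return A list with elements `panel` (a [length_panel()], raw mm
#'   scale) and `truth`.
#' @export
simulate_panel <- function(truth) {
  stopifnot(inherits(truth, "dfa_truth"))
  set.seed(truth$seed + 500000L)
  S <- truth$S; T_ <- truth$T
  R <- matrix(truth$obs_cov, S, S)
  diag(R) <- truth$obs_sd^2
  eps <- if (all(truth$obs_sd == 0) && truth$obs_cov == 0) {
    matrix(0, S, T_)
  } else {
    t(chol(R)) %*% matrix(rnorm(S * T_), S, T_)
  }
  yv <- truth$loadings %*% truth$trends + truth$offsets + eps
  yv[truth$missing_mask] <- NA_real_
  rivers <- data.frame(river = sprintf("river%02d", seq_len(S)),
                       latitude = seq(45, 55, length.out = S))
  panel <- length_panel(yv, truth$years, rivers, centered = FALSE)
  list(panel = panel, truth = truth)
}

#' Specification for a synthetic monthly SST / sea-ice grid
#'
#' @param lat_range,lon_range bounds in degrees; cells are 1 x 1 degree
#'   with centers at the half degrees.
#' @param years calendar years to simulate (all 12 months each).
#' @param mean_fun smooth climatology `function(lat, month)` returning
#'   SST in degC; the default is a latitudinal gradient with a seasonal
#'   cycle peaking in September.
#' @param trend_per_decade linear interannual warming (degC / decade).
#' @param noise_sd cell-month noise SD (degC).
#' @param ice_fun mapping from SST to ice concentration in \[0, 1\];
#'   default is a clamped linear ramp reaching 1 below -1 degC and 0
#'   above 1 degC.
#' @param seed integer seed.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(lat_range = c(40, 72), lon_range = c(-70, 0),
                      years = 1971:2021,
                      mean_fun = function(lat, month) {
                        26 - 0.4 * lat + 4 * cos(2 * pi * (month - 9) / 12)
                      },
                      trend_per_decade = 0.3, noise_sd = 0.5,
                      ice_fun = function(sst) pmin(1, pmax(0, (1 - sst) / 2)),
                      seed = 1L) {
  stopifnot(lat_range[1L] < lat_range[2L], lon_range[1L] < lon_range[2L])
  structure(list(lat_range = lat_range, lon_range = lon_range,
                 years = as.integer(years), mean_fun = mean_fun,
                 trend_per_decade = trend_per_decade, noise_sd = noise_sd,
                 ice_fun = ice_fun, seed = seed),
            class = "grid_spec")
}

#' Simulate a monthly gridded SST and sea-ice field
#'
#' One SST and one ice layer per month on a regular 1-degree grid:
#' climatology + linear interannual trend + white noise, with ice
#' concentration derived from SST through the spec's `ice_fun`.
#'
#' @param spec a [grid_spec()].
#' @return A `grid_field`: list with `lat`, `lon` (cell centers),
#'   `months` (data frame `year`, `month`) and arrays `sst`, `ice` of
#'   dimension `n_lat x n_lon x n_months`.
#' @export
simulate_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  set.seed(spec$seed)
  lat <- seq(spec$lat_range[1L] + 0.5, spec$lat_range[2L] - 0.5, by = 1)
  lon <- seq(spec$lon_range[1L] + 0.5, spec$lon_range[2L] - 0.5, by = 1)
  months <- expand.grid(month = 1:12, year = spec$years)[, c("year", "month")]
  nm <- nrow(months)
  y0 <- spec$years[1L]
  sst <- array(NA_real_, c(length(lat), length(lon), nm))
  # climatology, robust to non-vectorized mean functions
  clim <- vapply(1:12, function(mo) {
    rep_len(spec$mean_fun(lat, mo), length(lat))
  }, numeric(length(lat)))                   # n_lat x 12
  for (k in seq_len(nm)) {
    dec <- (months$year[k] - y0 + (months$month[k] - 0.5) / 12) / 10
    base <- clim[, months$month[k]] + spec$trend_per_decade * dec
    noise <- if (spec$noise_sd > 0) {
      matrix(rnorm(length(lat) * length(lon), 0, spec$noise_sd),
             length(lat), length(lon))
    } else 0
    sst[, , k] <- base + noise
  }
  ice <- array(spec$ice_fun(sst), dim(sst))
  structure(list(lat = lat, lon = lon, months = months,
                 sst = sst, ice = ice),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf(
    "grid_field: %d x %d cells (1 deg), %d months (%d-%d), SST %.1f..%.1f degC\n",
    length(x$lat), length(x$lon), nrow(x$months),
    min(x$months$year), max(x$months$year),
    min(x$sst, na.rm = TRUE), max(x$sst, na.rm = TRUE)))
  invisible(x)
}

#' Write / read a grid as long-format CSV
#'
#' Columns `year,month,lat,lon,sst,ice`; the on-disk interchange format
#' for gridded fields.
#'
#' @param grid a `grid_field`.
#' @param path CSV path.
#' @return `write_grid` returns `path` invisibly; `read_grid` a
#'   `grid_field`.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "grid_field"))
  nm <- nrow(grid$months)
  df <- data.frame(
    year = rep(grid$months$year, each = length(grid$lat) * length(grid$lon)),
    month = rep(grid$months$month, each = length(grid$lat) * length(grid$lon)),
    lat = rep(grid$lat, times = length(grid$lon) * nm),
    lon = rep(rep(grid$lon, each = length(grid$lat)), times = nm),
    sst = as.vector(grid$sst),
    ice = as.vector(grid$ice))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  df <- read.csv(path)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  months <- unique(df[, c("year", "month")])
  months <- months[order(months$year, months$month), ]
  rownames(months) <- NULL
  key <- paste(df$year, df$month)
  mkey <- paste(months$year, months$month)
  k <- match(key, mkey)
  i <- match(df$lat, lat); j <- match(df$lon, lon)
  sst <- array(NA_real_, c(length(lat), length(lon), nrow(months)))
  ice <- sst
  sst[cbind(i, j, k)] <- df$sst
  ice[cbind(i, j, k)] <- df$ice
  structure(list(lat = lat, lon = lon, months = months,
                 sst = sst, ice = ice),
            class = "grid_field")
}

#' Simulate annual covariate series
#'
#' Stationary AR(1) series (marginal SD 1) for each named covariate,
#' mimicking the autocorrelated climate, habitat, food, density and
#' exploitation series the covariate DFA consumes.
#'
#' @param years calendar years.
#' @param ar_coef lag-one autocorrelation, `|ar_coef| < 1`.
#' @param names covariate names.
#' @param seed integer seed.
#' @return A data frame (class `covariate_table`) with a `year` column
#'   and one column per covariate, unscaled.
#' @export
simulate_covariates <- function(years = 1971:2021, ar_coef = 0.6,
                                names = c("amo", "nao", "nlci",
                                          "th_summer1", "th_winter1",
                                          "food_pc1", "pfa_density",
                                          "er_nac_small"),
                                seed = 1L) {
  stopifnot(abs(ar_coef) < 1)
  set.seed(seed)
  T_ <- length(years)
  out <- data.frame(year = as.integer(years))
  innov_sd <- sqrt(1 - ar_coef^2)
  for (nm in names) {
    x <- numeric(T_)
    x[1L] <- rnorm(1L)
    if (T_ > 1L) {
      e <- rnorm(T_ - 1L, 0, innov_sd)
      for (t in 2:T_) x[t] <- ar_coef * x[t - 1L] + e[t - 1L]
    }
    out[[nm]] <- x
  }
  class(out) <- c("covariate_table", "data.frame")
  out
}
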