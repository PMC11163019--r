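#' Configuration of the thermal growth-potential habitat metric
#'
#' Encodes the age-specific piecewise-linear growth-potential curve,
#' the sea-ice cutoff, the spatial polygon, and the season window used
#' to turn monthly SST / ice fields into an annual habitat-area index.
#'
#' The curve is 0 below `t_zero_low` (1 degC), rises linearly to 1 at
#' `t_opt_low` (6 degC), stays 1 through `t_opt_high` (14 degC in the
#' first year at sea, 12 degC in the second), falls linearly to 0 at
#' `t_zero_high` (18 degC first year, 15 degC second year), and is 0
#' above; any cell with ice concentration >= `ice_cutoff` (0.5) scores 0
#' regardless of SST.
#'
#' The first-year polygon covers 45-61 N, 64-40 W.  The second-year
#' polygon adds the northern extension: to 70 N on the Labrador Sea side
#' and 66 N east of `labrador_east` (default -45, the Cape Farewell
#' meridian, configurable because the verbal boundary between the
#' Labrador and Irminger Seas is not exact), east to 6 W.
#'
#' Season windows: first-year summer Aug-Nov, winter Dec-Apr (both
#' years), second-year summer May-Nov.  A winter window spanning
#' Dec-Apr is labelled by the January year.
#'
#' @param sea_year `"first"` or `"second"` year at sea.
#' @param season `"summer"` or `"winter"`.
#' @param ice_cutoff ice concentration at or above which the weight is 0.
#' @param labrador_east eastern meridian of the 70 N Labrador Sea
#'   extension (degrees, second year only).
#' @param t_zero_low,t_opt_low,t_opt_high,t_zero_high curve knots in
#'   degC; defaults depend on `sea_year`.
#' @return A list of class `habitat_config`.
#' @export
habitat_config <- function(sea_year = c("first", "second"),
                           season = c("summer", "winter"),
                           ice_cutoff = 0.5, labrador_east = -45,
                           t_zero_low = 1, t_opt_low = 6,
                           t_opt_high = NULL, t_zero_high = NULL) {
  sea_year <- match.arg(sea_year)
  season <- match.arg(season)
  if (is.null(t_opt_high)) t_opt_high <- if (sea_year == "first") 14 else 12
  if (is.null(t_zero_high)) t_zero_high <- if (sea_year == "first") 18 else 15
  stopifnot(t_zero_low < t_opt_low, t_opt_low <= t_opt_high,
            t_opt_high < t_zero_high, ice_cutoff > 0, ice_cutoff <= 1)
  months <- if (season == "winter") c(12L, 1L, 2L, 3L, 4L)
            else if (sea_year == "first") 8:11 else 5:11
  polygon <- if (sea_year == "first") {
    list(c(lat_min = 45, lat_max = 61, lon_min = -64, lon_max = -40))
  } else {
    list(c(lat_min = 45, lat_max = 70, lon_min = -64, lon_max = labrador_east),
         c(lat_min = 45, lat_max = 66, lon_min = labrador_east, lon_max = -6))
  }
  structure(list(sea_year = sea_year, season = season, months = months,
                 ice_cutoff = ice_cutoff, polygon = polygon,
                 t_zero_low = t_zero_low, t_opt_low = t_opt_low,
                 t_opt_high = t_opt_high, t_zero_high = t_zero_high),
            class = "habitat_config")
}

#' Growth-potential weight of a grid cell
#'
#' Evaluates the piecewise-linear growth-potential curve (see
#' [habitat_config()]) at given SST and ice concentration.  Vectorized;
#' missing SST or ice gives a missing weight (excluded from sums).
#' Boundary conventions: weight 0 at exactly `t_zero_low` (start of the
#' rising ramp), 0 at and above `t_zero_high`, and 0 when
#' `ice >= ice_cutoff` (inclusive).
#'
#' @param sst sea surface temperature, degC.
#' @param ice sea-ice concentration in \[0, 1\].
#' @param config a [habitat_config()].
#' @return Weights in \[0, 1\] (or `NA`).
#' @examples
#' cfg <- habitat_config("first", "summer")
#' growth_potential_weight(2, 0, cfg)    # 0.2: one fifth up the ramp
#' @export
growth_potential_weight <- function(sst, ice, config) {
  stopifnot(inherits(config, "habitat_config"))
  n <- max(length(sst), length(ice))
  sst <- rep_len(sst, n); ice <- rep_len(ice, n)
  w <- rep(NA_real_, n)
  known <- !is.na(sst) & !is.na(ice)
  s <- sst[known]
  wk <- numeric(length(s))
  up <- s > config$t_zero_low & s < config$t_opt_low
  wk[up] <- (s[up] - config$t_zero_low) /
    (config$t_opt_low - config$t_zero_low)
  wk[s >= config$t_opt_low & s <= config$t_opt_high] <- 1
  dn <- s > config$t_opt_high & s < config$t_zero_high
  wk[dn] <- (config$t_zero_high - s[dn]) /
    (config$t_zero_high - config$t_opt_high)
  wk[ice[known] >= config$ice_cutoff] <- 0
  w[known] <- wk
  w
}

#' Spherical area of a 1-degree (or any) latitude-longitude cell
#'
#' Band area on a spherical Earth:
#' `R^2 * d_lambda * (sin(lat_N) - sin(lat_S))`, with `R = 6371` km.
#'
#' @param lat_south,lat_north cell edges in degrees, `-90 <= S < N <= 90`.
#' @param lon_width cell width in degrees of longitude.
#' @return Area in km^2 (vectorized).
#' @export
cell_area <- function(lat_south, lat_north, lon_width = 1) {
  if (any(lat_south >= lat_north)) stop("lat_south must be below lat_north")
  if (any(lat_south < -90 | lat_north > 90)) stop("latitudes out of range")
  Rearth <- 6371
  Rearth^2 * (lon_width * pi / 180) *
    (sin(lat_north * pi / 180) - sin(lat_south * pi / 180))
}

.cells_in_polygon <- function(lat, lon, polygon) {
  inside <- matrix(FALSE, length(lat), length(lon))
  for (rect in polygon) {
    in_lat <- lat > rect["lat_min"] & lat < rect["lat_max"]
    in_lon <- lon > rect["lon_min"] & lon < rect["lon_max"]
    inside <- inside | outer(in_lat, in_lon, `&`)
  }
  inside
}

#' Annual thermal-habitat area index
#'
#' Multiplies each polygon cell's monthly growth-potential weight by its
#' spherical cell area, sums over the polygon, and aggregates the
#' monthly totals of the season window into one value per year (mean
#' over months by default, so the index is an area in km^2 comparable
#' across windows of different length; `month_agg = "sum"` accumulates
#' instead).  Winter windows (Dec-Apr) are labelled by the January
#' year; years missing any window month are dropped.  Cells with SST
#' missing in every month are treated as land and excluded.
#'
#' @param grid a `grid_field` (see [simulate_grid()], [read_grid()]).
#' @param config a [habitat_config()].
#' @param month_agg `"mean"` (default) or `"sum"` across window months.
#' @return A data frame `year`, `index_km2`.
#' @export
thermal_habitat_index <- function(grid, config,
                                  month_agg = c("mean", "sum")) {
  stopifnot(inherits(grid, "grid_field"), inherits(config, "habitat_config"))
  month_agg <- match.arg(month_agg)
  inside <- .cells_in_polygon(grid$lat, grid$lon, config$polygon)
  if (!any(inside)) stop("polygon lies entirely outside the grid")
  land <- apply(is.na(grid$sst), c(1L, 2L), all)
  use <- inside & !land
  area <- matrix(rep(cell_area(grid$lat - 0.5, grid$lat + 0.5, 1),
                     length(grid$lon)), length(grid$lat))
  idx <- which(use)
  area_v <- area[idx]

  nm <- nrow(grid$months)
  monthly <- numeric(nm)
  for (k in seq_len(nm)) {
    sst_k <- grid$sst[, , k][idx]
    ice_k <- grid$ice[, , k][idx]
    w <- growth_potential_weight(sst_k, ice_k, config)
    monthly[k] <- sum(w * area_v, na.rm = TRUE)
  }
  # label: winter months Dec belong to the following (January) year
  lab <- grid$months$year + as.integer(config$season == "winter" &
                                         grid$months$month == 12L)
  keep <- grid$months$month %in% config$months
  agg <- tapply(monthly[keep], lab[keep], if (month_agg == "mean") mean
                else sum)
  cnt <- tapply(monthly[keep], lab[keep], length)
  full <- cnt == length(config$months)
  data.frame(year = as.integer(names(agg))[full],
             index_km2 = as.numeric(agg)[full], row.names = NULL)
}

#' Sea-year alignment between habitat/covariate windows and return year
#'
#' For a salmon returning in year `t`, each at-sea window falls a fixed
#' number of years earlier: a 1SW fish's first marine summer is year
#' `t - 1` and its first winter is the Dec(`t-1`)-Apr(`t`) window
#' labelled `t`; a 2SW fish spends an extra year at sea, shifting the
#' first-year windows one year earlier.
#'
#' @param age_class `"1SW"` or `"2SW"`.
#' @return Named integer vector of lags (window year = return year - lag).
#' @export
sea_year_alignment <- function(age_class = c("1SW", "2SW")) {
  age_class <- match.arg(age_class)
  if (age_class == "1SW") {
    c(first_summer = 1L, first_winter = 0L)
  } else {
    c(first_summer = 2L, first_winter = 1L,
      second_summer = 1L, second_winter = 0L)
  }
}

#' Align a window-year series to return year
#'
#' @param series data frame `year`, `value` (or `year`, `index_km2`).
#' @param lag integer lag from [sea_year_alignment()].
#' @return The series re-indexed so that `year` is the return year.
#' @export
align_to_return_year <- function(series, lag) {
  vcol <- setdiff(names(series), "year")[1L]
  data.frame(year = series$year + as.integer(lag),
             value = series[[vcol]])
}
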