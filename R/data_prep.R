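#' Read individual fish records from CSV
#'
#' Expects the header
#' `river,latitude,year,doy,fork_length_mm,sea_age,origin,gear`.
#' `sea_age` takes values `1SW`, `2SW`, `other` or `unknown`; `origin`
#' takes `wild`, `hatchery`, `captive`, `aquaculture` or `unknown`.
#'
#' @param path CSV file path.
#' @return A data frame of fish records.
#' @export
read_fish_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("river", "year", "fork_length_mm", "sea_age", "origin")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing columns in fish record file: ", paste(miss, collapse = ", "))
  }
  if (any(df$fork_length_mm <= 0, na.rm = TRUE)) {
    stop("fork lengths must be positive")
  }
  df
}

#' Inclusion filters for returning-salmon records
#'
#' Applies, in order: exclusion of known non-wild fish (hatchery, captive
#' breeding / smolt-to-adult supplementation, aquaculture; unknown-origin
#' fish are retained), selection of the requested sea-age class, the
#' year-range crop, removal of river-years with fewer than `min_n` fish of
#' that age class, and removal of rivers left with fewer than `min_years`
#' qualifying years.  The order matters between the last two steps: the
#' per-river year count is taken on the already-cleaned data.
#'
#' @param records data frame of fish records (see [read_fish_records()]).
#' @param age_class `"1SW"` or `"2SW"`.
#' @param year_min,year_max inclusive calendar-year range.
#' @param min_n minimum fish per river-year (default 10).
#' @param min_years minimum qualifying years per river (default 20).
#' @return The filtered records.  An empty result triggers a warning, not
#'   an error.
#' @export
filter_length_records <- function(records, age_class = c("1SW", "2SW"),
                                  year_min, year_max,
                                  min_n = 10L, min_years = 20L) {
  age_class <- match.arg(age_class)
  nonwild <- c("hatchery", "captive", "SAS", "captive/SAS", "aquaculture")
  rec <- records[!(records$origin %in% nonwild), , drop = FALSE]
  rec <- rec[rec$sea_age == age_class, , drop = FALSE]
  rec <- rec[rec$year >= year_min & rec$year <= year_max, , drop = FALSE]
  if (nrow(rec)) {
    key <- interaction(rec$river, rec$year, drop = TRUE)
    cnt <- table(key)
    rec <- rec[cnt[key] >= min_n, , drop = FALSE]
  }
  if (nrow(rec)) {
    yrs_per_river <- tapply(rec$year, rec$river, function(y) length(unique(y)))
    keep <- names(yrs_per_river)[yrs_per_river >= min_years]
    rec <- rec[rec$river %in% keep, , drop = FALSE]
  }
  if (!nrow(rec)) warning("no records remain after filtering")
  rec
}

#' Assign small unaged fish to the 1SW class
#'
#' In river-years where scale ages are unavailable, unaged fish below a
#' size threshold are relabelled 1SW (the size classes barely overlap at
#' the threshold).  Only `sea_age == "unknown"` records in the configured
#' river and years are touched; the comparison is strict (`< threshold`).
#'
#' @param records data frame of fish records.
#' @param river river identifier the rule applies to.
#' @param years integer years the rule applies to.
#' @param threshold_mm size threshold in mm (default 630).
#' @return Records with the relabelled `sea_age`.
#' @export
assign_small_unaged <- function(records, river, years, threshold_mm = 630) {
  idx <- records$river == river &
    records$year %in% years &
    records$sea_age == "unknown" &
    records$fork_length_mm < threshold_mm
  records$sea_age[idx] <- "1SW"
  records
}

#' Build the river-by-year mean fork-length panel
#'
#' Cell values are arithmetic means of fork length over the fish sampled
#' in that river-year; cells with no fish are missing.  With
#' `center = TRUE` each river's mean over its observed years is
#' subtracted (and stored for inversion), the form the DFA consumes.
#'
#' @param records filtered fish records ([filter_length_records()]).
#' @param year_min,year_max panel year range; defaults to the data range.
#' @param center logical; center on river-specific means.
#' @return A [length_panel()].
#' @export
build_length_panel <- function(records, year_min = NULL, year_max = NULL,
                               center = FALSE) {
  if (!nrow(records)) stop("no records to build a panel from")
  if (is.null(year_min)) year_min <- min(records$year)
  if (is.null(year_max)) year_max <- max(records$year)
  years <- seq.int(year_min, year_max)
  rivers <- sort(unique(records$river))
  lat <- if ("latitude" %in% names(records)) {
    vapply(rivers, function(r) records$latitude[match(r, records$river)],
           numeric(1))
  } else rep(NA_real_, length(rivers))
  ord <- order(lat, rivers)
  rivers <- rivers[ord]; lat <- lat[ord]

  vals <- matrix(NA_real_, length(rivers), length(years))
  nmat <- matrix(0L, length(rivers), length(years))
  ri <- match(records$river, rivers)
  yi <- match(records$year, years)
  ok <- !is.na(ri) & !is.na(yi)
  sums <- tapply(records$fork_length_mm[ok],
                 list(factor(ri[ok], seq_along(rivers)),
                      factor(yi[ok], seq_along(years))), sum)
  cnts <- tapply(records$fork_length_mm[ok],
                 list(factor(ri[ok], seq_along(rivers)),
                      factor(yi[ok], seq_along(years))), length)
  obs <- !is.na(cnts)
  vals[obs] <- sums[obs] / cnts[obs]
  nmat[obs] <- cnts[obs]

  panel <- length_panel(vals, years,
                        data.frame(river = rivers, latitude = lat),
                        n = nmat, centered = FALSE)
  if (center) center_panel(panel) else panel
}
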