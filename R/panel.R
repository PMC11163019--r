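#' River-by-year mean fork-length panel
#'
#' A `length_panel` holds the observation set of the dynamic factor
#' analysis: one row per river, one column per calendar year, cell values
#' the annual mean fork length (mm) and an accompanying matrix of fish
#' counts.  Missing river-years are `NA` and are treated as "no
#' observation" everywhere downstream, never as zero.
#'
#' @param values numeric matrix, rivers x years; `NA` for missing cells.
#' @param years integer vector of contiguous calendar years (columns).
#' @param rivers data frame with columns `river` and `latitude`, or a
#'   character vector of river names (latitude then `NA`).
#' @param n optional integer matrix of per-cell fish counts.
#' @param centered logical; `TRUE` when each river's values have had the
#'   river-specific mean subtracted.
#' @param river_means optional named vector of raw river means (mm),
#'   stored when centering so the transformation can be inverted.
#'
#' @return An object of class `length_panel`: a list with elements
#'   `values`, `n`, `years`, `rivers`, `centered`, `river_means`.
#' @seealso [build_length_panel()], [center_panel()], [fit_dfa()]
#' @export
length_panel <- function(values, years, rivers, n = NULL,
                         centered = FALSE, river_means = NULL) {
  values <- as.matrix(values)
  if (is.character(rivers)) {
    rivers <- data.frame(river = rivers, latitude = NA_real_)
  }
  stopifnot(nrow(values) == nrow(rivers), ncol(values) == length(years))
  if (length(years) > 1L && !all(diff(years) == 1L)) {
    stop("'years' must be a contiguous run of calendar years")
  }
  rownames(values) <- rivers$river
  colnames(values) <- years
  if (!is.null(n)) {
    n <- as.matrix(n)
    stopifnot(all(dim(n) == dim(values)))
    dimnames(n) <- dimnames(values)
  }
  if (centered) {
    rm_ <- rowMeans(values, na.rm = TRUE)
    rm_[!is.finite(rm_)] <- 0
    if (any(abs(rm_) > 1e-9)) {
      stop("panel flagged as centered but river means are not zero")
    }
  }
  structure(
    list(values = values, n = n, years = as.integer(years),
         rivers = rivers, centered = isTRUE(centered),
         river_means = river_means),
    class = "length_panel"
  )
}

#' @export
print.length_panel <- function(x, ...) {
  nobs <- sum(!is.na(x$values))
  cat(sprintf(
    "length_panel: %d rivers x %d years (%d-%d), %d observed river-years%s\n",
    nrow(x$values), ncol(x$values), min(x$years), max(x$years), nobs,
    if (x$centered) ", centered" else ""))
  invisible(x)
}

#' @export
summary.length_panel <- function(object, ...) {
  per_river <- rowSums(!is.na(object$values))
  cat(sprintf("rivers: %d, years %d-%d\n", nrow(object$values),
              min(object$years), max(object$years)))
  cat(sprintf("observed years per river: %d-%d (mean %.1f)\n",
              min(per_river), max(per_river), mean(per_river)))
  if (!object$centered) {
    cat(sprintf("mean fork length across cells: %.1f mm\n",
                mean(object$values, na.rm = TRUE)))
  }
  invisible(object)
}

#' Center a panel on river-specific means
#'
#' Subtracts each river's mean over its non-missing years, the scale on
#' which the DFA and the significance rule operate (zero = the river's
#' long-term mean length).  The raw means are stored so [uncenter_panel()]
#' reproduces the original panel exactly.
#'
#' @param panel a [length_panel()].
#' @return A centered `length_panel` with `river_means` filled in.
#' @export
center_panel <- function(panel) {
  stopifnot(inherits(panel, "length_panel"))
  if (panel$centered) return(panel)
  mns <- rowMeans(panel$values, na.rm = TRUE)
  vals <- sweep(panel$values, 1L, mns, `-`)
  length_panel(vals, panel$years, panel$rivers, n = panel$n,
               centered = TRUE, river_means = setNames(mns, rownames(panel$values)))
}

#' Undo river-specific centering
#'
#' @param panel a centered [length_panel()] carrying `river_means`.
#' @return The panel on the raw mm scale.
#' @export
uncenter_panel <- function(panel) {
  stopifnot(inherits(panel, "length_panel"))
  if (!panel$centered) return(panel)
  if (is.null(panel$river_means)) {
    stop("cannot uncenter: river means were not stored")
  }
  vals <- sweep(panel$values, 1L, panel$river_means, `+`)
  length_panel(vals, panel$years, panel$rivers, n = panel$n,
               centered = FALSE, river_means = panel$river_means)
}

#' Write / read a panel as a CSV matrix with a JSON sidecar
#'
#' The CSV has rivers as rows and years as columns with empty strings for
#' missing cells; the sidecar stores latitudes, river means, per-cell fish
#' counts and the centering flag so the panel round-trips exactly.
#'
#' @param panel a [length_panel()].
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_panel` returns `path` invisibly; `read_panel` returns a
#'   `length_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "length_panel"))
  df <- data.frame(river = rownames(panel$values),
                   panel$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  side <- list(
    years = panel$years,
    rivers = panel$rivers,
    centered = panel$centered,
    river_means = as.list(panel$river_means),
    n = panel$n
  )
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  years <- as.integer(colnames(vals))
  side_path <- paste0(path, ".json")
  rivers <- data.frame(river = df$river, latitude = NA_real_)
  centered <- FALSE; rmns <- NULL; nmat <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$rivers)) rivers <- as.data.frame(side$rivers)
    centered <- isTRUE(side$centered)
    if (length(side$river_means)) {
      rmns <- unlist(side$river_means)
    }
    if (!is.null(side$n)) nmat <- as.matrix(side$n)
  }
  length_panel(vals, years, rivers, n = nmat, centered = centered,
               river_means = rmns)
}
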