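#' Construct a census table
#'
#' A `census_table` holds the per-cell, per-year abundance of breeding pairs
#' on a square lattice of grid cells. Cells are identified by an opaque
#' `cell_id` and located by their centroid coordinates in projected
#' kilometres; years are an ordered integer vector; counts are non-negative
#' integers, one per (cell, year) combination.
#'
#' @param cells data.frame with columns `cell_id` (character, unique),
#'   `x_km`, `y_km` (finite numeric centroid coordinates).
#' @param years integer vector of census years (strictly increasing after
#'   sorting; duplicates are an error).
#' @param counts integer matrix, `nrow(cells)` rows by `length(years)`
#'   columns, of non-negative breeding-pair counts.
#' @return An object of class `census_table`: a list with elements `cells`,
#'   `years` and `counts` (dimnames `cell_id` x year).
#' @export
census_table <- function(cells, years, counts) {
  stopifnot(is.data.frame(cells))
  need <- c("cell_id", "x_km", "y_km")
  miss <- setdiff(need, names(cells))
  if (length(miss) > 0L)
    stop("cells is missing column(s): ", paste(miss, collapse = ", "))
  cells$cell_id <- as.character(cells$cell_id)
  if (anyDuplicated(cells$cell_id))
    stop("duplicated cell_id in cells table")
  if (!all(is.finite(cells$x_km)) || !all(is.finite(cells$y_km)))
    stop("cell centroid coordinates must be finite")
  years <- as.integer(years)
  if (anyDuplicated(years)) stop("duplicated census year")
  ord <- order(years)
  years <- years[ord]
  counts <- as.matrix(counts)[, ord, drop = FALSE]
  if (nrow(counts) != nrow(cells) || ncol(counts) != length(years))
    stop("counts must be nrow(cells) x length(years)")
  if (anyNA(counts)) stop("missing abundance value")
  if (any(counts < 0)) stop("negative abundance")
  if (any(counts != round(counts)))
    stop("abundance must be integer (territories are counted, not measured)")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(cells$cell_id, as.character(years))
  structure(list(cells = cells[, need], years = years, counts = counts),
            class = "census_table")
}

#' @export
print.census_table <- function(x, ...) {
  cat("Gridded census:", nrow(x$cells), "cells x", length(x$years),
      "years (", paste(x$years, collapse = ", "), ")\n")
  tot <- colSums(x$counts)
  occ <- colSums(x$counts > 0)
  for (j in seq_along(x$years))
    cat(sprintf("  %d: %d pairs in %d occupied cells\n",
                x$years[j], tot[j], occ[j]))
  invisible(x)
}

#' Read a long-format census CSV
#'
#' The file must have a header row with columns `cell_id`, `x_km`, `y_km`,
#' `year`, `abundance`, one row per (cell, year). Row order is irrelevant:
#' the table is canonicalised so downstream statistics do not depend on it.
#'
#' @param path path to a comma-separated, UTF-8, `.`-decimal CSV file.
#' @return A [census_table()].
#' @export
read_census_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x_km", "y_km", "year", "abundance")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L)
    stop("census CSV is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(d$abundance) | d$abundance < 0 |
                 d$abundance != round(d$abundance))
  if (length(bad) > 0L)
    stop("invalid abundance (negative, missing or non-integer) at row ",
         bad[1L])
  d$cell_id <- as.character(d$cell_id)
  if (anyDuplicated(d[, c("cell_id", "year")]))
    stop("duplicated (cell_id, year) row in census CSV")
  cells <- unique(d[, c("cell_id", "x_km", "y_km")])
  if (anyDuplicated(cells$cell_id))
    stop("inconsistent coordinates for a cell_id")
  cells <- cells[order(cells$cell_id), , drop = FALSE]
  rownames(cells) <- NULL
  years <- sort(unique(as.integer(d$year)))
  counts <- matrix(NA_integer_, nrow(cells), length(years))
  i <- match(d$cell_id, cells$cell_id)
  j <- match(as.integer(d$year), years)
  counts[cbind(i, j)] <- as.integer(d$abundance)
  if (anyNA(counts)) stop("census CSV is not complete: every cell needs a ",
                          "count for every year")
  census_table(cells, years, counts)
}

#' Write a census table as a long-format CSV
#'
#' Inverse of [read_census_csv()]: `read_census_csv(write_census_csv(x, p))`
#' reproduces `x` exactly (ids, coordinates, counts).
#'
#' @param x a [census_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_census_csv <- function(x, path) {
  stopifnot(inherits(x, "census_table"))
  n <- nrow(x$cells)
  d <- data.frame(
    cell_id = rep(x$cells$cell_id, times = length(x$years)),
    x_km = rep(x$cells$x_km, times = length(x$years)),
    y_km = rep(x$cells$y_km, times = length(x$years)),
    year = rep(x$years, each = n),
    abundance = as.vector(x$counts)
  )
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only cells that were ever occupied
#'
#' Restricts a census to the cells with at least one breeding pair in at
#' least one census year. This is the standard pre-filter for the spatial
#' analyses: cells never occupied over the whole period carry no information
#' about the species' occupancy-abundance structure. Idempotent.
#'
#' @param x a [census_table()].
#' @return A [census_table()] with the never-occupied cells removed.
#' @export
filter_ever_present <- function(x) {
  stopifnot(inherits(x, "census_table"))
  keep <- rowSums(x$counts) > 0L
  if (!any(keep))
    stop("no cell was ever occupied; downstream statistics are undefined")
  census_table(x$cells[keep, , drop = FALSE], x$years,
               x$counts[keep, , drop = FALSE])
}

#' Read a per-cell covariate CSV
#'
#' One row per cell, a `cell_id` column plus one numeric column per
#' covariate. The default expected set is the 16 standard variables
#' ([covariate_acronyms()]). Percentage-type land-cover columns must lie in
#' \[0, 100\]; missing values are rejected (no imputation).
#'
#' @param path CSV file path.
#' @param variables character vector of covariate columns that must be
#'   present; extra columns are kept. Default [covariate_acronyms()].
#' @return data.frame with `cell_id` (character) and numeric covariates.
#' @export
read_covariates_csv <- function(path, variables = covariate_acronyms()) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(d)) stop("covariate CSV is missing column: cell_id")
  miss <- setdiff(variables, names(d))
  if (length(miss) > 0L)
    stop("covariate CSV is missing column(s): ", paste(miss, collapse = ", "))
  d$cell_id <- as.character(d$cell_id)
  if (anyDuplicated(d$cell_id)) stop("duplicated cell_id in covariate CSV")
  validate_covariates(d, variables)
  d
}

#' The 16 standard covariate acronyms
#'
#' Land-cover percentages (NIC, IRR, TREE, DEH, ROC, FOR, PAS, URB),
#' altitude (ALT), livestock head counts (COW, SHEEP), landfills (LAND),
#' supplementary feeding stations (SFS), wind turbines (WTG), poisoning
#' events (POIS) and griffon-vulture breeding pairs (GF), each per
#' 100 km2 cell.
#'
#' @return character vector of length 16.
#' @export
covariate_acronyms <- function() {
  c("ALT", "NIC", "IRR", "TREE", "DEH", "ROC", "FOR", "PAS",
    "COW", "SHEEP", "LAND", "SFS", "URB", "WTG", "POIS", "GF")
}

# columns measured as percent cover of the 100 km2 cell
percentage_covariates <- function() {
  c("NIC", "IRR", "TREE", "DEH", "ROC", "FOR", "PAS", "URB")
}

validate_covariates <- function(d, variables) {
  for (v in variables) {
    col <- d[[v]]
    if (!is.numeric(col)) stop("covariate ", v, " is not numeric")
    if (anyNA(col)) stop("missing value in covariate ", v)
    if (any(col < 0)) stop("negative value in covariate ", v)
    if (v %in% percentage_covariates() && any(col > 100))
      stop("percentage covariate ", v, " outside [0, 100]")
  }
  invisible(d)
}

#' Export grid cells as a GeoJSON FeatureCollection
#'
#' Writes one square polygon feature per cell (side `cell_size_km`,
#' centred on the centroid) with any per-cell attributes embedded as
#' feature properties, e.g. for mapping LISA High/Low classes in a GIS.
#' Coordinates are written on the planar kilometre grid of the input (no
#' CRS handling).
#'
#' @param cells data.frame with `cell_id`, `x_km`, `y_km` (e.g.
#'   `census$cells`).
#' @param attributes optional data.frame keyed by a `cell_id` column; all
#'   other columns become feature properties. Every `cell_id` must exist in
#'   `cells`.
#' @param path output file path.
#' @param cell_size_km polygon side length in km (default 10).
#' @return `path`, invisibly.
#' @export
write_geojson <- function(cells, attributes = NULL, path, cell_size_km = 10) {
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "x_km", "y_km") %in% names(cells)))
  cells$cell_id <- as.character(cells$cell_id)
  props <- NULL
  if (!is.null(attributes)) {
    stopifnot(is.data.frame(attributes), "cell_id" %in% names(attributes))
    unknown <- setdiff(as.character(attributes$cell_id), cells$cell_id)
    if (length(unknown) > 0L)
      stop("attribute(s) for unknown cell_id: ",
           paste(utils::head(unknown, 3L), collapse = ", "))
    props <- attributes[match(cells$cell_id, as.character(attributes$cell_id)),
                        setdiff(names(attributes), "cell_id"), drop = FALSE]
  }
  h <- cell_size_km / 2
  features <- lapply(seq_len(nrow(cells)), function(i) {
    x <- cells$x_km[i]; y <- cells$y_km[i]
    ring <- list(c(x - h, y - h), c(x + h, y - h), c(x + h, y + h),
                 c(x - h, y + h), c(x - h, y - h))
    p <- list(cell_id = cells$cell_id[i])
    if (!is.null(props))
      for (nm in names(props)) p[[nm]] <- props[[nm]][i]
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = p)
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Pairwise abundance and occupancy changes between census years
#'
#' For every ordered pair of census years (later minus earlier) reports the
#' change in total abundance (sum of counts) and in occupancy (number of
#' cells with at least one pair). Exact integer bookkeeping.
#'
#' @param x a [census_table()].
#' @return data.frame with columns `year_a` (later), `year_b` (earlier),
#'   `abundance_change`, `occupancy_change`.
#' @export
change_table <- function(x) {
  stopifnot(inherits(x, "census_table"))
  tot <- colSums(x$counts)
  occ <- colSums(x$counts > 0)
  yrs <- x$years
  pairs <- which(upper.tri(matrix(0, length(yrs), length(yrs))), arr.ind = TRUE)
  data.frame(
    year_a = yrs[pairs[, 2L]],
    year_b = yrs[pairs[, 1L]],
    abundance_change = as.integer(tot[pairs[, 2L]] - tot[pairs[, 1L]]),
    occupancy_change = as.integer(occ[pairs[, 2L]] - occ[pairs[, 1L]])
  )
}
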