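#' @include AllClasses.R
NULL

cohortCSVColumns <- c("observer_id", "location", "contrast_sensitivity",
                      "wedge_area_mm2", "v1_area_mm2", "cortex_area_mm2")

#' Write a cohort table to tidy CSV
#'
#' One row per observer by location with columns `observer_id`, `location`
#' (one of `cortmagLocations()`), `contrast_sensitivity`,
#' `wedge_area_mm2`, `v1_area_mm2`, `cortex_area_mm2` — the same schema
#' accepted by [readCohortCSV()] for externally deposited per-observer
#' source-data tables.
#'
#' @param table a [CohortTable-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeCohortCSV <- function(table, path) {
  locs <- cortmagLocations()
  n <- length(observerIds(table))
  df <- data.frame(
    observer_id = rep(observerIds(table), each = 4),
    location = rep(locs, n),
    contrast_sensitivity = as.vector(t(contrastSensitivities(table))),
    wedge_area_mm2 = as.vector(t(wedgeAreas(table))),
    v1_area_mm2 = rep(v1Areas(table), each = 4),
    cortex_area_mm2 = rep(cortexAreas(table), each = 4))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from tidy CSV
#'
#' Reads the schema of [writeCohortCSV()]. `columnMap` renames external
#' column names onto the schema (a named character vector,
#' `c(observer_id = "their_name", ...)`), so deposited source-data layouts
#' with different headers can be ingested. Every observer must have all
#' four locations and all values must be positive.
#'
#' @param path CSV file path.
#' @param columnMap optional named character vector mapping schema names to
#'   the file's column names.
#' @return A [CohortTable-class].
#' @export
readCohortCSV <- function(path, columnMap = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(columnMap)) {
    for (nm in names(columnMap)) {
      if (!columnMap[[nm]] %in% names(df))
        stop("mapped column '", columnMap[[nm]], "' not found in ", path)
      names(df)[names(df) == columnMap[[nm]]] <- nm
    }
  }
  missing <- setdiff(cohortCSVColumns, names(df))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  locs <- cortmagLocations()
  ids <- unique(df$observer_id)
  get <- function(col) {
    m <- matrix(NA_real_, length(ids), 4, dimnames = list(NULL, locs))
    for (i in seq_along(ids)) for (l in locs) {
      row <- df[df$observer_id == ids[i] & df$location == l, ]
      if (nrow(row) == 0)
        stop("observer ", ids[i], " is missing location ", l)
      m[i, l] <- row[[col]][1]
    }
    m
  }
  cs <- get("contrast_sensitivity")
  wa <- get("wedge_area_mm2")
  if (any(cs <= 0) || any(wa <= 0))
    stop("contrast sensitivities and wedge areas must be positive")
  perObs <- function(col) vapply(ids, function(id)
    df[[col]][df$observer_id == id][1], numeric(1))
  new("CohortTable", observerId = as.character(ids),
      cs = cs, wedgeArea = wa,
      v1Area = unname(perObs("v1_area_mm2")),
      cortexArea = unname(perObs("cortex_area_mm2")))
}
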