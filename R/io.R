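# Plain-text serialization of landscape bundles: grid and land-use
# tables as CSV, intensity surfaces as long-format CSV (one row per
# set/cell/type), the species table as CSV with delimited list columns.

collapse_list_col <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}

split_list_col <- function(x, as_int = FALSE) {
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE),
         function(v) if (as_int) as.integer(v) else v)
}

#' Write a landscape bundle to a directory of CSV files
#'
#' @param landscape A `csar_landscape` (or any list with `grid`, `lu`,
#'   `species`, `intensity`, `catalogue` tables).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(landscape$grid, file.path(dir, "grid.csv"))
  readr::write_csv(landscape$lu, file.path(dir, "lu.csv"))
  readr::write_csv(landscape$catalogue, file.path(dir, "lu_catalogue.csv"))
  if (!is.null(landscape$intensity)) {
    readr::write_csv(landscape$intensity, file.path(dir, "intensity.csv"))
  }
  sp <- landscape$species
  sp$range_cells <- collapse_list_col(sp$range_cells)
  sp$ecosystem_affiliations <- collapse_list_col(sp$ecosystem_affiliations)
  sp$lu_affiliations <- collapse_list_col(sp$lu_affiliations)
  readr::write_csv(sp, file.path(dir, "species.csv"))
  invisible(dir)
}

#' Read a landscape bundle written by [write_landscape()]
#'
#' @param dir Directory holding `grid.csv`, `lu.csv`, `species.csv`,
#'   `lu_catalogue.csv` and optionally `intensity.csv`.
#' @return A list of class `csar_landscape`.
#' @export
read_landscape <- function(dir) {
  req <- c("grid.csv", "lu.csv", "species.csv", "lu_catalogue.csv")
  missing <- req[!file.exists(file.path(dir, req))]
  if (length(missing) > 0L) {
    stop_input(sprintf("landscape directory %s is missing: %s",
                       dir, paste(missing, collapse = ", ")))
  }
  grid <- readr::read_csv(file.path(dir, "grid.csv"),
                          show_col_types = FALSE)
  lu <- readr::read_csv(file.path(dir, "lu.csv"), show_col_types = FALSE)
  catalogue <- readr::read_csv(file.path(dir, "lu_catalogue.csv"),
                               show_col_types = FALSE)
  sp <- readr::read_csv(file.path(dir, "species.csv"),
                        show_col_types = FALSE)
  sp$range_cells <- split_list_col(sp$range_cells, as_int = TRUE)
  sp$ecosystem_affiliations <- split_list_col(sp$ecosystem_affiliations)
  sp$lu_affiliations <- split_list_col(sp$lu_affiliations)
  intensity <- NULL
  if (file.exists(file.path(dir, "intensity.csv"))) {
    intensity <- readr::read_csv(file.path(dir, "intensity.csv"),
                                 show_col_types = FALSE)
  }
  structure(
    list(grid = grid, lu = lu, species = sp, intensity = intensity,
         catalogue = catalogue, params = NULL),
    class = "csar_landscape"
  )
}

#' Export the refined pool as a sparse cell-by-species membership file
#'
#' Coordinate-list text format: one `cell_id,species_id` row per
#' membership.
#'
#' @param pool A `species_pool`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_membership <- function(pool, path) {
  readr::write_csv(pool$membership, path)
  invisible(path)
}
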