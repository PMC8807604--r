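# Area-of-habitat-refined species pools: per-cell potential richness,
# per-land-use-type affiliated counts and affinity fractions r.

#' Refine species ranges into per-cell potential species pools
#'
#' Applies the area-of-habitat refinement: a species belongs to a cell's
#' potential (pristine-condition) pool when its range includes the cell,
#' it is not exclusively aquatic, its habitat affiliations include the
#' cell's pristine ecosystem class, and its elevational range overlaps
#' the cell's elevational range (closed intervals: touching endpoints
#' count as overlap). Per-cell potential richness `S_pot` is counted per
#' taxonomic group, and each species' native area of habitat is the sum
#' of terrestrial areas of its refined range cells.
#'
#' @param species Species table as produced by [generate_landscape()]:
#'   one row per species with list-columns `range_cells`,
#'   `ecosystem_affiliations`, `lu_affiliations` and scalar columns
#'   `species_id`, `taxon_group`, `elev_min`, `elev_max`,
#'   `is_exclusively_aquatic`, `iucn_category`.
#' @param grid Grid table with `cell_id`, `area_pot`, `ecosystem_class`,
#'   `elev_min`, `elev_max`.
#' @return A list of class `species_pool` with elements
#'   \describe{
#'     \item{membership}{tibble `cell_id`, `taxon_group`, `species_id`
#'       (the refined cell x species incidence).}
#'     \item{s_pot}{tibble `cell_id`, `taxon_group`, `s_pot` (cells
#'       where the group has at least one species).}
#'     \item{native_aoh}{tibble `species_id`, `n_cells`,
#'       `native_aoh_area` (m2).}
#'     \item{species}{the input species table.}
#'     \item{empty_cells}{cell ids with no native species at all
#'       (flagged, excluded from averaged summaries downstream).}
#'   }
#' @export
refine_species_pool <- function(species, grid) {
  assert_columns(species, c("species_id", "taxon_group", "range_cells",
                            "ecosystem_affiliations", "elev_min", "elev_max",
                            "is_exclusively_aquatic"), "species")
  assert_columns(grid, c("cell_id", "area_pot", "ecosystem_class",
                         "elev_min", "elev_max"), "grid")
  all_range <- unique(unlist(species$range_cells))
  bad <- setdiff(all_range, grid$cell_id)
  if (length(bad) > 0L) {
    offender <- species$species_id[
      vapply(species$range_cells, function(rc) any(rc %in% bad), logical(1))
    ][1]
    stop_input(sprintf(
      "species %s has range cell(s) not in the grid (e.g. cell %s)",
      offender, bad[1]
    ))
  }
  if (any(species$elev_min > species$elev_max)) {
    stop_input("species elevational ranges must have elev_min <= elev_max")
  }

  land <- species[!species$is_exclusively_aquatic, , drop = FALSE]
  pairs <- tibble::tibble(
    species_id = rep(land$species_id, lengths(land$range_cells)),
    taxon_group = rep(land$taxon_group, lengths(land$range_cells)),
    sp_elev_min = rep(land$elev_min, lengths(land$range_cells)),
    sp_elev_max = rep(land$elev_max, lengths(land$range_cells)),
    cell_id = unlist(land$range_cells)
  )
  eco_ok <- mapply(
    function(aff, eco) eco %in% aff,
    rep(land$ecosystem_affiliations, lengths(land$range_cells)),
    grid$ecosystem_class[match(pairs$cell_id, grid$cell_id)]
  )
  if (length(eco_ok) == 0L) eco_ok <- logical(0)
  cell_lo <- grid$elev_min[match(pairs$cell_id, grid$cell_id)]
  cell_hi <- grid$elev_max[match(pairs$cell_id, grid$cell_id)]
  elev_ok <- pairs$sp_elev_min <= cell_hi & pairs$sp_elev_max >= cell_lo

  membership <- pairs[eco_ok & elev_ok,
                      c("cell_id", "taxon_group", "species_id")]
  membership <- dplyr::arrange(membership, .data$cell_id, .data$species_id)

  s_pot <- dplyr::summarise(
    dplyr::group_by(membership, .data$cell_id, .data$taxon_group),
    s_pot = dplyr::n(), .groups = "drop"
  )
  areas <- setNames(grid$area_pot, grid$cell_id)
  native_aoh <- dplyr::summarise(
    dplyr::group_by(membership, .data$species_id),
    n_cells = dplyr::n(),
    native_aoh_area = sum(areas[as.character(.data$cell_id)]),
    .groups = "drop"
  )
  empty_cells <- setdiff(grid$cell_id, unique(membership$cell_id))
  if (length(empty_cells) > 0L) {
    rlang::inform(sprintf(
      "%d cell(s) have no native species after refinement and are excluded from averaged summaries",
      length(empty_cells)
    ), class = "csarlui_empty_cells")
  }
  structure(
    list(membership = membership, s_pot = s_pot, native_aoh = native_aoh,
         species = species, empty_cells = empty_cells),
    class = "species_pool"
  )
}

#' @export
print.species_pool <- function(x, ...) {
  cat(sprintf(
    "<species_pool> %d cell x species memberships, %d occupied (cell, taxon) pools, %d species\n",
    nrow(x$membership), nrow(x$s_pot), nrow(x$native_aoh)
  ))
  invisible(x)
}

#' Compute per-land-use-type affinity fractions r
#'
#' For each occupied (cell, taxon) pool and each broad land-use type,
#' the affinity fraction is the share of the pool affiliated with the
#' type, `r = S_pot_LU / S_pot`. For the two unconverted broad types
#' (grazing land and forests) no land conversion precedes use, so every
#' native species counts as affiliated and r = 1.
#'
#' @param pool A `species_pool` from [refine_species_pool()].
#' @param broad_types Broad types to evaluate (default all six).
#' @return The pool with an `affinity` element added: tibble `cell_id`,
#'   `taxon_group`, `broad_type`, `s_pot`, `s_pot_lu`, `r`.
#' @export
compute_affinity_fractions <- function(pool, broad_types = broad_lu_types()) {
  stopifnot(inherits(pool, "species_pool"))
  unconverted <- c("grazing land", "forests")
  aff_sets <- setNames(pool$species$lu_affiliations, pool$species$species_id)

  per_type <- lapply(broad_types, function(b) {
    out <- pool$s_pot
    out$broad_type <- b
    if (b %in% unconverted) {
      out$s_pot_lu <- out$s_pot
    } else {
      affiliated <- vapply(
        aff_sets[pool$membership$species_id],
        function(a) b %in% a, logical(1)
      )
      counts <- dplyr::summarise(
        dplyr::group_by(
          pool$membership[affiliated, , drop = FALSE],
          .data$cell_id, .data$taxon_group
        ),
        s_pot_lu = dplyr::n(), .groups = "drop"
      )
      out <- dplyr::left_join(out, counts,
                              by = c("cell_id", "taxon_group"))
      out$s_pot_lu[is.na(out$s_pot_lu)] <- 0L
    }
    out
  })
  affinity <- dplyr::bind_rows(per_type)
  affinity$r <- affinity$s_pot_lu / affinity$s_pot
  pool$affinity <- affinity[, c("cell_id", "taxon_group", "broad_type",
                                "s_pot", "s_pot_lu", "r")]
  pool
}

#' Partition a cell's pool into affiliated and unaffiliated lists
#'
#' For one broad land-use type, splits every cell's refined species list
#' into the species affiliated with the type (candidates for
#' intensification-driven loss) and those unaffiliated (candidates for
#' conversion-driven loss). For the unconverted types (grazing land,
#' forests) the unaffiliated list is empty everywhere, matching the
#' r = 1 convention.
#'
#' @param pool A `species_pool`.
#' @param broad_type One broad land-use type.
#' @return Tibble `cell_id`, `taxon_group`, `species_id`, `affiliated`
#'   (logical); the two groups partition the refined list.
#' @export
partition_affiliation_lists <- function(pool, broad_type) {
  stopifnot(inherits(pool, "species_pool"))
  if (!broad_type %in% broad_lu_types()) {
    stop_input(sprintf("unknown broad land-use type: %s", broad_type))
  }
  m <- pool$membership
  if (broad_type %in% c("grazing land", "forests")) {
    m$affiliated <- TRUE
    return(m)
  }
  aff_sets <- setNames(pool$species$lu_affiliations, pool$species$species_id)
  m$affiliated <- vapply(
    aff_sets[m$species_id], function(a) broad_type %in% a, logical(1)
  )
  m
}
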