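# Area-weighted summary statistics and broad-type aggregation.

# Per-cell relative loss across taxonomic groups: summed losses over
# summed potential richness, as percentages of S_pot.
cell_relative_loss <- function(loss) {
  stopifnot(inherits(loss, "loss_result"))
  dplyr::summarise(
    dplyr::group_by(loss$cells, .data$cell_id),
    s_pot = sum(.data$s_pot),
    s_loss = sum(.data$s_loss),
    s_loss_conv = sum(.data$s_loss_conv),
    wilderness = .data$wilderness[1],
    .groups = "drop"
  )
}

#' Area-weighted loss summary
#'
#' Cell-area-weighted mean of the per-cell relative species loss (and
#' its conversion and intensity components) across all cells holding
#' native terrestrial vertebrate species, optionally excluding
#' wilderness cells (cells whose summed land-use area is zero). Results
#' can be grouped by biome or region label.
#'
#' @param loss A `loss_result`.
#' @param grid Grid table.
#' @param scope `"global"`, `"biome"` or `"region"`.
#' @param include_wilderness Include zero-land-use cells in the average?
#' @return Tibble with `mean_relative_loss_pct`,
#'   `mean_conversion_component_pct`, `mean_intensity_component_pct`
#'   (percentages of potential richness; components sum to the total),
#'   `n_cells`, `area` and, for non-global scopes, the group label.
#'   Empty groups are reported with `NA` means, not zero.
#' @export
area_weighted_summary <- function(loss, grid, scope = "global",
                                  include_wilderness = FALSE) {
  if (!scope %in% c("global", "biome", "region")) {
    stop_input(sprintf("unknown scope: %s", scope))
  }
  cells <- cell_relative_loss(loss)
  cells <- dplyr::left_join(
    cells,
    grid[, intersect(c("cell_id", "area_pot", "biome_label",
                       "region_label"), names(grid))],
    by = "cell_id"
  )
  if (!include_wilderness) {
    cells <- cells[!cells$wilderness, , drop = FALSE]
  }
  cells <- cells[cells$s_pot > 0, , drop = FALSE]
  group_col <- switch(scope, global = NULL, biome = "biome_label",
                      region = "region_label")
  if (!is.null(group_col) && !group_col %in% names(cells)) {
    stop_input(sprintf("grid has no `%s` column for scope \"%s\"",
                       group_col, scope))
  }
  summarise_block <- function(d) {
    if (nrow(d) == 0L) {
      return(tibble::tibble(
        mean_relative_loss_pct = NA_real_,
        mean_conversion_component_pct = NA_real_,
        mean_intensity_component_pct = NA_real_,
        n_cells = 0L, area = 0
      ))
    }
    w <- d$area_pot
    rel <- d$s_loss / d$s_pot
    conv <- d$s_loss_conv / d$s_pot
    tibble::tibble(
      mean_relative_loss_pct = 100 * sum(w * rel) / sum(w),
      mean_conversion_component_pct = 100 * sum(w * conv) / sum(w),
      mean_intensity_component_pct =
        100 * sum(w * (rel - conv)) / sum(w),
      n_cells = nrow(d), area = sum(w)
    )
  }
  if (is.null(group_col)) {
    out <- summarise_block(cells)
    if (out$n_cells == 0L) {
      rlang::inform("no eligible cells in summary scope",
                    class = "csarlui_empty_summary")
    }
    return(out)
  }
  groups <- split(cells, cells[[group_col]])
  out <- dplyr::bind_rows(lapply(groups, summarise_block), .id = group_col)
  tibble::as_tibble(out)
}

#' Share of area exceeding a relative-loss threshold
#'
#' Area of non-wilderness cells with native species whose relative loss
#' exceeds the threshold, divided by the total area of such cells.
#'
#' @param loss A `loss_result`.
#' @param grid Grid table.
#' @param threshold_pct Threshold in percent of potential richness
#'   (0--100).
#' @return A fraction in \[0, 1\].
#' @export
threshold_exceedance_share <- function(loss, grid, threshold_pct) {
  assert_scalar_number(threshold_pct, "threshold_pct", min = 0, max = 100)
  cells <- cell_relative_loss(loss)
  cells <- dplyr::left_join(cells, grid[, c("cell_id", "area_pot")],
                            by = "cell_id")
  cells <- cells[!cells$wilderness & cells$s_pot > 0, , drop = FALSE]
  if (nrow(cells) == 0L) {
    return(NA_real_)
  }
  rel_pct <- 100 * cells$s_loss / cells$s_pot
  sum(cells$area_pot[rel_pct > threshold_pct]) / sum(cells$area_pot)
}

#' Aggregate fine-type attributions to the six broad types
#'
#' Sums per-fine-type loss attributions within broad types; totals are
#' preserved exactly.
#'
#' @param attribution Attribution table from
#'   [attribute_loss_to_lu_types()].
#' @param mapping Fine-to-broad mapping (`lu_type`, `broad_type`);
#'   defaults to the mapping already carried by the attribution table.
#' @return Tibble per (cell, taxon, broad type) with summed
#'   `loss_total`, `loss_conv`, `loss_int`.
#' @export
aggregate_to_broad_types <- function(attribution, mapping = NULL) {
  att <- attribution
  if (!is.null(mapping)) {
    assert_columns(mapping, c("lu_type", "broad_type"), "mapping")
    idx <- match(att$lu_type, mapping$lu_type)
    if (anyNA(idx)) {
      stop_input(sprintf(
        "unmapped fine type(s): %s",
        paste(unique(att$lu_type[is.na(idx)]), collapse = ", ")
      ))
    }
    att$broad_type <- mapping$broad_type[idx]
  } else if (!"broad_type" %in% names(att)) {
    stop_input("attribution has no `broad_type` column and no mapping given")
  }
  dplyr::summarise(
    dplyr::group_by(att, .data$cell_id, .data$taxon_group,
                    .data$broad_type),
    loss_total = sum(.data$loss_total),
    loss_conv = sum(.data$loss_conv),
    loss_int = sum(.data$loss_int),
    .groups = "drop"
  )
}

#' Per-broad-type contribution to the area-weighted loss
#'
#' Area-weighted mean, over eligible cells, of each broad type's share
#' of relative loss (percentage points of potential richness), split
#' into conversion and intensity contributions.
#'
#' @inheritParams area_weighted_summary
#' @return Tibble per broad type with `loss_total_pct`, `loss_conv_pct`,
#'   `loss_int_pct` (percentage points).
#' @export
broad_type_summary <- function(loss, grid, include_wilderness = FALSE) {
  cells <- cell_relative_loss(loss)
  eligible <- cells[cells$s_pot > 0 &
                      (include_wilderness | !cells$wilderness), ,
                    drop = FALSE]
  broad <- aggregate_to_broad_types(loss$attribution)
  broad <- broad[broad$cell_id %in% eligible$cell_id, , drop = FALSE]
  per_cell <- dplyr::summarise(
    dplyr::group_by(broad, .data$cell_id, .data$broad_type),
    loss_total = sum(.data$loss_total),
    loss_conv = sum(.data$loss_conv),
    loss_int = sum(.data$loss_int),
    .groups = "drop"
  )
  per_cell <- dplyr::left_join(
    per_cell,
    dplyr::left_join(eligible[, c("cell_id", "s_pot")],
                     grid[, c("cell_id", "area_pot")], by = "cell_id"),
    by = "cell_id"
  )
  total_area <- sum(
    grid$area_pot[match(eligible$cell_id, grid$cell_id)]
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_cell, .data$broad_type),
    loss_total_pct = 100 *
      sum(.data$area_pot * .data$loss_total / .data$s_pot) / total_area,
    loss_conv_pct = 100 *
      sum(.data$area_pot * .data$loss_conv / .data$s_pot) / total_area,
    loss_int_pct = 100 *
      sum(.data$area_pot * .data$loss_int / .data$s_pot) / total_area,
    .groups = "drop"
  )
  tibble::as_tibble(out)
}
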