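# Independent scalar oracle for the cSAR loss and its decomposition.
# Deliberately written as plain scalar arithmetic straight from the
# model definition -- no vectorization and no code shared with the
# package -- so it can serve as a cross-check of the pipeline.

scalar_csar_cell <- function(s_pot, a_pot, a_cur, areas, r, f, z) {
  acc <- a_cur
  for (b in seq_along(areas)) {
    h_b <- (r[b]^(1 / z)) * (f[b]^(1 / z))
    acc <- acc + h_b * areas[b]
  }
  s_pot * (1 - (acc / a_pot)^z)
}

scalar_csar_decomposition <- function(s_pot, a_pot, a_cur, areas, r, f, z) {
  s_loss <- scalar_csar_cell(s_pot, a_pot, a_cur, areas, r, f, z)
  s_loss_conv <- scalar_csar_cell(s_pot, a_pot, a_cur, areas, r,
                                  rep(1, length(areas)), z)
  list(
    s_loss = s_loss,
    s_loss_conv = s_loss_conv,
    s_loss_int_rel = (s_loss - s_loss_conv) / s_pot
  )
}

# Random single-cell fixtures on which the oracle and the pipeline are
# compared. Returns parallel lists of inputs.
random_cells <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample(1:5, 1)
    a_pot <- runif(1, 0.5, 2) * 1e8
    shares <- runif(k, 0, 1)
    shares <- shares / sum(shares) * runif(1, 0, 1)
    list(
      s_pot = sample(5:200, 1),
      a_pot = a_pot,
      a_cur = a_pot * (1 - sum(shares)),
      areas = a_pot * shares,
      r = runif(k),
      f = runif(k),
      z = runif(1, 0.05, 0.95)
    )
  })
}

# Assemble the package-side objects for a list of random cells: a fake
# refined pool (one taxon), grid, land-use table and affinity field in
# the exact layout csar_loss() consumes.
cells_to_pipeline_inputs <- function(cells) {
  n <- length(cells)
  grid <- tibble::tibble(
    cell_id = seq_len(n),
    area_pot = vapply(cells, `[[`, 0, "a_pot"),
    area_pristine = vapply(cells, `[[`, 0, "a_cur"),
    z_exponent = vapply(cells, `[[`, 0, "z")
  )
  lu <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    k <- length(cells[[i]]$areas)
    tibble::tibble(
      cell_id = i,
      lu_type = paste0("t", seq_len(k)),
      broad_type = "cropland",
      response_class = "cropland",
      converted = TRUE,
      area = cells[[i]]$areas
    )
  }))
  field <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    c <- cells[[i]]
    k <- length(c$areas)
    tibble::tibble(
      cell_id = i, taxon_group = "birds",
      lu_type = paste0("t", seq_len(k)), broad_type = "cropland",
      area = c$areas, r = c$r, f = c$f, z = c$z,
      r_comp = c$r^(1 / c$z), f_comp = c$f^(1 / c$z),
      h = compute_affinity(c$r, c$f, c$z)
    )
  }))
  pool <- structure(
    list(
      s_pot = tibble::tibble(
        cell_id = seq_len(n), taxon_group = "birds",
        s_pot = vapply(cells, `[[`, 0, "s_pot")
      )
    ),
    class = "species_pool"
  )
  list(pool = pool, grid = grid, lu = lu, field = field)
}

# A tiny hand-specified species table builder for pool tests.
make_species_table <- function(...) {
  rows <- list(...)
  tibble::tibble(
    species_id = vapply(rows, `[[`, "", "id"),
    taxon_group = vapply(rows, function(r) r$taxon %||% "birds", ""),
    range_cells = lapply(rows, `[[`, "cells"),
    ecosystem_affiliations = lapply(rows, function(r) r$eco %||% "eco_1"),
    lu_affiliations = lapply(rows, function(r) r$lu %||% character()),
    elev_min = vapply(rows, function(r) r$elev[1] %||% 0, 0),
    elev_max = vapply(rows, function(r) r$elev[2] %||% 5000, 0),
    is_exclusively_aquatic = vapply(rows, function(r)
      isTRUE(r$aquatic), logical(1)),
    iucn_category = "LC"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

make_grid <- function(n, area_pot = 1e8, area_pristine = area_pot,
                      z = 0.25, eco = "eco_1", elev = c(0, 1000)) {
  tibble::tibble(
    cell_id = seq_len(n),
    area_pot = rep_len(area_pot, n),
    area_pristine = rep_len(area_pristine, n),
    z_exponent = rep_len(z, n),
    ecosystem_class = rep_len(eco, n),
    elev_min = rep_len(elev[1], n),
    elev_max = rep_len(elev[2], n),
    biome_label = "biome_1", region_label = "region_1",
    npp_pot = 600, canopy_openness = "open"
  )
}
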