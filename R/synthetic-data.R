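# Synthetic landscape generator. Produces small, fully closed landscapes
# (grid, land-use areas, raw intensity surfaces for both indicator sets,
# species records) with known construction parameters so that every
# downstream stage of the pipeline can be tested without external data.

#' Default scenario parameters for the synthetic generator
#'
#' The generator emulates the statistical structure of a gridded global
#' land-use/biodiversity data stack, not its geography. Parameters:
#' \describe{
#'   \item{lu_share_mean, lu_share_concentration}{Per-cell total used
#'     share of terrestrial area is Beta-distributed with this mean
#'     (default 0.4) and concentration (alpha + beta, default 10).}
#'   \item{wilderness_fraction}{Share of cells with zero land use
#'     (default 0.15), mirroring wilderness landscapes.}
#'   \item{max_types_per_cell}{Upper bound on distinct fine types per
#'     cell (default 8).}
#'   \item{affiliation_prob}{Probability a species tolerates a given
#'     converted broad land-use type (default 0.5).}
#'   \item{ecosystem_affiliation_prob}{Probability a species is adapted
#'     to a given pristine ecosystem class (default 0.7).}
#'   \item{aquatic_fraction}{Share of exclusively aquatic species
#'     (default 0.02), removed by pool refinement.}
#'   \item{area_pot_m2}{Typical terrestrial cell area (default 8.6e7 m2,
#'     a mid-latitude 5-arcmin cell).}
#'   \item{z_range}{Per-cell SAR exponent drawn uniformly (default
#'     0.15--0.35, the usual island/countryside SAR range).}
#'   \item{npp_pot_range}{Potential NPP drawn uniformly (gC/m2/yr,
#'     default 300--1200).}
#'   \item{n_ecosystem_classes, n_biomes, n_regions}{Numbers of
#'     categorical labels (defaults 3, 2, 2).}
#'   \item{n_rate_meanlog, n_rate_sdlog}{Log-normal nitrogen application
#'     rates, kg N/ha (default median 60).}
#'   \item{livestock_meanlog, livestock_sdlog}{Log-normal livestock
#'     density, livestock units per ha (default median 0.5).}
#' }
#' @return Named list of defaults; override entries via the
#'   `scenario_params` argument of [generate_landscape()].
#' @export
default_scenario_params <- function() {
  list(
    lu_share_mean = 0.4,
    lu_share_concentration = 10,
    wilderness_fraction = 0.15,
    max_types_per_cell = 8L,
    affiliation_prob = 0.5,
    ecosystem_affiliation_prob = 0.7,
    aquatic_fraction = 0.02,
    area_pot_m2 = 8.6e7,
    z_range = c(0.15, 0.35),
    npp_pot_range = c(300, 1200),
    n_ecosystem_classes = 3L,
    n_biomes = 2L,
    n_regions = 2L,
    n_rate_meanlog = log(60),
    n_rate_sdlog = 0.8,
    livestock_meanlog = log(0.5),
    livestock_sdlog = 0.7
  )
}

#' Generate a self-consistent synthetic landscape
#'
#' Draws a grid of cells with terrestrial areas, SAR exponents,
#' ecosystem classes and elevation ranges; land-use layers that
#' partition each cell's area between fine land-use types and a pristine
#' remainder; raw intensity surfaces for the HANPP-based set (`Set1`)
#' and the input/output set (`Set2`); and a species table with
#' contiguous ranges, habitat/elevation affiliations and IUCN
#' categories. Each component uses its own named random stream derived
#' from `seed`, so regenerating one component never perturbs another.
#'
#' @param n_cells Number of grid cells (>= 1).
#' @param n_species Number of species (>= 1).
#' @param n_lu_types Number of fine land-use types (1--45).
#' @param seed Integer master seed; identical seeds give bit-identical
#'   landscapes.
#' @param scenario_params Overrides for [default_scenario_params()].
#' @return A list of class `csar_landscape` with elements `grid`, `lu`,
#'   `species`, `intensity` (raw surfaces, both sets), `catalogue` and
#'   `params`.
#' @export
#' @examples
#' ls <- generate_landscape(n_cells = 10, n_species = 20, seed = 1)
#' ls$grid
generate_landscape <- function(n_cells, n_species, n_lu_types = 45L,
                               seed = 1L,
                               scenario_params = list()) {
  assert_scalar_number(n_cells, "n_cells", min = 1)
  assert_scalar_number(n_species, "n_species", min = 1)
  assert_scalar_number(n_lu_types, "n_lu_types", min = 1, max = 45)
  n_cells <- as.integer(n_cells)
  n_species <- as.integer(n_species)
  p <- utils::modifyList(default_scenario_params(), scenario_params)
  if (!is.null(p$lu_share_total_fixed)) {
    if (p$lu_share_total_fixed > 1) {
      stop_input(sprintf(
        "invalid scenario: fixed land-use share %.3f exceeds 1 (cells cannot allocate more than their terrestrial area)",
        p$lu_share_total_fixed
      ))
    }
  }
  if (p$lu_share_mean < 0 || p$lu_share_mean > 1) {
    stop_input("`lu_share_mean` must lie in [0, 1]")
  }
  catalogue <- lu_catalogue(n_lu_types)

  eco_classes <- paste0("eco_", seq_len(p$n_ecosystem_classes))
  biomes <- paste0("biome_", seq_len(p$n_biomes))
  regions <- paste0("region_", seq_len(p$n_regions))

  # --- grid ------------------------------------------------------------
  grid <- with_stream(seed, "grid", {
    elev_min <- runif(n_cells, 0, 3000)
    tibble::tibble(
      cell_id = seq_len(n_cells),
      area_pot = p$area_pot_m2 * exp(stats::rnorm(n_cells, 0, 0.2)),
      z_exponent = runif(n_cells, p$z_range[1], p$z_range[2]),
      ecosystem_class = sample(eco_classes, n_cells, replace = TRUE),
      elev_min = elev_min,
      elev_max = elev_min + runif(n_cells, 200, 1500),
      biome_label = sample(biomes, n_cells, replace = TRUE),
      region_label = sample(regions, n_cells, replace = TRUE),
      npp_pot = runif(n_cells, p$npp_pot_range[1], p$npp_pot_range[2]),
      canopy_openness = ifelse(
        sample(c(TRUE, FALSE), n_cells, replace = TRUE, prob = c(0.4, 0.6)),
        "closed", "open"
      )
    )
  })

  # --- land-use layers -------------------------------------------------
  lu <- with_stream(seed, "areas", {
    wilderness <- runif(n_cells) < p$wilderness_fraction
    share <- if (!is.null(p$lu_share_total_fixed)) {
      rep(p$lu_share_total_fixed, n_cells)
    } else {
      k <- p$lu_share_concentration
      stats::rbeta(n_cells, p$lu_share_mean * k, (1 - p$lu_share_mean) * k)
    }
    share[wilderness] <- 0
    rows <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      if (share[i] <= 0) next
      n_present <- sample.int(min(p$max_types_per_cell, n_lu_types), 1L)
      types <- catalogue$lu_type[
        sample.int(n_lu_types, n_present, replace = FALSE)
      ]
      w <- stats::rgamma(n_present, shape = 1)
      rows[[i]] <- tibble::tibble(
        cell_id = i,
        lu_type = types,
        area = grid$area_pot[i] * share[i] * w / sum(w)
      )
    }
    dplyr::bind_rows(rows)
  })
  if (nrow(lu) == 0L) {
    lu <- tibble::tibble(
      cell_id = integer(), lu_type = character(), area = double()
    )
  }
  lu <- dplyr::left_join(
    lu,
    catalogue[, c("lu_type", "broad_type", "response_class", "converted")],
    by = "lu_type"
  )
  used <- tapply(lu$area, factor(lu$cell_id, levels = grid$cell_id), sum)
  used[is.na(used)] <- 0
  grid$area_pristine <- grid$area_pot - as.double(used)

  # --- species ---------------------------------------------------------
  species <- with_stream(seed, "species", {
    # log-uniform contiguous range sizes so small-ranged species exist
    size <- pmin(
      n_cells,
      pmax(1L, as.integer(round(exp(runif(n_species, 0, log(n_cells + 1))))))
    )
    start <- sample.int(n_cells, n_species, replace = TRUE)
    ranges <- lapply(seq_len(n_species), function(i) {
      sort(((start[i] - 1L + seq_len(size[i]) - 1L) %% n_cells) + 1L)
    })
    eco_aff <- lapply(seq_len(n_species), function(i) {
      aff <- eco_classes[runif(length(eco_classes)) <
                           p$ecosystem_affiliation_prob]
      if (length(aff) == 0L) aff <- sample(eco_classes, 1L)
      aff
    })
    converted_broads <- c("cropland", "pastures", "builtup", "plantations")
    lu_aff <- lapply(seq_len(n_species), function(i) {
      converted_broads[runif(length(converted_broads)) < p$affiliation_prob]
    })
    elev_lo <- runif(n_species, 0, 2500)
    tibble::tibble(
      species_id = paste0("sp_", formatC(seq_len(n_species), width = 4,
                                         flag = "0")),
      taxon_group = sample(c("mammals", "birds", "amphibians", "reptiles"),
                           n_species, replace = TRUE),
      range_cells = ranges,
      ecosystem_affiliations = eco_aff,
      lu_affiliations = lu_aff,
      elev_min = elev_lo,
      elev_max = elev_lo + runif(n_species, 500, 3000),
      is_exclusively_aquatic = runif(n_species) < p$aquatic_fraction,
      iucn_category = sample(c("LC", "NT", "VU", "EN", "CR", "DD"),
                             n_species, replace = TRUE,
                             prob = c(0.5, 0.12, 0.13, 0.12, 0.08, 0.05))
    )
  })

  # --- raw intensity surfaces ------------------------------------------
  intensity <- with_stream(seed, "intensities", {
    if (nrow(lu) == 0L) {
      tibble::tibble(
        set_id = character(), cell_id = integer(), lu_type = character(),
        raw_value = double(), npp_pot = double(),
        canopy_openness = character()
      )
    } else {
      base <- dplyr::left_join(
        lu[, c("cell_id", "lu_type", "broad_type")],
        grid[, c("cell_id", "npp_pot", "canopy_openness", "region_label")],
        by = "cell_id"
      )
      metric <- catalogue$set2_metric[
        match(base$lu_type, catalogue$lu_type)
      ]
      grass <- base$broad_type %in% c("grazing land", "pastures")

      # Set 1: HANPP_harv / NPP_pot ratios in plausible per-type ranges.
      raw1 <- runif(nrow(base), 0, 1.2)
      raw1[base$broad_type == "builtup"] <-
        builtup_intensity_set1(base$npp_pot[base$broad_type == "builtup"])
      forestish <- base$broad_type == "forests" |
        base$lu_type == "timber_plantation"
      raw1[forestish] <- runif(sum(forestish), 0, 0.45)
      if (any(grass)) {
        acc <- accessible_npp(base$npp_pot[grass],
                              base$canopy_openness[grass])
        cap <- grazing_max_fraction(acc) * acc / base$npp_pot[grass]
        raw1[grass] <- runif(sum(grass), 0, 1.3 * cap)
      }
      set1 <- dplyr::mutate(base, set_id = "Set1", raw_value = raw1)

      # Set 2: metric depends on the fine type.
      raw2 <- double(nrow(base))
      is_crop <- metric == "crop_n"
      raw2[is_crop] <- stats::rlnorm(sum(is_crop), p$n_rate_meanlog,
                                     p$n_rate_sdlog)
      is_ls <- metric == "livestock"
      raw2[is_ls] <- stats::rlnorm(sum(is_ls), p$livestock_meanlog,
                                   p$livestock_sdlog)
      is_bu <- metric == "builtup_density"
      raw2[is_bu] <- runif(sum(is_bu), 0.05, 1)
      is_fh <- metric == "forest_harvest"
      if (any(is_fh)) {
        # national harvest allocated across forest cells by biomass gap
        gaps <- tibble::tibble(
          cell_id = seq_len(sum(is_fh)),
          country = base$region_label[is_fh],
          gap = stats::rlnorm(sum(is_fh), log(50), 0.5)
        )
        harvest <- stats::aggregate(gaps["gap"], gaps["country"], sum)
        harvest$harvest <- 0.3 * harvest$gap
        alloc <- allocate_forest_harvest_by_biomass_gap(
          harvest[, c("country", "harvest")], gaps
        )
        raw2[is_fh] <- alloc$harvest
      }
      set2 <- dplyr::mutate(base, set_id = "Set2", raw_value = raw2)

      out <- dplyr::bind_rows(set1, set2)
      out[, c("set_id", "cell_id", "lu_type", "raw_value", "npp_pot",
              "canopy_openness")]
    }
  })

  structure(
    list(
      grid = grid[, c("cell_id", "area_pot", "area_pristine", "z_exponent",
                      "ecosystem_class", "elev_min", "elev_max",
                      "biome_label", "region_label", "npp_pot",
                      "canopy_openness")],
      lu = tibble::as_tibble(lu),
      species = species,
      intensity = intensity,
      catalogue = catalogue,
      params = p
    ),
    class = "csar_landscape"
  )
}

#' @export
print.csar_landscape <- function(x, ...) {
  cat(sprintf(
    "<csar_landscape> %d cells, %d species, %d land-use rows, %d fine types\n",
    nrow(x$grid), nrow(x$species), nrow(x$lu),
    length(unique(x$catalogue$lu_type))
  ))
  invisible(x)
}

#' Fixed landscapes with analytically known outputs
#'
#' A small catalogue of hand-constructed landscapes whose expected model
#' outputs are computed in closed form, for use as test oracles:
#' \describe{
#'   \item{`"single-cell-closed-form"`}{One cell (area 1e8 m2, half
#'     converted to a single cropland type, z = 0.25), 100 species of
#'     which 50 are cropland-affiliated, land-use intensity 0 (so
#'     f = 1). The expected loss follows directly from the cSAR power
#'     law.}
#'   \item{`"all-minimal-intensity"`}{Five cells whose scaled intensity
#'     is 0.1 everywhere, below the Minimal anchor: the intensity
#'     component of loss is exactly 0.}
#'   \item{`"two-species-draw-oracle"`}{One cell, two
#'     cropland-affiliated species, an intensification loss target of
#'     exactly 1: each species is drawn with probability 1/2.}
#' }
#' @param case_id One of the case names above.
#' @return A list with the landscape tables (`grid`, `lu`, `species`,
#'   `lui`, `catalogue`), and an `expected` list of closed-form values.
#' @export
generate_known_truth_case <- function(case_id) {
  catalogue <- lu_catalogue(45L)
  make_species <- function(n, cells, affiliated, eco = "eco_1") {
    tibble::tibble(
      species_id = paste0("sp_", formatC(seq_len(n), width = 4, flag = "0")),
      taxon_group = "birds",
      range_cells = rep(list(cells), n),
      ecosystem_affiliations = rep(list(eco), n),
      lu_affiliations = lapply(seq_len(n), function(i) {
        if (affiliated[i]) c("cropland") else character()
      }),
      elev_min = 0, elev_max = 5000,
      is_exclusively_aquatic = FALSE,
      iucn_category = "LC"
    )
  }
  base_grid <- function(n, area_pot, area_pristine, z) {
    tibble::tibble(
      cell_id = seq_len(n),
      area_pot = area_pot, area_pristine = area_pristine,
      z_exponent = z, ecosystem_class = "eco_1",
      elev_min = 0, elev_max = 1000,
      biome_label = "biome_1", region_label = "region_1",
      npp_pot = 600, canopy_openness = "open"
    )
  }
  crop_row <- function(cell_id, area) {
    tibble::tibble(
      cell_id = cell_id, lu_type = "wheat", area = area,
      broad_type = "cropland", response_class = "cropland", converted = TRUE
    )
  }

  if (identical(case_id, "single-cell-closed-form")) {
    a_pot <- 1e8
    z <- 0.25
    grid <- base_grid(1L, a_pot, 0.5 * a_pot, z)
    lu <- crop_row(1L, 0.5 * a_pot)
    species <- make_species(100L, 1L, affiliated = rep(c(TRUE, FALSE), 50))
    lui <- tibble::tibble(set_id = "Set1", cell_id = 1L, lu_type = "wheat",
                          lui = 0)
    r <- 0.5
    h <- r^(1 / z)            # f = 1 at zero intensity
    s_loss <- 100 * (1 - ((0.5 * a_pot + h * 0.5 * a_pot) / a_pot)^z)
    expected <- list(s_pot = 100, r = r, h = h, s_loss = s_loss,
                     s_loss_conv = s_loss, s_loss_int_rel = 0)
  } else if (identical(case_id, "all-minimal-intensity")) {
    n <- 5L
    a_pot <- 1e8
    grid <- base_grid(n, a_pot, 0.6 * a_pot, 0.25)
    lu <- crop_row(seq_len(n), 0.4 * a_pot)
    species <- make_species(40L, seq_len(n),
                            affiliated = rep(c(TRUE, FALSE), 20))
    lui <- tibble::tibble(set_id = "Set1", cell_id = seq_len(n),
                          lu_type = "wheat", lui = 0.1)
    expected <- list(s_loss_int_rel = 0)
  } else if (identical(case_id, "two-species-draw-oracle")) {
    a_pot <- 1e8
    grid <- base_grid(1L, a_pot, 0, 0.25)
    lu <- crop_row(1L, a_pot)
    species <- make_species(2L, 1L, affiliated = c(TRUE, TRUE))
    lui <- tibble::tibble(set_id = "Set1", cell_id = 1L, lu_type = "wheat",
                          lui = 1)
    expected <- list(
      intensification_target = 1,
      per_species_loss_probability = c(sp_0001 = 0.5, sp_0002 = 0.5)
    )
  } else {
    stop_input(sprintf("unknown truth case id: %s", case_id))
  }
  list(grid = grid, lu = lu, species = species, lui = lui,
       catalogue = catalogue, expected = expected)
}
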