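#' Default land-use type catalogue
#'
#' The model computes on fine land-use types and reports on six broad
#' types: cropland (annual crops), pastures (converted grassland),
#' grazing land (natural/near-natural grazed land), builtup, plantations
#' (permanent crops plus timber plantations) and forests (natural or
#' near-natural forest under forestry). Each fine type additionally
#' carries one of four response classes that select the piecewise-linear
#' intensity response, and a `converted` flag: pastures, cropland,
#' builtup and plantations replace the pristine ecosystem, while grazing
#' land and forests are used without prior conversion.
#'
#' The shipped catalogue is a synthetic default of 45 fine types built
#' for self-contained testing; real-data users supply their own mapping
#' table with the same columns (`lu_type`, `broad_type`,
#' `response_class`, `converted`, `legume`).
#'
#' @param n_lu_types Number of fine types to keep (1--45). Types are kept
#'   in catalogue order, which guarantees that all six broad types appear
#'   once `n_lu_types >= 6`.
#' @return A tibble with one row per fine type.
#' @export
#' @examples
#' lu_catalogue(6)
lu_catalogue <- function(n_lu_types = 45L) {
  if (!is.numeric(n_lu_types) || length(n_lu_types) != 1L ||
      n_lu_types < 1 || n_lu_types > 45) {
    stop_input("`n_lu_types` must be a single integer between 1 and 45")
  }
  n_lu_types <- as.integer(n_lu_types)

  annual_crops <- c(
    "wheat", "maize", "rice", "barley", "millet", "sorghum", "potato",
    "sweet_potato", "cassava", "beans", "lentils", "chickpeas", "soybean",
    "cowpeas", "pigeon_peas", "other_pulses", "groundnut", "sunflower",
    "rapeseed", "sesame", "sugarcane", "sugarbeet", "cotton", "vegetables",
    "temperate_cereals_other", "tropical_cereals_other", "oilcrops_other",
    "fibres_other", "annual_other", "fodder"
  )
  legumes <- c(
    "beans", "lentils", "chickpeas", "soybean", "cowpeas", "pigeon_peas",
    "other_pulses"
  )
  permanent_crops <- c(
    "oil_palm", "coconut", "coffee", "cocoa", "tea", "banana_plantain",
    "citrus", "grapes", "tropical_fruit_other", "temperate_fruit_other"
  )

  catalogue <- dplyr::bind_rows(
    tibble::tibble(
      lu_type = "builtup", broad_type = "builtup",
      response_class = "urban", converted = TRUE
    ),
    tibble::tibble(
      lu_type = "pastures", broad_type = "pastures",
      response_class = "pasture", converted = TRUE
    ),
    tibble::tibble(
      lu_type = "grazing_land", broad_type = "grazing land",
      response_class = "pasture", converted = FALSE
    ),
    tibble::tibble(
      lu_type = "forest_used", broad_type = "forests",
      response_class = "plantation", converted = FALSE
    ),
    tibble::tibble(
      lu_type = annual_crops, broad_type = "cropland",
      response_class = "cropland", converted = TRUE
    ),
    tibble::tibble(
      lu_type = c(permanent_crops, "timber_plantation"),
      broad_type = "plantations",
      response_class = "plantation", converted = TRUE
    )
  )
  catalogue$legume <- catalogue$lu_type %in% legumes
  # Which raw descriptor feeds the input/output indicator set for the type:
  # nitrogen rates on crops, livestock density on grassland, built-up
  # density, and biomass-gap-allocated harvest on used/planted forest.
  catalogue$set2_metric <- dplyr::case_when(
    catalogue$broad_type %in% c("pastures", "grazing land") ~ "livestock",
    catalogue$broad_type == "builtup" ~ "builtup_density",
    catalogue$lu_type %in% c("forest_used", "timber_plantation") ~
      "forest_harvest",
    TRUE ~ "crop_n"
  )
  catalogue[seq_len(n_lu_types), , drop = FALSE]
}

#' Broad land-use types
#'
#' The six reporting aggregates, in canonical order.
#' @return Character vector of length six.
#' @export
broad_lu_types <- function() {
  c("cropland", "pastures", "grazing land", "builtup", "plantations",
    "forests")
}

#' Default intensity-response coefficients
#'
#' Categorical species-richness estimates at the Minimal, Light and
#' Intense management levels for each of the four response classes.
#' Ratios of these estimates anchor the piecewise-linear intensity
#' response (see [build_response_function()]); only the ratios
#' `est_light / est_minimal` and `est_intense / est_minimal` matter.
#'
#' The shipped values are a synthetic default chosen so that
#' intensification always reduces richness, ordered urban > cropland >
#' plantation > pasture in severity; real-data users supply estimates
#' from a published local-assemblage mixed model instead.
#'
#' @return A tibble with columns `response_class`, `est_minimal`,
#'   `est_light`, `est_intense`.
#' @export
default_response_coefficients <- function() {
  tibble::tibble(
    response_class = c("cropland", "pasture", "plantation", "urban"),
    est_minimal    = c(0.90, 0.95, 0.92, 0.85),
    est_light      = c(0.72, 0.855, 0.782, 0.595),
    est_intense    = c(0.54, 0.76, 0.644, 0.425)
  )
}

#' Nitrogen-application caps for the input/output indicator set
#'
#' Saturation thresholds (kg N per ha) used to winsorize crop nitrogen
#' application rates: 150 kg N/ha for all crops except legumes, which
#' saturate earlier because of their nitrogen-fixing capability (beans
#' and lentils 110, chickpeas 100, soybean 70, cowpeas/pigeon peas/other
#' pulses 90 kg N/ha).
#'
#' @param catalogue A land-use catalogue, see [lu_catalogue()].
#' @return A tibble with columns `lu_type` and `n_cap_kg_ha` covering
#'   every cropland and plantation fine type in the catalogue.
#' @export
default_n_caps <- function(catalogue = lu_catalogue()) {
  crops <- catalogue[catalogue$set2_metric == "crop_n", ]
  cap <- rep(150, nrow(crops))
  cap[crops$lu_type %in% c("beans", "lentils")] <- 110
  cap[crops$lu_type == "chickpeas"] <- 100
  cap[crops$lu_type == "soybean"] <- 70
  cap[crops$lu_type %in% c("cowpeas", "pigeon_peas", "other_pulses")] <- 90
  tibble::tibble(lu_type = crops$lu_type, n_cap_kg_ha = cap)
}
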