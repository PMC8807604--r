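# Land-use-intensity surfaces: raw indicator construction (indicator
# Set 1, HANPP-based, and Set 2, input/output metrics), winsorization and
# scaling to [0, 1], and the piecewise-linear intensity response f(LUI).

# Anchor positions of the three categorical management levels on the
# scaled intensity gradient: Minimal at the centre of the 1st-33rd
# percentile band, Light of the 34th-66th, Intense of the 67th-99th.
LUI_ANCHORS <- c(minimal = 0.17, light = 0.5, intense = 0.83)

#' Constant HANPP intensity of built-up land
#'
#' For the HANPP-based indicator set, harvested/extracted biomass on
#' sealed land is taken as half of its actual NPP, with actual NPP one
#' third of the potential natural vegetation's NPP. The resulting
#' HANPP_harv/NPP_pot ratio is therefore the constant 1/6 (~17% of
#' NPP_pot), independent of local productivity.
#'
#' @param npp_pot Potential natural vegetation NPP (gC/m2/yr), > 0.
#'   Vectorised; only used for validation, the ratio does not depend on it.
#' @return The dimensionless ratio 1/6, recycled to `length(npp_pot)`.
#' @export
#' @examples
#' builtup_intensity_set1(500)
builtup_intensity_set1 <- function(npp_pot) {
  if (!is.numeric(npp_pot) || any(!is.finite(npp_pot)) || any(npp_pot <= 0)) {
    stop_input("`npp_pot` must be finite and positive")
  }
  rep(0.5 * (1 / 3), length(npp_pot))
}

#' Maximum harvestable fraction on grazed land
#'
#' Low-productivity rangeland supports a lower maximum offtake than
#' productive grassland: the maximum harvest fraction rises linearly
#' from 40% at 20 gC/m2 of grazing-accessible NPP to 80% at 250 gC/m2,
#' and is held at those bounds outside the ramp.
#'
#' @param accessible_npp Grazing-accessible NPP (gC/m2), >= 0. Vectorised.
#' @return Fraction in \[0.4, 0.8\].
#' @export
#' @examples
#' grazing_max_fraction(c(20, 135, 250))
grazing_max_fraction <- function(accessible_npp) {
  if (!is.numeric(accessible_npp) || any(!is.finite(accessible_npp)) ||
      any(accessible_npp < 0)) {
    stop_input("`accessible_npp` must be finite and non-negative")
  }
  frac <- 0.40 + (accessible_npp - 20) * (0.80 - 0.40) / (250 - 20)
  pmin(pmax(frac, 0.40), 0.80)
}

#' NPP accessible for grazing
#'
#' Only the aboveground, non-woody share of potential NPP can be grazed:
#' 50% of NPP_pot is removable aboveground, of which 30% is non-woody
#' under closed-canopy cover and 100% on open land.
#'
#' @param npp_pot Potential NPP (gC/m2/yr), >= 0. Vectorised.
#' @param canopy_openness `"open"` or `"closed"`, recycled against
#'   `npp_pot`.
#' @return Accessible NPP (gC/m2).
#' @export
#' @examples
#' accessible_npp(200, "open")   # 100
#' accessible_npp(200, "closed") # 30
accessible_npp <- function(npp_pot, canopy_openness) {
  if (!is.numeric(npp_pot) || any(!is.finite(npp_pot)) || any(npp_pot < 0)) {
    stop_input("`npp_pot` must be finite and non-negative")
  }
  if (!all(canopy_openness %in% c("open", "closed"))) {
    stop_input("`canopy_openness` must be \"open\" or \"closed\"")
  }
  nonwoody <- ifelse(canopy_openness == "closed", 0.3, 1.0)
  npp_pot * 0.5 * nonwoody
}

#' Allocate national forest harvest by biomass gap
#'
#' For the input/output indicator set, national forest harvest is
#' distributed over forest cells in proportion to each cell's share of
#' the national difference between potential and actual biomass stocks,
#' so the national total is conserved exactly.
#'
#' @param national_harvest A tibble with columns `country` and `harvest`
#'   (one row per country), or a single number when `gap` carries no
#'   country column.
#' @param gap A tibble with columns `cell_id`, `country` and `gap`
#'   (potential minus actual biomass, >= 0), or a numeric vector of gaps
#'   for a single country.
#' @return A tibble `cell_id`, `country`, `harvest` (same cell order as
#'   `gap`).
#' @export
#' @examples
#' allocate_forest_harvest_by_biomass_gap(8, c(3, 1)) # 6, 2
allocate_forest_harvest_by_biomass_gap <- function(national_harvest, gap) {
  if (is.numeric(gap)) {
    gap <- tibble::tibble(
      cell_id = seq_along(gap), country = "all", gap = as.double(gap)
    )
  }
  if (is.numeric(national_harvest)) {
    assert_scalar_number(national_harvest, "national_harvest", min = 0)
    national_harvest <- tibble::tibble(
      country = unique(gap$country), harvest = national_harvest
    )
  }
  assert_columns(gap, c("cell_id", "country", "gap"), "gap")
  assert_columns(national_harvest, c("country", "harvest"), "national_harvest")
  if (any(!is.finite(gap$gap)) || any(gap$gap < 0)) {
    stop_input("biomass gaps must be finite and non-negative")
  }
  totals <- stats::aggregate(gap["gap"], by = gap["country"], FUN = sum)
  merged <- dplyr::left_join(totals, national_harvest, by = "country")
  merged$harvest[is.na(merged$harvest)] <- 0
  bad <- merged$country[merged$harvest > 0 & merged$gap <= 0]
  if (length(bad) > 0L) {
    stop_input(sprintf(
      "country with positive harvest but all-zero biomass gaps: %s",
      paste(bad, collapse = ", ")
    ))
  }
  out <- dplyr::left_join(
    gap,
    dplyr::rename(merged, gap_total = "gap"),
    by = "country"
  )
  out$harvest <- ifelse(
    out$gap_total > 0,
    out$harvest * out$gap / out$gap_total,
    0
  )
  tibble::as_tibble(out[, c("cell_id", "country", "harvest")])
}

#' Winsorization thresholds for an intensity surface
#'
#' Builds the saturation threshold T for every (set, cell, lu_type) row
#' of a raw intensity surface; `winsorize_and_scale()` then maps raw
#' values to `min(raw, T) / T`. Thresholds follow the indicator-set
#' rules:
#' \describe{
#'   \item{Set 1 cropland/plantation crops}{maximum intensity at
#'     harvesting 100% of NPP_pot, i.e. T = 1 on the HANPP ratio scale.}
#'   \item{Set 1 forests}{sustainable aboveground harvest limited to 30%
#'     of NPP_pot, multiplied by a per-biome belowground factor
#'     (default 1).}
#'   \item{Set 1 grazing land/pastures}{removal of all
#'     grazing-accessible NPP: T = `grazing_max_fraction(accNPP)` x
#'     accNPP / NPP_pot.}
#'   \item{Set 2 crops}{nitrogen caps from [default_n_caps()] (150 kg
#'     N/ha, lower for legumes).}
#'   \item{Set 2 grazing land/pastures}{the per-biome 80th percentile of
#'     livestock density.}
#'   \item{Set 2 builtup}{not winsorized (the raw density fraction is
#'     already in \[0, 1\]).}
#'   \item{Set 2 forests}{the per-country maximum of the biomass-gap
#'     harvest intensity (a synthetic-data convention; real-data users
#'     supply their own forest threshold).}
#' }
#' @keywords internal
intensity_thresholds <- function(surface, catalogue = lu_catalogue(),
                                 grid = NULL,
                                 n_caps = default_n_caps(catalogue),
                                 forest_belowground_factor = 1.0) {
  assert_columns(surface, c("set_id", "cell_id", "lu_type", "raw_value"),
                 "surface")
  cat_cols <- catalogue[, c("lu_type", "broad_type", "set2_metric")]
  s <- dplyr::left_join(surface, cat_cols, by = "lu_type")
  if (anyNA(s$broad_type)) {
    stop_input(sprintf(
      "intensity surface contains lu_type(s) absent from the catalogue: %s",
      paste(unique(s$lu_type[is.na(s$broad_type)]), collapse = ", ")
    ))
  }
  grass <- s$broad_type %in% c("grazing land", "pastures")

  threshold <- rep(NA_real_, nrow(s))

  # --- HANPP-based set -------------------------------------------------
  set1 <- s$set_id == "Set1"
  threshold[set1 & !grass & s$broad_type != "forests" &
              s$lu_type != "timber_plantation"] <- 1.0
  forest1 <- set1 & (s$broad_type == "forests" |
                       s$lu_type == "timber_plantation")
  if (any(forest1)) {
    fbf <- forest_belowground_factor
    if (length(fbf) > 1L) {
      if (is.null(fbf) || is.null(names(fbf)) || is.null(grid) ||
          !"biome_label" %in% names(grid)) {
        stop_input(paste(
          "per-biome forest belowground factors require a named vector",
          "and a grid with `biome_label`"
        ))
      }
      biome <- setNames(grid$biome_label, grid$cell_id)
      fbf <- unname(fbf[biome[as.character(s$cell_id[forest1])]])
      if (anyNA(fbf)) {
        stop_input("missing forest belowground factor for some biome")
      }
    }
    threshold[forest1] <- 0.30 * fbf
  }
  if (any(set1 & grass)) {
    need <- c("npp_pot", "canopy_openness")
    assert_columns(s, need, "surface (Set 1 grazing rows)")
    acc <- accessible_npp(s$npp_pot[set1 & grass],
                          s$canopy_openness[set1 & grass])
    threshold[set1 & grass] <-
      grazing_max_fraction(acc) * acc / s$npp_pot[set1 & grass]
  }

  # --- input/output set ------------------------------------------------
  set2 <- s$set_id == "Set2"
  crop2 <- set2 & s$set2_metric == "crop_n"
  if (any(crop2)) {
    caps <- setNames(n_caps$n_cap_kg_ha, n_caps$lu_type)
    missing <- setdiff(unique(s$lu_type[crop2]), names(caps))
    if (length(missing) > 0L) {
      stop_input(sprintf("no nitrogen cap supplied for crop type(s): %s",
                         paste(missing, collapse = ", ")))
    }
    threshold[crop2] <- caps[s$lu_type[crop2]]
  }
  grass2 <- set2 & grass
  if (any(grass2)) {
    biome <- if (!is.null(grid) && "biome_label" %in% names(grid)) {
      setNames(grid$biome_label, grid$cell_id)[as.character(s$cell_id)]
    } else {
      rep("all", nrow(s))
    }
    q80 <- tapply(s$raw_value[grass2], biome[grass2],
                  stats::quantile, probs = 0.8, names = FALSE)
    threshold[grass2] <- q80[as.character(biome[grass2])]
  }
  builtup2 <- set2 & s$broad_type == "builtup"
  threshold[builtup2] <- 1.0  # pass-through: raw density is a fraction
  forest2 <- set2 & s$set2_metric == "forest_harvest"
  if (any(forest2)) {
    mx <- tapply(s$raw_value[forest2], s$lu_type[forest2], max)
    threshold[forest2] <- pmax(mx[s$lu_type[forest2]], .Machine$double.eps)
  }

  if (anyNA(threshold) || any(threshold <= 0)) {
    bad <- unique(s$lu_type[is.na(threshold) | threshold <= 0])
    stop_input(sprintf("missing or non-positive threshold for: %s",
                       paste(bad, collapse = ", ")))
  }
  threshold
}

#' Winsorize raw intensity indicators and scale to \[0, 1\]
#'
#' Raw land-use-intensity indicators are capped (winsorized) at a
#' type-specific saturation threshold -- the intensity above which no
#' further species loss is assumed -- and then divided by it, yielding a
#' dimensionless index LUI in \[0, 1\].
#'
#' @param surface Raw intensity surface: tibble with `set_id`
#'   (`"Set1"`/`"Set2"`), `cell_id`, `lu_type`, `raw_value` and, for Set
#'   1 grazing rows, `npp_pot` and `canopy_openness` auxiliaries.
#' @param catalogue Land-use catalogue ([lu_catalogue()]).
#' @param grid Optional grid table; its `biome_label` drives the
#'   per-biome livestock-density percentile threshold.
#' @param n_caps Nitrogen caps table ([default_n_caps()]).
#' @param forest_belowground_factor Multiplier on the 30%-of-NPP_pot
#'   forest threshold accounting for belowground biomass destroyed by
#'   forestry; per-biome values may be supplied via a vector named by
#'   biome (default a neutral 1).
#' @return The surface with columns `threshold` and `lui` added;
#'   `lui = min(raw_value, threshold) / threshold`.
#' @export
winsorize_and_scale <- function(surface, catalogue = lu_catalogue(),
                                grid = NULL,
                                n_caps = default_n_caps(catalogue),
                                forest_belowground_factor = 1.0) {
  if (any(!is.finite(surface$raw_value)) || any(surface$raw_value < 0)) {
    stop_input("raw intensity values must be finite and non-negative")
  }
  threshold <- intensity_thresholds(
    surface, catalogue, grid, n_caps, forest_belowground_factor
  )
  out <- surface
  out$threshold <- threshold
  out$lui <- pmin(out$raw_value, threshold) / threshold
  tibble::as_tibble(out)
}

#' Build the piecewise-linear intensity response f(LUI)
#'
#' Converts categorical richness estimates at the Minimal, Light and
#' Intense management levels into a continuous response over the scaled
#' intensity gradient. The three levels are anchored at LUI = 0.17, 0.5
#' and 0.83; within a response class the relative richness is
#' `s_light = est_light/est_minimal` at 0.5 and
#' `s_intense = est_intense/est_minimal` at 0.83, linearly interpolated
#' between anchors. Below 0.17 the response is held at 1 (all affiliated
#' species persist under minimal management); above 0.83 it is held at
#' `s_intense` (no extrapolation beyond the measured intensity range).
#' Ratios above 1 are clipped to 1 with a warning.
#'
#' @param coeffs Coefficient table with columns `response_class`,
#'   `est_minimal`, `est_light`, `est_intense`
#'   ([default_response_coefficients()]).
#' @return A function `f(lui, response_class)`, vectorised over both
#'   arguments, returning values in \[0, 1\]. The returned function
#'   carries the per-class segment intercepts and slopes as attribute
#'   `"segments"`.
#' @export
#' @examples
#' f <- build_response_function(default_response_coefficients())
#' f(c(0, 0.17, 0.5, 0.83, 1), "cropland")
build_response_function <- function(coeffs = default_response_coefficients()) {
  assert_columns(
    coeffs,
    c("response_class", "est_minimal", "est_light", "est_intense"),
    "coeffs"
  )
  if (any(coeffs$est_minimal == 0)) {
    stop_input("`est_minimal` must be non-zero for every response class")
  }
  s_light <- coeffs$est_light / coeffs$est_minimal
  s_intense <- coeffs$est_intense / coeffs$est_minimal
  if (any(s_light > 1 | s_intense > 1)) {
    rlang::warn(paste(
      "richness ratio above 1 under intensification;",
      "clipping the response at 1"
    ))
    s_light <- pmin(s_light, 1)
    s_intense <- pmin(s_intense, 1)
  }
  if (any(s_light <= 0 | s_intense <= 0)) {
    rlang::warn("non-positive richness ratio; clipping the response at 0")
    s_light <- pmax(s_light, 0)
    s_intense <- pmax(s_intense, 0)
  }
  a <- LUI_ANCHORS
  seg <- tibble::tibble(
    response_class = coeffs$response_class,
    s_light = s_light,
    s_intense = s_intense,
    # segment 1: (0.17, 1) -> (0.5, s_light)
    slope1 = (s_light - 1) / (a[["light"]] - a[["minimal"]]),
    int1 = 1 - (s_light - 1) / (a[["light"]] - a[["minimal"]]) * a[["minimal"]],
    # segment 2: (0.5, s_light) -> (0.83, s_intense)
    slope2 = (s_intense - s_light) / (a[["intense"]] - a[["light"]]),
    int2 = s_light -
      (s_intense - s_light) / (a[["intense"]] - a[["light"]]) * a[["light"]]
  )

  f <- function(lui, response_class) {
    if (any(!is.finite(lui)) || any(lui < 0 | lui > 1)) {
      stop_input("`lui` must lie in [0, 1]")
    }
    idx <- match(response_class, seg$response_class)
    if (anyNA(idx)) {
      stop_input(sprintf(
        "unknown response class(es): %s",
        paste(unique(response_class[is.na(idx)]), collapse = ", ")
      ))
    }
    if (length(idx) == 1L) idx <- rep(idx, length(lui))
    val <- ifelse(
      lui <= a[["minimal"]],
      1,
      ifelse(
        lui <= a[["light"]],
        seg$int1[idx] + seg$slope1[idx] * lui,
        ifelse(
          lui <= a[["intense"]],
          seg$int2[idx] + seg$slope2[idx] * lui,
          seg$s_intense[idx]
        )
      )
    )
    pmin(pmax(val, 0), 1)
  }
  attr(f, "segments") <- seg
  f
}
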