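# Per-species native area-of-habitat loss: stochastic rounding of the
# modelled loss counts, randomized draws of individual species per cell,
# and resampling confidence intervals over repeated runs.

#' Stochastic (expectation-preserving) rounding
#'
#' Rounds a non-negative real target up with probability equal to its
#' fractional part, down otherwise, so that the expectation of the
#' rounded value equals the input. This avoids systematically rounding
#' sub-0.5 loss targets to zero in species-poor cells.
#'
#' @param x Non-negative numeric vector.
#' @return Integer vector; `E[stochastic_round(x)] = x` elementwise.
#' @export
#' @examples
#' set.seed(1)
#' mean(replicate(1000, stochastic_round(0.3)))
stochastic_round <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_input("`x` must be finite and non-negative")
  }
  lo <- floor(x)
  frac <- x - lo
  as.integer(lo + (stats::runif(length(x)) < frac))
}

# Precompute the draw context: per (cell, taxon, fine type) real-valued
# conversion and intensification targets, and per (cell, taxon, broad
# type) affiliated / unaffiliated species index lists.
build_draw_context <- function(pool, loss) {
  stopifnot(inherits(pool, "species_pool"), inherits(loss, "loss_result"))
  att <- loss$attribution
  att <- att[att$loss_conv > 0 | att$loss_int > 0, , drop = FALSE]

  species_ids <- sort(unique(pool$membership$species_id))
  sp_index <- setNames(seq_along(species_ids), species_ids)

  # membership split by (cell, taxon); affiliation flags per broad type
  m <- pool$membership
  m$sp <- sp_index[m$species_id]
  key <- paste(m$cell_id, m$taxon_group, sep = "\r")
  members <- split(m$sp, key)
  aff_flags <- lapply(broad_lu_types(), function(b) {
    part <- partition_affiliation_lists(pool, b)
    split(part$affiliated, paste(part$cell_id, part$taxon_group,
                                 sep = "\r"))
  })
  names(aff_flags) <- broad_lu_types()

  list(
    attribution = att,
    species_ids = species_ids,
    members = members,
    aff_flags = aff_flags
  )
}

#' Draw individual lost species for one run
#'
#' Within each cell (and taxonomic group), land-use types are visited in
#' a random order; for each type the stochastically rounded conversion
#' target is drawn uniformly without replacement from the species
#' unaffiliated with the type, then the intensification target from the
#' affiliated species. A species can be drawn at most once per cell,
#' whatever the type or cause; when fewer eligible species remain than
#' the target, all remaining are drawn and the shortfall is recorded.
#'
#' @param context Draw context from `build_draw_context()` (internal);
#'   most users call [run_aoh_draws()] instead.
#' @param run_id Integer run index (used only for labelling).
#' @return A list with `losses` (tibble `cell_id`, `taxon_group`,
#'   `species_id`, `lu_type`, `broad_type`, `cause`) and `shortfall`
#'   (total undrawable target count).
#' @keywords internal
draw_lost_species_run <- function(context, run_id = 1L) {
  att <- context$attribution
  n <- nrow(att)
  if (n == 0L) {
    return(list(
      losses = tibble::tibble(
        cell_id = integer(), taxon_group = character(),
        species_id = character(), lu_type = character(),
        broad_type = character(), cause = character()
      ),
      shortfall = 0L
    ))
  }
  t_conv <- stochastic_round(att$loss_conv)
  t_int <- stochastic_round(att$loss_int)
  active <- which(t_conv > 0L | t_int > 0L)
  if (length(active) == 0L) {
    return(list(
      losses = tibble::tibble(
        cell_id = integer(), taxon_group = character(),
        species_id = character(), lu_type = character(),
        broad_type = character(), cause = character()
      ),
      shortfall = 0L
    ))
  }
  keys <- paste(att$cell_id, att$taxon_group, sep = "\r")
  groups <- split(active, keys[active])

  out_sp <- integer(0)
  out_row <- integer(0)
  out_cause <- character(0)
  shortfall <- 0L

  for (key in names(groups)) {
    rows <- groups[[key]]
    # randomly iterate the sequence by which land-use types are considered
    rows <- rows[sample.int(length(rows))]
    pool_sp <- context$members[[key]]
    drawn <- integer(0)
    for (i in rows) {
      b <- att$broad_type[i]
      flags <- context$aff_flags[[b]][[key]]
      for (cause in c("conversion", "intensification")) {
        target <- if (cause == "conversion") t_conv[i] else t_int[i]
        if (target == 0L) next
        eligible <- if (cause == "conversion") {
          pool_sp[!flags]
        } else {
          pool_sp[flags]
        }
        eligible <- setdiff(eligible, drawn)
        k <- min(target, length(eligible))
        if (k < target) shortfall <- shortfall + (target - k)
        if (k == 0L) next
        pick <- eligible[sample.int(length(eligible), k)]
        drawn <- c(drawn, pick)
        out_sp <- c(out_sp, pick)
        out_row <- c(out_row, rep.int(i, k))
        out_cause <- c(out_cause, rep.int(cause, k))
      }
    }
    if (anyDuplicated(drawn)) {
      stop_internal("species drawn twice within one cell and run")
    }
  }
  list(
    losses = tibble::tibble(
      cell_id = att$cell_id[out_row],
      taxon_group = att$taxon_group[out_row],
      species_id = context$species_ids[out_sp],
      lu_type = att$lu_type[out_row],
      broad_type = att$broad_type[out_row],
      cause = out_cause
    ),
    shortfall = shortfall
  )
}

#' Repeated randomized draws of lost species
#'
#' Repeats the stochastic-rounding + random-draw procedure `n_runs`
#' times (default 100) with per-run seeds derived deterministically from
#' the master seed, and returns all per-run losses for summarisation.
#'
#' @param pool A `species_pool` with affinity fractions.
#' @param loss A `loss_result` from [decompose_conversion_intensity()].
#' @param n_runs Number of repeated runs (>= 2).
#' @param seed Master seed.
#' @return A list of class `aoh_draws`: `runs` (tibble of per-run
#'   losses with a `run_id` column), `n_runs`, `shortfalls` (per-run
#'   undrawable counts).
#' @export
run_aoh_draws <- function(pool, loss, n_runs = 100L, seed = 1L) {
  assert_scalar_number(n_runs, "n_runs", min = 2)
  n_runs <- as.integer(n_runs)
  context <- build_draw_context(pool, loss)
  runs <- vector("list", n_runs)
  shortfalls <- integer(n_runs)
  for (run in seq_len(n_runs)) {
    res <- with_stream(seed, paste0("aoh-run-", run), {
      draw_lost_species_run(context, run)
    })
    res$losses$run_id <- run
    runs[[run]] <- res$losses
    shortfalls[run] <- res$shortfall
  }
  if (sum(shortfalls) > 0L) {
    rlang::inform(sprintf(
      "draw shortfall: %d target(s) exceeded the eligible list across %d run(s)",
      sum(shortfalls), sum(shortfalls > 0)
    ), class = "csarlui_shortfall")
  }
  structure(
    list(runs = dplyr::bind_rows(runs), n_runs = n_runs,
         shortfalls = shortfalls),
    class = "aoh_draws"
  )
}

#' Summarise repeated draws into per-species AOH loss
#'
#' For each run and species, the lost area is the sum of terrestrial
#' areas of the cells the species was drawn in; across runs the mean and
#' the 0.025/0.975 empirical quantiles are computed and divided by the
#' species' native area of habitat, giving proportional AOH loss with a
#' 95% confidence interval. Species whose interval reaches 100% are
#' flagged as facing impending global extinction. Per-cause and
#' per-broad-type means are reported alongside.
#'
#' @param draws An `aoh_draws` object.
#' @param pool The `species_pool` the draws were made from.
#' @param grid Grid table (cell areas).
#' @return Tibble per species: `species_id`, `taxon_group`,
#'   `iucn_category`, `native_aoh_area`, `mean_loss_fraction`, `ci_low`,
#'   `ci_high`, `impending_global_extinction`, per-cause columns
#'   (`loss_conversion`, `loss_intensification`) and one `loss_<broad
#'   type>` column per broad type (all fractions of native AOH).
#' @export
summarize_runs <- function(draws, pool, grid) {
  stopifnot(inherits(draws, "aoh_draws"), inherits(pool, "species_pool"))
  if (draws$n_runs < 2L) stop_input("need at least 2 runs to summarise")
  areas <- setNames(grid$area_pot, grid$cell_id)
  base <- pool$native_aoh
  if (any(base$native_aoh_area <= 0)) {
    stop_internal("species with non-positive native area of habitat")
  }
  r <- draws$runs
  r$area <- areas[as.character(r$cell_id)]

  per_run <- function(sub) {
    # species x run lost-area matrix, absent runs contributing zero
    agg <- dplyr::summarise(
      dplyr::group_by(sub, .data$species_id, .data$run_id),
      area = sum(.data$area), .groups = "drop"
    )
    mat <- matrix(0, nrow = nrow(base), ncol = draws$n_runs,
                  dimnames = list(base$species_id, NULL))
    if (nrow(agg) > 0L) {
      mat[cbind(match(agg$species_id, base$species_id), agg$run_id)] <-
        agg$area
    }
    mat
  }

  total <- per_run(r)
  mean_frac <- unname(rowMeans(total)) / base$native_aoh_area
  qs <- apply(total, 1, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  ci_low <- unname(qs[1, ]) / base$native_aoh_area
  ci_high <- unname(qs[2, ]) / base$native_aoh_area

  out <- tibble::tibble(
    species_id = base$species_id,
    native_aoh_area = base$native_aoh_area,
    mean_loss_fraction = mean_frac,
    ci_low = ci_low,
    ci_high = ci_high,
    impending_global_extinction = ci_high >= 1 - 1e-12
  )
  sp_meta <- pool$species[, c("species_id", "taxon_group", "iucn_category")]
  out <- dplyr::left_join(out, sp_meta, by = "species_id")

  for (cz in c("conversion", "intensification")) {
    mat <- per_run(r[r$cause == cz, , drop = FALSE])
    out[[paste0("loss_", cz)]] <- unname(rowMeans(mat)) /
      base$native_aoh_area
  }
  for (b in broad_lu_types()) {
    mat <- per_run(r[r$broad_type == b, , drop = FALSE])
    col <- paste0("loss_", gsub(" ", "_", b))
    out[[col]] <- unname(rowMeans(mat)) / base$native_aoh_area
  }
  out[, c("species_id", "taxon_group", "iucn_category", "native_aoh_area",
          "mean_loss_fraction", "ci_low", "ci_high",
          "impending_global_extinction",
          "loss_conversion", "loss_intensification",
          paste0("loss_", gsub(" ", "_", broad_lu_types())))]
}
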