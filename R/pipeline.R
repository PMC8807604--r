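# End-to-end pipeline: synthetic generation (or CSV ingestion), pool
# refinement, intensity scaling, cSAR decomposition per scenario and
# indicator set, randomized AOH draws, and summary tables, driven by a
# YAML configuration.

#' Default pipeline configuration
#'
#' @return Nested list accepted by [run_pipeline()]: a `synthetic` block
#'   (cells, species, fine types, scenario parameter overrides) or an
#'   `input_dir` with CSV tables; `sets` (indicator sets to run),
#'   `scenarios`, `aoh_runs` (number of randomized draw repetitions),
#'   `seed`, `thresholds` (exceedance thresholds in %), and `out_dir`
#'   (optional; when set, all artifacts are written as CSV/YAML).
#' @export
default_pipeline_config <- function() {
  list(
    synthetic = list(n_cells = 400L, n_species = 100L, n_lu_types = 45L,
                     scenario_params = list()),
    input_dir = NULL,
    sets = c("Set1", "Set2"),
    scenarios = c("current", "conversion_only", "full_intensification"),
    aoh_runs = 100L,
    seed = 1L,
    thresholds = c(50),
    out_dir = NULL
  )
}

validate_config <- function(config) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (is.null(cfg$synthetic) && is.null(cfg$input_dir)) {
    stop_input("config needs either a `synthetic` block or an `input_dir`")
  }
  if (!all(cfg$sets %in% c("Set1", "Set2"))) {
    stop_input("`sets` must be a subset of Set1, Set2")
  }
  if (!all(cfg$scenarios %in% c("current", "conversion_only",
                                "full_intensification"))) {
    stop_input("unknown scenario in `scenarios`")
  }
  assert_scalar_number(cfg$aoh_runs, "aoh_runs", min = 2)
  assert_scalar_number(cfg$seed, "seed")
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes generation/ingestion, pool refinement, intensity scaling
#' (per configured indicator set), the cSAR conversion/intensity
#' decomposition (per configured scenario), the randomized
#' area-of-habitat draws (on the `current` scenario), and the summary
#' statistics. All stages are deterministic given the config seed;
#' identical configs yield byte-identical outputs.
#'
#' @param config A config list (see [default_pipeline_config()]) or the
#'   path to a YAML file holding one.
#' @return A list of class `csar_pipeline_result`: `landscape`, `pool`,
#'   `lui` (per set), `loss` (per set x scenario), `aoh` (per set),
#'   `summary` (per set and, with two sets, their mean and per-cell
#'   difference layer), `provenance`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop_input(sprintf("config file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config(config)

  landscape <- if (!is.null(cfg$input_dir)) {
    read_landscape(cfg$input_dir)
  } else {
    generate_landscape(
      n_cells = cfg$synthetic$n_cells,
      n_species = cfg$synthetic$n_species,
      n_lu_types = cfg$synthetic$n_lu_types %||% 45L,
      seed = cfg$seed,
      scenario_params = cfg$synthetic$scenario_params %||% list()
    )
  }
  grid <- landscape$grid
  lu <- landscape$lu
  catalogue <- landscape$catalogue

  pool <- withCallingHandlers(
    compute_affinity_fractions(refine_species_pool(landscape$species, grid)),
    csarlui_empty_cells = function(c) invokeRestart("muffleMessage")
  )

  scaled <- list()
  for (set in cfg$sets) {
    surf <- landscape$intensity[landscape$intensity$set_id == set, ,
                                drop = FALSE]
    scaled[[set]] <- winsorize_and_scale(surf, catalogue, grid)
  }

  loss <- list()
  for (set in cfg$sets) {
    for (scn in cfg$scenarios) {
      loss[[paste(set, scn, sep = ".")]] <- decompose_conversion_intensity(
        pool, grid, lu, scaled[[set]], scenario = scn
      )
    }
  }

  aoh <- list()
  for (set in cfg$sets) {
    key <- paste(set, "current", sep = ".")
    if (!key %in% names(loss)) next
    draws <- withCallingHandlers(
      run_aoh_draws(pool, loss[[key]], n_runs = cfg$aoh_runs,
                    seed = derive_seed(cfg$seed, paste0("aoh-", set))),
      csarlui_shortfall = function(c) invokeRestart("muffleMessage")
    )
    aoh[[set]] <- summarize_runs(draws, pool, grid)
  }

  summary <- list()
  for (set in cfg$sets) {
    key <- paste(set, "current", sep = ".")
    if (!key %in% names(loss)) next
    s <- area_weighted_summary(loss[[key]], grid)
    for (th in cfg$thresholds) {
      s[[sprintf("share_area_exceeding_%g_pct", th)]] <-
        threshold_exceedance_share(loss[[key]], grid, th)
    }
    summary[[set]] <- s
  }
  if (all(c("Set1", "Set2") %in% names(summary))) {
    c1 <- cell_relative_loss(loss[["Set1.current"]])
    c2 <- cell_relative_loss(loss[["Set2.current"]])
    diff <- dplyr::left_join(
      c1[, c("cell_id", "s_pot", "s_loss")],
      dplyr::rename(c2[, c("cell_id", "s_loss")], s_loss_2 = "s_loss"),
      by = "cell_id"
    )
    diff$rel_loss_diff_pct <- ifelse(
      diff$s_pot > 0,
      100 * (diff$s_loss - diff$s_loss_2) / diff$s_pot, NA_real_
    )
    summary$set_difference <- diff[, c("cell_id", "rel_loss_diff_pct")]
    summary$mean_of_sets <- tibble::tibble(
      mean_relative_loss_pct = mean(c(
        summary$Set1$mean_relative_loss_pct,
        summary$Set2$mean_relative_loss_pct
      ))
    )
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("csarlui")),
    seed = cfg$seed,
    sets = cfg$sets,
    scenarios = cfg$scenarios,
    aoh_runs = cfg$aoh_runs,
    n_cells = nrow(grid),
    n_species = nrow(landscape$species)
  )

  result <- structure(
    list(landscape = landscape, pool = pool, lui = scaled, loss = loss,
         aoh = aoh, summary = summary, provenance = provenance),
    class = "csar_pipeline_result"
  )

  if (!is.null(cfg$out_dir)) {
    write_pipeline_outputs(result, cfg$out_dir)
  }
  result
}

#' @export
print.csar_pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<csar_pipeline_result> %d cells, %d species; sets: %s\n",
    x$provenance$n_cells, x$provenance$n_species,
    paste(x$provenance$sets, collapse = ", ")
  ))
  for (set in x$provenance$sets) {
    s <- x$summary[[set]]
    if (!is.null(s)) {
      cat(sprintf(
        "  %s: mean loss %.2f%% (conversion %.2f + intensity %.2f %%-pts)\n",
        set, s$mean_relative_loss_pct, s$mean_conversion_component_pct,
        s$mean_intensity_component_pct
      ))
    }
  }
  invisible(x)
}

# Write per-cell tables, per-species tables, summaries and a provenance
# log under out_dir.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_landscape(result$landscape, file.path(out_dir, "landscape"))
  write_membership(result$pool, file.path(out_dir, "membership.csv"))
  for (set in names(result$lui)) {
    readr::write_csv(result$lui[[set]],
                     file.path(out_dir, sprintf("lui_%s.csv", set)))
  }
  for (key in names(result$loss)) {
    readr::write_csv(result$loss[[key]]$cells,
                     file.path(out_dir, sprintf("loss_%s.csv", key)))
    readr::write_csv(result$loss[[key]]$attribution,
                     file.path(out_dir, sprintf("attribution_%s.csv", key)))
  }
  for (set in names(result$aoh)) {
    readr::write_csv(result$aoh[[set]],
                     file.path(out_dir, sprintf("aoh_%s.csv", set)))
  }
  for (nm in names(result$summary)) {
    obj <- result$summary[[nm]]
    if (is.data.frame(obj)) {
      readr::write_csv(obj, file.path(out_dir, sprintf("summary_%s.csv",
                                                       nm)))
    }
  }
  yaml::write_yaml(result$provenance, file.path(out_dir, "provenance.yaml"))
  invisible(out_dir)
}
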