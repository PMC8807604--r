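fabricate_loss <- function(attribution) {
  structure(
    list(cells = NULL, attribution = attribution, scenario_id = "current"),
    class = "loss_result"
  )
}

att_row <- function(cell_id, lu_type, broad_type, loss_conv, loss_int,
                    taxon = "birds") {
  tibble::tibble(
    cell_id = cell_id, taxon_group = taxon, lu_type = lu_type,
    broad_type = broad_type, loss_total = loss_conv + loss_int,
    loss_conv = loss_conv, loss_int = loss_int
  )
}

test_that("stochastic rounding preserves expectation and adjacency", {
  expect_identical(stochastic_round(c(2, 0, 7)), c(2L, 0L, 7L))
  set.seed(1)
  draws <- replicate(2000, stochastic_round(2.7))
  expect_true(all(draws %in% c(2L, 3L)))
  set.seed(2)
  reps <- replicate(10000, stochastic_round(0.3))
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(mean(reps) - 0.3), 3 * se)
  expect_error(stochastic_round(-0.1), "non-negative")
})

test_that("two eligible species are drawn with probability 1/2 each", {
  tc <- generate_known_truth_case("two-species-draw-oracle")
  pool <- compute_affinity_fractions(refine_species_pool(tc$species, tc$grid))
  loss <- fabricate_loss(att_row(1L, "wheat", "cropland", 0, 1))
  n <- 10000L
  draws <- run_aoh_draws(pool, loss, n_runs = n, seed = 99)
  freq <- table(draws$runs$species_id) / n
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(freq[["sp_0001"]] - 0.5), 3 * se)
  expect_lt(abs(freq[["sp_0002"]] - 0.5), 3 * se)
  expect_equal(nrow(draws$runs), n)  # exactly one loss per run
})

test_that("draw frequencies match exhaustive enumeration over type orders", {
  # One cell, two types with an intensification target of 1 each.
  # Species A is cropland-affiliated, B is not (forests admit both).
  # Enumerating the two type orders and all uniform draws by hand:
  # cropland first -> {A, B} with probability 1; forests first -> A is
  # drawn by forests with p = 1/2 (then cropland finds nobody eligible)
  # else B by forests then A by cropland. Hence P(A) = 1, P(B) = 0.75.
  grid <- make_grid(1, area_pristine = 0.2e8)
  lu <- tibble::tibble(
    cell_id = 1L, lu_type = c("wheat", "forest_used"),
    broad_type = c("cropland", "forests"),
    response_class = c("cropland", "plantation"),
    converted = c(TRUE, FALSE), area = c(0.4e8, 0.4e8)
  )
  sp <- make_species_table(
    list(id = "A", cells = 1L, lu = "cropland"),
    list(id = "B", cells = 1L)
  )
  pool <- compute_affinity_fractions(refine_species_pool(sp, grid))
  loss <- fabricate_loss(dplyr::bind_rows(
    att_row(1L, "wheat", "cropland", 0, 1),
    att_row(1L, "forest_used", "forests", 0, 1)
  ))
  n <- 10000L
  draws <- suppressMessages(run_aoh_draws(pool, loss, n_runs = n, seed = 4))
  pA <- sum(draws$runs$species_id == "A") / n
  pB <- sum(draws$runs$species_id == "B") / n
  expect_equal(pA, 1)
  expect_lt(abs(pB - 0.75), 3 * sqrt(0.75 * 0.25 / n))
  # shortfalls occur exactly when forests drew A first
  expect_lt(abs(mean(draws$shortfalls) - 0.25),
            3 * sqrt(0.25 * 0.75 / n))
})

test_that("targets beyond the eligible list draw everyone exactly once", {
  tc <- generate_known_truth_case("two-species-draw-oracle")
  pool <- compute_affinity_fractions(refine_species_pool(tc$species, tc$grid))
  loss <- fabricate_loss(att_row(1L, "wheat", "cropland", 0, 5))
  expect_message(
    draws <- run_aoh_draws(pool, loss, n_runs = 10, seed = 1),
    "shortfall"
  )
  per_run <- table(draws$runs$run_id)
  expect_true(all(per_run == 2))
  expect_false(any(duplicated(
    draws$runs[, c("run_id", "cell_id", "species_id")]
  )))
  expect_true(all(draws$shortfalls == 3L))
})

test_that("zero targets yield an empty loss set", {
  tc <- generate_known_truth_case("two-species-draw-oracle")
  pool <- compute_affinity_fractions(refine_species_pool(tc$species, tc$grid))
  loss <- fabricate_loss(att_row(1L, "wheat", "cropland", 0, 0))
  draws <- run_aoh_draws(pool, loss, n_runs = 5, seed = 1)
  expect_equal(nrow(draws$runs), 0L)
})

test_that("no species is ever drawn twice in a cell within one run", {
  ls <- generate_landscape(n_cells = 40, n_species = 50, seed = 3)
  pool <- suppressMessages(
    compute_affinity_fractions(refine_species_pool(ls$species, ls$grid))
  )
  lui <- winsorize_and_scale(
    ls$intensity[ls$intensity$set_id == "Set1", ], ls$catalogue, ls$grid
  )
  res <- decompose_conversion_intensity(pool, ls$grid, ls$lu, lui)
  draws <- suppressMessages(run_aoh_draws(pool, res, n_runs = 30, seed = 8))
  expect_false(any(duplicated(
    draws$runs[, c("run_id", "cell_id", "species_id")]
  )))
})

test_that("averaged over runs, drawn counts are unbiased for the targets", {
  grid <- make_grid(1, area_pristine = 0.4e8)
  lu <- tibble::tibble(
    cell_id = 1L, lu_type = "wheat", broad_type = "cropland",
    response_class = "cropland", converted = TRUE, area = 0.6e8
  )
  rows <- lapply(1:6, function(i) {
    list(id = sprintf("s%d", i), cells = 1L,
         lu = if (i <= 3) "cropland" else character())
  })
  sp <- do.call(make_species_table, rows)
  pool <- compute_affinity_fractions(refine_species_pool(sp, grid))
  loss <- fabricate_loss(att_row(1L, "wheat", "cropland", 0.6, 0.9))
  n <- 2000L
  draws <- run_aoh_draws(pool, loss, n_runs = n, seed = 12)
  mean_drawn <- nrow(draws$runs) / n
  se <- sqrt((0.6 * 0.4 + 0.9 * 0.1) / n)
  expect_lt(abs(mean_drawn - 1.5), 3 * se)
})

test_that("draws are deterministic in the seed and blind to input order", {
  ls <- generate_landscape(n_cells = 30, n_species = 40, seed = 6)
  pool <- suppressMessages(
    compute_affinity_fractions(refine_species_pool(ls$species, ls$grid))
  )
  lui <- winsorize_and_scale(
    ls$intensity[ls$intensity$set_id == "Set2", ], ls$catalogue, ls$grid
  )
  res <- decompose_conversion_intensity(pool, ls$grid, ls$lu, lui)
  d1 <- suppressMessages(run_aoh_draws(pool, res, n_runs = 10, seed = 5))
  d2 <- suppressMessages(run_aoh_draws(pool, res, n_runs = 10, seed = 5))
  expect_identical(d1$runs, d2$runs)

  shuffled <- ls$species[rev(seq_len(nrow(ls$species))), ]
  pool_s <- suppressMessages(
    compute_affinity_fractions(refine_species_pool(shuffled, ls$grid))
  )
  res_s <- decompose_conversion_intensity(pool_s, ls$grid, ls$lu, lui)
  d3 <- suppressMessages(run_aoh_draws(pool_s, res_s, n_runs = 10, seed = 5))
  s1 <- summarize_runs(d1, pool, ls$grid)
  s3 <- summarize_runs(d3, pool_s, ls$grid)
  expect_equal(
    dplyr::arrange(s1, species_id)$mean_loss_fraction,
    dplyr::arrange(s3, species_id)$mean_loss_fraction
  )
})

test_that("run summaries recover degenerate and deterministic cases", {
  grid <- make_grid(10)
  sp <- make_species_table(
    list(id = "always4", cells = 1:10),
    list(id = "never", cells = 1:10)
  )
  pool <- refine_species_pool(sp, grid)
  runs <- dplyr::bind_rows(lapply(1:50, function(run) {
    tibble::tibble(
      cell_id = 1:4, taxon_group = "birds", species_id = "always4",
      lu_type = "wheat", broad_type = "cropland", cause = "conversion",
      run_id = run
    )
  }))
  draws <- structure(list(runs = runs, n_runs = 50L,
                          shortfalls = integer(50)),
                     class = "aoh_draws")
  out <- summarize_runs(draws, pool, grid)
  a <- out[out$species_id == "always4", ]
  expect_equal(a$mean_loss_fraction, 0.4)
  expect_equal(a$ci_low, 0.4)
  expect_equal(a$ci_high, 0.4)
  expect_equal(a$loss_conversion, 0.4)
  expect_equal(a$loss_cropland, 0.4)
  expect_false(a$impending_global_extinction)
  nv <- out[out$species_id == "never", ]
  expect_equal(nv$mean_loss_fraction, 0)
  expect_equal(c(nv$ci_low, nv$ci_high), c(0, 0))
})

test_that("losing one of two equal cells per run gives exactly half the AOH", {
  grid <- make_grid(2)
  sp <- make_species_table(list(id = "c", cells = 1:2))
  pool <- refine_species_pool(sp, grid)
  set.seed(77)
  runs <- dplyr::bind_rows(lapply(1:100, function(run) {
    tibble::tibble(
      cell_id = sample(1:2, 1), taxon_group = "birds", species_id = "c",
      lu_type = "wheat", broad_type = "cropland", cause = "conversion",
      run_id = run
    )
  }))
  draws <- structure(list(runs = runs, n_runs = 100L,
                          shortfalls = integer(100)),
                     class = "aoh_draws")
  out <- summarize_runs(draws, pool, grid)
  expect_equal(out$mean_loss_fraction, 0.5)
  expect_equal(c(out$ci_low, out$ci_high), c(0.5, 0.5))
})

test_that("a species lost everywhere in every run is flagged as impending", {
  grid <- make_grid(2)
  sp <- make_species_table(list(id = "doomed", cells = 1:2))
  pool <- refine_species_pool(sp, grid)
  runs <- dplyr::bind_rows(lapply(1:20, function(run) {
    tibble::tibble(
      cell_id = 1:2, taxon_group = "birds", species_id = "doomed",
      lu_type = "wheat", broad_type = "cropland", cause = "conversion",
      run_id = run
    )
  }))
  draws <- structure(list(runs = runs, n_runs = 20L,
                          shortfalls = integer(20)),
                     class = "aoh_draws")
  out <- summarize_runs(draws, pool, grid)
  expect_equal(out$mean_loss_fraction, 1)
  expect_true(out$impending_global_extinction)
})
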