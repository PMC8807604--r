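test_that("the affinity parameter follows (r f)^(1/z) with its edge cases", {
  expect_equal(compute_affinity(1, 1, 0.25), 1)
  expect_equal(compute_affinity(0, 0.7, 0.4), 0)
  expect_equal(compute_affinity(0.5, 1, 0.5), 0.25)
  expect_equal(compute_affinity(0.5, 0.5, 0.5), 0.0625)
  expect_error(compute_affinity(0.5, 1, 0), "strictly between")
  expect_error(compute_affinity(0.5, 1, 1), "strictly between")
  expect_error(compute_affinity(1.5, 1, 0.5), "0, 1")
})

test_that("single-cell losses match the closed-form power law", {
  # wilderness: habitat ratio 1, no loss
  cells <- list(list(s_pot = 50, a_pot = 1e8, a_cur = 1e8,
                     areas = numeric(0), r = numeric(0), f = numeric(0),
                     z = 0.25))
  inp <- cells_to_pipeline_inputs(cells)
  res <- csar_loss(inp$pool, inp$grid, inp$lu, inp$field)
  expect_equal(res$s_loss, 0)
  expect_true(res$wilderness)

  # total conversion with zero affinity loses the whole pool
  cells <- list(list(s_pot = 50, a_pot = 1e8, a_cur = 0,
                     areas = 1e8, r = 0, f = 1, z = 0.25))
  inp <- cells_to_pipeline_inputs(cells)
  res <- csar_loss(inp$pool, inp$grid, inp$lu, inp$field)
  expect_equal(res$s_loss, 50)

  # the worked half-converted example, h = 0.5
  cells <- list(list(s_pot = 100, a_pot = 1, a_cur = 0.5,
                     areas = 0.5, r = 0.5^0.25, f = 1, z = 0.25))
  inp <- cells_to_pipeline_inputs(cells)
  expect_equal(inp$field$h, 0.5)
  res <- csar_loss(inp$pool, inp$grid, inp$lu, inp$field)
  expect_equal(res$s_loss, 100 * (1 - 0.75^0.25))  # = 6.9395...
})

test_that("pipeline and scalar oracle agree to 1e-12 on 1000 random cells", {
  cells <- random_cells(1000, seed = 101)
  inp <- cells_to_pipeline_inputs(cells)
  res <- csar_loss(inp$pool, inp$grid, inp$lu, inp$field)
  res <- res[order(res$cell_id), ]
  oracle <- vapply(cells, function(c) {
    scalar_csar_cell(c$s_pot, c$a_pot, c$a_cur, c$areas, c$r, c$f, c$z)
  }, 0)
  expect_lt(max(abs(res$s_loss - oracle)), 1e-12)
  expect_true(all(res$s_loss >= 0 & res$s_loss <= res$s_pot))
})

test_that("the conversion/intensity identity holds to 1e-12 on 1000 random cells", {
  ls <- generate_landscape(n_cells = 1000, n_species = 60, seed = 19)
  pool <- suppressMessages(
    compute_affinity_fractions(refine_species_pool(ls$species, ls$grid))
  )
  lui <- winsorize_and_scale(
    ls$intensity[ls$intensity$set_id == "Set1", ], ls$catalogue, ls$grid
  )
  res <- decompose_conversion_intensity(pool, ls$grid, ls$lu, lui)
  lhs <- res$cells$s_loss / res$cells$s_pot
  rhs <- res$cells$s_loss_conv / res$cells$s_pot + res$cells$s_loss_int_rel
  expect_lt(max(abs(lhs - rhs)), 1e-12)
  # conversion alone never exceeds the full loss when f <= 1
  expect_true(all(res$cells$s_loss_conv <= res$cells$s_loss + 1e-12))
  # decomposition against the scalar oracle on the worked fixture
  tc <- generate_known_truth_case("single-cell-closed-form")
  tp <- suppressMessages(
    compute_affinity_fractions(refine_species_pool(tc$species, tc$grid))
  )
  tres <- decompose_conversion_intensity(tp, tc$grid, tc$lu, tc$lui)
  expect_equal(tres$cells$s_loss, tc$expected$s_loss, tolerance = 1e-12)
  expect_equal(tres$cells$s_loss_int_rel, 0)
})

test_that("intensity below the Minimal anchor contributes no loss", {
  tc <- generate_known_truth_case("all-minimal-intensity")
  pool <- suppressMessages(
    compute_affinity_fractions(refine_species_pool(tc$species, tc$grid))
  )
  res <- decompose_conversion_intensity(pool, tc$grid, tc$lu, tc$lui)
  expect_equal(res$cells$s_loss_int_rel, rep(0, nrow(res$cells)))
})

test_that("unconverted types at zero intensity are invisible to the model", {
  grid <- make_grid(1, area_pristine = 0.3e8)
  lu <- tibble::tibble(
    cell_id = 1L,
    lu_type = c("grazing_land", "forest_used"),
    broad_type = c("grazing land", "forests"),
    response_class = c("pasture", "plantation"),
    converted = FALSE,
    area = c(0.4e8, 0.3e8)
  )
  sp <- make_species_table(
    list(id = "a", cells = 1L), list(id = "b", cells = 1L)
  )
  pool <- compute_affinity_fractions(refine_species_pool(sp, grid))
  lui <- tibble::tibble(cell_id = 1L,
                        lu_type = c("grazing_land", "forest_used"),
                        lui = 0)
  res <- decompose_conversion_intensity(pool, grid, lu, lui)
  expect_equal(res$cells$s_loss, 0)
})

test_that("with r = 1 and f = 1 everywhere, used land is pristine", {
  cells <- random_cells(50, seed = 7)
  cells <- lapply(cells, function(c) {
    c$r <- rep(1, length(c$r)); c$f <- rep(1, length(c$f)); c
  })
  inp <- cells_to_pipeline_inputs(cells)
  res <- csar_loss(inp$pool, inp$grid, inp$lu, inp$field)
  expect_lt(max(abs(res$s_loss)), 1e-9)
})

test_that("loss is non-increasing in each type's affinity", {
  cells <- random_cells(50, seed = 23)
  inp <- cells_to_pipeline_inputs(cells)
  base <- csar_loss(inp$pool, inp$grid, inp$lu, inp$field)
  for (eps in c(0.01, 0.1)) {
    pert <- inp$field
    pert$h <- pmin(1, pert$h + eps)
    res <- csar_loss(inp$pool, inp$grid, inp$lu, pert)
    expect_true(all(res$s_loss <= base$s_loss + 1e-12))
  }
})

test_that("scenario losses are ordered conversion-only <= current <= full", {
  ls <- generate_landscape(n_cells = 120, n_species = 50, seed = 31)
  pool <- suppressMessages(
    compute_affinity_fractions(refine_species_pool(ls$species, ls$grid))
  )
  lui <- winsorize_and_scale(
    ls$intensity[ls$intensity$set_id == "Set2", ], ls$catalogue, ls$grid
  )
  conv <- run_scenario(pool, ls$grid, ls$lu, lui, scenario = "conversion_only")
  cur <- run_scenario(pool, ls$grid, ls$lu, lui, scenario = "current")
  full <- run_scenario(pool, ls$grid, ls$lu, lui,
                       scenario = "full_intensification")
  expect_true(all(conv$cells$s_loss <= cur$cells$s_loss + 1e-12))
  expect_true(all(cur$cells$s_loss <= full$cells$s_loss + 1e-12))
  # idempotence: forcing LUI = 1 when it already is 1 changes nothing
  lui1 <- lui
  lui1$lui <- 1
  cur1 <- run_scenario(pool, ls$grid, ls$lu, lui1, scenario = "current")
  expect_equal(cur1$cells$s_loss, full$cells$s_loss)
  expect_error(
    decompose_conversion_intensity(pool, ls$grid, ls$lu, lui,
                                   scenario = "jackpot"),
    "unknown scenario"
  )
})

test_that("closure violations are rejected naming the cell", {
  cells <- random_cells(3, seed = 5)
  inp <- cells_to_pipeline_inputs(cells)
  inp$grid$area_pristine[2] <- inp$grid$area_pristine[2] + 0.2e8
  expect_error(csar_loss(inp$pool, inp$grid, inp$lu, inp$field),
               "closure violated in cell 2")
})

test_that("loss attribution splits proportionally to habitat deficits", {
  # single type carries the whole loss
  cells <- list(list(s_pot = 80, a_pot = 1e8, a_cur = 0.4e8, areas = 0.6e8,
                     r = 0.5, f = 0.8, z = 0.3))
  inp <- cells_to_pipeline_inputs(cells)
  res <- csar_loss(inp$pool, inp$grid, inp$lu, inp$field)
  res$s_loss_conv <- res$s_loss * 0.7
  att <- attribute_loss_to_lu_types(res, inp$field)
  expect_equal(att$loss_total, res$s_loss)

  # two identical types share equally
  cells <- list(list(s_pot = 80, a_pot = 1e8, a_cur = 0.4e8,
                     areas = c(0.3e8, 0.3e8), r = c(0.5, 0.5),
                     f = c(0.8, 0.8), z = 0.3))
  inp <- cells_to_pipeline_inputs(cells)
  res <- csar_loss(inp$pool, inp$grid, inp$lu, inp$field)
  res$s_loss_conv <- res$s_loss * 0.7
  att <- attribute_loss_to_lu_types(res, inp$field)
  expect_equal(att$loss_total[1], att$loss_total[2])
  expect_equal(sum(att$loss_total), res$s_loss)

  # deficits 0.3 vs 0.1 give shares 0.75 / 0.25 of the cell loss
  inp$field$area <- c(1, 1)
  inp$field$h <- c(0.7, 0.9)
  res2 <- tibble::tibble(cell_id = 1L, taxon_group = "birds", s_pot = 80,
                         s_loss = 10, s_loss_conv = 4)
  att <- attribute_loss_to_lu_types(res2, inp$field)
  expect_equal(att$loss_total, c(7.5, 2.5))

  # attribution sums reproduce each component's cell total
  ls <- generate_landscape(n_cells = 60, n_species = 40, seed = 41)
  pool <- suppressMessages(
    compute_affinity_fractions(refine_species_pool(ls$species, ls$grid))
  )
  lui <- winsorize_and_scale(
    ls$intensity[ls$intensity$set_id == "Set1", ], ls$catalogue, ls$grid
  )
  full <- decompose_conversion_intensity(pool, ls$grid, ls$lu, lui)
  sums <- dplyr::summarise(
    dplyr::group_by(full$attribution, cell_id, taxon_group),
    tot = sum(loss_total), conv = sum(loss_conv), int = sum(loss_int),
    .groups = "drop"
  )
  merged <- dplyr::inner_join(sums, full$cells,
                              by = c("cell_id", "taxon_group"))
  expect_lt(max(abs(merged$tot - merged$s_loss)), 1e-9)
  expect_lt(max(abs(merged$conv - merged$s_loss_conv)), 1e-9)
  expect_lt(
    max(abs(merged$int - (merged$s_loss - merged$s_loss_conv))), 1e-9
  )
})
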