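test_that("summarize_to_grid counts pixel areas into cell compositions", {
  # 8x8 block of 100-m pixels: one cell, single class
  px <- matrix("grassland", 8, 8)
  ls <- summarize_to_grid(px, pixel_size = 100)
  expect_equal(unname(ls$composition[1, "grassland"]), 64)
  expect_equal(sum(ls$composition), 64)

  # mixed block: 16 cropland + 48 pasture pixels -> 16 + 48 ha
  px2 <- matrix("pasture", 8, 8)
  px2[1:2, ] <- "cropland"
  ls2 <- summarize_to_grid(px2, pixel_size = 100)
  expect_equal(unname(ls2$composition[1, "cropland"]), 16)
  expect_equal(unname(ls2$composition[1, "pasture"]), 48)

  # integer codes through a code map
  px3 <- matrix(c(1L, 2L), 8, 16)
  ls3 <- summarize_to_grid(px3, pixel_size = 100,
                           code_map = c("1" = "forest", "2" = "water"))
  expect_equal(unname(colSums(ls3$composition)[c("forest", "water")]),
               c(64, 64))
})

test_that("summarize_to_grid conserves per-class area on multi-cell rasters", {
  set.seed(4)
  classes <- c("forest", "grassland", "cropland", "water", "road")
  px <- matrix(sample(classes, 24 * 32, replace = TRUE), 24, 32)
  ls <- summarize_to_grid(px, pixel_size = 100)
  expect_equal(ls$n_rows, 3)
  expect_equal(ls$n_cols, 4)
  for (cl in classes)
    expect_equal(sum(ls$composition[, cl]), sum(px == cl) * 1)
  expect_true(all(abs(rowSums(ls$composition) - 64) < 1e-9))
})

test_that("summarize_to_grid rejects bad rasters", {
  px <- matrix("grassland", 8, 8)
  px[3, 3] <- NA
  expect_error(summarize_to_grid(px, pixel_size = 100), "nodata")
  expect_error(summarize_to_grid(matrix("slagheap", 8, 8), pixel_size = 100),
               "unknown landcover class: slagheap")
  expect_error(summarize_to_grid(matrix(9L, 8, 8), pixel_size = 100,
                                 code_map = c("1" = "forest")),
               "unknown class code: 9")
  expect_error(summarize_to_grid(matrix("forest", 7, 8), pixel_size = 100),
               "align")
  expect_error(summarize_to_grid(matrix("forest", 8, 8), pixel_size = 300),
               "divide")
})

test_that("pasture conversion follows the draw < proportion rule", {
  ls <- tiny_landscape(3, 3, comp = list(c(pasture = 40, cropland = 10)))
  expect_error(convert_pasture_cell(ls, 1, 0.5, -0.1), "\\[0, 1\\]")
  expect_error(convert_pasture_cell(ls, 1, 0.5, 1.4), "\\[0, 1\\]")

  # draw 0.30 < proportion 0.40 -> converts; 0.50 does not
  c1 <- convert_pasture_cell(ls, 5, 0.30, 0.40, rotation_year = 2)
  expect_equal(unname(c1$composition[5, "pasture"]), 0)
  expect_equal(unname(c1$composition[5, "cropland"]), 50)
  expect_equal(c1$canola[5, 2], 40)          # whole pasture, one rotation year
  expect_equal(sum(c1$canola[5, ]), 40)
  validate_landscape(c1)

  c2 <- convert_pasture_cell(ls, 5, 0.50, 0.40)
  expect_equal(unname(c2$composition[5, "pasture"]), 40)

  # proportion 0 never converts; proportion 1 converts every pasture cell
  set.seed(1)
  z <- convert_pasture(ls, 0)
  expect_identical(z$composition, ls$composition)
  a <- convert_pasture(ls, 1)
  expect_true(all(a$composition[, "pasture"] == 0))
  expect_true(all(abs(rowSums(a$composition) - 64) < 1e-9))
})

test_that("synthetic landscapes are reproducible and closed", {
  a <- generate_synthetic_landscape(synthetic_config(10, 12), seed = 5)
  b <- generate_synthetic_landscape(synthetic_config(10, 12), seed = 5)
  expect_identical(a, b)
  d <- generate_synthetic_landscape(synthetic_config(10, 12), seed = 6)
  expect_false(identical(a$composition, d$composition))

  ls <- generate_synthetic_landscape(synthetic_config(20, 20), seed = 1)
  expect_true(all(abs(rowSums(ls$composition) - 64) < 1e-6))
  expect_s3_class(ls, "grid_landscape")
  expect_true(validate_landscape(ls))
  # west-to-east gradient: forest dominates the west, cropland the east
  west <- ls$cells$col <= 5; east <- ls$cells$col >= 16
  expect_gt(sum(ls$composition[west, "forest"]),
            sum(ls$composition[east, "forest"]))
  expect_gt(sum(ls$composition[east, "cropland"]),
            sum(ls$composition[west, "cropland"]))
})

test_that("degenerate generator configs behave as specified", {
  expect_error(generate_synthetic_landscape(synthetic_config(4, 4)),
               "at least 8 x 8")
  # no forest anywhere -> no cohorts, no mills
  bare <- synthetic_config(8, 8, archetypes = list(
    Mountains = c(grassland = 0.7, pasture = 0.3),
    Foothills = c(grassland = 0.7, pasture = 0.3),
    Boreal    = c(grassland = 0.7, pasture = 0.3),
    Parkland  = c(grassland = 0.5, cropland = 0.5),
    Grassland = c(grassland = 0.5, cropland = 0.5)))
  ls <- generate_synthetic_landscape(bare, seed = 2)
  expect_equal(nrow(ls$cohorts), 0)
  expect_null(ls$mills)
})

test_that("composition closure survives aging, harvest and conversion", {
  ls <- forest_landscape(12, 12, seed = 31)
  sim <- run_timber_simulation(ls, years = 5, seed = 3)
  expect_true(validate_landscape(sim$landscape))
  conv <- convert_pasture(sim$landscape, 0.5,
                          draws = rep(0.25, n_cells(ls)),
                          rotation_years = rep(1L, n_cells(ls)))
  expect_true(validate_landscape(conv))
})
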