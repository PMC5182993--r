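test_that("cost surfaces equal the exhaustive path oracle on small grids", {
  # 1x3 grid, uniform per-step rate 2 -> 0, 2, 4 from the left end
  ls <- tiny_landscape(1, 3)
  ls$cells$road_class <- "none"
  cs <- build_cost_surface(ls, list(cell_id = 1L), c(none = 2))
  expect_equal(cs$costs, c(0, 2, 4))

  # 3x3 with a cheap-road corridor, checked against brute-force enumeration
  ls3 <- tiny_landscape(3, 3)
  ls3$cells$road_class <- c("none", "none", "none",
                            "paved", "paved", "paved",
                            "none", "none", "none")
  rates <- default_traversal_costs()[ls3$cells$road_class]
  cs3 <- build_cost_surface(ls3, list(cell_id = 4L))
  for (cell in 1:9)
    expect_equal(cs3$costs[cell], oracle_least_cost(3, 3, rates, 4L, cell))

  # random rates, every pair of a 3x3
  set.seed(11)
  lsr <- tiny_landscape(3, 3)
  lsr$cells$road_class <- sample(names(default_traversal_costs()), 9,
                                 replace = TRUE)
  ratesr <- default_traversal_costs()[lsr$cells$road_class]
  for (mill in c(1L, 5L, 9L)) {
    csr <- build_cost_surface(lsr, list(cell_id = mill))
    expect_equal(csr$costs[mill], 0)
    for (cell in 1:9)
      expect_equal(csr$costs[cell], oracle_least_cost(3, 3, ratesr, mill, cell))
  }
  expect_error(build_cost_surface(lsr, list(cell_id = 99L)), "not located")
})

test_that("realized AAC fractions are truncated-normal draws in [0, 1]", {
  expect_equal(draw_aac_fraction(0.9, 0), 0.9)
  expect_error(draw_aac_fraction(1.5, 0.1), "\\[0, 1\\]")
  expect_error(draw_aac_fraction(0.5, -1), ">= 0")
  set.seed(2)
  x <- draw_aac_fraction(0.9, 0.05, n = 10000)
  expect_true(all(x >= 0 & x <= 1))
  mu <- truncnorm_mean(0.9, 0.05)
  expect_lt(abs(mean(x) - mu), 3 * sd(x) / sqrt(length(x)))
  # heavy truncation case
  y <- draw_aac_fraction(0.95, 0.2, n = 10000)
  expect_true(all(y <= 1))
  expect_lt(abs(mean(y) - truncnorm_mean(0.95, 0.2)), 3 * sd(y) / sqrt(1e4))
})

test_that("eligibility flips exactly at the threshold age", {
  ls <- tiny_landscape(2, 2, comp = list(c(forest = 64)))
  ls$cells$fmu_id <- 1L
  ls$cohorts <- data.frame(cell_id = 1:4, stand_type = "pine",
                           ecozone = "Boreal Plains",
                           age = c(79L, 80L, 200L, 81L), area = 64)
  el <- eligible_stands(ls, 1, min_age = 80)
  expect_setequal(el$cell_id, c(2L, 3L, 4L))
  expect_equal(nrow(eligible_stands(ls, 2)), 0)       # empty FMU
  ls$cohorts$age <- 200L
  expect_equal(nrow(eligible_stands(ls, 1)), 4)       # all ancient -> all in
  ls$cohorts$area[1] <- 0
  expect_equal(nrow(eligible_stands(ls, 1)), 3)       # zero area excluded
})

test_that("greedy scheduling takes cheapest cells until the target", {
  ls <- tiny_landscape(1, 3, comp = list(c(forest = 64)))
  ls$cells$fmu_id <- 1L
  ls$cohorts <- data.frame(cell_id = 1:3, stand_type = "pine",
                           ecozone = "Boreal Plains", age = 100L, area = 64)
  # constant 1000 m3 volume per cell via a flat curve of 1000/64 m3/ha
  lib <- curve_library(
    list(growth_curve("pine", "Boreal Plains", c(1000 / 64), 300)),
    list(carbon_curve("pine", "Boreal Plains", c(1), 300)))
  cs <- list(mill_cell = 1L, costs = c(3, 5, 7))
  sched <- schedule_annual_harvest(ls, 1, lib, cs, target = 2000)
  expect_setequal(sched$cell, c(1L, 2L))
  expect_equal(sum(sched$volume), 2000)
  expect_false(attr(sched, "exhausted"))
  # zero target -> no harvest
  expect_equal(nrow(schedule_annual_harvest(ls, 1, lib, cs, target = 0)), 0)
  # unreachable target -> everything taken, flagged exhausted
  all3 <- schedule_annual_harvest(ls, 1, lib, cs, target = 1e7)
  expect_equal(sum(all3$volume), 3000)
  expect_true(attr(all3, "exhausted"))
  # variable retention only ever takes 25/50/75%
  set.seed(9)
  vr <- schedule_annual_harvest(ls, 1, lib, cs, target = 2000,
                                mode = "variable_retention")
  expect_true(all(vr$fraction %in% c(0.25, 0.5, 0.75)))
})

test_that("apply_harvest splits cohorts and books the cutblock footprint", {
  ls <- tiny_landscape(2, 2, comp = list(c(forest = 40, grassland = 24)))
  ls$cohorts <- data.frame(cell_id = 1L, stand_type = "spruce",
                           ecozone = "Boreal Plains", age = 120L, area = 40)
  h <- apply_harvest(ls, 1, 0.25)
  expect_equal(h$cohorts$age, c(120L, 0L))
  expect_equal(h$cohorts$area, c(30, 10))
  expect_equal(unname(h$composition[1, "cutblock"]), 10)
  expect_equal(unname(h$composition[1, "forest"]), 30)
  expect_equal(sum(h$cohorts$area), 40)               # area conserved
  expect_true(validate_landscape(h))
  # clearcut limit: one age-0 cohort, full cutblock
  h1 <- apply_harvest(ls, 1, 1)
  expect_equal(h1$cohorts$age, 0L)
  expect_equal(unname(h1$composition[1, "cutblock"]), 40)
  expect_error(apply_harvest(ls, 1, 0), "\\(0, 1\\]")
  expect_error(apply_harvest(ls, 1, 1.2), "\\(0, 1\\]")
})

test_that("cash flow and NPV follow the stated arithmetic", {
  ledger <- data.frame(volume = 1000, transport_cost = 10)
  mill <- list(conversion = 1, price = 100, unit_cost = 40)
  expect_equal(mill_cashflow(ledger, mill), 50000)
  expect_equal(mill_cashflow(ledger[0, ], mill), 0)
  # raising transport cost strictly decreases cash flow
  dearer <- transform(ledger, transport_cost = 20)
  expect_lt(mill_cashflow(dearer, mill), mill_cashflow(ledger, mill))

  expect_equal(npv(100, 0.02), 100 / 1.02)
  expect_equal(npv(c(10, 20, 30), 0), 60)
  expect_equal(npv(numeric(0), 0.05), 0)
  expect_error(npv(1, -1.5), "rate")
})

test_that("the timber simulation is deterministic and respects its contracts", {
  ls <- forest_landscape(14, 14, seed = 77)
  a <- run_timber_simulation(ls, years = 10, seed = 5)
  b <- run_timber_simulation(ls, years = 10, seed = 5)
  expect_identical(a$npv_total, b$npv_total)
  expect_identical(a$ledger, b$ledger)
  z <- run_timber_simulation(ls, years = 0, seed = 5)
  expect_equal(z$npv_total, 0)
  expect_equal(z$carbon_change, 0)

  # per FMU-year: overshoot bounded by the final cell; greedy cost order
  led <- a$ledger[!is.na(a$ledger$cell), ]
  for (key in unique(paste(led$year, led$fmu_id))) {
    sub <- led[paste(led$year, led$fmu_id) == key, ]
    tot <- sum(sub$volume)
    last_cell <- sub$cell[which.max(sub$transport_cost)]
    over <- tot - sub$target[1]
    expect_lte(over, sum(sub$volume[sub$cell == last_cell]) + 1e-9)
    if (!any(sub$exhausted)) expect_gte(tot, sub$target[1] - 1e-9)
  }
})
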