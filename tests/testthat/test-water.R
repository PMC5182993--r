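test_that("sink filling drains every cell without lowering the DEM", {
  # tilted plane already drains: unchanged
  plane <- outer(seq(30, 10, length.out = 5), seq(20, 0, length.out = 6), `+`)
  expect_equal(fill_sinks(plane), plane)

  # single-cell pit raised to its rim (plus epsilon)
  pit <- plane
  pit[3, 3] <- -50
  filled <- fill_sinks(pit, epsilon = 1e-4)
  rim <- min(pit[2:4, 2:4][-5])
  expect_gte(filled[3, 3], rim)
  expect_lte(filled[3, 3], rim + 10 * 1e-4)
  expect_true(all(filled >= pit))

  # random rough DEMs all pass a walk-to-edge reachability check
  set.seed(13)
  for (i in 1:5) {
    dem <- matrix(rnorm(100, 100, 20), 10, 10)
    expect_true(drains_to_edge(fill_sinks(dem)))
  }
})

test_that("D8 directions and accumulation match hand cases and the oracle", {
  # uniform west-tilted plane: all interior flow points west
  nr <- 5; nc <- 6
  dem <- matrix(rep(seq(0, 50, length.out = nc), each = nr), nr, nc)
  flow <- d8_flow_directions(dem)
  ids <- matrix(seq_len(nr * nc), nr, nc, byrow = TRUE)
  for (r in 1:nr) for (cc in 2:nc)
    expect_equal(flow$down[ids[r, cc]], ids[r, cc - 1L])
  # accumulation along a 1x5 west-flowing line is 1..5
  # each row is an independent 1x6 line: outlet (col 1) accumulates 6
  expect_equal(flow$acc[ids[3, 1]], 6)
  expect_equal(flow$acc[ids[3, 4]], 3)

  # cells are conserved: accumulation at outlets sums to n
  set.seed(7)
  dem2 <- fill_sinks(matrix(rnorm(64, 100, 15), 8, 8))
  f2 <- d8_flow_directions(dem2)
  expect_equal(sum(f2$acc[is.na(f2$down)]), 64L)
  # against the path-following oracle
  expect_equal(f2$acc, oracle_accumulation(f2$down))
})

test_that("river networks form a forest at the accumulation threshold", {
  set.seed(19)
  dem <- fill_sinks(matrix(rnorm(144, 100, 10), 12, 12) +
                      outer(rep(0, 12), seq(60, 0, length.out = 12), `+`))
  flow <- d8_flow_directions(dem)
  net1 <- extract_river_network(flow, 1)
  expect_true(all(net1$river))                       # threshold 1: all river
  net <- extract_river_network(flow, 10)
  outlets <- sum(net$river & (is.na(flow$down) | !net$river[pmax(flow$down, 1)]))
  n_outlets <- sum(vapply(which(net$river), function(c) {
    d <- flow$down[c]; is.na(d) || !net$river[d] }, TRUE))
  expect_equal(nrow(net$links), sum(net$river) - n_outlets)
  expect_warning(extract_river_network(flow, 1e6), "empty")

  # V-shaped valley: the mainstem runs along the valley floor
  vdem <- outer(seq(12, 0, length.out = 7),    # tilt to the south
                c(3, 2, 1, 0, 1, 2, 3) * 10, `+`)
  vflow <- d8_flow_directions(fill_sinks(vdem))
  vnet <- extract_river_network(vflow, 8)
  river_cols <- ((which(vnet$river) - 1L) %% 7L) + 1L
  expect_true(all(river_cols == 4))
})

test_that("runoff and loading follow the area-weighted coefficients", {
  p <- water_params()
  p$runoff[c("grassland", "cropland")] <- c(0.2, 0.4)
  ls <- tiny_landscape(2, 2, comp = list(c(grassland = 32, cropland = 32)),
                       precipitation = 100)
  ro <- cell_runoff(ls, p)
  expect_equal(ro$depth_mm, rep(30, 4))              # 0.5*0.2 + 0.5*0.4 of 100
  expect_equal(ro$volume_m3, rep(30 / 1000 * 64e4, 4))
  expect_true(all(ro$depth_mm <= ls$cells$precipitation))
  zero <- p; zero$runoff[] <- 0
  expect_equal(cell_runoff(ls, zero)$volume_m3, rep(0, 4))

  # single class, e = 0.01 kg/ha/mm, 450 mm, 64 ha -> 288 kg
  pe <- water_params()
  pe$export["grassland", "P", "plains"] <- 0.01
  lsg <- tiny_landscape(1, 1, precipitation = 450)
  expect_equal(unname(cell_loading(lsg, pe)[1, "P"]), 450 * 64 * 0.01)
  # loads double with precipitation
  ls2 <- lsg; ls2$cells$precipitation <- 900
  expect_equal(cell_loading(ls2, pe)[, c("N", "P", "TSS")],
               2 * cell_loading(lsg, pe)[, c("N", "P", "TSS")])
  expect_equal(unname(cell_loading(ls2, pe)[1, "sediment"]),
               2 * unname(cell_loading(lsg, pe)[1, "sediment"]))
})

test_that("RUSLE is the plain factor product", {
  expect_equal(rusle_erosion(100, 0.3, 1.2, 0.2, 1, 1), 7.2)
  expect_equal(rusle_erosion(100, 0.3, 1.2, 0, 1, 10), 0)
  expect_equal(rusle_erosion(2 * 100, 0.3, 1.2, 0.2, 1, 1), 2 * 7.2)
  expect_error(rusle_erosion(-1, 0.3, 1.2, 0.2), ">= 0")
})

test_that("overland routing attenuates multiplicatively over transit cells", {
  # a west-east chain in the middle row; river cell imposed at column 4
  ls <- tiny_landscape(3, 5)
  # retention via composition: "water" retains 1.0, "road" retains 0
  p <- water_params()
  p$retention["water", ] <- 1
  p$retention["road", ] <- 0
  p$retention["grassland", ] <- 0
  ca <- ls$cell_area
  set_cell <- function(ls, cell, r) {
    ls$composition[cell, ] <- 0
    ls$composition[cell, "water"] <- r * ca
    ls$composition[cell, "road"] <- (1 - r) * ca
    ls
  }
  mid <- sapply(1:5, function(cc) cell_at(ls, 2, cc))
  ls <- set_cell(ls, mid[2], 0.5)                    # first transit cell
  ls <- set_cell(ls, mid[3], 0.2)                    # second transit cell
  elev <- matrix(100, 3, 5) + outer(rep(10, 3), seq(50, 10, length.out = 5))
  elev[2, ] <- seq(50, 10, length.out = 5)           # valley along row 2
  ls$cells$elevation <- as.vector(t(elev))
  ls <- suppressWarnings(prepare_hydrology(ls, river_threshold = 1e5))
  ls$hydrology$network$river[mid[4]] <- TRUE
  loads <- matrix(0, n_cells(ls), 1, dimnames = list(NULL, "P"))
  loads[mid[1], "P"] <- 100
  out <- route_overland(ls, p, loads, volumes = rep(0, n_cells(ls)))
  expect_equal(unname(out$river_input[mid[4], "P"]), 100 * 0.5 * 0.8)
  expect_equal(unname(out$removed[mid[2], "P"]), 50)
  expect_equal(unname(out$removed[mid[3], "P"]), 10)
  expect_equal(unname(out$supplied[mid[1], "P"]), 40)

  # origin adjacent to the river: no attenuation
  loads2 <- matrix(0, n_cells(ls), 1, dimnames = list(NULL, "P"))
  loads2[mid[3], "P"] <- 70
  out2 <- route_overland(ls, p, loads2, volumes = rep(0, n_cells(ls)))
  expect_equal(unname(out2$river_input[mid[4], "P"]), 70)

  # a full-retention transit cell delivers nothing
  ls3 <- set_cell(ls, mid[3], 1)
  out3 <- route_overland(ls3, p, loads, volumes = rep(0, n_cells(ls)))
  expect_equal(unname(out3$river_input[mid[4], "P"]), 0)
  expect_equal(sum(out3$removed[, "P"]), 100)
})

test_that("river accumulation matches the upstream-set oracle", {
  ls <- generate_synthetic_landscape(synthetic_config(10, 10), seed = 23)
  res <- run_water_year(ls)
  net <- ls$hydrology$network
  expect_lte(sum(net$river), 50)
  acc <- accumulate_river(ls, res$routed$river_input, res$routed$flow_in)
  for (cell in which(net$river)) {
    expect_equal(acc$load[cell, ],
                 oracle_river_load(net$links, res$routed$river_input, cell))
  }
  # two tributaries joining are additive: total at outlet = sum of entries
  expect_error(
    accumulate_river(ls, res$routed$river_input, res$routed$flow_in,
                     monitors = data.frame(label = "dry", cell_id =
                                             which(!net$river)[1])),
    "off the river network")
})

test_that("a water year conserves mass and volume", {
  ls <- generate_synthetic_landscape(synthetic_config(15, 15), seed = 3)
  res <- run_water_year(ls)
  expect_true(all(res$totals$balance_error < 1e-9))
  # outlet flow: all runoff reaches a river or the grid edge
  total_in <- sum(res$runoff$volume_m3)
  total_out <- sum(res$routed$flow_in) + res$routed$edge_flow
  expect_equal(total_out, total_in)
  # zero precipitation -> all-zero result
  dry <- ls; dry$cells$precipitation <- 0
  dres <- run_water_year(dry)
  expect_equal(sum(dres$loading), 0)
  expect_equal(sum(dres$runoff$volume_m3), 0)

  # adding cropland (high export) upstream weakly increases P downstream
  monitor_cell <- ls$monitors$cell_id[ls$monitors$label == "outlet"]
  up <- which(res$routed$destination > 0 &
                ls$composition[, "pasture"] > 5)[1]
  expect_false(is.na(up))
  more <- ls
  a <- more$composition[up, "pasture"]
  more$composition[up, "pasture"] <- 0
  more$composition[up, "cropland"] <- more$composition[up, "cropland"] + a
  res2 <- run_water_year(more, water_params())
  expect_gte(res2$totals$supplied_river[2], res$totals$supplied_river[2])
})

test_that("latin hypercube designs stratify every parameter", {
  rng <- list(a = c(0, 1), b = c(10, 30), c = c(-5, 5))
  d <- latin_hypercube_sample(rng, 10, seed = 4)
  for (j in colnames(d)) {
    lo <- rng[[j]][1]; hi <- rng[[j]][2]
    strata <- floor((d[, j] - lo) / (hi - lo) * 10)
    expect_setequal(strata, 0:9)                     # one sample per decile
  }
  expect_identical(latin_hypercube_sample(rng, 10, seed = 4), d)
  expect_false(identical(latin_hypercube_sample(rng, 10, seed = 5), d))
  one <- latin_hypercube_sample(rng, 1, seed = 1)
  expect_true(all(one >= c(0, 10, -5) & one <= c(1, 30, 5)))
  expect_error(latin_hypercube_sample(list(a = c(1, 0)), 5), "inverted")
})

test_that("calibration recovers the generating coefficient set", {
  ls <- generate_synthetic_landscape(synthetic_config(12, 12), seed = 41)
  base <- water_params()
  classes <- rownames(base$export)
  des <- latin_hypercube_sample(
    stats::setNames(rep(list(c(0.25, 4)), length(classes)), classes),
    10, seed = 6)
  candidates <- lapply(seq_len(10), function(i) scale_export(base$export, des[i, ]))
  truth <- candidates[[4]]
  tp <- base; tp$export <- truth
  obs_run <- run_water_year(ls, tp)
  observed <- data.frame(label = rep(obs_run$monitors$label, each = 1),
                         substance = "P",
                         load_kg = obs_run$monitors$P)
  cal <- calibrate_export_coefficients(ls, observed, candidates, base)
  expect_true(all(cal$best == 4))
  expect_true(all(cal$objective[4, ] < 1e-6))
  # the combined table takes each calibrated group's slice from the winner
  for (g in names(cal$best))
    expect_equal(cal$export[, , g], truth[, , g])
  # single candidate returns trivially
  one <- calibrate_export_coefficients(ls, observed, candidates[4], base)
  expect_true(all(one$best == 1))
  # objective invariant to observation order
  cal2 <- calibrate_export_coefficients(ls, observed[rev(seq_len(nrow(observed))), ],
                                        candidates, base)
  expect_equal(cal$objective, cal2$objective)
  expect_error(calibrate_export_coefficients(ls, observed[0, ], candidates),
               "no observations")
})
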