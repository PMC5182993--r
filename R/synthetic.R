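#' Configuration for the synthetic-landscape generator
#'
#' The generator emulates the regional structure of a large
#' prairie-province watershed running west to east from mountains through
#' foothills and boreal forest into parkland and grassland: composition
#' archetypes follow that gradient, elevation and precipitation decline
#' eastward, forestry (FMUs, mills) occupies the forested west, and annual
#' cropping with a 4-year canola rotation occupies the east. All knobs are
#' plain list entries so a YAML config can override any of them.
#'
#' @param n_rows,n_cols grid dimensions (at least 8 x 8)
#' @param cell_size cell edge (m)
#' @param ... overrides for any default entry
#' @return a config list
#' @export
synthetic_config <- function(n_rows = 20, n_cols = 20, cell_size = 800, ...) {
  cfg <- list(
    n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
    # west -> east region bands, as cumulative column fractions
    region_breaks = c(Mountains = 0.15, Foothills = 0.35, Boreal = 0.55,
                      Parkland = 0.80, Grassland = 1.00),
    # mean composition proportions per region (rescaled to the cell area);
    # per-cell realizations are Dirichlet draws around these means
    archetypes = list(
      Mountains = c(forest = 0.78, shrub = 0.10, grassland = 0.07,
                    water = 0.03, road = 0.02),
      Foothills = c(forest = 0.65, grassland = 0.10, shrub = 0.08,
                    pasture = 0.05, water = 0.03, road = 0.02, trail = 0.02,
                    cropland = 0.03, industrial = 0.02),
      Boreal    = c(forest = 0.45, grassland = 0.10, shrub = 0.10,
                    water = 0.05, pasture = 0.12, cropland = 0.15,
                    road = 0.02, trail = 0.01),
      Parkland  = c(forest = 0.08, grassland = 0.12, shrub = 0.04,
                    water = 0.03, pasture = 0.25, cropland = 0.42,
                    road = 0.03, urban = 0.02, industrial = 0.01),
      Grassland = c(grassland = 0.40, pasture = 0.28, cropland = 0.25,
                    shrub = 0.03, water = 0.02, road = 0.02)),
    dirichlet_concentration = 60,
    stand_age_mean = 70, stand_age_max = 200,
    stand_type_probs = c(deciduous = 0.35, spruce = 0.25, pine = 0.25,
                         mixedwood = 0.15),
    dem = list(west = 1500, east = 600, roughness = 15, ns_tilt = 0.4),
    precip = list(west = 900, east = 420, sd = 20, min = 300),
    n_fmus = 2, frac_mean = 0.9, frac_sd = 0.05, aac_factor = 1,
    road = list(unpaved_prob = 0.15, corridor_prob = 0.10),
    river_threshold = NULL, canola_share = 1)
  cfg[names(list(...))] <- list(...)
  cfg
}

mill_type_defaults <- function() {
  data.frame(
    mill_type = c("lumber", "pulp", "OSB"),
    price = c(260, 640, 185),        # $ per product unit
    conversion = c(0.45, 0.24, 0.55),# product units per m3 raw timber
    unit_cost = c(55, 95, 48),       # harvest + processing, $/m3
    stringsAsFactors = FALSE)
}

# walk downstream from a cell until a river cell (or the grid edge)
walk_to_river <- function(cell, down, river) {
  while (!is.na(cell) && !river[cell]) cell <- down[cell]
  cell
}

#' Generate a synthetic landscape
#'
#' Builds a complete, reproducible `grid_landscape` from a config: regional
#' composition gradient, drainable DEM (sink-filled, with cached hydrology
#' and river network), precipitation surface, forest cohorts with
#' fire-cycle-like exponential stand ages, FMUs with mills and sustainable
#' annual allowable cuts, road classes, RUSLE soil/slope factors, water
#' monitoring points per calibration region group, and 4-year canola
#' rotation maps. Identical seed and config give a bitwise-identical
#' landscape.
#'
#' @param config see [synthetic_config()]
#' @param seed integer seed
#' @param curves curve library used to set sustainable AACs
#' @return a `grid_landscape`
#' @export
generate_synthetic_landscape <- function(config = synthetic_config(),
                                         seed = 1,
                                         curves = default_curve_library()) {
  if (config$n_rows < 8 || config$n_cols < 8)
    stop("synthetic landscape must be at least 8 x 8 cells")
  with_seed(derive_seed(seed, "landscape"), {
    nr <- config$n_rows; nc <- config$n_cols
    cs <- config$cell_size
    n <- nr * nc
    cell_area <- (cs / 100)^2
    cells <- make_cells(nr, nc, cs)
    colfrac <- (cells$col - 0.5) / nc
    breaks <- config$region_breaks
    region <- names(breaks)[findInterval(colfrac, c(0, unname(breaks)),
                                         rightmost.closed = TRUE)]
    cells$region <- region

    classes <- all_classes()
    comp <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
    k <- config$dirichlet_concentration
    for (rg in unique(region)) {
      sel <- which(region == rg)
      p <- config$archetypes[[rg]]
      p <- p / sum(p)
      draws <- matrix(0, length(sel), length(p))
      for (j in seq_along(p))
        draws[, j] <- stats::rgamma(length(sel), shape = p[j] * k)
      draws <- draws / rowSums(draws)
      comp[sel, names(p)] <- draws * cell_area
    }

    cells$elevation <- config$dem$west +
      (config$dem$east - config$dem$west) * colfrac +
      config$dem$ns_tilt * cells$row +
      stats::rnorm(n, 0, config$dem$roughness)
    cells$precipitation <- pmax(config$precip$min,
      config$precip$west + (config$precip$east - config$precip$west) *
        colfrac + stats::rnorm(n, 0, config$precip$sd))

    # roads: a paved east-west corridor through the middle, plus scattered
    # unpaved roads and low-speed corridors
    cells$road_class <- "none"
    u <- stats::runif(n)
    cells$road_class[u < config$road$corridor_prob] <- "corridor"
    cells$road_class[u >= config$road$corridor_prob &
                       u < config$road$corridor_prob +
                       config$road$unpaved_prob] <- "unpaved"
    cells$road_class[cells$row == (nr %/% 2)] <- "paved"

    cells$rusle_k <- stats::runif(n, 0.2, 0.45)

    # forest cohorts: 1-2 cohorts per forest cell, exponential age
    # distribution (fire-cycle analogue) capped at stand_age_max
    cohorts <- empty_cohorts()
    fc <- which(comp[, "forest"] > 0)
    if (length(fc)) {
      rows <- list()
      for (cell in fc) {
        m <- sample(1:2, 1)
        w <- if (m == 1) 1 else { s <- stats::runif(1, 0.3, 0.7); c(s, 1 - s) }
        age <- pmin(round(stats::rexp(m, 1 / config$stand_age_mean)),
                    config$stand_age_max)
        ez <- if (region[cell] %in% c("Mountains", "Foothills"))
          "Montane Cordillera" else "Boreal Plains"
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = cell,
          stand_type = sample(names(config$stand_type_probs), m,
                              replace = TRUE,
                              prob = config$stand_type_probs),
          ecozone = ez, age = as.integer(age),
          area = comp[cell, "forest"] * w, stringsAsFactors = FALSE)
      }
      cohorts <- do.call(rbind, rows)
    }

    # FMUs: vertical bands over the forested west; one mill per FMU
    mills <- NULL; fmus <- NULL
    forest_cells <- which(comp[, "forest"] > 0)
    if (config$n_fmus > 0 && length(forest_cells)) {
      if (config$n_fmus > length(forest_cells))
        stop("infeasible config: more mills than forest cells")
      forest_band <- cells$col <= ceiling(breaks["Boreal"] * nc)
      band_cols <- range(cells$col[forest_band])
      edges <- round(seq(band_cols[1] - 1, band_cols[2],
                         length.out = config$n_fmus + 1))
      fmu_of <- rep(NA_integer_, n)
      for (f in seq_len(config$n_fmus)) {
        fmu_of[forest_band & cells$col > edges[f] &
                 cells$col <= edges[f + 1]] <- f
      }
      cells$fmu_id <- fmu_of
      types <- mill_type_defaults()
      mill_rows <- list(); fmu_rows <- list()
      for (f in seq_len(config$n_fmus)) {
        members <- which(fmu_of == f)
        fcand <- intersect(members, forest_cells)
        if (!length(fcand))
          stop("infeasible config: FMU ", f, " contains no forest")
        # mill at the FMU cell nearest its centroid
        cx <- mean(cells$x[members]); cy <- mean(cells$y[members])
        mc <- fcand[which.min((cells$x[fcand] - cx)^2 +
                                (cells$y[fcand] - cy)^2)]
        cells$road_class[mc] <- "paved"
        ty <- types[(f - 1L) %% nrow(types) + 1L, ]
        co <- cohorts[cohorts$cell_id %in% members, ]
        aac <- if (nrow(co)) {
          v80 <- vapply(seq_len(nrow(co)), function(i)
            stand_volume(get_curve(curves, co$stand_type[i], co$ecozone[i]),
                         80), 0)
          sum(v80 * co$area) / 80 * config$aac_factor
        } else 0
        mill_rows[[f]] <- data.frame(id = f, cell_id = mc,
                                     mill_type = ty$mill_type,
                                     price = ty$price,
                                     conversion = ty$conversion,
                                     unit_cost = ty$unit_cost, fmu_id = f,
                                     stringsAsFactors = FALSE)
        fmu_rows[[f]] <- data.frame(id = f, aac = aac,
                                    frac_mean = config$frac_mean,
                                    frac_sd = config$frac_sd)
      }
      mills <- do.call(rbind, mill_rows)
      fmus <- do.call(rbind, fmu_rows)
    }

    # canola rotation: each cropland cell grows canola in one of 4 years
    canola <- NULL
    crop_cells <- which(comp[, "cropland"] > 0)
    if (length(crop_cells)) {
      canola <- matrix(0, n, 4)
      ry <- sample.int(4L, length(crop_cells), replace = TRUE)
      canola[cbind(crop_cells, ry)] <-
        comp[crop_cells, "cropland"] * config$canola_share
    }

    ls <- grid_landscape(nr, nc, cs, composition = comp, cells = cells,
                         cohorts = cohorts, canola = canola,
                         mills = mills, fmus = fmus, validate = FALSE)
    ls <- prepare_hydrology(ls, config$river_threshold)

    # RUSLE LS factor from the filled DEM's steepest slope
    z <- ls$hydrology$flow$z
    down <- ls$hydrology$flow$down
    slope <- ifelse(is.na(down), 0.005,
                    pmax(0.001, (z - z[ifelse(is.na(down), 1L, down)]) / cs))
    ls$cells$rusle_ls <- 0.065 + 4.56 * slope + 65.41 * slope^2

    # monitoring points: the highest-accumulation river cell in each
    # calibration region group, plus the overall network outlet
    acc <- ls$hydrology$flow$acc
    river <- ls$hydrology$network$river
    monitors <- list()
    for (g in c("mountains", "foothills", "plains")) {
      sel <- which(region_group(cells$region) == g)
      cand <- sel[river[sel]]
      if (!length(cand)) {
        # walk the group's wettest cell down to the river
        top <- sel[which.max(acc[sel])]
        hit <- walk_to_river(top, down, river)
        if (is.na(hit)) next
        cand <- hit
      }
      monitors[[g]] <- data.frame(label = g,
                                  cell_id = cand[which.max(acc[cand])],
                                  stringsAsFactors = FALSE)
    }
    if (any(river)) {
      monitors$outlet <- data.frame(label = "outlet",
                                    cell_id = which.max(acc * river),
                                    stringsAsFactors = FALSE)
    }
    ls$monitors <- do.call(rbind, c(monitors, make.row.names = FALSE))
    validate_landscape(ls)
    ls
  })
}
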