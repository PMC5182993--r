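#' Default per-cell traversal costs for timber transport
#'
#' Dollars per m3 of timber per 800 m cell step, by the best road class in
#' the cell; diagonal steps cost sqrt(2) times more. Travel time (hence
#' fixed hourly hauling cost) dominates transport cost, so high-speed paved
#' roads are cheapest and roadless cells most expensive.
#'
#' @return named numeric vector ($ m-3 per step)
#' @export
default_traversal_costs <- function() {
  c(paved = 0.02, unpaved = 0.06, corridor = 0.12, none = 0.25)
}

#' Build a mill's least-cost transport surface
#'
#' Accumulated least cost ($/m3) from every cell to the mill over the
#' 8-connected grid (Dijkstra). A step between two cells costs the mean of
#' their per-cell traversal rates, times sqrt(2) for diagonal moves; the
#' mill's own cell costs 0. Unreachable cells receive infinite cost and are
#' simply never harvested.
#'
#' @param landscape a `grid_landscape`
#' @param mill one row of the landscape's mill table (or a list with
#'   `cell_id`)
#' @param traversal_costs named $/m3-per-step rates per road class
#' @return a `cost_surface`: list with per-cell `costs` and the mill cell
#' @export
build_cost_surface <- function(landscape, mill,
                               traversal_costs = default_traversal_costs()) {
  stopifnot(all(traversal_costs > 0))
  rc <- landscape$cells$road_class
  if (!all(rc %in% names(traversal_costs)))
    stop("no traversal cost for road class: ",
         paste(setdiff(unique(rc), names(traversal_costs)), collapse = ", "))
  rate <- unname(traversal_costs[rc])
  n <- n_cells(landscape)
  mill_cell <- mill$cell_id
  if (is.null(mill_cell) || mill_cell < 1 || mill_cell > n)
    stop("mill is not located on the grid")
  nr <- landscape$n_rows; nc <- landscape$n_cols
  row_i <- landscape$cells$row; col_i <- landscape$cells$col
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (d in 1:4) {                     # E, SE, S, SW: each pair once
    rn <- row_i + d8_drow[d]; cn <- col_i + d8_dcol[d]
    ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    id <- (rn - 1L) * nc + cn
    from <- c(from, which(ok)); to <- c(to, id[ok])
    mult <- if (d %% 2 == 0) sqrt(2) else 1
    w <- c(w, 0.5 * (rate[ok] + rate[id[ok]]) * mult)
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  costs <- as.vector(igraph::distances(g, v = mill_cell, weights = w,
                                       algorithm = "dijkstra"))
  structure(list(mill_cell = mill_cell, costs = costs,
                 traversal_costs = traversal_costs), class = "cost_surface")
}

#' Draw the realized fraction of the Annual Allowable Cut
#'
#' The full AAC is typically not harvested; the realized fraction is a
#' normal draw (mean/sd reflecting historical harvest rates) truncated to
#' `[0, 1]` by inverse-CDF sampling.
#'
#' @param mean mean fraction, in `[0, 1]`
#' @param sd standard deviation, `>= 0`
#' @param n number of draws
#' @return fraction(s) in `[0, 1]`
#' @export
draw_aac_fraction <- function(mean, sd, n = 1) {
  if (!is.numeric(mean) || mean < 0 || mean > 1)
    stop("AAC fraction mean must lie in [0, 1]")
  if (!is.numeric(sd) || sd < 0) stop("AAC fraction sd must be >= 0")
  if (sd == 0) return(rep(mean, n))
  p0 <- stats::pnorm(0, mean, sd)
  p1 <- stats::pnorm(1, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (p1 - p0), mean, sd)
}

#' Cohorts eligible for harvest in an FMU
#'
#' Exactly the cohorts sitting in the FMU's cells with age at or above the
#' eligibility threshold (default 80 years) and positive area.
#'
#' @param landscape a `grid_landscape`
#' @param fmu_id FMU identifier
#' @param min_age harvest eligibility age (years)
#' @return data frame of eligible cohorts with their cohort-table row index
#' @export
eligible_stands <- function(landscape, fmu_id, min_age = 80) {
  co <- landscape$cohorts
  if (!nrow(co)) return(cbind(co, cohort = integer(0)))
  in_fmu <- !is.na(landscape$cells$fmu_id[co$cell_id]) &
    landscape$cells$fmu_id[co$cell_id] == fmu_id
  sel <- which(in_fmu & co$age >= min_age & co$area > 0)
  cbind(co[sel, , drop = FALSE], cohort = sel)
}

#' Cells a mill may enter this year
#'
#' The harvestable set is the cells holding eligible cohorts (see
#' [eligible_stands()]) minus cells that already carry an active cutblock
#' footprint: mills do not re-enter a recently harvested cell (a green-up
#' rule). Without it, partial-retention harvest would simply return to the
#' same cheapest cells year after year instead of extending across the
#' landscape.
#'
#' @inheritParams eligible_stands
#' @return integer vector of cell ids
#' @export
harvestable_cells <- function(landscape, fmu_id, min_age = 80) {
  elig <- eligible_stands(landscape, fmu_id, min_age)
  cells <- unique(elig$cell_id)
  cells[landscape$composition[cells, "cutblock"] <= 0]
}

#' Schedule one year of harvest for a mill
#'
#' Greedy profit-maximizing schedule: harvestable cells (eligible cohorts,
#' no active cutblock) are taken in ascending transport-cost order (ties by
#' row then column) until the cumulative harvested volume reaches the
#' realized AAC target or eligibles run out. Under `clearcut`, a selected
#' cell loses all of its eligible volume; under `variable_retention` each
#' selected cell has 25%, 50% or 75% of its volume harvested, chosen
#' uniformly at random per cell. The final cell is never split, so the
#' target may be overshot by at most one cell's volume.
#'
#' @param landscape a `grid_landscape`
#' @param fmu_id FMU to harvest in
#' @param curves a `curve_library`
#' @param cost_surface the mill's `cost_surface`
#' @param target volume target (m3) for the year
#' @param mode `"clearcut"` or `"variable_retention"`
#' @param min_age eligibility age
#' @return data frame of planned harvest entries (cell, cohort row, age,
#'   fraction, volume, transport cost), with attribute `exhausted`
#' @export
schedule_annual_harvest <- function(landscape, fmu_id, curves, cost_surface,
                                    target,
                                    mode = c("clearcut", "variable_retention"),
                                    min_age = 80) {
  mode <- match.arg(mode)
  if (is.null(cost_surface)) stop("no cost surface supplied")
  empty <- data.frame(cell = integer(), cohort = integer(), age = integer(),
                      fraction = numeric(), volume = numeric(),
                      transport_cost = numeric())
  if (target <= 0) { attr(empty, "exhausted") <- FALSE; return(empty) }
  elig <- eligible_stands(landscape, fmu_id, min_age)
  open <- harvestable_cells(landscape, fmu_id, min_age)
  elig <- elig[elig$cell_id %in% open &
                 is.finite(cost_surface$costs[elig$cell_id]), , drop = FALSE]
  if (!nrow(elig)) { attr(empty, "exhausted") <- TRUE; return(empty) }
  vol <- cohort_density(elig, curves, "growth") * elig$area
  cells <- unique(elig$cell_id)
  ord <- order(cost_surface$costs[cells],
               landscape$cells$row[cells], landscape$cells$col[cells])
  cells <- cells[ord]
  out <- vector("list", length(cells))
  cum <- 0; taken <- 0L
  for (cell in cells) {
    frac <- if (mode == "clearcut") 1 else sample(c(0.25, 0.5, 0.75), 1L)
    rows <- which(elig$cell_id == cell)
    taken <- taken + 1L
    out[[taken]] <- data.frame(
      cell = cell, cohort = elig$cohort[rows], age = elig$age[rows],
      fraction = frac, volume = vol[rows] * frac,
      transport_cost = cost_surface$costs[cell])
    cum <- cum + sum(vol[rows]) * frac
    if (cum >= target) break
  }
  res <- do.call(rbind, out[seq_len(taken)])
  attr(res, "exhausted") <- cum < target
  res
}

#' Apply a harvest to one cohort
#'
#' The harvested fraction of the cohort's area becomes a new age-0
#' regenerating cohort; the retained remainder keeps its age. The harvested
#' area is moved from the forest class into the forestry-cutblock footprint
#' class (composition closure is preserved), which is what the biodiversity
#' index sees.
#'
#' @param landscape a `grid_landscape`
#' @param cohort row index into the cohort table
#' @param fraction fraction of the cohort harvested, in `(0, 1]`
#' @return the updated landscape
#' @export
apply_harvest <- function(landscape, cohort, fraction) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("harvest fraction must lie in (0, 1]")
  co <- landscape$cohorts
  stopifnot(cohort >= 1, cohort <= nrow(co))
  cell <- co$cell_id[cohort]
  harvested <- fraction * co$area[cohort]
  if (fraction == 1) {
    landscape$cohorts$age[cohort] <- 0L
  } else {
    landscape$cohorts$area[cohort] <- co$area[cohort] - harvested
    landscape$cohorts <- rbind(landscape$cohorts, data.frame(
      cell_id = cell, stand_type = co$stand_type[cohort],
      ecozone = co$ecozone[cohort], age = 0L, area = harvested,
      stringsAsFactors = FALSE))
  }
  avail <- landscape$composition[cell, "forest"]
  if (avail < harvested - 1e-9 * landscape$cell_area)
    stop("harvest exceeds the cell's forest area")
  landscape$composition[cell, "forest"] <- max(0, avail - harvested)
  landscape$composition[cell, "cutblock"] <-
    landscape$composition[cell, "cutblock"] + min(harvested, avail)
  landscape
}

#' Annual cash flow of a mill
#'
#' Revenue is harvested volume times the mill's conversion factor (product
#' units per m3) times product price, less per-m3 harvest/processing cost
#' and the per-m3 transport cost of each harvested cell.
#'
#' @param ledger_year harvest entries for the year (see
#'   [schedule_annual_harvest()])
#' @param mill mill row/list with `price`, `conversion`, `unit_cost`
#' @return net cash flow ($) for the year
#' @export
mill_cashflow <- function(ledger_year, mill) {
  if (is.null(ledger_year) || !nrow(ledger_year)) return(0)
  sum(ledger_year$volume *
        (mill$conversion * mill$price - mill$unit_cost -
           ledger_year$transport_cost))
}

#' Net present value of a cash-flow stream
#'
#' `sum_t cashflow_t / (1 + rate)^t` with the first cash flow discounted one
#' period (t = 1).
#'
#' @param cashflows numeric vector, one value per year
#' @param rate discount rate (fraction), `> -1`
#' @return NPV ($)
#' @export
npv <- function(cashflows, rate = 0.02) {
  stopifnot(rate > -1)
  if (!length(cashflows)) return(0)
  sum(cashflows / (1 + rate)^seq_along(cashflows))
}

#' Run the multi-year timber-harvest simulation
#'
#' Annual loop: forests age one year, then each mill draws its realized AAC
#' fraction, schedules harvest greedily on its static transport-cost
#' surface, the harvest is applied (cohort splits, cutblock footprint), and
#' the year's cash flow is recorded. Outputs the NPV of harvesting, the
#' carbon trajectory, a per-cell discounted harvest-value map, the full
#' ledger and the post-harvest landscape. Identical seeds give identical
#' results.
#'
#' @param landscape a `grid_landscape` carrying `mills` and `fmus` tables
#' @param curves a `curve_library`
#' @param years simulation horizon (default 20)
#' @param mode `"clearcut"` or `"variable_retention"`
#' @param seed master seed for the run
#' @param discount_rate NPV discount rate
#' @param traversal_costs transport cost table
#' @param min_age harvest eligibility age
#' @return a `timber_sim` list
#' @export
run_timber_simulation <- function(landscape, curves = default_curve_library(),
                                  years = 20,
                                  mode = c("clearcut", "variable_retention"),
                                  seed = 1, discount_rate = 0.02,
                                  traversal_costs = default_traversal_costs(),
                                  min_age = 80) {
  mode <- match.arg(mode)
  mills <- landscape$mills; fmus <- landscape$fmus
  if (is.null(mills) || !nrow(mills)) stop("landscape has no mills")
  surfaces <- lapply(seq_len(nrow(mills)), function(i)
    build_cost_surface(landscape, mills[i, ], traversal_costs))
  n <- n_cells(landscape)
  cell_npv <- numeric(n)
  carbon <- numeric(years + 1)
  carbon[1] <- total_carbon(landscape, curves)
  cash <- matrix(0, max(years, 1), nrow(mills))
  ledger <- list()
  with_seed(derive_seed(seed, "timber"), {
    if (years >= 1) for (t in seq_len(years)) {
      landscape <- age_forests(landscape)
      for (i in seq_len(nrow(mills))) {
        mill <- mills[i, ]
        fmu <- fmus[fmus$id == mill$fmu_id, ]
        frac <- draw_aac_fraction(fmu$frac_mean, fmu$frac_sd)
        target <- frac * fmu$aac
        sched <- schedule_annual_harvest(landscape, fmu$id, curves,
                                         surfaces[[i]], target, mode, min_age)
        if (nrow(sched)) {
          for (k in order(sched$cohort)) {
            landscape <- apply_harvest(landscape, sched$cohort[k],
                                       sched$fraction[k])
          }
          cf <- mill_cashflow(sched, mill)
          cash[t, i] <- cf
          net <- sched$volume * (mill$conversion * mill$price -
                                   mill$unit_cost - sched$transport_cost)
          agg <- tapply(net, sched$cell, sum)
          cell_npv[as.integer(names(agg))] <-
            cell_npv[as.integer(names(agg))] +
            agg / (1 + discount_rate)^t
          ledger[[length(ledger) + 1L]] <- data.frame(
            year = t, mill_id = mill$id, fmu_id = fmu$id, sched,
            target = target,
            exhausted = attr(sched, "exhausted"))
        } else {
          ledger[[length(ledger) + 1L]] <- data.frame(
            year = t, mill_id = mill$id, fmu_id = fmu$id,
            cell = NA_integer_, cohort = NA_integer_, age = NA_integer_,
            fraction = NA_real_, volume = 0, transport_cost = NA_real_,
            target = target, exhausted = attr(sched, "exhausted"))
        }
      }
      carbon[t + 1] <- total_carbon(landscape, curves)
    }
  })
  ledger <- if (length(ledger)) do.call(rbind, ledger) else NULL
  cash_year <- rowSums(cash)
  structure(list(
    npv_total = npv(cash_year, discount_rate),
    npv_by_mill = apply(cash, 2, npv, rate = discount_rate),
    cashflows = cash_year, ledger = ledger,
    carbon = carbon, carbon_change = carbon[years + 1] - carbon[1],
    cell_npv = cell_npv, landscape = landscape,
    mode = mode, years = years, seed = seed), class = "timber_sim")
}

#' @export
print.timber_sim <- function(x, ...) {
  cat(sprintf("timber_sim: %d-year %s simulation\n", x$years, x$mode))
  cat(sprintf("  NPV: $%.0f; carbon %f -> %f t CO2e (%+.2f%%)\n",
              x$npv_total, x$carbon[1], x$carbon[length(x$carbon)],
              100 * x$carbon_change / max(x$carbon[1], 1e-12)))
  if (!is.null(x$ledger))
    cat(sprintf("  %d harvest entries over %d cells\n", nrow(x$ledger),
                length(unique(stats::na.omit(x$ledger$cell)))))
  invisible(x)
}
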