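#' Pollination model parameters
#'
#' Wild-bee abundance near a canola field is a saturating function of the
#' nesting habitat (natural plus semi-natural tame-pasture area) within
#' foraging distance; the additional canola yield attributable to
#' pollinators scales with that abundance. Value is the yield uplift times a
#' user-set canola price, discounted to net present value over the 4-year
#' crop rotation.
#'
#' @param radius foraging radius in metres (default 750)
#' @param radius_basis whether the radius is measured from the edge of the
#'   focal field (`"field_edge"`, the default: a field spans its cell, so
#'   the effective centroid radius is `radius + cell_size/2` and a 750 m
#'   radius reaches the 8 neighbors of an 800 m cell) or between cell
#'   centroids (`"centroid"`)
#' @param habitat_half_sat habitat area (ha) at which bee abundance reaches
#'   half its maximum; the default is scaled to neighborhood-aggregate
#'   habitat (a 3x3 block of 64 ha cells)
#' @param abundance_max maximum abundance index (dimensionless)
#' @param uplift_max maximum additional yield attributable to pollinators
#'   (t/ha) at full abundance
#' @param baseline_yield pollinator-independent canola yield (t/ha)
#' @param price canola price ($/t); default the 2010 crop price 461.81
#' @param discount_rate NPV discount rate (default 2%)
#' @param habitat_classes classes counted as nesting habitat
#' @return a `pollination_params` object
#' @export
pollination_params <- function(radius = 750,
                               radius_basis = c("field_edge", "centroid"),
                               habitat_half_sat = 200,
                               abundance_max = 1, uplift_max = 0.3,
                               baseline_yield = 1.3, price = 461.81,
                               discount_rate = 0.02,
                               habitat_classes = c("forest", "grassland",
                                                   "shrub", "pasture")) {
  radius_basis <- match.arg(radius_basis)
  stopifnot(radius >= 0, habitat_half_sat > 0, abundance_max >= 0,
            uplift_max >= 0, baseline_yield >= 0, price >= 0,
            discount_rate > -1)
  structure(list(radius = radius, radius_basis = radius_basis,
                 habitat_half_sat = habitat_half_sat,
                 abundance_max = abundance_max, uplift_max = uplift_max,
                 baseline_yield = baseline_yield, price = price,
                 discount_rate = discount_rate,
                 habitat_classes = habitat_classes),
            class = "pollination_params")
}

effective_radius <- function(params, cell_size) {
  params$radius + if (params$radius_basis == "field_edge") cell_size / 2 else 0
}

neighborhood_offsets <- function(radius, cell_size) {
  k <- floor(radius / cell_size)
  dr <- rep(-k:k, each = 2 * k + 1)
  dc <- rep(-k:k, times = 2 * k + 1)
  keep <- (dr * cell_size)^2 + (dc * cell_size)^2 <= radius^2
  cbind(dr = dr[keep], dc = dc[keep])
}

#' Nesting habitat within foraging distance of every cell
#'
#' Sums natural + semi-natural (tame pasture) area over all cells whose
#' centroids lie within `radius` of the focal cell's centroid, including the
#' focal cell. Cells beyond the grid edge contribute nothing. Note the
#' centroid semantics: a radius below the cell size degenerates to the
#' focal cell alone; [run_pollination()] translates a field-edge foraging
#' radius into the equivalent centroid radius first.
#'
#' @param landscape a `grid_landscape`
#' @param radius centroid-to-centroid radius in metres
#' @param habitat_classes classes counted as nesting habitat
#' @return numeric vector of habitat area (ha) per cell
#' @export
nesting_habitat_area <- function(landscape, radius = 750,
                                 habitat_classes = c("forest", "grassland",
                                                     "shrub", "pasture")) {
  stopifnot(radius >= 0)
  cls <- intersect(habitat_classes, colnames(landscape$composition))
  hab <- rowSums(landscape$composition[, cls, drop = FALSE])
  offs <- neighborhood_offsets(radius, landscape$cell_size)
  if (nrow(offs) == 1L) return(hab)
  nr <- landscape$n_rows; nc <- landscape$n_cols
  row_i <- landscape$cells$row; col_i <- landscape$cells$col
  out <- numeric(length(hab))
  for (k in seq_len(nrow(offs))) {
    rn <- row_i + offs[k, 1L]; cn <- col_i + offs[k, 2L]
    ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    out[ok] <- out[ok] + hab[(rn[ok] - 1L) * nc + cn[ok]]
  }
  out
}

#' Bee abundance as a saturating function of nesting habitat
#'
#' Michaelis-Menten form: `a_max * h / (h + h_half)`. Zero habitat gives
#' zero abundance; abundance is monotone non-decreasing and saturates at
#' `a_max`. The functional form is pluggable by replacing this function in
#' downstream code; all shipped behaviour relies only on the zero,
#' monotonicity and saturation properties.
#'
#' @param habitat_ha habitat area (ha), vectorized
#' @param params a `pollination_params`
#' @return abundance index (dimensionless, >= 0)
#' @export
bee_abundance <- function(habitat_ha, params = pollination_params()) {
  stopifnot(all(habitat_ha >= 0))
  params$abundance_max * habitat_ha / (habitat_ha + params$habitat_half_sat)
}

uplift_per_ha <- function(habitat_ha, params) {
  params$uplift_max * bee_abundance(habitat_ha, params) / params$abundance_max
}

#' Pollinator-attributable yield and value for one cell-year
#'
#' Additional yield is the cell's canola area times the per-ha uplift at the
#' local bee abundance; value multiplies by the canola price. Cells not
#' growing canola that year return zero by contract.
#'
#' @param landscape a `grid_landscape` with a 4-year canola rotation
#' @param cell cell id
#' @param rotation_year rotation year (1-4)
#' @param params a `pollination_params`
#' @return list with `uplift_t` (t) and `value` ($)
#' @export
pollination_uplift <- function(landscape, cell, rotation_year,
                               params = pollination_params()) {
  if (is.null(landscape$canola)) stop("landscape has no canola rotation maps")
  area <- landscape$canola[cell, rotation_year]
  if (area <= 0) return(list(uplift_t = 0, value = 0))
  hab <- nesting_habitat_area(landscape,
                              effective_radius(params, landscape$cell_size),
                              params$habitat_classes)[cell]
  up <- area * uplift_per_ha(hab, params)
  list(uplift_t = up, value = up * params$price)
}

#' Run the pollination model over the crop rotation
#'
#' Computes, for every simulated year, each canola cell's
#' pollinator-attributable value and total canola revenue
#' `(baseline + uplift) x area x price`, then discounts to net present
#' value. The 4-year rotation repeats when `years > 4`.
#'
#' @param landscape a `grid_landscape` with canola rotation maps
#' @param params a `pollination_params`
#' @param years number of years simulated (default one full rotation)
#' @return a `pollination_result`: per-cell NPV map, totals, per-year values
#' @export
run_pollination <- function(landscape, params = pollination_params(),
                            years = 4) {
  if (is.null(landscape$canola))
    stop("landscape has no canola rotation maps (4 years required)")
  if (ncol(landscape$canola) != 4L) stop("rotation requires exactly 4 years")
  hab <- nesting_habitat_area(landscape,
                              effective_radius(params, landscape$cell_size),
                              params$habitat_classes)
  up_ha <- uplift_per_ha(hab, params)
  n <- n_cells(landscape)
  cell_value_npv <- numeric(n)
  year_value <- numeric(years)
  year_revenue <- numeric(years)
  for (t in seq_len(years)) {
    ry <- ((t - 1L) %% 4L) + 1L
    area <- landscape$canola[, ry]
    value <- area * up_ha * params$price
    revenue <- area * (params$baseline_yield + up_ha) * params$price
    disc <- (1 + params$discount_rate)^t
    cell_value_npv <- cell_value_npv + value / disc
    year_value[t] <- sum(value)
    year_revenue[t] <- sum(revenue)
  }
  # a field is a planting unit: one (cell, rotation-year) parcel of canola;
  # converted pasture becomes a new field in its own rotation year, distinct
  # from the cell's pre-existing cropland parcel
  fields <- sum(landscape$canola > 0)
  structure(list(
    cell_value_npv = cell_value_npv,
    total_value_npv = sum(cell_value_npv),
    per_field_value_npv = if (fields > 0)
      sum(cell_value_npv) / fields else 0,
    revenue_npv = npv(year_revenue, params$discount_rate),
    year_value = year_value, year_revenue = year_revenue,
    n_fields = fields, habitat = hab),
    class = "pollination_result")
}

#' @export
print.pollination_result <- function(x, ...) {
  cat(sprintf(paste0("pollination_result: NPV $%.0f over %d fields ",
                     "($%.0f per field); canola revenue NPV $%.0f\n"),
              x$total_value_npv, x$n_fields, x$per_field_value_npv,
              x$revenue_npv))
  invisible(x)
}
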