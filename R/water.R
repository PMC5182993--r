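#' Fill sinks in a DEM by priority flooding
#'
#' Raises closed depressions to their spill elevation plus a small epsilon
#' gradient so that every cell drains to a grid edge and D8 directions are
#' resolvable everywhere (no flats). The output DEM is elementwise greater
#' than or equal to the input; already-drainable surfaces are unchanged.
#'
#' @param dem matrix of elevations (row 1 = northern edge)
#' @param epsilon minimal downhill increment imposed on filled flats (m)
#' @return the filled DEM matrix
#' @export
fill_sinks <- function(dem, epsilon = 1e-4) {
  stopifnot(is.matrix(dem), all(is.finite(dem)))
  nr <- nrow(dem); nc <- ncol(dem)
  if (nr < 3 || nc < 3) return(dem)
  filled <- dem
  seen <- matrix(FALSE, nr, nc)
  border <- which(row(dem) == 1 | row(dem) == nr | col(dem) == 1 | col(dem) == nc)
  seen[border] <- TRUE
  pq_i <- border
  pq_p <- dem[border]
  while (length(pq_i)) {
    k <- which.min(pq_p)
    cc <- pq_i[k]; pc <- pq_p[k]
    pq_i <- pq_i[-k]; pq_p <- pq_p[-k]
    ri <- ((cc - 1L) %% nr) + 1L
    cj <- ((cc - 1L) %/% nr) + 1L
    for (d in 1:8) {
      rn <- ri + d8_drow[d]; cn <- cj + d8_dcol[d]
      if (rn < 1L || rn > nr || cn < 1L || cn > nc) next
      nn <- rn + (cn - 1L) * nr
      if (seen[nn]) next
      seen[nn] <- TRUE
      filled[nn] <- max(dem[nn], pc + epsilon)
      pq_i <- c(pq_i, nn)
      pq_p <- c(pq_p, filled[nn])
    }
  }
  filled
}

# landscape elevations (id order, row-major) <-> matrix form
elev_matrix <- function(landscape, values = landscape$cells$elevation) {
  matrix(values, landscape$n_rows, landscape$n_cols, byrow = TRUE)
}
matrix_to_ids <- function(m) as.vector(t(m))

#' D8 flow directions and flow accumulation
#'
#' Each cell drains to its steepest-descent neighbor among the 8 adjacent
#' cells (diagonal distance sqrt(2) x cell size); ties break by the fixed
#' E, SE, S, SW, W, NW, N, NE ordering. Border cells with no lower neighbor
#' drain off-grid (`NA` direction). Flow accumulation counts the number of
#' cells draining through each cell, including itself.
#'
#' @param dem sink-filled DEM matrix (see [fill_sinks()])
#' @param cell_size cell edge length (m)
#' @return a `flow_field`: list with `down` (downstream cell id per cell, NA
#'   = off-grid outlet), `acc` (accumulation counts), `z` (filled elevations,
#'   id order), `order` (ids from high to low elevation)
#' @export
d8_flow_directions <- function(dem, cell_size = 800) {
  nr <- nrow(dem); nc <- ncol(dem); n <- nr * nc
  z <- matrix_to_ids(dem)
  row_i <- ((seq_len(n) - 1L) %/% nc) + 1L
  col_i <- ((seq_len(n) - 1L) %% nc) + 1L
  dist <- cell_size * c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))
  grad <- matrix(-Inf, n, 8)
  nid <- matrix(NA_integer_, n, 8)
  for (d in 1:8) {
    rn <- row_i + d8_drow[d]; cn <- col_i + d8_dcol[d]
    ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    id <- (rn - 1L) * nc + cn
    nid[ok, d] <- id[ok]
    grad[ok, d] <- (z[ok] - z[id[ok]]) / dist[d]
  }
  best <- do.call(pmax, as.data.frame(grad))
  down <- rep(NA_integer_, n)
  has <- best > 0
  pick <- rep(NA_integer_, n)
  for (d in 8:1) pick[has & grad[, d] == best] <- d
  down[has] <- nid[cbind(which(has), pick[has])]
  # interior cell without a lower neighbor can only arise on an unfilled
  # DEM; route it to its lowest neighbor (first in the tie order)
  interior <- row_i > 1L & row_i < nr & col_i > 1L & col_i < nc
  flat <- !has & interior
  if (any(flat)) {
    zz <- matrix(Inf, n, 8)
    ok <- !is.na(nid)
    zz[ok] <- z[nid[ok]]
    lowest <- do.call(pmin, as.data.frame(zz))
    pick2 <- rep(NA_integer_, n)
    for (d in 8:1) pick2[flat & zz[, d] == lowest] <- d
    down[flat] <- nid[cbind(which(flat), pick2[flat])]
  }
  ord <- order(z, decreasing = TRUE)
  acc <- rep(1L, n)
  for (c in ord) {
    dn <- down[c]
    if (!is.na(dn)) acc[dn] <- acc[dn] + acc[c]
  }
  structure(list(down = down, acc = acc, z = z, order = ord,
                 n_rows = nr, n_cols = nc, cell_size = cell_size),
            class = "flow_field")
}

#' Extract the river network from flow accumulation
#'
#' Cells with at least `threshold` cells of upstream accumulation are river
#' cells; directed links between consecutive river cells follow the D8
#' directions, forming a forest (each river cell has at most one downstream
#' link).
#'
#' @param flow a `flow_field` from [d8_flow_directions()]
#' @param threshold stream-initiation threshold in cells of accumulation
#' @return a `river_network`: list with logical `river` per cell, `links`
#'   data frame (from, to), and the threshold used
#' @export
extract_river_network <- function(flow, threshold) {
  stopifnot(threshold >= 1)
  river <- flow$acc >= threshold
  if (!any(river))
    warning("river threshold exceeds all accumulation values; empty network")
  from <- which(river & !is.na(flow$down))
  from <- from[river[flow$down[from]]]
  links <- data.frame(from = from, to = flow$down[from])
  structure(list(river = river, links = links, threshold = threshold),
            class = "river_network")
}

#' Prepare and cache the hydrological skeleton of a landscape
#'
#' Fills sinks, derives D8 directions/accumulation and the river network,
#' and stores them on the landscape so repeated water-year runs (and
#' scenario sweeps that never touch the DEM) do not recompute them.
#'
#' @param landscape a `grid_landscape`
#' @param river_threshold stream-initiation threshold (cells); default 1% of
#'   the grid, at least 5
#' @param epsilon sink-filling epsilon
#' @return the landscape with `$hydrology` populated
#' @export
prepare_hydrology <- function(landscape, river_threshold = NULL,
                              epsilon = 1e-4) {
  if (is.null(river_threshold))
    river_threshold <- max(5, round(0.01 * n_cells(landscape)))
  filled <- fill_sinks(elev_matrix(landscape), epsilon)
  flow <- d8_flow_directions(filled, landscape$cell_size)
  net <- extract_river_network(flow, river_threshold)
  landscape$hydrology <- list(flow = flow, network = net,
                              river_threshold = river_threshold)
  landscape
}

#' Water-purification parameter tables
#'
#' Named coefficient tables keyed by landcover class, substance and
#' calibration region group. Runoff coefficients are the fraction of annual
#' precipitation leaving each class as surface runoff; export coefficients
#' (kg ha-1 mm-1 of annual precipitation) give non-point-source loading of
#' N, P and TSS; retention fractions are the share of a transported load
#' removed while runoff crosses a cell of each class; RUSLE C factors (with
#' a precipitation-proportional R factor and practice factor P) drive
#' sediment erosion. The three regional coefficient groups are `mountains`,
#' `foothills` and `plains` (Boreal, Parkland and Grassland pooled).
#'
#' All shipped values are placeholder magnitudes with the right ordering
#' (cropland and developed classes export more and retain less than intact
#' cover); calibrate against observations for any real deployment.
#'
#' @param runoff named fraction per class
#' @param export 3-d array `class x substance(N,P,TSS) x group`
#' @param retention matrix `class x substance(N,P,TSS,sediment)`
#' @param rusle_c named C factor per class
#' @param rusle_p support-practice factor
#' @param r_per_mm rainfall-erosivity factor per mm annual precipitation
#' @param river_threshold optional stream-initiation threshold (cells)
#' @return a `water_params` object
#' @export
water_params <- function(runoff = NULL, export = NULL, retention = NULL,
                         rusle_c = NULL, rusle_p = 1, r_per_mm = 0.5,
                         river_threshold = NULL) {
  classes <- all_classes()
  if (is.null(runoff)) {
    runoff <- c(forest = 0.15, grassland = 0.22, shrub = 0.18, water = 0.95,
                pasture = 0.25, road = 0.85, trail = 0.55, cutblock = 0.30,
                cropland = 0.40, industrial = 0.80, urban = 0.85)
  }
  if (is.null(export)) {
    base <- rbind(
      N   = c(forest = 0.0012, grassland = 0.0015, shrub = 0.0013,
              water = 0.0008, pasture = 0.0030, road = 0.0050,
              trail = 0.0020, cutblock = 0.0035, cropland = 0.0065,
              industrial = 0.0060, urban = 0.0080),
      P   = c(forest = 0.00010, grassland = 0.00015, shrub = 0.00012,
              water = 0.00008, pasture = 0.00040, road = 0.00080,
              trail = 0.00030, cutblock = 0.00045, cropland = 0.00110,
              industrial = 0.00090, urban = 0.00120),
      TSS = c(forest = 0.05, grassland = 0.08, shrub = 0.06, water = 0.01,
              pasture = 0.20, road = 1.20, trail = 0.40, cutblock = 0.50,
              cropland = 0.90, industrial = 1.00, urban = 1.10))
    export <- array(0, dim = c(length(classes), 3, 3),
                    dimnames = list(classes, c("N", "P", "TSS"),
                                    c("mountains", "foothills", "plains")))
    mult <- c(mountains = 0.6, foothills = 0.8, plains = 1.0)
    for (g in names(mult)) export[, , g] <- t(base)[classes, ] * mult[g]
  }
  if (is.null(retention)) {
    retention <- rbind(
      forest     = c(0.40, 0.50, 0.70, 0.70),
      grassland  = c(0.30, 0.35, 0.55, 0.55),
      shrub      = c(0.35, 0.40, 0.60, 0.60),
      water      = c(0.70, 0.75, 0.85, 0.85),
      pasture    = c(0.25, 0.30, 0.45, 0.45),
      road       = c(0.00, 0.00, 0.00, 0.00),
      trail      = c(0.05, 0.05, 0.05, 0.05),
      cutblock   = c(0.20, 0.25, 0.35, 0.35),
      cropland   = c(0.08, 0.10, 0.15, 0.15),
      industrial = c(0.02, 0.02, 0.02, 0.02),
      urban      = c(0.05, 0.05, 0.05, 0.05))
    colnames(retention) <- c("N", "P", "TSS", "sediment")
  }
  if (is.null(rusle_c)) {
    rusle_c <- c(forest = 0.001, grassland = 0.003, shrub = 0.003, water = 0,
                 pasture = 0.02, road = 0.05, trail = 0.08, cutblock = 0.15,
                 cropland = 0.30, industrial = 0.05, urban = 0.01)
  }
  stopifnot(all(runoff >= 0 & runoff <= 1), all(export >= 0),
            all(retention >= 0 & retention <= 1))
  structure(list(runoff = runoff, export = export, retention = retention,
                 rusle_c = rusle_c, rusle_p = rusle_p, r_per_mm = r_per_mm,
                 river_threshold = river_threshold),
            class = "water_params")
}

region_group <- function(region) {
  ifelse(region == "Mountains", "mountains",
         ifelse(region == "Foothills", "foothills", "plains"))
}

check_classes_covered <- function(landscape, coef_names, what) {
  present <- colnames(landscape$composition)[colSums(landscape$composition) > 0]
  missing <- setdiff(present, coef_names)
  if (length(missing))
    stop("missing ", what, " coefficient for class: ",
         paste(missing, collapse = ", "))
}

#' Annual runoff depth and volume per cell
#'
#' The cell runoff coefficient is the area-weighted sum of per-class runoff
#' coefficients; depth (mm) is that fraction of annual precipitation, and
#' volume converts depth over the cell area.
#'
#' @param landscape a `grid_landscape`
#' @param params a `water_params`
#' @return data frame with `depth_mm` and `volume_m3` per cell
#' @export
cell_runoff <- function(landscape, params = water_params()) {
  check_classes_covered(landscape, names(params$runoff), "runoff")
  cls <- intersect(colnames(landscape$composition), names(params$runoff))
  coeff <- drop(landscape$composition[, cls, drop = FALSE] %*%
                  params$runoff[cls]) / landscape$cell_area
  depth <- landscape$cells$precipitation * coeff
  data.frame(depth_mm = depth,
             volume_m3 = depth / 1000 * landscape$cell_area * 1e4)
}

#' RUSLE annual soil loss
#'
#' `A = R * K * LS * C * P` per hectare, times the area considered.
#'
#' @param R rainfall erosivity
#' @param K soil erodibility
#' @param LS slope length-steepness factor
#' @param C cover factor (area-weighted over a cell's classes upstream)
#' @param P support-practice factor
#' @param area_ha area the loss applies to
#' @return soil loss in t/yr (vectorized)
#' @export
rusle_erosion <- function(R, K, LS, C, P = 1, area_ha = 1) {
  if (any(c(R, K, LS, C, P, area_ha) < 0)) stop("RUSLE factors must be >= 0")
  R * K * LS * C * P * area_ha
}

#' Annual substance loading per cell
#'
#' N, P and TSS loads are export-coefficient based:
#' `load_s = precip (mm) * sum_class area_class (ha) * e(class, s, region)`.
#' Sediment is the RUSLE estimate with the C factor area-weighted over the
#' cell's classes, converted to kg.
#'
#' @inheritParams cell_runoff
#' @return matrix `n_cells x c("N","P","TSS","sediment")`, kg/yr
#' @export
cell_loading <- function(landscape, params = water_params()) {
  comp <- landscape$composition
  check_classes_covered(landscape, rownames(params$export), "export")
  check_classes_covered(landscape, names(params$rusle_c), "RUSLE C")
  n <- n_cells(landscape)
  out <- matrix(0, n, 4, dimnames = list(NULL, c("N", "P", "TSS", "sediment")))
  grp <- region_group(landscape$cells$region)
  cls <- rownames(params$export)
  cls <- intersect(colnames(comp), cls)
  for (g in unique(grp)) {
    sel <- grp == g
    for (s in c("N", "P", "TSS")) {
      out[sel, s] <- landscape$cells$precipitation[sel] *
        drop(comp[sel, cls, drop = FALSE] %*% params$export[cls, s, g])
    }
  }
  ccls <- intersect(colnames(comp), names(params$rusle_c))
  cw <- drop(comp[, ccls, drop = FALSE] %*% params$rusle_c[ccls]) /
    landscape$cell_area
  R <- params$r_per_mm * landscape$cells$precipitation
  out[, "sediment"] <- 1000 * rusle_erosion(
    R, landscape$cells$rusle_k, landscape$cells$rusle_ls, cw,
    params$rusle_p, landscape$cell_area)
  out
}

# area-weighted retention fraction per cell and substance
cell_retention <- function(landscape, params) {
  cls <- intersect(colnames(landscape$composition), rownames(params$retention))
  check_classes_covered(landscape, rownames(params$retention), "retention")
  r <- (landscape$composition[, cls, drop = FALSE] %*%
          params$retention[cls, , drop = FALSE]) / landscape$cell_area
  clamp(r, 0, 1)
}

#' Route runoff loads overland to the river network
#'
#' Every cell's annual runoff is a water parcel ("raindrop") that follows
#' the D8 path downslope. While crossing each transit cell (cells strictly
#' between the origin and the river; the origin's own load leaves
#' unattenuated), the parcel loses the transit cell's area-weighted
#' retention fraction of each substance; water volume is conserved. Parcels
#' whose path exits the grid edge without meeting the river are tallied
#' against an implicit edge outlet. The traversal is a single topological
#' pass over the flow field, so it is exactly the per-parcel product chain
#' `delivered = load * prod(1 - r_i)` for every origin.
#'
#' @param landscape a `grid_landscape` with prepared hydrology
#' @param params a `water_params`
#' @param loads matrix `n_cells x substances` of origin loads (kg);
#'   defaults to [cell_loading()]
#' @param volumes per-cell runoff volumes (m3); defaults to [cell_runoff()]
#' @return list with per-cell matrices `supplied` (amount of each origin's
#'   load delivered to the river), `supplied_edge`, `removed` (removal
#'   credited to each transit cell), `river_input` (delivery at each river
#'   entry cell), per-cell `flow_in` volumes entering river cells,
#'   `transmission` and `destination`, plus edge totals
#' @export
route_overland <- function(landscape, params = water_params(), loads = NULL,
                           volumes = NULL) {
  if (is.null(landscape$hydrology))
    stop("hydrology not prepared; call prepare_hydrology() first")
  if (is.null(loads)) loads <- cell_loading(landscape, params)
  if (is.null(volumes)) volumes <- cell_runoff(landscape, params)$volume_m3
  flow <- landscape$hydrology$flow
  river <- landscape$hydrology$network$river
  n <- n_cells(landscape)
  subs <- colnames(loads)
  r <- cell_retention(landscape, params)[, subs, drop = FALSE]
  down <- flow$down
  ord <- flow$order                      # upstream (high) first
  arriving <- matrix(0, n, length(subs), dimnames = list(NULL, subs))
  vol_arriving <- numeric(n)
  removed <- matrix(0, n, length(subs), dimnames = list(NULL, subs))
  river_input <- matrix(0, n, length(subs), dimnames = list(NULL, subs))
  flow_in <- numeric(n)
  edge_load <- stats::setNames(numeric(length(subs)), subs)
  edge_flow <- 0
  for (c in ord) {
    if (river[c]) {
      river_input[c, ] <- arriving[c, ] + loads[c, ]
      flow_in[c] <- vol_arriving[c] + volumes[c]
    } else {
      rem <- arriving[c, ] * r[c, ]
      removed[c, ] <- rem
      out <- arriving[c, ] - rem + loads[c, ]
      vout <- vol_arriving[c] + volumes[c]
      d <- down[c]
      if (is.na(d)) {
        edge_load <- edge_load + out
        edge_flow <- edge_flow + vout
      } else {
        arriving[d, ] <- arriving[d, ] + out
        vol_arriving[d] <- vol_arriving[d] + vout
      }
    }
  }
  # per-origin transmission and destination (each cell has a unique path)
  trans <- matrix(1, n, length(subs), dimnames = list(NULL, subs))
  dest <- integer(n)                     # 0 = edge outlet, else river cell id
  for (c in rev(ord)) {                  # downstream first
    if (river[c]) { dest[c] <- c; next }
    d <- down[c]
    if (is.na(d)) { dest[c] <- 0L; next }
    if (river[d]) { dest[c] <- d; next }
    trans[c, ] <- (1 - r[d, ]) * trans[d, ]
    dest[c] <- dest[d]
  }
  delivered <- loads * trans
  supplied <- delivered
  supplied[dest == 0L, ] <- 0
  supplied_edge <- delivered
  supplied_edge[dest != 0L, ] <- 0
  list(supplied = supplied, supplied_edge = supplied_edge, removed = removed,
       river_input = river_input, flow_in = flow_in,
       transmission = trans, destination = dest,
       edge_load = edge_load, edge_flow = edge_flow)
}

#' Accumulate deliveries down the river network
#'
#' Loads and flow entering each river cell move downstream along the network
#' links with no in-stream attenuation; each monitoring point reports the
#' cumulative annual flow and load of everything upstream of (and including)
#' its cell.
#'
#' @param landscape a `grid_landscape` with prepared hydrology
#' @param river_input matrix `n_cells x substances` of loads entering each
#'   river cell (kg)
#' @param flow_in per-cell water volume entering each river cell (m3)
#' @param monitors data frame with columns `label`, `cell_id`; defaults to
#'   the landscape's monitoring points
#' @return list with accumulated matrices (`load`, `flow` per river cell)
#'   and the `monitors` table of cumulative annual flow and loads
#' @export
accumulate_river <- function(landscape, river_input, flow_in,
                             monitors = landscape$monitors) {
  hy <- landscape$hydrology
  if (is.null(hy)) stop("hydrology not prepared")
  river <- hy$network$river
  down <- hy$flow$down
  if (!is.null(monitors) && nrow(monitors) &&
      !all(river[monitors$cell_id]))
    stop("monitoring point off the river network: ",
         paste(monitors$label[!river[monitors$cell_id]], collapse = ", "))
  load <- river_input
  flow <- flow_in
  for (c in hy$flow$order) {             # upstream first
    if (!river[c]) next
    d <- down[c]
    if (!is.na(d) && river[d]) {
      load[d, ] <- load[d, ] + load[c, ]
      flow[d] <- flow[d] + flow[c]
    }
  }
  mon <- NULL
  if (!is.null(monitors) && nrow(monitors)) {
    mon <- cbind(monitors,
                 flow_m3 = flow[monitors$cell_id],
                 as.data.frame(load[monitors$cell_id, , drop = FALSE]))
  }
  list(load = load, flow = flow, monitors = mon)
}

#' Simulate one water year
#'
#' Composes runoff, loading, RUSLE erosion, overland routing with retention,
#' and river accumulation into the annual water-purification result:
#' per-cell loading/removal/supplied maps, the monitoring-point table, and
#' landscape totals with their mass balance (loading = supplied to river +
#' supplied past the grid edge + retained overland, exactly, per substance).
#'
#' @param landscape a `grid_landscape`; hydrology is prepared on the fly if
#'   absent
#' @param params a `water_params`
#' @return a `water_result` list
#' @export
run_water_year <- function(landscape, params = water_params()) {
  if (is.null(landscape$hydrology))
    landscape <- prepare_hydrology(landscape, params$river_threshold)
  runoff <- cell_runoff(landscape, params)
  loading <- cell_loading(landscape, params)
  routed <- route_overland(landscape, params, loading, runoff$volume_m3)
  acc <- accumulate_river(landscape, routed$river_input, routed$flow_in)
  subs <- colnames(loading)
  totals <- data.frame(
    substance = subs,
    loading = colSums(loading),
    supplied_river = colSums(routed$supplied),
    supplied_edge = colSums(routed$supplied_edge),
    removed = colSums(routed$removed),
    row.names = NULL)
  totals$balance_error <- with(totals, abs(
    loading - supplied_river - supplied_edge - removed) / pmax(loading, 1e-12))
  structure(list(
    cells = data.frame(landscape$cells[c("id", "row", "col")],
                       runoff_mm = runoff$depth_mm,
                       runoff_m3 = runoff$volume_m3,
                       loading = loading, supplied = routed$supplied,
                       removed = routed$removed),
    monitors = acc$monitors,
    river = list(load = acc$load, flow = acc$flow),
    routed = routed, loading = loading, runoff = runoff,
    totals = totals), class = "water_result")
}

#' @export
print.water_result <- function(x, ...) {
  cat("water_result: annual water-purification simulation\n")
  print(x$totals[c("substance", "loading", "supplied_river", "removed")],
        row.names = FALSE)
  if (!is.null(x$monitors)) {
    cat("monitoring points:\n")
    print(x$monitors, row.names = FALSE)
  }
  invisible(x)
}
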