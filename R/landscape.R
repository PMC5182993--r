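#' Default landcover / human-footprint taxonomy
#'
#' The cellular landscape stores, for every cell, the area (ha) of each
#' landcover or footprint class present. Classes are partitioned into natural
#' classes (forest, grassland, shrub, water, and semi-natural tame pasture)
#' and human-footprint classes (roads, trails, forestry cutblocks, annual
#' cropland, industrial and urban development). The taxonomy is configurable:
#' any replacement must keep the same two-list structure, and unknown classes
#' encountered in inputs are rejected rather than silently pooled.
#'
#' @return a list with character vectors `natural` and `footprint`
#' @export
default_taxonomy <- function() {
  list(
    natural   = c("forest", "grassland", "shrub", "water", "pasture"),
    footprint = c("road", "trail", "cutblock", "cropland", "industrial", "urban")
  )
}

#' All classes of a taxonomy, natural first
#' @param taxonomy a taxonomy list as returned by [default_taxonomy()]
#' @export
all_classes <- function(taxonomy = default_taxonomy()) {
  unname(unlist(taxonomy))
}

empty_cohorts <- function() {
  data.frame(cell_id = integer(), stand_type = character(),
             ecozone = character(), age = integer(), area = numeric(),
             stringsAsFactors = FALSE)
}

make_cells <- function(n_rows, n_cols, cell_size) {
  id <- seq_len(n_rows * n_cols)
  row <- ((id - 1L) %/% n_cols) + 1L
  col <- ((id - 1L) %% n_cols) + 1L
  data.frame(
    id = id, row = row, col = col,
    x = (col - 0.5) * cell_size,
    y = (n_rows - row + 0.5) * cell_size,
    elevation = 0, region = "Grassland", fmu_id = NA_integer_,
    precipitation = 450, road_class = "none",
    rusle_k = 0.3, rusle_ls = 0.5,
    stringsAsFactors = FALSE
  )
}

#' Construct a gridded landscape
#'
#' A `grid_landscape` is a uniform grid of square cells. Each cell holds a
#' fractional landcover composition (areas in ha summing to the cell area),
#' per-cell environmental state (elevation, precipitation, region, road
#' class, RUSLE soil/slope factors), and forest stand cohorts. The default
#' 800 m cell mirrors the quarter-section parcels at which many land-use
#' decisions are made; the cell size is a free parameter and all areas are
#' stored in hectares (800 m -> 64 ha cells).
#'
#' @param n_rows,n_cols grid dimensions
#' @param cell_size cell edge length in metres (default 800)
#' @param composition numeric matrix `n_cells x classes` of areas (ha); if
#'   `NULL`, every cell is initialized as pure grassland
#' @param cells data frame of per-cell state (built automatically if `NULL`)
#' @param cohorts forest stand cohort table with columns `cell_id`,
#'   `stand_type`, `ecozone`, `age`, `area`
#' @param taxonomy class taxonomy, see [default_taxonomy()]
#' @param canola optional `n_cells x 4` matrix of canola area (ha) per
#'   rotation year
#' @param mills,fmus,monitors optional agent tables (see
#'   [generate_synthetic_landscape()])
#' @param validate check invariants on construction
#' @param tol relative tolerance for composition closure
#' @return an object of class `grid_landscape`
#' @export
grid_landscape <- function(n_rows, n_cols, cell_size = 800,
                           composition = NULL, cells = NULL, cohorts = NULL,
                           taxonomy = default_taxonomy(), canola = NULL,
                           mills = NULL, fmus = NULL, monitors = NULL,
                           validate = TRUE, tol = 1e-6) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  n <- as.integer(n_rows) * as.integer(n_cols)
  cell_area <- (cell_size / 100)^2
  classes <- all_classes(taxonomy)
  if (is.null(composition)) {
    composition <- matrix(0, n, length(classes),
                          dimnames = list(NULL, classes))
    composition[, "grassland"] <- cell_area
  }
  if (is.null(colnames(composition)))
    stop("composition matrix must have class column names")
  if (!all(colnames(composition) %in% classes))
    stop("unknown landcover class: ",
         paste(setdiff(colnames(composition), classes), collapse = ", "))
  # expand to the full taxonomy so downstream code can index by class name
  full <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  full[, colnames(composition)] <- composition
  if (is.null(cells)) cells <- make_cells(n_rows, n_cols, cell_size)
  if (is.null(cohorts)) cohorts <- empty_cohorts()
  x <- structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size = cell_size, cell_area = cell_area,
    cells = cells, composition = full, cohorts = cohorts,
    taxonomy = taxonomy, canola = canola,
    mills = mills, fmus = fmus, monitors = monitors,
    hydrology = NULL
  ), class = "grid_landscape")
  if (validate) validate_landscape(x, tol = tol)
  x
}

n_cells <- function(landscape) landscape$n_rows * landscape$n_cols

#' Validate the invariants of a gridded landscape
#'
#' Checks composition closure (per-cell class areas sum to the cell area),
#' non-negativity, cohort consistency (per-cell cohort areas sum to the
#' forest plus cutblock area, the cutblock share being regenerating stands
#' created by harvest), finite elevations and non-negative precipitation.
#'
#' @param landscape a `grid_landscape`
#' @param tol relative tolerance on area sums
#' @return invisibly `TRUE`; stops with an informative error otherwise
#' @export
validate_landscape <- function(landscape, tol = 1e-6) {
  x <- landscape
  comp <- x$composition
  if (any(comp < -tol * x$cell_area)) stop("negative class area in composition")
  bad <- abs(rowSums(comp) - x$cell_area) > tol * x$cell_area
  if (any(bad))
    stop("composition closure violated in ", sum(bad), " cell(s), e.g. cell ",
         which(bad)[1])
  if (!all(is.finite(x$cells$elevation))) stop("non-finite elevation")
  if (any(x$cells$precipitation < 0)) stop("negative precipitation")
  co <- x$cohorts
  if (nrow(co)) {
    if (any(co$age < 0)) stop("negative cohort age")
    if (any(co$area < -tol)) stop("negative cohort area")
    # cells carrying cohorts must balance; forest cells without cohort
    # entries are treated as un-aged (e.g. hand-built fixtures)
    with_co <- unique(co$cell_id)
    sums <- tapply(co$area, factor(co$cell_id, levels = with_co), sum,
                   default = 0)
    target <- comp[with_co, "forest"] + comp[with_co, "cutblock"]
    bad <- abs(sums - target) > tol * x$cell_area
    if (any(bad))
      stop("cohort areas do not match forest + cutblock area in cell ",
           with_co[which(bad)[1]])
  }
  if (!is.null(x$canola)) {
    if (ncol(x$canola) != 4L) stop("canola rotation must have 4 years")
    if (any(x$canola > comp[, "cropland"] + tol * x$cell_area))
      stop("canola area exceeds cropland area")
  }
  invisible(TRUE)
}

#' @export
print.grid_landscape <- function(x, ...) {
  cat(sprintf("grid_landscape: %d x %d cells of %g m (%g ha each)\n",
              x$n_rows, x$n_cols, x$cell_size, x$cell_area))
  tot <- colSums(x$composition)
  tot <- tot[tot > 0]
  cat("composition (ha): ",
      paste(sprintf("%s=%.0f", names(tot), tot), collapse = ", "), "\n")
  cat(sprintf("%d forest cohorts; %d mills; %d monitoring points\n",
              nrow(x$cohorts),
              if (is.null(x$mills)) 0L else nrow(x$mills),
              if (is.null(x$monitors)) 0L else nrow(x$monitors)))
  invisible(x)
}

#' Summarize a fine-resolution classified raster onto the model grid
#'
#' Converts a per-pixel classified map (pixels strictly finer than the model
#' cell) into per-cell class areas. Sub-cell spatial arrangement is discarded
#' by design: only the area of each class within each cell is kept, which
#' retains spatially small but influential features such as roads.
#'
#' @param pixels matrix of class labels (or integer codes with `code_map`);
#'   pixel `[i, j]` is row i from the top, column j from the left
#' @param pixel_size pixel edge length (m); must divide `cell_size`
#' @param cell_size model cell size (m)
#' @param code_map optional named vector translating raster codes to class
#'   names, e.g. `c("1" = "forest", "2" = "cropland")`
#' @param taxonomy class taxonomy; unknown classes are an error
#' @param default_stand stand attributes given to forest created by the
#'   summary (a classified map carries no age structure)
#' @return a `grid_landscape`
#' @export
summarize_to_grid <- function(pixels, pixel_size, cell_size = 800,
                              code_map = NULL,
                              taxonomy = default_taxonomy(),
                              default_stand = list(stand_type = "mixedwood",
                                                   ecozone = "Boreal Plains",
                                                   age = 100L)) {
  if (!is.matrix(pixels) || nrow(pixels) == 0L || ncol(pixels) == 0L)
    stop("classified raster must be a non-empty matrix")
  if (anyNA(pixels)) stop("classified raster contains nodata pixels")
  f <- cell_size / pixel_size
  if (abs(f - round(f)) > 1e-9 || f < 1)
    stop("pixel size must divide the cell size")
  f <- as.integer(round(f))
  if (nrow(pixels) %% f != 0L || ncol(pixels) %% f != 0L)
    stop("raster extent does not align with the cell grid")
  cls <- as.vector(pixels)
  if (!is.null(code_map)) {
    mapped <- unname(code_map[as.character(cls)])
    if (anyNA(mapped))
      stop("unknown class code: ",
           paste(unique(cls[is.na(mapped)]), collapse = ", "))
    cls <- mapped
  }
  known <- all_classes(taxonomy)
  bad <- setdiff(unique(cls), known)
  if (length(bad))
    stop("unknown landcover class: ", paste(bad, collapse = ", "))
  n_rows <- nrow(pixels) %/% f
  n_cols <- ncol(pixels) %/% f
  pi <- rep(seq_len(nrow(pixels)), times = ncol(pixels))
  pj <- rep(seq_len(ncol(pixels)), each = nrow(pixels))
  cid <- ((pi - 1L) %/% f) * n_cols + ((pj - 1L) %/% f) + 1L
  counts <- table(factor(cid, levels = seq_len(n_rows * n_cols)),
                  factor(cls, levels = known))
  comp <- matrix(as.numeric(counts), nrow = n_rows * n_cols,
                 dimnames = list(NULL, known)) * (pixel_size / 100)^2
  cohorts <- empty_cohorts()
  fc <- which(comp[, "forest"] > 0)
  if (length(fc)) {
    cohorts <- data.frame(cell_id = fc,
                          stand_type = default_stand$stand_type,
                          ecozone = default_stand$ecozone,
                          age = as.integer(default_stand$age),
                          area = comp[fc, "forest"],
                          stringsAsFactors = FALSE)
  }
  grid_landscape(n_rows, n_cols, cell_size, composition = comp,
                 cohorts = cohorts, taxonomy = taxonomy)
}

#' Write per-cell composition as a long CSV
#'
#' @param landscape a `grid_landscape`
#' @param path output file; columns row, col, class, area_ha
#' @export
write_composition_csv <- function(landscape, path) {
  comp <- landscape$composition
  out <- data.frame(
    row = rep(landscape$cells$row, ncol(comp)),
    col = rep(landscape$cells$col, ncol(comp)),
    class = rep(colnames(comp), each = nrow(comp)),
    area_ha = as.vector(comp)
  )
  out <- out[out$area_ha > 0, ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Convert one cell's pasture to cropland by the stochastic conversion rule
#'
#' A cell converts when its uniform draw falls below the conversion
#' proportion; the cell's entire pasture area is then reclassified as
#' cropland and the newly converted cropland is assigned to grow canola in
#' exactly one (randomly chosen unless given) year of the 4-year rotation.
#'
#' @param landscape a `grid_landscape`
#' @param cell cell id
#' @param draw uniform(0,1) random number for the cell
#' @param proportion conversion proportion in `[0, 1]`
#' @param rotation_year optional rotation year 1-4 for the new canola
#' @return the updated landscape
#' @export
convert_pasture_cell <- function(landscape, cell, draw, proportion,
                                 rotation_year = NULL) {
  if (!is.numeric(proportion) || proportion < 0 || proportion > 1)
    stop("conversion proportion must lie in [0, 1]")
  p <- landscape$composition[cell, "pasture"]
  if (draw < proportion && p > 0) {
    landscape$composition[cell, "pasture"] <- 0
    landscape$composition[cell, "cropland"] <-
      landscape$composition[cell, "cropland"] + p
    if (is.null(landscape$canola))
      landscape$canola <- matrix(0, n_cells(landscape), 4)
    if (is.null(rotation_year)) rotation_year <- sample.int(4L, 1L)
    landscape$canola[cell, rotation_year] <-
      landscape$canola[cell, rotation_year] + p
  }
  landscape
}

#' Convert pasture across the landscape at a given conversion proportion
#'
#' Vectorized application of [convert_pasture_cell()]: every cell receives an
#' independent uniform draw and converts when the draw is below `proportion`.
#'
#' @param landscape a `grid_landscape`
#' @param proportion conversion proportion in `[0, 1]`
#' @param draws optional vector of uniform draws (one per cell); drawn from
#'   the current RNG stream when `NULL`. Supplying the same draws at
#'   increasing proportions yields nested converted sets (common random
#'   numbers).
#' @param rotation_years optional vector of rotation-year assignments (1-4)
#'   per cell, used for cells that convert
#' @return the updated landscape, with attribute `converted` giving the ids
#'   of converted cells
#' @export
convert_pasture <- function(landscape, proportion, draws = NULL,
                            rotation_years = NULL) {
  if (!is.numeric(proportion) || proportion < 0 || proportion > 1)
    stop("conversion proportion must lie in [0, 1]")
  n <- n_cells(landscape)
  if (is.null(draws)) draws <- stats::runif(n)
  stopifnot(length(draws) == n)
  if (is.null(rotation_years)) rotation_years <- sample.int(4L, n, replace = TRUE)
  pas <- landscape$composition[, "pasture"]
  sel <- which(draws < proportion & pas > 0)
  if (length(sel)) {
    if (is.null(landscape$canola)) landscape$canola <- matrix(0, n, 4)
    moved <- pas[sel]
    landscape$composition[sel, "pasture"] <- 0
    landscape$composition[sel, "cropland"] <-
      landscape$composition[sel, "cropland"] + moved
    idx <- cbind(sel, rotation_years[sel])
    landscape$canola[idx] <- landscape$canola[idx] + moved
  }
  attr(landscape, "converted") <- sel
  landscape
}
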