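#' Write a per-cell map as an ESRI ASCII grid
#'
#' ASCII grids are the plain-text raster interchange format readable by any
#' GIS; one value per cell, row 1 = northern edge.
#'
#' @param values numeric vector (cell-id order) or matrix of per-cell values
#' @param landscape the `grid_landscape` defining the grid geometry
#' @param path output path
#' @param nodata value written for `NA` cells
#' @return the path, invisibly
#' @export
write_ascii_grid <- function(values, landscape, path, nodata = -9999) {
  if (!is.matrix(values) && length(values) != n_cells(landscape))
    stop("map dimensions do not match the landscape grid")
  m <- if (is.matrix(values)) values else elev_matrix(landscape, values)
  if (nrow(m) != landscape$n_rows || ncol(m) != landscape$n_cols)
    stop("map dimensions do not match the landscape grid")
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    "xllcorner 0", "yllcorner 0",
    sprintf("cellsize %g", landscape$cell_size),
    sprintf("NODATA_value %g", nodata))
  m[is.na(m)] <- nodata
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path
#' @return list with `values` (matrix, row 1 = north), `cell_size`,
#'   `xllcorner`, `yllcorner`, `nodata` (`NA`-substituted in `values`)
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nd <- hdr$nodata_value
  if (!is.null(nd)) m[m == nd] <- NA
  list(values = m, cell_size = hdr$cellsize, xllcorner = hdr$xllcorner,
       yllcorner = hdr$yllcorner, nodata = nd)
}

#' Read a DEM or precipitation ASCII grid onto a landscape
#'
#' @param landscape a `grid_landscape`
#' @param path ASCII grid path
#' @param field cell field to fill (`"elevation"` or `"precipitation"`)
#' @return the updated landscape (hydrology cache cleared if the DEM
#'   changed)
#' @export
read_grid_field <- function(landscape, path, field = "elevation") {
  g <- read_ascii_grid(path)
  if (nrow(g$values) != landscape$n_rows ||
      ncol(g$values) != landscape$n_cols)
    stop("grid dimensions do not match the landscape")
  landscape$cells[[field]] <- matrix_to_ids(g$values)
  if (field == "elevation") landscape$hydrology <- NULL
  landscape
}
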