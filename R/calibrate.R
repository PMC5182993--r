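#' Latin hypercube parameter sets
#'
#' Draws `n` parameter sets such that, for every parameter, the `n` samples
#' occupy the `n` equal-width strata of its range exactly once (the defining
#' stratification property of Latin hypercube sampling).
#'
#' @param ranges named list of `c(min, max)` ranges, one per parameter
#' @param n number of parameter sets
#' @param seed RNG seed (the design is reproducible for a fixed seed)
#' @return matrix `n x parameters`
#' @export
latin_hypercube_sample <- function(ranges, n, seed = 1) {
  stopifnot(n >= 1, length(ranges) >= 1)
  lo <- vapply(ranges, `[`, 0, 1)
  hi <- vapply(ranges, `[`, 0, 2)
  if (any(!is.finite(lo)) || any(!is.finite(hi))) stop("ranges must be finite")
  if (any(hi <= lo)) stop("inverted parameter range: ",
                          paste(names(ranges)[hi <= lo], collapse = ", "))
  u <- with_seed(seed, lhs::randomLHS(n, length(ranges)))
  out <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(out) <- names(ranges)
  out
}

#' Scale an export-coefficient table by per-class multipliers
#'
#' Convenience for building calibration candidates: multiplies every
#' substance and region-group slice of the export array by a per-class
#' factor.
#'
#' @param export base export array (`class x substance x group`)
#' @param multipliers named vector of per-class multipliers (classes absent
#'   from the vector keep factor 1)
#' @return the scaled array
#' @export
scale_export <- function(export, multipliers) {
  m <- rep(1, dim(export)[1])
  names(m) <- rownames(export)
  m[names(multipliers)] <- multipliers
  sweep(export, 1, m, `*`)
}

#' Calibrate export coefficients against observed annual loads
#'
#' Runs one water year per candidate export-coefficient set and selects,
#' independently for each calibration region group (`mountains`,
#' `foothills`, `plains`), the candidate minimizing the RMSE between
#' modelled and observed cumulative annual loads at the monitoring points of
#' that group. The returned combined table takes each group's slice from its
#' winning candidate.
#'
#' @param landscape a `grid_landscape` with monitoring points
#' @param observed data frame with columns `label`, `substance`, `load_kg`
#' @param candidates list of export arrays (same shape as
#'   `water_params()$export`)
#' @param params base `water_params`; everything but `export` is held fixed
#' @return list with `objective` (candidate x group RMSE table), `best`
#'   (winning candidate index per group), and `export` (combined array)
#' @export
calibrate_export_coefficients <- function(landscape, observed, candidates,
                                          params = water_params()) {
  if (is.null(observed) || !nrow(observed)) stop("no observations supplied")
  stopifnot(all(c("label", "substance", "load_kg") %in% names(observed)),
            length(candidates) >= 1)
  monitors <- landscape$monitors
  if (is.null(monitors) || !nrow(monitors))
    stop("landscape has no monitoring points")
  if (!all(observed$label %in% monitors$label))
    stop("observations at unknown monitoring points: ",
         paste(setdiff(observed$label, monitors$label), collapse = ", "))
  grp <- region_group(landscape$cells$region[monitors$cell_id])
  names(grp) <- monitors$label
  groups <- intersect(c("mountains", "foothills", "plains"),
                      grp[unique(observed$label)])
  obj <- matrix(NA_real_, length(candidates), length(groups),
                dimnames = list(NULL, groups))
  for (i in seq_along(candidates)) {
    p <- params
    p$export <- candidates[[i]]
    res <- run_water_year(landscape, p)
    pred <- res$monitors
    for (g in groups) {
      labs <- names(grp)[grp == g]
      o <- observed[observed$label %in% labs, ]
      if (!nrow(o)) next
      err <- vapply(seq_len(nrow(o)), function(k)
        pred[match(o$label[k], pred$label), o$substance[k]], 0)
      obj[i, g] <- sqrt(mean((err - o$load_kg)^2))
    }
  }
  best <- apply(obj, 2, which.min)
  combined <- params$export
  for (g in names(best)) combined[, , g] <- candidates[[best[[g]]]][, , g]
  list(objective = as.data.frame(obj), best = best, export = combined)
}
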