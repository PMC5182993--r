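#' Compare clearcut against variable-retention harvest strategies
#'
#' Runs the timber simulation under both harvest modes from the same
#' baseline landscape and seed, then evaluates the water-purification and
#' biodiversity models (pollination is excluded: commercial forestry and
#' cropping do not overlap) on the post-harvest landscapes. Indicators are
#' reported raw and standardized to the pre-harvest landscape (baseline =
#' 100%); timber NPV, which has no baseline, is standardized to the clearcut
#' run.
#'
#' @param landscape a `grid_landscape` with mills and FMUs
#' @param curves a `curve_library`
#' @param water a `water_params`
#' @param biodiv a `biodiversity_model`
#' @param years simulation horizon
#' @param n_replicates paired replicate seeds (means reported when > 1)
#' @param seed master seed; replicate r uses the derived seed of stream
#'   `"strategy-r"`
#' @return a `scenario_result` data frame (one row per mode x indicator)
#'   with attributes `replicates` (per-replicate values) and `baseline`
#' @export
compare_harvest_strategies <- function(landscape,
                                       curves = default_curve_library(),
                                       water = water_params(),
                                       biodiv = biodiversity_model(),
                                       years = 20, n_replicates = 1,
                                       seed = 1) {
  if (is.null(landscape$hydrology))
    landscape <- prepare_hydrology(landscape, water$river_threshold)
  base_water <- run_water_year(landscape, water)
  # the carbon baseline is the no-harvest counterfactual at the same
  # horizon, so reported deltas isolate the harvest impact from growth
  grown <- Reduce(function(l, .) age_forests(l), seq_len(max(years, 1)),
                  landscape)
  baseline <- c(
    timber_npv = 0,
    carbon_t = total_carbon(grown, curves),
    N_supplied_kg = base_water$totals$supplied_river[1],
    P_supplied_kg = base_water$totals$supplied_river[2],
    TSS_supplied_kg = base_water$totals$supplied_river[3],
    biodiversity_pct = regional_mean_index(landscape, biodiv),
    cells_harvested = 0)
  modes <- c("clearcut", "variable_retention")
  reps <- expand.grid(replicate = seq_len(n_replicates), mode = modes,
                      stringsAsFactors = FALSE)
  vals <- vector("list", nrow(reps))
  for (i in seq_len(nrow(reps))) {
    sim <- run_timber_simulation(
      landscape, curves, years = years, mode = reps$mode[i],
      seed = derive_seed(seed, paste0("strategy-", reps$replicate[i])))
    post <- sim$landscape
    w <- run_water_year(post, water)
    vals[[i]] <- data.frame(
      mode = reps$mode[i], replicate = reps$replicate[i],
      timber_npv = sim$npv_total,
      carbon_t = total_carbon(post, curves),
      N_supplied_kg = w$totals$supplied_river[1],
      P_supplied_kg = w$totals$supplied_river[2],
      TSS_supplied_kg = w$totals$supplied_river[3],
      biodiversity_pct = regional_mean_index(post, biodiv),
      cells_harvested =
        length(unique(stats::na.omit(sim$ledger$cell))))
  }
  rep_df <- do.call(rbind, vals)
  ind_cols <- setdiff(names(rep_df), c("mode", "replicate"))
  means <- stats::aggregate(rep_df[ind_cols], list(mode = rep_df$mode), mean)
  cc_npv <- means$timber_npv[means$mode == "clearcut"]
  long <- do.call(rbind, lapply(ind_cols, function(ind) {
    ref <- if (ind == "timber_npv") cc_npv else baseline[[ind]]
    data.frame(mode = means$mode, indicator = ind, value = means[[ind]],
               baseline = baseline[[ind]],
               standardized_pct = if (!is.na(ref) && ref > 0)
                 100 * means[[ind]] / ref else NA_real_)
  }))
  structure(long, class = c("scenario_result", "data.frame"),
            replicates = rep_df, baseline = baseline, seed = seed)
}

#' Standardize an ecosystem-service suite across landscapes
#'
#' Expresses each landscape's value of each indicator as a percentage of the
#' maximum value across the compared landscapes (so every indicator has one
#' 100% landscape). The biodiversity index is already a percentage and is
#' passed through unscaled. Indicators are scaled only against themselves:
#' cross-indicator comparison of the scores is meaningless by construction.
#'
#' @param values matrix/data frame `landscapes x indicators` of non-negative
#'   values; a column named `biodiversity` (any capitalization) is passed
#'   through
#' @return matrix of percentage scores
#' @export
standardize_es_suite <- function(values) {
  m <- as.matrix(values)
  if (nrow(m) < 2) stop("need at least two landscapes to standardize")
  if (any(m < 0)) stop("indicator values must be non-negative")
  out <- m
  for (j in seq_len(ncol(m))) {
    if (grepl("^biodiv", colnames(m)[j], ignore.case = TRUE)) next
    mx <- max(m[, j])
    if (mx == 0) {
      warning("indicator '", colnames(m)[j], "' is zero everywhere")
      out[, j] <- 0
    } else {
      out[, j] <- 100 * m[, j] / mx
    }
  }
  out
}

#' Agricultural-expansion scenario sweep
#'
#' Iteratively converts the region's remaining pasture to cropland at
#' conversion proportions from 0 to 100% (default 5% steps). Every level
#' converts independently from the baseline landscape: a cell converts when
#' its uniform draw falls below the level, and newly converted cropland
#' grows canola in one random year of the 4-year rotation. Within a
#' replicate the same draws are used at every level (common random numbers),
#' so converted sets are nested across levels. Per level and replicate the
#' pollination model (4-year NPV), one water year and the biodiversity index
#' are evaluated; the timber model is excluded (forestry and cropping do not
#' overlap).
#'
#' @param landscape baseline `grid_landscape`
#' @param proportions conversion levels
#' @param n_replicates replicate conversions per level (default 20)
#' @param seed master seed
#' @param poll a `pollination_params`
#' @param water a `water_params`
#' @param biodiv a `biodiversity_model`
#' @return an `expansion_sweep` list: `results` (long data frame: level,
#'   replicate, indicator, value) and `summary` (replicate means and
#'   standard errors per level)
#' @export
agricultural_expansion_sweep <- function(landscape,
                                         proportions = seq(0, 1, by = 0.05),
                                         n_replicates = 20, seed = 1,
                                         poll = pollination_params(),
                                         water = water_params(),
                                         biodiv = biodiversity_model()) {
  stopifnot(all(proportions >= 0 & proportions <= 1))
  if (!any(landscape$composition[, "pasture"] > 0))
    stop("landscape has no pasture to convert")
  if (is.null(landscape$hydrology))
    landscape <- prepare_hydrology(landscape, water$river_threshold)
  n <- n_cells(landscape)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    dr <- with_seed(derive_seed(seed, paste0("sweep-", r)), list(
      draws = stats::runif(n),
      rotation = sample.int(4L, n, replace = TRUE)))
    for (p in proportions) {
      ls <- convert_pasture(landscape, p, draws = dr$draws,
                            rotation_years = dr$rotation)
      pol <- run_pollination(ls, poll)
      w <- run_water_year(ls, water)
      rows[[length(rows) + 1L]] <- data.frame(
        level = p, replicate = r,
        canola_revenue_npv = pol$revenue_npv,
        pollination_total_npv = pol$total_value_npv,
        pollination_per_field_npv = pol$per_field_value_npv,
        P_supplied_kg = w$totals$supplied_river[2],
        biodiversity_pct = regional_mean_index(ls, biodiv),
        cropland_ha = sum(ls$composition[, "cropland"]),
        pasture_ha = sum(ls$composition[, "pasture"]))
    }
  }
  wide <- do.call(rbind, rows)
  ind <- setdiff(names(wide), c("level", "replicate"))
  long <- stats::reshape(wide, direction = "long", varying = ind,
                         v.names = "value", times = ind,
                         timevar = "indicator", idvar = c("level", "replicate"))
  rownames(long) <- NULL
  smry <- stats::aggregate(long$value,
                           by = list(level = long$level,
                                     indicator = long$indicator),
                           FUN = function(v) c(mean = mean(v),
                                               se = stats::sd(v) /
                                                 sqrt(length(v))))
  smry <- data.frame(level = smry$level, indicator = smry$indicator,
                     mean = smry$x[, "mean"], se = smry$x[, "se"])
  structure(list(results = long, summary = smry,
                 proportions = proportions, n_replicates = n_replicates,
                 seed = seed),
            class = "expansion_sweep")
}

#' @export
print.expansion_sweep <- function(x, ...) {
  cat(sprintf("expansion_sweep: %d levels x %d replicates\n",
              length(x$proportions), x$n_replicates))
  s <- x$summary
  for (ind in unique(s$indicator)) {
    v <- s$mean[s$indicator == ind]
    cat(sprintf("  %-26s %0.4g -> %0.4g\n", ind, v[1], v[length(v)]))
  }
  invisible(x)
}
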