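#' Polynomial growth and carbon curves
#'
#' Stand-level timber volume (m3/ha) and carbon density (t CO2e/ha, combined
#' above- and below-ground pool) are polynomial functions of stand age,
#' evaluated per (stand type, ecozone) stratum. Fitted polynomials behave
#' badly outside the data range, so curves are clamped at zero and held flat
#' beyond `age_max` (a plateau, not an extrapolation).
#'
#' @param stand_type one of `"deciduous"`, `"pine"`, `"spruce"`, `"mixedwood"`
#' @param ecozone `"Montane Cordillera"` or `"Boreal Plains"`
#' @param coefficients numeric vector `c(c0, c1, c2, ...)` of polynomial
#'   coefficients in increasing degree
#' @param age_max end of the valid age range (years); the curve plateaus here
#' @return a `growth_curve` / `carbon_curve` object
#' @export
growth_curve <- function(stand_type, ecozone, coefficients, age_max) {
  stopifnot(age_max > 0, length(coefficients) >= 1)
  structure(list(stand_type = stand_type, ecozone = ecozone,
                 coefficients = coefficients, age_max = age_max),
            class = c("growth_curve", "age_curve"))
}

#' @rdname growth_curve
#' @export
carbon_curve <- function(stand_type, ecozone, coefficients, age_max) {
  structure(growth_curve(stand_type, ecozone, coefficients, age_max),
            class = c("carbon_curve", "age_curve"))
}

eval_age_curve <- function(curve, age) {
  if (any(age < 0)) stop("stand age must be non-negative")
  a <- pmin(age, curve$age_max)
  k <- seq_along(curve$coefficients) - 1
  v <- drop(outer(a, k, `^`) %*% curve$coefficients)
  pmax(0, v)
}

#' Stand volume density at a given age
#'
#' Evaluates the clamped polynomial: `max(0, poly(min(age, age_max)))`.
#'
#' @param curve a `growth_curve`
#' @param age stand age in years (vectorized)
#' @return volume density, m3/ha
#' @export
stand_volume <- function(curve, age) {
  stopifnot(inherits(curve, "growth_curve"))
  eval_age_curve(curve, age)
}

#' Stand carbon density at a given age
#' @param curve a `carbon_curve`
#' @param age stand age in years (vectorized)
#' @return carbon density, t CO2e/ha
#' @export
stand_carbon <- function(curve, age) {
  stopifnot(inherits(curve, "carbon_curve"))
  eval_age_curve(curve, age)
}

#' Library of growth and carbon curves per (stand type, ecozone)
#'
#' @param growth,carbon lists of curves; each stratum appearing in a cohort
#'   table must be covered, otherwise evaluation errors
#' @export
curve_library <- function(growth, carbon) {
  key <- function(cv) paste(cv$stand_type, cv$ecozone, sep = "|")
  g <- stats::setNames(growth, vapply(growth, key, ""))
  c_ <- stats::setNames(carbon, vapply(carbon, key, ""))
  structure(list(growth = g, carbon = c_), class = "curve_library")
}

get_curve <- function(curves, stand_type, ecozone,
                      which = c("growth", "carbon")) {
  which <- match.arg(which)
  cv <- curves[[which]][[paste(stand_type, ecozone, sep = "|")]]
  if (is.null(cv))
    stop("no ", which, " curve for stand type '", stand_type,
         "' in ecozone '", ecozone, "'")
  cv
}

#' Built-in growth/carbon curve set
#'
#' Eight (stand type x ecozone) strata with cubic volume and quadratic carbon
#' polynomials. These are documented placeholder fits with the qualitative
#' shape of boreal stand dynamics (slow establishment, sustained rise,
#' plateau near 140-150 years); any deployment against real inventory data
#' should replace them via [read_curve_table()] or [curve_library()].
#'
#' @return a `curve_library`
#' @export
default_curve_library <- function() {
  vol <- list(
    deciduous = list(c(0, 0.20, 0.045, -2.0e-4), 140),
    pine      = list(c(0, 0.15, 0.040, -1.8e-4), 150),
    spruce    = list(c(0, 0.10, 0.048, -2.0e-4), 150),
    mixedwood = list(c(0, 0.18, 0.042, -1.9e-4), 145)
  )
  carb <- list(
    deciduous = list(c(25, 4.2, -0.0090), 140),
    pine      = list(c(22, 4.0, -0.0090), 150),
    spruce    = list(c(30, 4.8, -0.0100), 150),
    mixedwood = list(c(26, 4.4, -0.0095), 145)
  )
  growth <- list(); carbon <- list()
  for (st in names(vol)) {
    for (ez in c("Boreal Plains", "Montane Cordillera")) {
      # montane strata grow a little slower than their boreal counterparts
      m <- if (ez == "Montane Cordillera") 0.85 else 1
      growth[[length(growth) + 1L]] <-
        growth_curve(st, ez, vol[[st]][[1]] * m, vol[[st]][[2]])
      mc <- if (ez == "Montane Cordillera") 0.9 else 1
      cc <- carb[[st]][[1]] * c(1, mc, mc)
      carbon[[length(carbon) + 1L]] <-
        carbon_curve(st, ez, cc, carb[[st]][[2]])
    }
  }
  curve_library(growth, carbon)
}

#' Read a curve table (CSV or YAML) into a curve library
#'
#' Expected columns/fields: `kind` (growth|carbon), `stand_type`, `ecozone`,
#' `age_max`, and coefficients `c0`, `c1`, ... in increasing degree.
#'
#' @param path file path
#' @return a `curve_library`
#' @export
read_curve_table <- function(path) {
  df <- if (grepl("\\.ya?ml$", path)) {
    do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  ccols <- grep("^c[0-9]+$", names(df), value = TRUE)
  ccols <- ccols[order(as.integer(sub("^c", "", ccols)))]
  mk <- function(r) {
    co <- as.numeric(r[ccols]); co[is.na(co)] <- 0
    if (r[["kind"]] == "growth")
      growth_curve(r[["stand_type"]], r[["ecozone"]], co, as.numeric(r[["age_max"]]))
    else
      carbon_curve(r[["stand_type"]], r[["ecozone"]], co, as.numeric(r[["age_max"]]))
  }
  rows <- split(df, seq_len(nrow(df)))
  curves <- lapply(rows, mk)
  curve_library(Filter(function(x) !inherits(x, "carbon_curve"), curves),
                Filter(function(x) inherits(x, "carbon_curve"), curves))
}

#' Advance every forest cohort by one year
#'
#' The annual aging step: every cohort's age increases by one; nothing else
#' changes.
#'
#' @param landscape a `grid_landscape`
#' @return the aged landscape
#' @export
age_forests <- function(landscape) {
  if (nrow(landscape$cohorts))
    landscape$cohorts$age <- landscape$cohorts$age + 1L
  landscape
}

cohort_density <- function(cohorts, curves, which) {
  if (!nrow(cohorts)) return(numeric(0))
  dens <- numeric(nrow(cohorts))
  strata <- unique(cohorts[c("stand_type", "ecozone")])
  for (i in seq_len(nrow(strata))) {
    sel <- cohorts$stand_type == strata$stand_type[i] &
      cohorts$ecozone == strata$ecozone[i]
    cv <- get_curve(curves, strata$stand_type[i], strata$ecozone[i], which)
    dens[sel] <- eval_age_curve(cv, cohorts$age[sel])
  }
  dens
}

#' Total forest carbon stored on the landscape
#'
#' Sum over all cohorts of carbon density at the cohort's age times cohort
#' area.
#'
#' @param landscape a `grid_landscape`
#' @param curves a `curve_library`
#' @return total carbon, t CO2e
#' @export
total_carbon <- function(landscape, curves = default_curve_library()) {
  co <- landscape$cohorts
  if (!nrow(co)) return(0)
  sum(cohort_density(co, curves, "carbon") * co$area)
}

#' Per-cell forest carbon map
#' @inheritParams total_carbon
#' @return numeric vector of t CO2e per cell
#' @export
cell_carbon <- function(landscape, curves = default_curve_library()) {
  out <- numeric(n_cells(landscape))
  co <- landscape$cohorts
  if (nrow(co)) {
    v <- cohort_density(co, curves, "carbon") * co$area
    agg <- tapply(v, co$cell_id, sum)
    out[as.integer(names(agg))] <- agg
  }
  out
}
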