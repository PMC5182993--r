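#' Biodiversity-intactness regression model
#'
#' The biodiversity index (0-100%) of a cell is a clamped linear function of
#' the human-footprint areas present: `clamp(intercept + sum coef_c *
#' area_c, 0, 100)`. A footprint-free cell scores the intercept (100% = no
#' change from the reference community); each footprint class carries a
#' non-positive %/ha coefficient. The shipped coefficients are configurable
#' placeholders with plausible relative severities; refit against index
#' observations with [fit_footprint_model()].
#'
#' @param intercept index of a footprint-free cell (%)
#' @param coefficients named vector, % per ha of each footprint class
#' @return a `biodiversity_model`
#' @export
biodiversity_model <- function(intercept = 100,
                               coefficients = c(road = -1.2, trail = -0.4,
                                                cutblock = -0.5,
                                                cropland = -0.8,
                                                industrial = -1.5,
                                                urban = -1.2)) {
  structure(list(intercept = intercept, coefficients = coefficients),
            class = "biodiversity_model")
}

#' Biodiversity index of cells or footprint vectors
#'
#' @param x a `grid_landscape` (uses the footprint columns of its
#'   composition) or a named numeric vector / matrix of footprint areas (ha)
#' @param model a `biodiversity_model`
#' @return index score(s) in `[0, 100]` (%)
#' @export
biodiversity_index <- function(x, model = biodiversity_model()) {
  co <- model$coefficients
  if (inherits(x, "grid_landscape")) {
    fp_classes <- intersect(x$taxonomy$footprint, colnames(x$composition))
    fp <- x$composition[, fp_classes, drop = FALSE]
  } else if (is.matrix(x)) {
    fp <- x
  } else {
    fp <- matrix(x, 1, dimnames = list(NULL, names(x)))
  }
  unknown <- setdiff(colnames(fp), names(co))
  if (length(unknown))
    stop("no model coefficient for footprint class: ",
         paste(unknown, collapse = ", "))
  if (any(fp < 0)) stop("negative footprint area")
  raw <- model$intercept + drop(fp %*% co[colnames(fp)])
  clamp(raw, 0, 100)
}

#' Mean biodiversity index over a region
#'
#' Unweighted mean of per-cell index scores over the masked cells.
#'
#' @param landscape a `grid_landscape`
#' @param model a `biodiversity_model`
#' @param mask logical vector selecting cells (default: all)
#' @return mean index (%)
#' @export
regional_mean_index <- function(landscape, model = biodiversity_model(),
                                mask = NULL) {
  idx <- biodiversity_index(landscape, model)
  if (is.null(mask)) mask <- rep(TRUE, length(idx))
  mean(idx[mask])
}

#' Refit the footprint-biodiversity regression
#'
#' Ordinary least squares of an observed biodiversity index on footprint
#' areas. Returns the refitted model plus r-squared. Rank-deficient designs
#' error naming the collinear classes; a constant response is flagged
#' (coefficients zero, r-squared undefined).
#'
#' @param footprints matrix/data frame of footprint areas (ha), one column
#'   per class
#' @param observed observed index values (%), one per row
#' @return list with `model` (a `biodiversity_model`), `r_squared`, and the
#'   underlying `lm` fit
#' @export
fit_footprint_model <- function(footprints, observed) {
  fp <- as.matrix(footprints)
  stopifnot(nrow(fp) == length(observed))
  if (nrow(fp) < ncol(fp) + 1L)
    stop("need at least one more training cell than footprint classes")
  df <- data.frame(.index = observed, fp)
  fit <- stats::lm(.index ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear footprint classes (rank-deficient design): ",
         paste(bad, collapse = ", "))
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warning("constant observed index; r-squared undefined")
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum(stats::resid(fit)^2) / ss_tot
  }
  co <- stats::coef(fit)
  list(model = biodiversity_model(intercept = unname(co[1]),
                                  coefficients = co[-1]),
       r_squared = r2, fit = fit)
}
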