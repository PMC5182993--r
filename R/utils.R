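# internal helpers shared across modules

clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Derive a module-specific random seed from a master seed
#'
#' Each stochastic component draws from its own named substream so that adding
#' a component never perturbs the draws of existing ones. The derived seed is
#' always a positive 32-bit integer.
#'
#' @param master single integer master seed
#' @param stream character name of the substream (e.g. "timber", "sweep")
#' @return an integer seed
#' @export
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  v <- utf8ToInt(stream)
  h <- sum(v * seq_along(v)) %% 104729
  as.integer((abs(master) %% 1000003) * 2039 + h * 17 + 1)
}

# evaluate `code` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# D8 neighbor ordering used everywhere a tie must break deterministically:
# E, SE, S, SW, W, NW, N, NE (delta row, delta col)
d8_drow <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
d8_dcol <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
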