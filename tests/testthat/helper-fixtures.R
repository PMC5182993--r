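# Fixtures and independent oracles, all built in code.

# A minimal landscape with hand-set compositions. `comp` is a named list of
# per-cell class-area vectors (recycled); unset area is topped up with
# grassland so closure holds.
tiny_landscape <- function(n_rows, n_cols, cell_size = 800, comp = list(),
                           elevation = NULL, precipitation = 450) {
  n <- n_rows * n_cols
  cell_area <- (cell_size / 100)^2
  classes <- all_classes()
  m <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  for (i in seq_len(n)) {
    if (length(comp)) {
      v <- comp[[((i - 1L) %% length(comp)) + 1L]]
      m[i, names(v)] <- v
    }
    slack <- cell_area - sum(m[i, ])
    m[i, "grassland"] <- m[i, "grassland"] + slack
  }
  cells <- NULL
  ls <- grid_landscape(n_rows, n_cols, cell_size, composition = m)
  if (!is.null(elevation)) ls$cells$elevation <- elevation
  ls$cells$precipitation <- precipitation
  ls
}

cell_at <- function(ls, row, col) (row - 1L) * ls$n_cols + col

# --- routing oracles -------------------------------------------------------

# flow accumulation by following every cell's path to the outlet
oracle_accumulation <- function(down) {
  n <- length(down)
  acc <- rep(1L, n)
  for (c in seq_len(n)) {
    d <- down[c]
    while (!is.na(d)) {
      acc[d] <- acc[d] + 1L
      d <- down[d]
    }
  }
  acc
}

# cumulative load at a river cell: sum river inputs over its upstream river
# set (breadth-first over reversed links), including itself
oracle_river_load <- function(links, river_input, cell) {
  up <- cell
  frontier <- cell
  while (length(frontier)) {
    nxt <- links$from[links$to %in% frontier]
    nxt <- setdiff(nxt, up)
    up <- c(up, nxt)
    frontier <- nxt
  }
  colSums(river_input[up, , drop = FALSE])
}

# exhaustive least-cost path between two cells on a small grid, using the
# same step-cost rule as the package (mean of the two cells' rates, sqrt(2)
# on diagonals) but via depth-first enumeration of all simple paths
oracle_least_cost <- function(n_rows, n_cols, rates, from, to) {
  rates <- unname(rates)
  if (from == to) return(0)
  nbrs <- function(c) {
    r <- (c - 1L) %/% n_cols + 1L; cc <- (c - 1L) %% n_cols + 1L
    out <- list()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rn <- r + dr; cn <- cc + dc
      if (rn < 1 || rn > n_rows || cn < 1 || cn > n_cols) next
      out[[length(out) + 1L]] <- c(id = (rn - 1L) * n_cols + cn,
                                   diag = as.integer(dr != 0 && dc != 0))
    }
    out
  }
  best <- Inf
  dfs <- function(c, cost, visited) {
    if (cost >= best) return()
    if (c == to) { best <<- cost; return() }
    for (nb in nbrs(c)) {
      if (visited[nb[["id"]]]) next
      step <- 0.5 * (rates[c] + rates[nb[["id"]]]) *
        (if (nb[["diag"]] == 1L) sqrt(2) else 1)
      v <- visited; v[nb[["id"]]] <- TRUE
      dfs(nb[["id"]], cost + step, v)
    }
  }
  vis <- rep(FALSE, n_rows * n_cols); vis[from] <- TRUE
  dfs(from, 0, vis)
  unname(best)
}

# mean of a normal truncated to [0, 1]
truncnorm_mean <- function(m, s) {
  a <- (0 - m) / s; b <- (1 - m) / s
  m + s * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# every cell can walk downhill (non-ascending on the filled DEM) to an edge
drains_to_edge <- function(filled) {
  nr <- nrow(filled); nc <- ncol(filled)
  flow <- d8_flow_directions(filled, 800)
  ok <- TRUE
  for (c in seq_len(nr * nc)) {
    cur <- c; steps <- 0
    while (!is.na(flow$down[cur])) {
      cur <- flow$down[cur]
      steps <- steps + 1
      if (steps > nr * nc) return(FALSE)  # cycle
    }
  }
  ok
}

# small landscape with mills/FMUs for timber tests
forest_landscape <- function(n_rows = 14, n_cols = 14, seed = 99, ...) {
  generate_synthetic_landscape(synthetic_config(n_rows, n_cols, ...),
                               seed = seed)
}
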