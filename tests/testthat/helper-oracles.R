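# Independent brute-force oracles and small fixture builders.
# These deliberately share no code with the package internals.

# stack-based flood fill over a 0/1 matrix; the reference for patch counts
flood_fill_count <- function(grid, connectivity = 8, wrap = FALSE) {
  nr <- nrow(grid); nc <- ncol(grid)
  offsets <- if (connectivity == 4)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  visited <- matrix(FALSE, nr, nc)
  count <- 0L
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (grid[i0, j0] != 1 || visited[i0, j0]) next
    count <- count + 1L
    stack <- list(c(i0, j0))
    visited[i0, j0] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in offsets) {
        ni <- cur[1] + d[1]
        nj <- cur[2] + d[2]
        if (ni < 1 || ni > nr) next
        if (wrap) nj <- ((nj - 1) %% nc) + 1
        if (nj < 1 || nj > nc) next
        if (grid[ni, nj] == 1 && !visited[ni, nj]) {
          visited[ni, nj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  count
}

# random 0/1 slice; full_ring = TRUE makes the lattice span 360 degrees so
# the longitude wrap engages
random_slice <- function(nr, nc, p, seed, full_ring = TRUE) {
  set.seed(seed)
  g <- matrix(as.numeric(runif(nr * nc) < p), nr, nc)
  lon_max <- if (full_ring) 180 else 170
  habitat_slice(g,
                lat_edges = seq(-20, 20, length.out = nr + 1),
                lon_edges = seq(-180, lon_max, length.out = nc + 1),
                age = 0)
}

# small wiggly environmental curve covering [0, 40] Ma
test_env <- function(span = 40) {
  env_series(0:span, 10 + 6 * sin((0:span) / 5), kind = "patch_count")
}

# a handful of cached simulated chronograms shared across expensive checks
sim_trees_m1 <- local({
  cache <- NULL
  function(n = 10, lambda = 0.15, mu = 0.04, f = 0.9, crown_age = 22) {
    if (is.null(cache) || length(cache) < n)
      cache <<- lapply(seq_len(n), function(i)
        simulate_tree(constant_rates(lambda, mu), f = f,
                      crown_age = crown_age, seed = 5000 + i))
    cache[seq_len(n)]
  }
})
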