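# Shared fixtures: small grids and engineered climates, built in code.

# grids are deterministic; cache per resolution across test files
.grid_cache <- new.env(parent = emptyenv())
test_grid <- function(resolution) {
  key <- as.character(resolution)
  if (is.null(.grid_cache[[key]])) {
    .grid_cache[[key]] <- build_grid(resolution)
  }
  .grid_cache[[key]]
}

# spatially uniform, temporally constant climate (everything suitable for a
# niche seeded anywhere on it)
constant_climate <- function(n_cells, n_slices, tmax = 20, tmin = 5,
                             prcp = 3) {
  climate_series(matrix(tmax, n_cells, n_slices),
                 matrix(tmin, n_cells, n_slices),
                 matrix(prcp, n_cells, n_slices))
}

# northern-hemisphere landmass whose mid-latitude ring turns lethally hot
# from step `barrier_step` on: the range splits into a polar and a
# subtropical fragment at exactly that step
barrier_world <- function(barrier_step = 150, n_slices = 261) {
  g <- test_grid(3)
  n <- g$n_cells
  mask <- g$cells$lat > 0
  g <- apply_land_mask(g, mask)
  tmax <- matrix(20, n, n_slices)
  ring <- mask & g$cells$lat > 35 & g$cells$lat < 50
  tmax[ring, (barrier_step + 1):n_slices] <- 100
  cl <- climate_series(tmax, tmax - 15, matrix(3, n, n_slices))
  list(grid = g, climate = cl,
       seed_cell = which(mask & g$cells$lat > 60)[1],
       ring = which(ring))
}

# independent BFS oracle over an adjacency list (used to cross-check both
# neighbors_within() and the engine's component structure)
bfs_ball_oracle <- function(adjacency, start, k) {
  dist <- rep(NA_integer_, length(adjacency))
  dist[start] <- 0L
  queue <- start
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    if (dist[v] >= k) next
    for (nb in adjacency[[v]]) {
      if (is.na(dist[nb])) {
        dist[nb] <- dist[v] + 1L
        queue <- c(queue, nb)
      }
    }
  }
  sort(which(!is.na(dist) & dist > 0L))
}
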