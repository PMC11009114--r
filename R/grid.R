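# Icosahedral geodesic grid: aperture-3 subdivision of the icosahedron, cells
# taken as spherical Voronoi regions of the subdivision vertices.

# Authalic Earth radius in km
.EARTH_RADIUS_KM <- 6371.007

.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

# One aperture-3 refinement: insert projected face centroids as new vertices
# and re-triangulate across each old edge, so the vertex count follows
# 10 * 3^r + 2 and the dual tessellation is hexagonal except at the 12
# original icosahedron vertices.
.subdivide_a3 <- function(mesh) {
  v <- mesh$v
  f <- mesh$f
  nv <- nrow(v)
  nf <- nrow(f)
  cent <- v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]
  cent <- cent / sqrt(rowSums(cent^2))
  cidx <- nv + seq_len(nf)
  ea <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fi <- rep.int(seq_len(nf), 3L)
  lo <- pmin(ea[, 1], ea[, 2])
  hi <- pmax(ea[, 1], ea[, 2])
  o <- order(lo, hi)
  lo <- lo[o]
  hi <- hi[o]
  fi <- fi[o]
  i1 <- seq(1L, length(fi), by = 2L)
  i2 <- i1 + 1L
  stopifnot(all(lo[i1] == lo[i2]), all(hi[i1] == hi[i2]))
  c1 <- cidx[fi[i1]]
  c2 <- cidx[fi[i2]]
  newf <- rbind(cbind(lo[i1], c1, c2), cbind(hi[i1], c1, c2))
  list(v = rbind(v, cent), f = newf)
}

.mesh_edges <- function(mesh) {
  f <- mesh$f
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2])
  hi <- pmax(e[, 1], e[, 2])
  key <- lo * (nrow(mesh$v) + 1) + hi  # exact in doubles for any feasible grid
  keep <- !duplicated(key)
  cbind(lo[keep], hi[keep])
}

.mesh_adjacency <- function(mesh) {
  nv <- nrow(mesh$v)
  e <- .mesh_edges(mesh)
  from <- c(e[, 1], e[, 2])
  to <- c(e[, 2], e[, 1])
  adj <- split(to, factor(from, levels = seq_len(nv)))
  lapply(adj, function(x) sort.int(as.integer(x)))
}

# Spherical circumcenter of each triangular face, oriented outward.
.face_circumcenters <- function(mesh) {
  v <- mesh$v
  f <- mesh$f
  a <- v[f[, 1], ]
  b <- v[f[, 2], ]
  c_ <- v[f[, 3], ]
  u <- b - a
  w <- c_ - a
  n <- cbind(
    u[, 2] * w[, 3] - u[, 3] * w[, 2],
    u[, 3] * w[, 1] - u[, 1] * w[, 3],
    u[, 1] * w[, 2] - u[, 2] * w[, 1])
  n <- n / sqrt(rowSums(n^2))
  flip <- rowSums(n * a) < 0
  n[flip, ] <- -n[flip, ]
  n
}

# Spherical excess of triangles (a_i, b_i, c_i) on the unit sphere
# (Eriksson / van Oosterom-Strackee formula).
.spherical_excess <- function(a, b, c_) {
  triple <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  denom <- 1 + rowSums(a * b) + rowSums(b * c_) + rowSums(a * c_)
  2 * atan2(abs(triple), denom)
}

# Per-vertex Voronoi cell areas: fan of spherical triangles from the vertex
# to consecutive circumcenters of its incident faces, ordered by azimuth in
# the vertex tangent plane.
.voronoi_areas <- function(mesh, radius_km) {
  v <- mesh$v
  f <- mesh$f
  cc <- .face_circumcenters(mesh)
  vi <- c(f[, 1], f[, 2], f[, 3])
  fidx <- rep.int(seq_len(nrow(f)), 3L)
  vv <- v[vi, ]
  # tangent basis at each vertex (stable choice of reference axis)
  ref <- cbind(rep(0, length(vi)), rep(0, length(vi)), rep(1, length(vi)))
  polar <- abs(vv[, 3]) > 0.9
  if (any(polar)) {
    ref[polar, ] <- matrix(c(1, 0, 0), nrow = sum(polar), ncol = 3,
                           byrow = TRUE)
  }
  e1 <- ref - vv * rowSums(ref * vv)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(
    vv[, 2] * e1[, 3] - vv[, 3] * e1[, 2],
    vv[, 3] * e1[, 1] - vv[, 1] * e1[, 3],
    vv[, 1] * e1[, 2] - vv[, 2] * e1[, 1])
  d <- cc[fidx, ]
  ang <- atan2(rowSums(d * e2), rowSums(d * e1))
  o <- order(vi, ang)
  vi_o <- vi[o]
  fo <- fidx[o]
  new_grp <- !duplicated(vi_o)
  grp_id <- cumsum(new_grp)
  last_of_grp <- c(new_grp[-1], TRUE)
  nxt <- c(fo[-1], fo[1])
  nxt[last_of_grp] <- fo[new_grp][grp_id[last_of_grp]]
  exc <- .spherical_excess(v[vi_o, , drop = FALSE], cc[fo, , drop = FALSE],
                           cc[nxt, , drop = FALSE])
  area <- rowsum(exc, vi_o)
  as.numeric(area) * radius_km^2
}

# Spring relaxation (edge-length equalization): every edge pulls or pushes
# its endpoints toward a common target length beta * mean edge length, as
# used for icosahedral climate-model grids. Deterministic; stops when the
# largest per-sweep displacement falls below tol_frac of the mean edge
# length. Keeps neighbour centre spacings within a factor of ~1.23 at every
# resolution (and Voronoi areas within a factor of ~1.27).
.relax_mesh <- function(mesh, k = 0.04, beta = 1.2, tol_frac = 2e-4,
                        max_iter = 300L) {
  e <- .mesh_edges(mesh)
  ef <- c(e[, 1], e[, 2])
  et <- c(e[, 2], e[, 1])
  v <- mesh$v
  mean_edge <- mean(acos(pmin(1, pmax(-1,
    rowSums(v[e[, 1], , drop = FALSE] * v[e[, 2], , drop = FALSE])))))
  tol <- tol_frac * mean_edge
  for (i in seq_len(max_iter)) {
    a <- v[ef, , drop = FALSE]
    b <- v[et, , drop = FALSE]
    dotp <- pmin(1, pmax(-1, rowSums(a * b)))
    d <- acos(dotp)
    u <- b - a * dotp  # unit tangent at a toward b after normalization
    u <- u / sqrt(rowSums(u^2))
    disp <- rowsum(u * (k * (d - beta * mean(d))), ef)
    v2 <- v + disp
    v2 <- v2 / sqrt(rowSums(v2^2))
    moved <- sqrt(max(rowSums((v2 - v)^2)))
    v <- v2
    if (moved < tol) break
  }
  mesh$v <- v
  mesh
}

.xyz_to_latlon <- function(xyz) {
  lat <- asin(pmin(1, pmax(-1, xyz[, 3]))) * 180 / pi
  lon <- atan2(xyz[, 2], xyz[, 1]) * 180 / pi
  cbind(lat = lat, lon = lon)
}

#' Build an icosahedral hexagonal global grid
#'
#' Constructs a near-equal-area, near-equidistant global tessellation by
#' recursive aperture-3 subdivision of the icosahedron. Grid cells are the
#' spherical Voronoi regions of the subdivision vertices: 12 pentagons (at
#' the icosahedron vertices) and hexagons elsewhere, `10 * 3^resolution + 2`
#' cells in total. At resolution 8 the global cell count is 65,612 and the
#' mean cell area is about 7,774 km2, roughly 99 km between neighbouring
#' cell centres.
#'
#' @param resolution Non-negative integer subdivision level.
#' @param radius_km Sphere radius in km; defaults to the authalic Earth
#'   radius 6371.007 km.
#' @param max_cells Capacity cap on the cell count; exceeded resolutions
#'   raise an error rather than exhausting memory.
#'
#' @return An object of class `nichesim_grid`: a list with `resolution`,
#'   `radius_km`, `n_cells`, a `cells` data frame (`cell_id`, `lat`, `lon`,
#'   `area_km2`, `is_pentagon`, `is_land`), an `adjacency` list mapping each
#'   cell to its 5 or 6 neighbours, and the unit-sphere `xyz` centre
#'   coordinates. All cells start as land; see [apply_land_mask()].
#'
#' @details After each subdivision the vertices are spring-relaxed to
#'   equalize edge lengths (fixed gain and displacement tolerance), which is
#'   deterministic: the same resolution always yields the same centres. Cell
#'   areas are true spherical Voronoi areas, so they sum to the sphere
#'   surface up to floating-point error; the max/min area ratio is about
#'   1.27 at the pentagon/hexagon transition (the grid is approximately, not
#'   exactly, equal-area) and neighbour centre spacings vary by less than a
#'   factor of 1.3.
#'
#' @examples
#' g <- build_grid(2)
#' g$n_cells                      # 92
#' sum(g$cells$is_pentagon)       # 12
#' @export
build_grid <- function(resolution, radius_km = .EARTH_RADIUS_KM,
                       max_cells = 3e6) {
  stopifnot(length(resolution) == 1, resolution >= 0,
            resolution == as.integer(resolution))
  n_cells <- 10 * 3^resolution + 2
  if (n_cells > max_cells) {
    stop("grid with ", n_cells, " cells exceeds max_cells = ", max_cells)
  }
  mesh <- .icosahedron()
  r <- 0
  while (r < resolution) {
    mesh <- .subdivide_a3(mesh)
    mesh <- .relax_mesh(mesh)
    r <- r + 1
  }
  adj <- .mesh_adjacency(mesh)
  deg <- lengths(adj)
  area <- .voronoi_areas(mesh, radius_km)
  ll <- .xyz_to_latlon(mesh$v)
  cells <- data.frame(
    cell_id = seq_len(nrow(mesh$v)),
    lat = ll[, "lat"],
    lon = ll[, "lon"],
    area_km2 = area,
    is_pentagon = deg == 5L,
    is_land = TRUE)
  structure(
    list(resolution = as.integer(resolution), radius_km = radius_km,
         n_cells = as.integer(n_cells), cells = cells, adjacency = adj,
         xyz = mesh$v),
    class = "nichesim_grid")
}

#' @export
print.nichesim_grid <- function(x, ...) {
  cat("Icosahedral hexagonal grid (aperture 3)\n")
  cat("  resolution:", x$resolution, " cells:", x$n_cells,
      " (12 pentagons)\n")
  cat(sprintf("  mean cell area: %.1f km2; land cells: %d\n",
              mean(x$cells$area_km2), sum(x$cells$is_land)))
  invisible(x)
}

#' Cells within k adjacency hops of a cell
#'
#' Breadth-first search over the grid adjacency graph. Returns all cells at
#' graph distance between 1 and `k` from `cell_id` (the cell itself is
#' excluded); `k = 0` gives an empty set. Distances are adjacency hops, not
#' km: dispersal reach in the simulator is measured in cell steps.
#'
#' @param grid A `nichesim_grid`.
#' @param cell_id Cell index.
#' @param k Non-negative hop radius.
#' @return Sorted integer vector of cell ids.
#' @export
neighbors_within <- function(grid, cell_id, k) {
  stopifnot(inherits(grid, "nichesim_grid"), k >= 0)
  if (length(cell_id) != 1 || is.na(cell_id) || cell_id < 1 ||
      cell_id > grid$n_cells) {
    stop("invalid cell_id: ", cell_id)
  }
  if (k == 0) return(integer(0))
  dist <- rep.int(NA_integer_, grid$n_cells)
  dist[cell_id] <- 0L
  frontier <- as.integer(cell_id)
  d <- 0L
  while (d < k && length(frontier)) {
    nb <- unique(unlist(grid$adjacency[frontier], use.names = FALSE))
    nb <- nb[is.na(dist[nb])]
    dist[nb] <- d + 1L
    frontier <- nb
    d <- d + 1L
  }
  sort.int(which(!is.na(dist) & dist > 0L))
}

#' Restrict a grid to land cells
#'
#' Sets the `is_land` flag from a logical mask. Adjacency is unchanged: sea
#' cells remain traversable gaps that jump-dispersal can cross, but they can
#' never be occupied.
#'
#' @param grid A `nichesim_grid`.
#' @param mask Logical vector of length `n_cells` (`TRUE` = land).
#' @return The grid with `is_land` updated.
#' @export
apply_land_mask <- function(grid, mask) {
  stopifnot(inherits(grid, "nichesim_grid"))
  if (!is.logical(mask) || length(mask) != grid$n_cells || anyNA(mask)) {
    stop("mask must be a complete logical vector of length ", grid$n_cells)
  }
  grid$cells$is_land <- mask
  grid
}

#' Generate a synthetic continental land mask
#'
#' Builds `n_continents` compact landmasses as spherical caps with
#' noise-modulated coastlines: each continent is the set of cells within an
#' angular radius of a random centre, the radius varying smoothly along the
#' coast. Compact continents avoid the thin isthmuses and satellite islets
#' that a coarse grid would otherwise pepper the map with (and which act as
#' permanent vicariance traps at desk-scale resolutions). Used to build
#' synthetic worlds with ocean dispersal barriers when no empirical mask is
#' supplied. Deterministic under `seed`.
#'
#' @param grid A `nichesim_grid`.
#' @param n_continents Number of landmasses.
#' @param coverage Target land fraction of all cells (default 0.3, roughly
#'   the Earth's land fraction). Coast noise makes the realized fraction
#'   approximate.
#' @param seed Integer RNG seed.
#' @param coast_noise_deg Standard deviation of the coastal radius
#'   modulation in degrees of arc (default 4).
#' @return Logical land mask of length `n_cells`.
#' @export
synthetic_land_mask <- function(grid, n_continents = 2, coverage = 0.3,
                                seed = 1, coast_noise_deg = 4) {
  stopifnot(inherits(grid, "nichesim_grid"), coverage > 0, coverage <= 1,
            n_continents >= 1)
  n <- grid$n_cells
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  # smooth per-cell field modulating the coastal radius
  eta <- stats::rnorm(n)
  idx <- rep.int(seq_len(n), lengths(grid$adjacency))
  nbr <- unlist(grid$adjacency, use.names = FALSE)
  for (h in 1:4) {
    eta <- 0.5 * eta +
      0.5 * as.numeric(rowsum(eta[nbr], idx)) / lengths(grid$adjacency)
  }
  eta <- eta / stats::sd(eta) * coast_noise_deg * pi / 180
  # cap radius so the continents jointly cover ~coverage of the sphere
  frac_each <- coverage / n_continents
  theta <- acos(1 - 2 * frac_each)
  centers <- sample.int(n, n_continents)
  land <- rep.int(FALSE, n)
  for (c0 in centers) {
    ang <- acos(pmin(1, pmax(-1, grid$xyz %*% grid$xyz[c0, ])))
    land <- land | (as.numeric(ang) < theta + eta)
  }
  # keep the n_continents largest contiguous landmasses (coast noise can
  # pinch off islets; caps may also merge, which is fine)
  comps <- list()
  seen <- logical(n)
  for (c0 in which(land)) {
    if (seen[c0]) next
    comp <- integer(0)
    frontier <- c0
    seen[c0] <- TRUE
    while (length(frontier)) {
      comp <- c(comp, frontier)
      nb <- unique(unlist(grid$adjacency[frontier], use.names = FALSE))
      nb <- nb[land[nb] & !seen[nb]]
      seen[nb] <- TRUE
      frontier <- nb
    }
    comps[[length(comps) + 1L]] <- comp
  }
  keep <- order(lengths(comps), decreasing = TRUE)[
    seq_len(min(n_continents, length(comps)))]
  land <- rep.int(FALSE, n)
  land[unlist(comps[keep], use.names = FALSE)] <- TRUE
  land
}

# Preserve caller RNG state around internally seeded draws.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Flattened BFS balls for all cells up to max_k hops, depth-sorted, for the
# compiled engine: cells[ptr[i]:(ptr[i+1]-1)] are the neighbours of cell i
# ordered by hop distance, and cnt[i, d] counts those within d hops.
.grid_neighbor_balls <- function(grid, max_k) {
  n <- grid$n_cells
  adj <- grid$adjacency
  cells_list <- vector("list", n)
  cnt <- matrix(0L, n, max_k)
  for (i in seq_len(n)) {
    dist <- rep.int(NA_integer_, n)
    dist[i] <- 0L
    frontier <- i
    out <- integer(0)
    for (d in seq_len(max_k)) {
      nb <- unique(unlist(adj[frontier], use.names = FALSE))
      nb <- nb[is.na(dist[nb])]
      dist[nb] <- d
      out <- c(out, sort.int(nb))
      cnt[i, d] <- length(out)
      frontier <- nb
    }
    cells_list[[i]] <- out
  }
  lens <- lengths(cells_list)
  # cells are 0-based for direct use by the compiled engine
  list(ptr = c(0L, cumsum(lens)),
       cells = unlist(cells_list, use.names = FALSE) - 1L,
       cnt = cnt)
}

#' Great-circle distance between cell centres
#'
#' @param grid A `nichesim_grid`.
#' @param from,to Cell id vectors (recycled).
#' @return Distances in km along the sphere surface.
#' @export
cell_distance_km <- function(grid, from, to) {
  a <- grid$xyz[from, , drop = FALSE]
  b <- grid$xyz[to, , drop = FALSE]
  d <- pmin(1, pmax(-1, rowSums(a * b)))
  acos(d) * grid$radius_km
}

#' Write / read a grid as plain-text CSV
#'
#' `write_grid()` writes two CSVs: `<path>_cells.csv` (cell_id, lat, lon,
#' area_km2, is_pentagon, is_land) and `<path>_adjacency.csv` (cell_id,
#' neighbor_id, one row per directed edge). `read_grid()` reconstructs the
#' grid object (without `xyz` centre coordinates).
#'
#' @param grid A `nichesim_grid`.
#' @param path File path stem (no extension).
#' @rdname grid_io
#' @export
write_grid <- function(grid, path) {
  utils::write.csv(grid$cells, paste0(path, "_cells.csv"), row.names = FALSE)
  adj <- data.frame(
    cell_id = rep.int(seq_along(grid$adjacency), lengths(grid$adjacency)),
    neighbor_id = unlist(grid$adjacency, use.names = FALSE))
  utils::write.csv(adj, paste0(path, "_adjacency.csv"), row.names = FALSE)
  invisible(path)
}

#' @param resolution,radius_km Metadata to attach on read (not stored in the
#'   CSVs themselves).
#' @rdname grid_io
#' @export
read_grid <- function(path, resolution = NA_integer_,
                      radius_km = .EARTH_RADIUS_KM) {
  cells <- utils::read.csv(paste0(path, "_cells.csv"))
  adj_df <- utils::read.csv(paste0(path, "_adjacency.csv"))
  n <- nrow(cells)
  adj <- split(as.integer(adj_df$neighbor_id),
               factor(adj_df$cell_id, levels = seq_len(n)))
  adj <- lapply(adj, sort.int)
  xyz <- cbind(
    cos(cells$lat * pi / 180) * cos(cells$lon * pi / 180),
    cos(cells$lat * pi / 180) * sin(cells$lon * pi / 180),
    sin(cells$lat * pi / 180))
  structure(
    list(resolution = resolution, radius_km = radius_km, n_cells = n,
         cells = cells, adjacency = adj, xyz = xyz),
    class = "nichesim_grid")
}
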