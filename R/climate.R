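# Per-cell climate series: three variables on the grid at fixed time steps,
# ordered from the start of the run (oldest) to the present day.

#' Construct a climate series
#'
#' Bundles per-cell time series of the three climate variables driving the
#' simulation: `tmax` (mean monthly maximum temperature, degC), `tmin` (mean
#' monthly minimum temperature, degC) and `prcp` (mean monthly maximum
#' precipitation, mm/d). Values are matrices with one row per grid cell and
#' one column per time slice; column 1 is the start of the record (by
#' default 120 kyr before present) and the last column is the present day.
#'
#' @param tmax,tmin,prcp Numeric matrices `n_cells x n_slices`. `NA` is
#'   permitted (sea cells); where both are present `tmax >= tmin` and
#'   `prcp >= 0` are enforced.
#' @param timestep_years Years between consecutive slices (default 100).
#' @param times_years_bp Optional vector of slice ages in years before
#'   present, strictly decreasing and ending at 0. Defaults to an evenly
#'   spaced axis implied by `timestep_years`.
#' @return A `climate_series` object.
#' @export
climate_series <- function(tmax, tmin, prcp, timestep_years = 100,
                           times_years_bp = NULL) {
  tmax <- as.matrix(tmax)
  tmin <- as.matrix(tmin)
  prcp <- as.matrix(prcp)
  if (!all(dim(tmax) == dim(tmin)) || !all(dim(tmax) == dim(prcp))) {
    stop("tmax, tmin and prcp must have identical dimensions")
  }
  if (any(prcp < 0, na.rm = TRUE)) {
    stop("prcp must be non-negative everywhere")
  }
  if (any(tmax < tmin, na.rm = TRUE)) {
    stop("tmax must be >= tmin at every (cell, slice)")
  }
  n_slices <- ncol(tmax)
  if (is.null(times_years_bp)) {
    times_years_bp <- seq((n_slices - 1) * timestep_years, 0,
                          by = -timestep_years)
  }
  if (length(times_years_bp) != n_slices || any(diff(times_years_bp) >= 0)) {
    stop("times_years_bp must be strictly decreasing with one entry per slice")
  }
  structure(
    list(tmax = tmax, tmin = tmin, prcp = prcp,
         n_cells = nrow(tmax), n_slices = n_slices,
         timestep_years = timestep_years,
         times_years_bp = as.numeric(times_years_bp)),
    class = "climate_series")
}

#' @export
print.climate_series <- function(x, ...) {
  cat("Climate series:", x$n_cells, "cells x", x$n_slices, "slices (",
      max(x$times_years_bp), "to", min(x$times_years_bp), "yr BP )\n")
  cat(sprintf("  TMAX %.1f..%.1f degC, TMIN %.1f..%.1f degC, PRCP %.2f..%.2f mm/d\n",
              min(x$tmax, na.rm = TRUE), max(x$tmax, na.rm = TRUE),
              min(x$tmin, na.rm = TRUE), max(x$tmin, na.rm = TRUE),
              min(x$prcp, na.rm = TRUE), max(x$prcp, na.rm = TRUE)))
  invisible(x)
}

#' Check a climate series against a grid
#'
#' Verifies dimensions and that no land cell carries a missing value at any
#' slice. Sea cells may be `NA`.
#'
#' @param series A `climate_series`.
#' @param grid A `nichesim_grid`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_climate <- function(series, grid) {
  stopifnot(inherits(series, "climate_series"), inherits(grid, "nichesim_grid"))
  if (series$n_cells != grid$n_cells) {
    stop("climate series has ", series$n_cells, " cells; grid has ",
         grid$n_cells)
  }
  land <- grid$cells$is_land
  for (v in c("tmax", "tmin", "prcp")) {
    if (anyNA(series[[v]][land, ])) {
      stop("missing ", v, " values on land cells")
    }
  }
  invisible(TRUE)
}

#' Combine paleoclimate anomalies with a modern climatology
#'
#' The anomaly (delta) method for bias-correcting climate-model output:
#' temperature variables are the observed present-day climatology plus the
#' modelled change relative to the model's own present day; precipitation is
#' the climatology multiplied by the modelled ratio. This removes systematic
#' model bias while preserving modelled change through time.
#'
#' @param paleo A `climate_series` of raw model output; its final slice is
#'   taken as the model's present day.
#' @param climatology A list with numeric per-cell vectors `tmax`, `tmin`
#'   and `prcp` (observed present-day values). `prcp` must be non-negative.
#' @param prcp_ratio_floor When the model's present-day precipitation in a
#'   cell is below this floor (mm/d), the precipitation ratio is taken as 1
#'   to avoid division blow-up in arid cells. Default 0.01.
#' @return A `climate_series` on the same time axis as `paleo`. At the
#'   present-day slice the output equals the climatology exactly.
#' @export
anomaly_combine <- function(paleo, climatology, prcp_ratio_floor = 0.01) {
  stopifnot(inherits(paleo, "climate_series"))
  for (v in c("tmax", "tmin", "prcp")) {
    if (length(climatology[[v]]) != paleo$n_cells) {
      stop("climatology$", v, " must have one value per cell")
    }
  }
  if (any(climatology$prcp < 0, na.rm = TRUE)) {
    stop("climatology precipitation must be non-negative")
  }
  pres <- paleo$n_slices
  tmax <- climatology$tmax + (paleo$tmax - paleo$tmax[, pres])
  tmin <- climatology$tmin + (paleo$tmin - paleo$tmin[, pres])
  ref <- paleo$prcp[, pres]
  ratio <- paleo$prcp / ifelse(ref < prcp_ratio_floor, NA, ref)
  ratio[is.na(ratio) & !is.na(paleo$prcp)] <- 1
  prcp <- pmax(climatology$prcp * ratio, 0)
  climate_series(tmax, tmin, prcp,
                 timestep_years = paleo$timestep_years,
                 times_years_bp = paleo$times_years_bp)
}

#' Interpolate a climate series to a finer, regular time step
#'
#' Linear interpolation in time, per cell and variable. A 120,000-year span
#' at 100-year target steps yields 1,201 equal-duration slices, endpoints
#' included; values at the coarse timestamps are preserved exactly.
#'
#' @param series A `climate_series` on a coarse (possibly irregular,
#'   strictly decreasing years-BP) time axis ending at the present day.
#' @param target_step_years Output step in years (default 100). The total
#'   span must be divisible by it.
#' @return A `climate_series` on the regular axis.
#' @export
interpolate_timesteps <- function(series, target_step_years = 100) {
  stopifnot(inherits(series, "climate_series"))
  t_bp <- series$times_years_bp
  span <- t_bp[1] - t_bp[length(t_bp)]
  if (span %% target_step_years != 0) {
    stop("time span (", span, " yr) is not divisible by target step (",
         target_step_years, " yr)")
  }
  out_bp <- seq(t_bp[1], t_bp[length(t_bp)], by = -target_step_years)
  # bracketing coarse slice and weight for each output slice
  tt <- -t_bp  # increasing
  ot <- -out_bp
  i1 <- findInterval(ot, tt, rightmost.closed = TRUE)
  i1 <- pmin(pmax(i1, 1L), length(tt) - 1L)
  i2 <- i1 + 1L
  w <- (ot - tt[i1]) / (tt[i2] - tt[i1])
  interp <- function(m) {
    m[, i1, drop = FALSE] * rep(1 - w, each = nrow(m)) +
      m[, i2, drop = FALSE] * rep(w, each = nrow(m))
  }
  climate_series(interp(series$tmax), interp(series$tmin),
                 pmax(interp(series$prcp), 0),
                 timestep_years = target_step_years,
                 times_years_bp = out_bp)
}

#' Generate a synthetic glacial-interglacial climate
#'
#' Produces a reproducible paleoclimate on any grid, emulating the broad
#' structure of late-Pleistocene change: a latitudinal temperature gradient,
#' a glacial cycle shared by all cells (warm at both ends of the record,
#' coldest mid-record), a tropical wet belt for precipitation, and
#' spatially and temporally autocorrelated anomalies. Maximum temperature
#' is generated first; minimum temperature is the same field minus a fixed
#' offset, which guarantees `tmax >= tmin`; precipitation is floored at 0.
#'
#' @param grid A `nichesim_grid`.
#' @param n_steps Number of 100-year steps after the initial slice; the
#'   series has `n_steps + 1` slices. Must be >= 1.
#' @param base_tmax Equatorial mean TMAX, degC (default 30).
#' @param lapse Temperature fall per degree of absolute latitude, degC
#'   (default 0.55, giving roughly -20 degC poleward extremes).
#' @param amplitude Half peak-to-peak amplitude of the temperature cycle,
#'   degC (default 4, a glacial-interglacial contrast of ~8 degC).
#' @param period_steps Cycle period in steps (default: the full record, one
#'   glacial cycle per run). Must be positive.
#' @param tmin_offset TMAX minus TMIN, degC (default 15).
#' @param prcp_base Equatorial wet-belt precipitation, mm/d (default 8).
#' @param prcp_belt_width Gaussian width of the wet belt in degrees latitude
#'   (default 20).
#' @param prcp_floor Baseline precipitation everywhere, mm/d (default 0.5).
#' @param prcp_cycle_amplitude Amplitude of the shared precipitation cycle,
#'   mm/d (default 0.5; wetter in warm phases).
#' @param noise_sd_temp,noise_sd_prcp Standard deviation of the cell-level
#'   anomaly fields (degC, mm/d; defaults 1 and 0.5).
#' @param noise_smooth_hops Number of neighbour-averaging passes applied to
#'   the anomaly fields (spatial correlation; default 2).
#' @param ar1_rho Lag-1 autocorrelation of the anomaly fields across steps
#'   (default 0.8; centennial anomalies persist).
#' @param seed Integer RNG seed; the same seed gives a bit-identical series.
#' @return A `climate_series` with `n_steps + 1` slices at 100-year steps.
#' @export
generate_synthetic_climate <- function(grid, n_steps,
                                       base_tmax = 30, lapse = 0.55,
                                       amplitude = 4, period_steps = n_steps,
                                       tmin_offset = 15,
                                       prcp_base = 8, prcp_belt_width = 20,
                                       prcp_floor = 0.5,
                                       prcp_cycle_amplitude = 0.5,
                                       noise_sd_temp = 1,
                                       noise_sd_prcp = 0.5,
                                       noise_smooth_hops = 2,
                                       ar1_rho = 0.8,
                                       seed = 1) {
  stopifnot(inherits(grid, "nichesim_grid"), n_steps >= 1)
  if (period_steps <= 0) stop("period_steps must be positive")
  if (amplitude < 0 || prcp_cycle_amplitude < 0 ||
      noise_sd_temp < 0 || noise_sd_prcp < 0) {
    stop("amplitudes and noise scales must be non-negative")
  }
  n <- grid$n_cells
  nt <- n_steps + 1L
  lat <- grid$cells$lat
  steps <- 0:n_steps
  cyc <- cos(2 * pi * steps / period_steps)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  noise_field <- function(sd) {
    if (sd == 0) return(matrix(0, n, nt))
    z <- matrix(stats::rnorm(n * nt), n, nt)
    if (noise_smooth_hops > 0) {
      idx <- rep.int(seq_len(n), lengths(grid$adjacency))
      nbr <- unlist(grid$adjacency, use.names = FALSE)
      deg <- lengths(grid$adjacency)
      for (h in seq_len(noise_smooth_hops)) {
        z <- 0.5 * z + 0.5 * rowsum(z[nbr, , drop = FALSE], idx) / deg
      }
    }
    if (ar1_rho > 0) {
      for (j in 2:nt) {
        z[, j] <- ar1_rho * z[, j - 1] + sqrt(1 - ar1_rho^2) * z[, j]
      }
    }
    z * (sd / stats::sd(as.numeric(z)))
  }
  temp_anom <- noise_field(noise_sd_temp)
  prcp_anom <- noise_field(noise_sd_prcp)
  tmax <- outer(base_tmax - lapse * abs(lat), rep(1, nt)) +
    outer(rep(1, n), amplitude * cyc) + temp_anom
  tmin <- tmax - tmin_offset
  belt <- prcp_floor + prcp_base * exp(-(lat / prcp_belt_width)^2)
  prcp <- pmax(outer(belt, rep(1, nt)) +
                 outer(rep(1, n), prcp_cycle_amplitude * cyc) + prcp_anom, 0)
  climate_series(tmax, tmin, prcp, timestep_years = 100)
}

#' Write / read a climate series as long-format CSV
#'
#' One row per (cell, slice): `cell_id, step, years_bp, tmax, tmin, prcp`.
#' `step` is the 0-based slice index.
#'
#' @param series A `climate_series`.
#' @param path CSV file path.
#' @rdname climate_io
#' @export
write_climate_csv <- function(series, path) {
  n <- series$n_cells
  nt <- series$n_slices
  df <- data.frame(
    cell_id = rep.int(seq_len(n), nt),
    step = rep(0:(nt - 1), each = n),
    years_bp = rep(series$times_years_bp, each = n),
    tmax = as.numeric(series$tmax),
    tmin = as.numeric(series$tmin),
    prcp = as.numeric(series$prcp))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname climate_io
#' @export
read_climate_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "step", "tmax", "tmin", "prcp")
  if (!all(need %in% names(df))) {
    stop("climate CSV must have columns: ", paste(need, collapse = ", "))
  }
  n <- max(df$cell_id)
  steps <- sort(unique(df$step))
  nt <- length(steps)
  if (nrow(df) != n * nt) {
    stop("climate CSV is not a complete (cell, step) long table")
  }
  o <- order(df$step, df$cell_id)
  df <- df[o, ]
  times <- if ("years_bp" %in% names(df)) {
    df$years_bp[seq(1, nrow(df), by = n)]
  } else {
    NULL
  }
  step_years <- if (!is.null(times) && nt > 1) times[1] - times[2] else 100
  climate_series(matrix(df$tmax, n, nt), matrix(df$tmin, n, nt),
                 matrix(df$prcp, n, nt),
                 timestep_years = step_years, times_years_bp = times)
}

#' Nearest-neighbour regrid from lat/lon points to grid cells
#'
#' Convenience utility assigning each grid cell the value of the nearest
#' input point (great-circle distance). Intended for moving coarse lat/lon
#' rasters onto the icosahedral grid; no interpolation is performed.
#'
#' @param grid A `nichesim_grid`.
#' @param lat,lon Coordinates of the input points, degrees.
#' @param values Numeric vector (or matrix with one row per point).
#' @return Per-cell values: a vector, or a matrix with `n_cells` rows.
#' @export
regrid_nearest <- function(grid, lat, lon, values) {
  stopifnot(length(lat) == length(lon))
  pts <- cbind(cos(lat * pi / 180) * cos(lon * pi / 180),
               cos(lat * pi / 180) * sin(lon * pi / 180),
               sin(lat * pi / 180))
  vmat <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (nrow(vmat) != length(lat)) stop("values must have one row per point")
  out <- matrix(NA_real_, grid$n_cells, ncol(vmat))
  chunk <- 2000L
  for (s in seq(1, grid$n_cells, by = chunk)) {
    e <- min(s + chunk - 1L, grid$n_cells)
    sim <- grid$xyz[s:e, , drop = FALSE] %*% t(pts)
    nearest <- max.col(sim, ties.method = "first")
    out[s:e, ] <- vmat[nearest, , drop = FALSE]
  }
  if (ncol(out) == 1) as.numeric(out) else out
}
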