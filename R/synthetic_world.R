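# The canonical synthetic study world: a compact continent on the
# icosahedral grid plus a glacial-interglacial climate with orographic
# heterogeneity and millennial-scale, spatially coherent variability.

#' Build a synthetic world for simulation experiments
#'
#' Composes a grid, a land mask and a 120-kyr style climate into the
#' package's standard synthetic study conditions. The climate is the sum
#' of:
#'
#' * a zonal mean state (equatorial maximum temperature minus a latitudinal
#'   lapse; a tropical wet belt for precipitation),
#' * a static orographic anomaly field, smooth at the scale of several
#'   cells (mountains, rain shadows),
#' * a glacial cycle shaped like the late-Pleistocene record: slow cooling
#'   from an interglacial start to a glacial maximum at `lgm_kyr_bp`, rapid
#'   deglacial warming until `deglacial_end_kyr_bp`, then a stable
#'   interglacial to the present; the temperature amplitude grows toward
#'   the poles (polar amplification),
#' * spatially coherent, millennial-scale AR(1) anomalies (the desk-scale
#'   analogue of Dansgaard-Oeschger style variability).
#'
#' The start of the record therefore has a climate close to the present
#' day's, as in the last interglacial. Everything is deterministic under
#' `seed`.
#'
#' @param resolution Grid resolution (default 4; 812 global cells).
#' @param n_steps Number of 100-year steps (default 1200, i.e. 120 kyr).
#' @param seed Integer seed controlling the landmass, orography and
#'   anomalies.
#' @param n_continents,coverage Passed to [synthetic_land_mask()].
#' @param base_tmax,lapse Zonal mean state: equatorial TMAX (degC) and
#'   its fall per degree latitude (defaults 30 and 0.8).
#' @param tmin_offset TMAX minus TMIN (degC, default 15).
#' @param prcp_base,prcp_belt_width,prcp_floor Wet-belt precipitation
#'   parameters (mm/d and degrees; defaults 8, 20, 1.5).
#' @param topo_sd_temp,topo_sd_prcp Standard deviation of the static
#'   orographic anomalies (degC, mm/d; defaults 5 and 2).
#' @param topo_smooth_hops Neighbour-averaging passes applied to the
#'   orography (default 6: features span several cells).
#' @param glacial_amplitude Equatorial glacial-interglacial TMAX contrast
#'   (degC, default 6); the local amplitude is this times
#'   `1 + |latitude| / 90`.
#' @param glacial_drying Precipitation reduction at the glacial maximum
#'   (mm/d, default 2).
#' @param lgm_kyr_bp,deglacial_end_kyr_bp Timing of the glacial maximum
#'   and the end of the deglacial warming (kyr before present; defaults 21
#'   and 11).
#' @param noise_sd_temp,noise_sd_prcp Standard deviation of the transient
#'   anomalies (degC, mm/d; defaults 2.5 and 0.8).
#' @param noise_smooth_hops Spatial coherence of the transient anomalies
#'   (default 8: near continental scale).
#' @param ar1_rho Temporal persistence of the anomalies per 100-year step
#'   (default 0.995: decorrelation over millennia).
#' @return A list with `grid` (land-masked `nichesim_grid`) and `climate`
#'   (a `climate_series` with `n_steps + 1` slices).
#' @export
synthetic_world <- function(resolution = 4, n_steps = 1200, seed = 1,
                            n_continents = 1, coverage = 0.35,
                            base_tmax = 30, lapse = 0.8, tmin_offset = 15,
                            prcp_base = 8, prcp_belt_width = 20,
                            prcp_floor = 1.5,
                            topo_sd_temp = 5, topo_sd_prcp = 2,
                            topo_smooth_hops = 6,
                            glacial_amplitude = 6, glacial_drying = 2,
                            lgm_kyr_bp = 21, deglacial_end_kyr_bp = 11,
                            noise_sd_temp = 2.5, noise_sd_prcp = 0.8,
                            noise_smooth_hops = 8, ar1_rho = 0.995) {
  grid <- build_grid(resolution)
  mask <- synthetic_land_mask(grid, n_continents = n_continents,
                              coverage = coverage, seed = seed)
  grid <- apply_land_mask(grid, mask)
  n <- grid$n_cells
  # transient anomalies + zonal state from the base generator (cycle off)
  cl0 <- generate_synthetic_climate(
    grid, n_steps, base_tmax = base_tmax, lapse = lapse, amplitude = 0,
    tmin_offset = tmin_offset, prcp_base = prcp_base,
    prcp_belt_width = prcp_belt_width, prcp_floor = prcp_floor,
    prcp_cycle_amplitude = 0, noise_sd_temp = noise_sd_temp,
    noise_sd_prcp = noise_sd_prcp, noise_smooth_hops = noise_smooth_hops,
    ar1_rho = ar1_rho, seed = seed)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed + 1)
  smooth_field <- function(sd) {
    z <- stats::rnorm(n)
    idx <- rep.int(seq_len(n), lengths(grid$adjacency))
    nbr <- unlist(grid$adjacency, use.names = FALSE)
    for (h in seq_len(topo_smooth_hops)) {
      z <- 0.5 * z +
        0.5 * as.numeric(rowsum(z[nbr], idx)) / lengths(grid$adjacency)
    }
    z / stats::sd(z) * sd
  }
  topo_t <- smooth_field(topo_sd_temp)
  topo_p <- smooth_field(topo_sd_prcp)
  # glacial sawtooth: 0 at both interglacial ends, 1 at the glacial maximum
  t_bp <- cl0$times_years_bp
  lgm <- lgm_kyr_bp * 1000
  degl <- deglacial_end_kyr_bp * 1000
  s <- ifelse(t_bp >= lgm, (t_bp[1] - t_bp) / (t_bp[1] - lgm),
       ifelse(t_bp >= degl, (t_bp - degl) / (lgm - degl), 0))
  amp <- glacial_amplitude * (1 + abs(grid$cells$lat) / 90)
  tmax <- cl0$tmax + topo_t - outer(amp, s)
  tmin <- cl0$tmin + topo_t - outer(amp, s)
  prcp <- pmax(cl0$prcp + topo_p - outer(rep(glacial_drying, n), s), 0)
  list(grid = grid,
       climate = climate_series(tmax, tmin, prcp,
                                timestep_years = cl0$timestep_years))
}
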