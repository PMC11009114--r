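# Fundamental-niche envelopes and the ten niche-evolution scenarios.

# Scenario registry: identifier -> (kind, adaptive rate x). The rate applies
# only to the adaptive (directional / omnidirectional) scenarios.
.SCENARIOS <- list(
  "conservatism"       = list(kind = "conservatism",      x = NA_real_),
  "dir-shift-10"       = list(kind = "dir-shift",         x = 0.1),
  "dir-shift-50"       = list(kind = "dir-shift",         x = 0.5),
  "dir-expand-10"      = list(kind = "dir-expand",        x = 0.1),
  "dir-expand-50"      = list(kind = "dir-expand",        x = 0.5),
  "omni-expand-10"     = list(kind = "omni-expand",       x = 0.1),
  "omni-expand-50"     = list(kind = "omni-expand",       x = 0.5),
  "rand-shift"         = list(kind = "rand-shift",        x = NA_real_),
  "rand-expand-reduce" = list(kind = "rand-expand-reduce", x = NA_real_),
  "rand-change-shift"  = list(kind = "rand-change-shift", x = NA_real_)
)

#' Niche-evolution scenario identifiers
#'
#' The ten supported scenarios: full conservatism; directional shift,
#' directional expansion and omnidirectional expansion, each at a 10% or
#' 50% adaptive rate; and three random-change modes (shift,
#' expansion/reduction, combined change and shift).
#'
#' @return Character vector of the ten scenario identifiers.
#' @export
scenario_ids <- function() names(.SCENARIOS)

.scenario_info <- function(scenario) {
  info <- .SCENARIOS[[scenario]]
  if (is.null(info)) {
    stop("unknown scenario '", scenario, "'; see scenario_ids()")
  }
  info
}

# Initial niche breadths by configuration: full tolerance ranges (the
# envelope spans value +/- breadth/2). Temperature breadth applies to the
# TMAX and TMIN envelopes independently; precipitation breadth to PRCP.
.BREADTHS <- list(
  narrow = c(temp = 40, prcp = 5),
  broad  = c(temp = 60, prcp = 10)
)

#' Initialize a species' climatic niche from its seed cell
#'
#' The climate of the starting cell defines the centre of the fundamental
#' niche on every axis; the configured breadth defines its full width.
#' Narrow corresponds to tolerance ranges of 40 degC (temperature) and
#' 5 mm/d (precipitation); broad to 60 degC and 10 mm/d. A lower
#' precipitation limit below 0 is legal (suitability still requires the
#' observed value, which is never negative, to fall inside the envelope).
#'
#' @param seed_values Named numeric vector with `tmax`, `tmin`, `prcp`: the
#'   seed cell's climate at the first time slice.
#' @param breadth_config `"narrow"` or `"broad"`.
#' @param scenario One of [scenario_ids()].
#' @return A `species_niche`: envelopes (each `c(lower, upper)`) for the
#'   three variables, the initial per-axis breadths `nb0` (fixed for the
#'   species' whole lifetime and copied unchanged to daughters), the
#'   scenario and its adaptive rate.
#' @export
initialize_niche <- function(seed_values, breadth_config = c("narrow", "broad"),
                             scenario = "conservatism") {
  breadth_config <- match.arg(breadth_config)
  info <- .scenario_info(scenario)
  need <- c("tmax", "tmin", "prcp")
  if (!all(need %in% names(seed_values)) || anyNA(seed_values[need])) {
    stop("seed_values must supply tmax, tmin and prcp")
  }
  b <- .BREADTHS[[breadth_config]]
  env <- function(v, half) {
    c(lower = unname(v) - unname(half), upper = unname(v) + unname(half))
  }
  structure(
    list(envelopes = list(
           tmax = env(seed_values["tmax"], b["temp"] / 2),
           tmin = env(seed_values["tmin"], b["temp"] / 2),
           prcp = env(seed_values["prcp"], b["prcp"] / 2)),
         nb0 = b,
         scenario = scenario,
         rate_x = info$x),
    class = "species_niche")
}

#' @export
print.species_niche <- function(x, ...) {
  cat("Species niche [", x$scenario, "]\n", sep = "")
  for (v in names(x$envelopes)) {
    e <- x$envelopes[[v]]
    cat(sprintf("  %s: [%.2f, %.2f]%s\n", v, e["lower"], e["upper"],
                if (e["upper"] < e["lower"]) "  (inverted: nothing suitable)"
                else ""))
  }
  invisible(x)
}

#' Is a cell's climate inside a species' niche?
#'
#' `TRUE` iff each of the three values lies inside the corresponding closed
#' envelope `[lower, upper]`. An inverted envelope (upper < lower, possible
#' under random niche reduction) admits no value at all.
#'
#' @param niche A `species_niche`.
#' @param cell_values Named numeric vector with `tmax`, `tmin`, `prcp`.
#' @return Logical scalar.
#' @export
is_suitable <- function(niche, cell_values) {
  need <- c("tmax", "tmin", "prcp")
  if (!all(need %in% names(cell_values)) || anyNA(cell_values[need])) {
    stop("cell_values must supply tmax, tmin and prcp")
  }
  for (v in need) {
    e <- niche$envelopes[[v]]
    val <- unname(cell_values[v])
    if (val < e["lower"] || val > e["upper"]) return(FALSE)
  }
  TRUE
}

#' Mean climate change across a species' range
#'
#' For each niche axis, the difference between the unweighted mean over the
#' currently occupied cells at `step` and the mean over the same cells at
#' `step - 1`. The temperature axis is computed from TMAX (one delta per
#' axis; it is applied to both the TMAX and TMIN envelopes); the
#' precipitation axis from PRCP.
#'
#' @param series A `climate_series`.
#' @param occupied Non-empty vector of occupied cell ids (the range at the
#'   current step).
#' @param step 1-based slice index >= 2 (change from the previous slice).
#' @return Named numeric `c(temp = ..., prcp = ...)`.
#' @export
compute_delta_V <- function(series, occupied, step) {
  stopifnot(inherits(series, "climate_series"))
  if (length(occupied) == 0) {
    stop("occupied set is empty (species should already be extinct)")
  }
  if (step < 2 || step > series$n_slices) stop("step out of range")
  c(temp = mean(series$tmax[occupied, step]) -
      mean(series$tmax[occupied, step - 1]),
    prcp = mean(series$prcp[occupied, step]) -
      mean(series$prcp[occupied, step - 1]))
}

#' Draw the random niche deltas for one time step
#'
#' For each axis, the centre and edge deltas are independent draws from
#' `Uniform(-NB0, NB0) * 0.01`, where NB0 is the species' initial niche
#' breadth on that axis. Redrawn every time step; uses R's global RNG.
#'
#' @param nb0 Named numeric `c(temp = ..., prcp = ...)` initial breadths.
#' @return List with `centre` and `edge`, each `c(temp, prcp)`.
#' @export
draw_random_deltas <- function(nb0) {
  stopifnot(all(c("temp", "prcp") %in% names(nb0)))
  list(
    centre = c(temp = stats::runif(1, -nb0[["temp"]], nb0[["temp"]]) * 0.01,
               prcp = stats::runif(1, -nb0[["prcp"]], nb0[["prcp"]]) * 0.01),
    edge   = c(temp = stats::runif(1, -nb0[["temp"]], nb0[["temp"]]) * 0.01,
               prcp = stats::runif(1, -nb0[["prcp"]], nb0[["prcp"]]) * 0.01))
}

# Update one envelope under one scenario given the axis-level deltas.
.evolve_envelope <- function(env, kind, x, dv, centre, edge) {
  lo <- env[["lower"]]
  hi <- env[["upper"]]
  switch(kind,
    "conservatism" = NULL,
    "dir-shift" = {
      lo <- lo + x * dv
      hi <- hi + x * dv
    },
    "dir-expand" = {
      if (dv > 0) hi <- hi + x * dv
      if (dv < 0) lo <- lo + x * dv
    },
    "omni-expand" = {
      hi <- hi + x * abs(dv)
      lo <- lo - x * abs(dv)
    },
    "rand-shift" = {
      lo <- lo + centre
      hi <- hi + centre
    },
    "rand-expand-reduce" = {
      lo <- lo + edge
      hi <- hi - edge
    },
    "rand-change-shift" = {
      hi <- hi + centre + edge
      lo <- lo + centre - edge
    },
    stop("unknown scenario kind '", kind, "'"))
  c(lower = lo, upper = hi)
}

#' Apply one time step of niche evolution
#'
#' Updates the three envelopes according to the niche's scenario. The
#' temperature-axis delta is applied to both the TMAX and TMIN envelopes;
#' the precipitation delta to PRCP. Under conservatism nothing changes.
#' Adaptive scenarios use the range-level climate change `delta$dv`
#' (see [compute_delta_V()]) scaled by the scenario rate; random scenarios
#' use the pre-drawn `delta$centre` / `delta$edge`
#' (see [draw_random_deltas()]). Envelopes may invert (upper < lower) under
#' random reduction; they are deliberately not clamped — an inverted
#' envelope renders every cell unsuitable, which is the extinction pathway.
#'
#' @param niche A `species_niche`.
#' @param delta List with any of `dv`, `centre`, `edge`, each a named
#'   numeric `c(temp, prcp)`. Missing parts default to 0.
#' @return The updated `species_niche`.
#' @export
evolve_niche <- function(niche, delta) {
  info <- .scenario_info(niche$scenario)
  zero <- c(temp = 0, prcp = 0)
  dv <- if (is.null(delta$dv)) zero else delta$dv
  centre <- if (is.null(delta$centre)) zero else delta$centre
  edge <- if (is.null(delta$edge)) zero else delta$edge
  if (info$kind == "conservatism") return(niche)
  for (v in c("tmax", "tmin")) {
    niche$envelopes[[v]] <- .evolve_envelope(
      niche$envelopes[[v]], info$kind, info$x,
      dv[["temp"]], centre[["temp"]], edge[["temp"]])
  }
  niche$envelopes$prcp <- .evolve_envelope(
    niche$envelopes$prcp, info$kind, info$x,
    dv[["prcp"]], centre[["prcp"]], edge[["prcp"]])
  niche
}
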