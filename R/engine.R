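# Simulation configuration, the run wrapper around the compiled automaton,
# and component-tracking / phylogeny bookkeeping.

.SCENARIO_KIND_CODE <- c(
  "conservatism" = 0L, "dir-shift" = 1L, "dir-expand" = 2L,
  "omni-expand" = 3L, "rand-shift" = 4L, "rand-expand-reduce" = 5L,
  "rand-change-shift" = 6L)

#' Configure a single simulation run
#'
#' A run starts one species at `seed_cell` at the first climate slice and
#' iterates the per-timestep automaton to the last slice: unsuitable
#' occupied cells are dropped, colonizations proposed and occupied,
#' extinction recorded if the range vanishes, the niche evolved under the
#' configured scenario, population components tracked, and speciation
#' triggered when a fragmented range stays isolated for
#' `isolation_steps` consecutive steps (100 steps = 10 kyr at the default
#' 100-year step).
#'
#' @param grid A `nichesim_grid`.
#' @param climate A `climate_series` on the same grid; its slices define the
#'   simulation steps.
#' @param seed_cell Land cell id where the initial species originates.
#' @param breadth `"narrow"` or `"broad"` initial niche breadth.
#' @param dispersal `"poor"` or `"good"`, or supply `kernel` directly.
#' @param scenario One of [scenario_ids()].
#' @param kernel Optional `dispersal_kernel` overriding `dispersal`.
#' @param isolation_steps Minimum consecutive steps of range fragmentation
#'   before speciation (default 100).
#' @param max_species Cap on cumulative species; a run exceeding it aborts
#'   with its partial outputs flagged (guards against run-away speciation).
#' @param rng_seed Integer master seed for this run.
#' @return A `sim_config`.
#' @export
simulation_config <- function(grid, climate, seed_cell,
                              breadth = c("narrow", "broad"),
                              dispersal = c("good", "poor"),
                              scenario = "conservatism",
                              kernel = NULL,
                              isolation_steps = 100L,
                              max_species = 10000L,
                              rng_seed = 1) {
  breadth <- match.arg(breadth)
  dispersal <- match.arg(dispersal)
  .scenario_info(scenario)
  validate_climate(climate, grid)
  stopifnot(isolation_steps >= 1, max_species >= 1)
  if (length(seed_cell) != 1 || seed_cell < 1 || seed_cell > grid$n_cells) {
    stop("invalid seed_cell")
  }
  if (!grid$cells$is_land[seed_cell]) {
    stop("seed cell ", seed_cell, " is not land")
  }
  if (is.null(kernel)) kernel <- make_kernel(dispersal)
  structure(
    list(grid = grid, climate = climate, seed_cell = as.integer(seed_cell),
         breadth = breadth, dispersal = dispersal, scenario = scenario,
         kernel = kernel, isolation_steps = as.integer(isolation_steps),
         max_species = as.integer(max_species), rng_seed = rng_seed),
    class = "sim_config")
}

.EVENT_NAMES <- c("speciation", "extinction", "fragmentation", "reconnection")

#' Run one simulation
#'
#' Executes the configured run in the compiled engine and assembles the
#' results: the species ledger (with parent links, so the full phylogeny of
#' the run is recoverable), the chronological event log, per-step extant
#' richness, final occupancy, and optional per-step diagnostics.
#'
#' Fully reproducible: the same config and seed give identical output.
#' Each species draws from its own counter-based RNG substream keyed by
#' `(rng_seed, species_id)`.
#'
#' @param config A `sim_config`.
#' @param record_components Record per-step component counts per species
#'   (default `TRUE`; needed by [fragmentation_series()]).
#' @param record_occupancy Record full per-step occupancy (testing /
#'   small runs only; memory grows with steps x range sizes).
#' @param record_niche Record per-step niche envelopes and the deltas
#'   applied (testing; allows replaying niche evolution externally).
#' @param balls Optional precomputed neighbour-ball structure from
#'   `grid_neighbor_balls()`; computed on the fly when `NULL`.
#' @return A `nichesim_run`: list with `species` (data frame: `species_id`,
#'   `parent_id`, `origin_step`, `end_step`, `status` in
#'   extant/extinct/split, final envelope columns), `events` (data frame),
#'   `richness` (extant count after each step, index 1 = step 0),
#'   `occupancy` (list of final cell sets per species), `newick`,
#'   `cumulative`, `aborted`, `config`, and the requested diagnostics.
#' @export
run_simulation <- function(config, record_components = TRUE,
                           record_occupancy = FALSE, record_niche = FALSE,
                           balls = NULL) {
  stopifnot(inherits(config, "sim_config"))
  grid <- config$grid
  if (is.null(balls)) {
    balls <- grid_neighbor_balls(grid, max(1L, config$kernel$max_steps))
  }
  if (ncol(balls$cnt) < config$kernel$max_steps) {
    stop("neighbour balls shallower than the kernel's maximum reach")
  }
  b <- .BREADTHS[[config$breadth]]
  kind <- .SCENARIO_KIND_CODE[[.scenario_info(config$scenario)$kind]]
  x <- .scenario_info(config$scenario)$x
  raw <- .sim_run_cpp(
    n_cells = grid$n_cells,
    land = as.integer(grid$cells$is_land),
    ball_ptr = balls$ptr, ball_cells = balls$cells, ball_cnt = balls$cnt,
    tmax = config$climate$tmax, tmin = config$climate$tmin,
    prcp = config$climate$prcp,
    seed_cell = config$seed_cell,
    temp_breadth = b[["temp"]], prcp_breadth = b[["prcp"]],
    scenario_kind = kind,
    rate_x = if (is.na(x)) 0 else x,
    kernel_probs = unname(config$kernel$probs),
    isolation_steps = config$isolation_steps,
    max_species = config$max_species,
    run_seed = as.numeric(config$rng_seed),
    record_components = record_components,
    record_occupancy = record_occupancy,
    record_niche = record_niche)
  species <- as.data.frame(raw$species)
  species$status <- c("extant", "extinct", "split")[species$status + 1L]
  env <- raw$envelopes
  colnames(env) <- c("tmax_lower", "tmax_upper", "tmin_lower", "tmin_upper",
                     "prcp_lower", "prcp_upper")
  species <- cbind(species, as.data.frame(env))
  events <- as.data.frame(raw$events)
  events$event <- .EVENT_NAMES[events$type]
  events <- events[, c("step", "event", "species_id", "detail")]
  occupancy <- raw$occupancy
  names(occupancy) <- paste0("sp", species$species_id)
  run <- structure(
    list(species = species, events = events,
         richness = as.integer(raw$richness),
         occupancy = occupancy,
         cumulative = raw$cumulative, aborted = raw$aborted,
         n_steps = config$climate$n_slices - 1L,
         config = config),
    class = "nichesim_run")
  run$newick <- run_newick(run)
  if (!is.null(raw$fragmentation)) {
    run$fragmentation <- as.data.frame(raw$fragmentation)
  }
  if (!is.null(raw$occupancy_steps)) {
    run$occupancy_steps <- as.data.frame(raw$occupancy_steps)
  }
  if (!is.null(raw$niche_trace)) {
    nt <- raw$niche_trace
    tr <- data.frame(step = nt$step, species_id = nt$species_id)
    env2 <- nt$envelopes
    colnames(env2) <- colnames(env)
    del <- nt$deltas
    colnames(del) <- c("dv_temp", "dv_prcp", "centre_temp", "centre_prcp",
                       "edge_temp", "edge_prcp")
    run$niche_trace <- cbind(tr, as.data.frame(env2), as.data.frame(del))
  }
  run
}

#' @export
print.nichesim_run <- function(x, ...) {
  n_spec <- sum(x$events$event == "speciation")
  n_ext <- sum(x$events$event == "extinction")
  cat("Eco-evolutionary simulation run (", x$n_steps, " steps)\n", sep = "")
  cat("  scenario:", x$config$scenario, "| breadth:", x$config$breadth,
      "| dispersal:", x$config$dispersal, "\n")
  cat("  cumulative species:", x$cumulative,
      "| extant at end:", x$richness[length(x$richness)], "\n")
  cat("  speciation events:", n_spec, "| extinctions:", n_ext,
      if (x$aborted) "| ABORTED at species cap" else "", "\n")
  invisible(x)
}

#' @export
summary.nichesim_run <- function(object, ...) {
  print(object)
  cat("  final range sizes (cells):",
      paste(utils::head(sort(lengths(
        object$occupancy[object$species$status == "extant"]),
        decreasing = TRUE), 10), collapse = " "), "\n")
  invisible(object)
}

#' Neighbour balls for the compiled engine
#'
#' Precomputes, for every cell, the cells within `max_k` adjacency hops,
#' depth-sorted. Computing this once and passing it to repeated
#' [run_simulation()] calls on the same grid avoids re-deriving it per run.
#'
#' @param grid A `nichesim_grid`.
#' @param max_k Maximum hop depth (the kernel's `max_steps`).
#' @return An opaque list (`ptr`, `cells`, `cnt`).
#' @export
grid_neighbor_balls <- function(grid, max_k) {
  stopifnot(inherits(grid, "nichesim_grid"), max_k >= 1)
  .grid_neighbor_balls(grid, as.integer(max_k))
}

#' Update population components and isolation clocks
#'
#' Matches the connected components of a species' current range to the
#' previous step's components by maximal cell overlap (each previous
#' component is assigned to the current component it overlaps most; ties go
#' to the lower-numbered current component). A current component receiving
#' exactly one previous component inherits its isolation clock plus one —
#' provided the species entered the step with at least two components, so
#' the component spent the whole step separated (a lone component is the
#' whole species, not an isolate; at the step a range first splits, both
#' fragments start at 0). Components formed by merging (receiving two or
#' more previous components) reset to 0 (reconnection), as do brand-new
#' fragments.
#'
#' @param previous List of components, each `list(cells, clock)`.
#' @param current_cellsets List of disjoint cell-id vectors: the connected
#'   components of the current occupied set.
#' @return List of components (`cells` sorted, updated `clock`).
#' @export
track_components <- function(previous, current_cellsets) {
  n_cur <- length(current_cellsets)
  n_prev <- length(previous)
  allc <- unlist(current_cellsets, use.names = FALSE)
  if (anyDuplicated(allc)) stop("current component cell sets overlap")
  assigned <- integer(n_cur)
  inherit <- rep(NA_integer_, n_cur)
  for (p in seq_along(previous)) {
    ov <- vapply(current_cellsets, function(cs) {
      sum(previous[[p]]$cells %in% cs)
    }, integer(1))
    if (max(ov) > 0) {
      best <- which.max(ov)  # ties resolve to the lower current index
      assigned[best] <- assigned[best] + 1L
      if (assigned[best] == 1L) inherit[best] <- previous[[p]]$clock
    }
  }
  lapply(seq_len(n_cur), function(q) {
    list(cells = sort.int(as.integer(current_cellsets[[q]])),
         clock = if (assigned[q] == 1L && n_prev >= 2L) {
           inherit[q] + 1L
         } else {
           0L
         })
  })
}

#' Connected components of a cell set under grid adjacency
#'
#' @param grid A `nichesim_grid`.
#' @param cells Vector of cell ids.
#' @return List of sorted cell-id vectors, one per component, ordered by
#'   smallest member.
#' @export
connected_components <- function(grid, cells) {
  cells <- sort.int(unique(as.integer(cells)))
  inset <- logical(grid$n_cells)
  inset[cells] <- TRUE
  seen <- logical(grid$n_cells)
  comps <- list()
  for (c0 in cells) {
    if (seen[c0]) next
    comp <- integer(0)
    frontier <- c0
    seen[c0] <- TRUE
    while (length(frontier)) {
      comp <- c(comp, frontier)
      nb <- unique(unlist(grid$adjacency[frontier], use.names = FALSE))
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      frontier <- nb
    }
    comps[[length(comps) + 1L]] <- sort.int(comp)
  }
  comps
}

#' Newick phylogeny of a run
#'
#' Builds the complete tree of the run, extinct tips included. Tip and node
#' labels are `sp<id>`; branch lengths are lifetimes in kyr (steps x 0.1).
#' Speciation replaces the parent with its daughter components, so parents
#' appear as internal nodes (possibly multifurcating) and every
#' never-splitting species is a tip. With `annotate_extinct = TRUE` extinct
#' tips carry a `[&extinct=<step>]` comment (not all parsers accept
#' comments; the default plain form round-trips through
#' [ape::read.tree()]).
#'
#' @param run A `nichesim_run`.
#' @param annotate_extinct Add extinction-step comments (default `FALSE`).
#' @param step_kyr Duration of one step in kyr (default 0.1).
#' @return A single Newick string, terminated by `;`.
#' @export
run_newick <- function(run, annotate_extinct = FALSE, step_kyr = 0.1) {
  sp <- run$species
  end <- ifelse(is.na(sp$end_step), run$n_steps, sp$end_step)
  len <- (end - sp$origin_step) * step_kyr
  kids <- split(sp$species_id, factor(sp$parent_id, levels = sp$species_id))
  lab <- function(i) {
    tag <- paste0("sp", sp$species_id[i])
    if (annotate_extinct && sp$status[i] == "extinct") {
      tag <- paste0(tag, "[&extinct=", sp$end_step[i], "]")
    }
    tag
  }
  build <- function(i) {
    ch <- kids[[i]]
    if (length(ch) == 0) {
      paste0(lab(i), ":", format(len[i], trim = TRUE))
    } else {
      paste0("(", paste(vapply(match(ch, sp$species_id), build, ""),
                        collapse = ","),
             ")", lab(i), ":", format(len[i], trim = TRUE))
    }
  }
  paste0(build(1L), ";")
}

#' Event-log JSON Lines writer / reader
#'
#' One JSON object per line with fields `step`, `event`, `species_id`,
#' `detail`.
#'
#' @param events Event data frame from a `nichesim_run`.
#' @param path Output file.
#' @rdname events_io
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    writeLines(jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname events_io
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(data.frame(step = integer(0), event = character(0),
                      species_id = integer(0), detail = integer(0)))
  }
  do.call(rbind, lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l))
  }))
}
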