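# The per-timestep automaton: determinism, event mechanics, bookkeeping.

test_that("a lone species on a static suitable world absorbs all land, no events", {
  g <- test_grid(3)
  cl <- constant_climate(g$n_cells, 151)
  for (disp in c("poor", "good")) {
    cfg <- simulation_config(g, cl, seed_cell = 5, dispersal = disp,
                             scenario = "conservatism", rng_seed = 2)
    run <- run_simulation(cfg)
    expect_identical(run$cumulative, 1L)
    expect_identical(nrow(run$events[run$events$event %in%
                                       c("speciation", "extinction"), ]), 0L)
    expect_identical(sort(run$occupancy[[1]]), seq_len(g$n_cells))
    expect_true(all(run$richness == 1L))
  }
})

test_that("runs replay byte-identically under the same config and seed", {
  w <- barrier_world()
  cfg <- simulation_config(w$grid, w$climate, w$seed_cell,
                           scenario = "rand-change-shift", rng_seed = 31)
  r1 <- run_simulation(cfg, record_niche = TRUE)
  r2 <- run_simulation(cfg, record_niche = TRUE)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$species, r2$species)
  expect_identical(r1$occupancy, r2$occupancy)
  expect_identical(r1$niche_trace, r2$niche_trace)
  r3 <- run_simulation(simulation_config(w$grid, w$climate, w$seed_cell,
                                         scenario = "rand-change-shift",
                                         rng_seed = 32))
  expect_false(identical(r1$events, r3$events))
})

test_that("a range split by a persistent barrier speciates at +100 steps", {
  w <- barrier_world(barrier_step = 150)
  cfg <- simulation_config(w$grid, w$climate, w$seed_cell,
                           scenario = "conservatism", rng_seed = 11)
  run <- run_simulation(cfg)
  ev <- run$events
  expect_identical(ev$step[ev$event == "fragmentation"][1], 150L)
  spec <- ev[ev$event == "speciation", ]
  expect_identical(nrow(spec), 1L)
  expect_identical(spec$step, 250L)       # fragmentation + isolation time
  expect_identical(spec$detail, 2L)       # two daughters
  expect_identical(run$cumulative, 3L)
  # daughters inherit the parent's envelope exactly under conservatism
  sp <- run$species
  expect_equal(sp$tmax_lower, rep(sp$tmax_lower[1], 3))
  expect_equal(sp$prcp_upper, rep(sp$prcp_upper[1], 3))
  # topology (A,B) with the split at the right height
  expect_match(run$newick, "^\\(sp[23]:[0-9.]+,sp[23]:[0-9.]+\\)sp1:")
  tree <- ape::read.tree(text = run$newick)
  expect_identical(sort(tree$tip.label), c("sp2", "sp3"))
  expect_equal(tree$edge.length, c(1, 1))  # 10 steps to the run end = 1 kyr
})

test_that("losing every suitable cell extinguishes the species", {
  g <- test_grid(2)
  n <- g$n_cells
  tmax <- matrix(20, n, 61)
  tmax[, 41:61] <- 100  # world turns lethal at step 40
  cl <- climate_series(tmax, tmax - 15, matrix(3, n, 61))
  cfg <- simulation_config(g, cl, seed_cell = 1, rng_seed = 4)
  run <- run_simulation(cfg)
  ev <- run$events
  expect_identical(ev$event[nrow(ev)], "extinction")
  expect_identical(ev$step[nrow(ev)], 40L)
  expect_identical(run$richness[40], 1L)  # after step 39, still alive
  expect_identical(run$richness[41], 0L)  # after step 40, extinct
  expect_identical(run$species$status, "extinct")
  expect_length(run$occupancy[[1]], 0)
})

test_that("reconnection before the isolation time resets the clock", {
  # barrier opens at 150 and closes again at 200 (< 100 steps of isolation)
  g <- test_grid(3)
  n <- g$n_cells
  mask <- g$cells$lat > 0
  gm <- apply_land_mask(g, mask)
  tmax <- matrix(20, n, 351)
  ring <- mask & g$cells$lat > 35 & g$cells$lat < 50
  tmax[ring, 151:200] <- 100
  cl <- climate_series(tmax, tmax - 15, matrix(3, n, 351))
  cfg <- simulation_config(gm, cl, which(mask & g$cells$lat > 60)[1],
                           rng_seed = 11)
  run <- run_simulation(cfg)
  expect_identical(sum(run$events$event == "speciation"), 0L)
  expect_identical(sum(run$events$event == "reconnection"), 1L)
  expect_identical(run$cumulative, 1L)
})

test_that("species ledger identities hold on eventful runs", {
  w <- barrier_world()
  for (sc in c("conservatism", "rand-expand-reduce")) {
    run <- run_simulation(simulation_config(
      w$grid, w$climate, w$seed_cell, scenario = sc, rng_seed = 77))
    sp <- run$species
    ev <- run$events
    expect_identical(run$cumulative, nrow(sp))
    expect_identical(sp$species_id, seq_len(nrow(sp)))
    # cumulative = 1 + sum of daughters per speciation event
    expect_identical(nrow(sp),
                     1L + sum(ev$detail[ev$event == "speciation"]))
    # extant = cumulative - extinct - pseudo-extinct parents
    expect_identical(sum(sp$status == "extant"),
                     run$richness[length(run$richness)])
    expect_identical(nrow(sp), sum(sp$status == "extant") +
                       sum(sp$status == "extinct") +
                       sum(sp$status == "split"))
    # extinct species have empty final ranges; extant non-empty
    expect_true(all(lengths(run$occupancy[sp$status != "extant"]) == 0))
    expect_true(all(lengths(run$occupancy[sp$status == "extant"]) > 0))
    # parents precede daughters and bracket their lifetimes
    kids <- sp[!is.na(sp$parent_id), ]
    expect_true(all(kids$parent_id < kids$species_id))
    expect_identical(kids$origin_step,
                     sp$end_step[match(kids$parent_id, sp$species_id)])
  }
})

test_that("phylogenies round-trip through Newick with matching tip counts", {
  w <- barrier_world()
  run <- run_simulation(simulation_config(
    w$grid, w$climate, w$seed_cell, scenario = "rand-shift", rng_seed = 5))
  sp <- run$species
  tree <- ape::read.tree(text = run$newick)
  tips <- sum(!(sp$species_id %in% sp$parent_id))
  expect_identical(length(tree$tip.label), tips)
  # all branch lengths are non-negative lifetimes in kyr
  expect_true(all(tree$edge.length >= 0))
  expect_lte(max(tree$edge.length), run$n_steps * 0.1)
  # re-writing the parsed tree preserves the topology
  expect_identical(sort(tree$tip.label),
                   sort(paste0("sp", sp$species_id[
                     !(sp$species_id %in% sp$parent_id)])))
  annotated <- run_newick(run, annotate_extinct = TRUE)
  expect_identical(grepl("extinct=", annotated),
                   any(sp$status == "extinct"))
})

test_that("occupied cells are always land and suitable; components partition", {
  skip_if_not_installed("igraph")
  g <- test_grid(3)
  mask <- synthetic_land_mask(g, n_continents = 1, coverage = 0.5, seed = 3)
  gm <- apply_land_mask(g, mask)
  cl <- generate_synthetic_climate(gm, 200, noise_sd_temp = 2,
                                   noise_sd_prcp = 0.8, amplitude = 5,
                                   ar1_rho = 0.9, seed = 14)
  seedc <- which(mask)[10]
  run <- run_simulation(simulation_config(
    gm, cl, seedc, scenario = "rand-change-shift", dispersal = "good",
    rng_seed = 21), record_occupancy = TRUE, record_components = TRUE,
    record_niche = TRUE)
  oc <- run$occupancy_steps
  tr <- run$niche_trace
  fr <- run$fragmentation
  edges <- cbind(rep.int(seq_along(gm$adjacency), lengths(gm$adjacency)),
                 unlist(gm$adjacency, use.names = FALSE))
  ig <- igraph::graph_from_edgelist(edges[edges[, 1] < edges[, 2], ],
                                    directed = FALSE)
  some_steps <- unique(round(seq(2, 200, length.out = 40)))
  for (st in some_steps) {
    rows <- oc[oc$step == st, ]
    if (!nrow(rows)) break
    for (sid in unique(rows$species_id)) {
      cells <- rows$cell_id[rows$species_id == sid]
      expect_true(all(gm$cells$is_land[cells]))
      # cells occupied at step st passed suitability under the envelope in
      # force DURING the step, i.e. the one recorded after step st - 1
      # (range update precedes niche evolution in the step order)
      env <- tr[tr$step == st - 1 & tr$species_id == sid, ]
      if (nrow(env) == 1) {
        expect_true(all(
          cl$tmax[cells, st + 1] >= env$tmax_lower &
          cl$tmax[cells, st + 1] <= env$tmax_upper &
          cl$prcp[cells, st + 1] >= env$prcp_lower &
          cl$prcp[cells, st + 1] <= env$prcp_upper))
      }
      # component count matches an igraph components oracle
      ncomp <- fr$n_components[fr$step == st & fr$species_id == sid]
      sub <- igraph::induced_subgraph(ig, cells)
      expect_identical(ncomp, as.integer(igraph::components(sub)$no))
      # and the package's own BFS helper agrees
      expect_identical(length(connected_components(gm, cells)), ncomp)
    }
  }
})

test_that("recorded niche trajectories replay through the R update rules", {
  w <- barrier_world()
  for (sc in c("dir-shift-50", "omni-expand-10", "rand-change-shift")) {
    run <- run_simulation(simulation_config(
      w$grid, w$climate, w$seed_cell, scenario = sc, rng_seed = 13),
      record_niche = TRUE)
    tr <- run$niche_trace
    tr1 <- tr[tr$species_id == 1, ]
    niche <- initialize_niche(
      c(tmax = w$climate$tmax[w$seed_cell, 1],
        tmin = w$climate$tmin[w$seed_cell, 1],
        prcp = w$climate$prcp[w$seed_cell, 1]),
      "narrow", sc)
    for (i in seq_len(min(nrow(tr1), 120))) {
      niche <- evolve_niche(niche, list(
        dv = c(temp = tr1$dv_temp[i], prcp = tr1$dv_prcp[i]),
        centre = c(temp = tr1$centre_temp[i], prcp = tr1$centre_prcp[i]),
        edge = c(temp = tr1$edge_temp[i], prcp = tr1$edge_prcp[i])))
      expect_equal(unname(niche$envelopes$tmax),
                   c(tr1$tmax_lower[i], tr1$tmax_upper[i]), tolerance = 1e-12)
      expect_equal(unname(niche$envelopes$prcp),
                   c(tr1$prcp_lower[i], tr1$prcp_upper[i]), tolerance = 1e-12)
    }
  }
})

test_that("random-scenario engine deltas respect the NB0 * 1% bounds", {
  w <- barrier_world()
  run <- run_simulation(simulation_config(
    w$grid, w$climate, w$seed_cell, scenario = "rand-change-shift",
    breadth = "broad", rng_seed = 55), record_niche = TRUE)
  tr <- run$niche_trace
  expect_true(all(abs(tr$centre_temp) <= 0.6))   # NB0 = 60 -> +/- 0.6
  expect_true(all(abs(tr$edge_prcp) <= 0.1))     # NB0 = 10 -> +/- 0.1
  expect_gt(max(abs(tr$centre_temp)), 0.3)       # actually exercises range
})

test_that("the species cap aborts runs in a flagged, controlled way", {
  w <- barrier_world()
  run <- run_simulation(simulation_config(
    w$grid, w$climate, w$seed_cell, scenario = "conservatism",
    max_species = 2, rng_seed = 11))
  expect_true(run$aborted)
  expect_identical(run$cumulative, 3L)  # stopped right after exceeding cap
})

test_that("track_components follows the clock rules", {
  p0 <- list(list(cells = 1:10, clock = 0L))
  # a first split: both fragments start at 0
  cur <- list(1:4, 6:10)
  t1 <- track_components(p0, cur)
  expect_identical(vapply(t1, `[[`, 0L, "clock"), c(0L, 0L))
  # persisting split: both tick
  t2 <- track_components(t1, cur)
  expect_identical(vapply(t2, `[[`, 0L, "clock"), c(1L, 1L))
  t3 <- track_components(t2, cur)
  expect_identical(vapply(t3, `[[`, 0L, "clock"), c(2L, 2L))
  # merge resets to zero
  t4 <- track_components(t3, list(1:10))
  expect_identical(t4[[1]]$clock, 0L)
  # lone component stays at zero no matter how long
  t5 <- track_components(t4, list(1:10))
  expect_identical(t5[[1]]$clock, 0L)
  # a new fragment starts at 0 while an old one keeps ticking
  t6 <- track_components(t3, list(1:4, 6:8, 10L))
  expect_identical(vapply(t6, `[[`, 0L, "clock"), c(3L, 3L, 0L))
  # identity by maximal overlap: the larger remnant inherits the clock
  t7 <- track_components(t3, list(c(1:3), c(4L), 6:10))
  expect_identical(t7[[1]]$clock, 3L)  # 3 of prev cells
  expect_identical(t7[[2]]$clock, 0L)  # brand-new by assignment
  expect_error(track_components(p0, list(1:4, 4:6)), "overlap")
})
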