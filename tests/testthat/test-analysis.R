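# Windowed rates, gradients, fragmentation and scenario statistics.

test_that("windowed per-capita rates are events over lineage-time", {
  # 1200-step run, constant 5 extant; 1 speciation in the last window
  richness <- rep(5L, 1201)
  events <- data.frame(step = c(1195L, 500L),
                       event = c("speciation", "extinction"),
                       species_id = 1:2, detail = c(2L, 0L))
  rw <- windowed_rates(events, richness)
  expect_identical(nrow(rw), 10L)
  expect_equal(rw$window_start_kyr_bp, 10:1)
  expect_equal(rw$lineage_time_kyr, rep(5, 10))  # 5 lineages x 1 kyr
  expect_equal(rw$speciation_rate, c(rep(0, 9), 1 / 5))
  expect_equal(rw$extinction_rate, rep(0, 10))   # step 500 outside window
  expect_equal(rw$net_rate, rw$speciation_rate - rw$extinction_rate)
  # no events at all
  rw0 <- windowed_rates(events[0, ], richness)
  expect_true(all(rw0$net_rate == 0))
})

test_that("windows with zero lineage-time report missing rates", {
  richness <- c(rep(2L, 1101), rep(0L, 100))  # everything died at 10 ka
  events <- data.frame(step = integer(0), event = character(0),
                       species_id = integer(0), detail = integer(0))
  rw <- windowed_rates(events, richness)
  expect_true(all(is.na(rw$speciation_rate)))
  expect_true(all(is.na(rw$net_rate)))
})

test_that("rates are invariant to event ordering within a step", {
  richness <- rep(3L, 1201)
  ev <- data.frame(step = c(1150L, 1150L, 1150L),
                   event = c("speciation", "extinction", "speciation"),
                   species_id = 1:3, detail = c(2L, 0L, 2L))
  perm <- ev[c(3, 1, 2), ]
  expect_equal(windowed_rates(ev, richness)[, -(1:2)],
               windowed_rates(perm, richness)[, -(1:2)])
})

test_that("the default window layout yields 10 windows and 40 box-plot points", {
  richness <- rep(4L, 1201)
  ev <- data.frame(step = 1101L, event = "speciation", species_id = 1L,
                   detail = 2L)
  rw <- windowed_rates(ev, richness, window_kyr = 1, start_kyr_bp = 10)
  expect_identical(nrow(rw), 10L)
  # means per window x breadth x dispersal -> 10 x 2 x 2 = 40 points
  cells <- expand.grid(window = seq_len(nrow(rw)),
                       breadth = c("narrow", "broad"),
                       dispersal = c("poor", "good"))
  expect_identical(nrow(cells), 40L)
})

test_that("bootstrap gradients recover degenerate and analytic cases", {
  g <- test_grid(2)
  # every seed leaves exactly one species on its own seed cell
  seeds <- c(which.max(g$cells$lat), which.min(abs(g$cells$lat - 3)))
  ranges <- lapply(seeds, function(s) list(s))
  lg <- suppressWarnings(
    latitudinal_gradient(ranges, seeds, g, n_per_band = 10, n_boot = 50,
                         seed = 1))
  # a band with a single seed samples it 10x with replacement, CI width 0
  seed_band_mid <- 5 * floor(g$cells$lat[seeds[1]] / 5) + 2.5
  polar_band <- lg[lg$band_mid_lat == seed_band_mid, ]
  expect_equal(polar_band$mean_richness, 10)
  expect_equal(polar_band$ci_lower, 10)
  expect_equal(polar_band$ci_upper, 10)
  # bands holding no species report zero richness
  expect_true(any(lg$mean_richness == 0))
  expect_warning(
    latitudinal_gradient(ranges, seeds, g, n_per_band = 2, n_boot = 5),
    "no seeds")
})

test_that("bootstrap gradient converges to its analytic expectation", {
  g <- test_grid(4)
  # two seeds in the SAME cell band with known, different band footprints
  band_cells <- which(g$cells$lat > 0.1 & g$cells$lat < 4.9)
  expect_gte(length(band_cells), 4)
  seeds <- band_cells[1:2]
  r1 <- list(band_cells[1:4])                  # one species, 4 band cells
  r2 <- list(band_cells[1], band_cells[2])     # two 1-cell species
  n_boot <- 4000
  lg <- suppressWarnings(
    latitudinal_gradient(list(r1, r2), seeds, g, n_per_band = 1,
                         n_boot = n_boot, seed = 2))
  band <- lg[lg$band_mid_lat == 2.5, ]
  # each replicate draws one of the two seeds equally: E = (1 + 2) / 2
  se <- sqrt(0.25) / sqrt(n_boot)
  expect_lt(abs(band$mean_richness - 1.5), 3 * se + 1e-9)
  expect_identical(c(band$ci_lower, band$ci_upper), c(1, 2))
})

test_that("fragmentation series reproduce engineered component counts", {
  w <- barrier_world(barrier_step = 150, n_slices = 231)
  run <- run_simulation(simulation_config(
    w$grid, w$climate, w$seed_cell, rng_seed = 11),
    record_components = TRUE)
  fr <- fragmentation_series(run)
  sp1 <- fr[fr$species_id == 1, ]
  expect_true(all(sp1$n_components[sp1$step < 150] == 1))
  expect_true(all(sp1$n_components[sp1$step >= 150] == 2))
  ag <- aggregate_fragmentation(run)
  expect_equal(ag$mean_components[ag$step == 100], 1)
  expect_equal(ag$mean_components[ag$step == 200], 2)
  run2 <- run_simulation(simulation_config(
    w$grid, w$climate, w$seed_cell, rng_seed = 11),
    record_components = FALSE)
  expect_error(fragmentation_series(run2), "record_components")
})

test_that("range sizes sum occupied cell areas and skip the extinct", {
  w <- barrier_world()
  run <- run_simulation(simulation_config(
    w$grid, w$climate, w$seed_cell, rng_seed = 11))
  rs <- range_size_summary(run)
  expect_identical(nrow(rs), sum(run$species$status == "extant"))
  i <- 1
  expect_equal(rs$area_km2[i],
               sum(w$grid$cells$area_km2[
                 run$occupancy[[which(run$species$species_id ==
                                        rs$species_id[i])]]]))
  # a 1-cell range has that cell's area
  g <- test_grid(2)
  cl <- constant_climate(g$n_cells, 2)
  k0 <- make_kernel("poor", custom_probs = c(1, 0, 0))
  run1 <- run_simulation(simulation_config(
    g, cl, seed_cell = 7, kernel = k0, rng_seed = 1))
  rs1 <- range_size_summary(run1)
  expect_equal(rs1$area_km2, g$cells$area_km2[7])
})

test_that("scenario comparisons detect shifts and respect pairing", {
  set.seed(21)
  base <- expand.grid(seed = 1:12, breadth = c("n", "b"),
                      dispersal = c("p", "g"), window = 1:5,
                      stringsAsFactors = FALSE)
  noise <- rnorm(nrow(base), sd = 0.05)
  a <- cbind(base, scenario = "conservatism", rate = 0.5 + noise)
  # scenario B = A + exactly 0.1 on every paired observation
  b <- cbind(base, scenario = "shifted", rate = 0.5 + noise + 0.1)
  # scenario C identical to A
  c_ <- cbind(base, scenario = "identical", rate = 0.5 + noise)
  cmp <- compare_scenarios(rbind(a, b, c_))
  paired <- cmp$paired
  sh <- paired[paired$scenario == "shifted", ]
  expect_equal(sh$mean_diff, 0.1, tolerance = 1e-12)
  expect_lt(sh$p_adj, 0.001)
  id <- paired[paired$scenario == "identical", ]
  expect_equal(id$mean_diff, 0)
  hsd <- cmp$hsd
  expect_equal(hsd$diff[hsd$scenario == "shifted"], 0.1, tolerance = 0.02)
  expect_true(hsd$lwr[hsd$scenario == "shifted"] > 0)
  expect_true(hsd$p_adj[hsd$scenario == "identical"] > 0.9)
  # incomplete blocks are dropped from pairing with a count
  b_missing <- b[-(1:10), ]
  cmp2 <- compare_scenarios(rbind(a, b_missing))
  expect_identical(cmp2$paired$n_pairs, nrow(base) - 10L)
  expect_identical(cmp2$paired$n_dropped, 10L)
})

test_that("HSD confidence intervals cover a known effect at the right rate", {
  set.seed(33)
  hits <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    d <- data.frame(
      seed = rep(1:20, 2),
      scenario = rep(c("conservatism", "other"), each = 20),
      rate = c(rnorm(20, 1, 0.3), rnorm(20, 1.2, 0.3)))
    cmp <- compare_scenarios(d)
    hits <- hits + (cmp$hsd$lwr <= 0.2 && 0.2 <= cmp$hsd$upr)
  }
  # nominal 95% coverage; binomial 3-sigma band around it
  expect_gt(hits / n_rep, 0.95 - 3 * sqrt(0.05 * 0.95 / n_rep))
})
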