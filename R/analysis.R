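# Downstream analysis: windowed per-capita rates, latitudinal gradients,
# fragmentation series, range sizes and cross-scenario statistics.

#' Windowed per-capita speciation, extinction and net diversification rates
#'
#' Splits the analysis period (by default the last 10 kyr of the run,
#' allowing time for speciation to initiate) into fixed windows of
#' `window_kyr` (default 1 kyr = 10 windows) and computes, per window,
#' events per lineage per kyr. The per-capita denominator is lineage-time:
#' the extant species count summed over the window's steps times the step
#' length in kyr. Windows with zero lineage-time get `NA` rates (missing,
#' not zero). `net_rate = speciation_rate - extinction_rate` exactly.
#'
#' @param events Event data frame of a run (`step`, `event`, ...).
#' @param richness Integer vector of extant counts after each step
#'   (element 1 = step 0), as returned in a `nichesim_run`.
#' @param window_kyr Window width in kyr (default 1).
#' @param start_kyr_bp Start of the analysis period in kyr before present
#'   (default 10).
#' @param step_years Step length in years (default 100).
#' @return Data frame with one row per window: `window_start_kyr_bp`,
#'   `window_end_kyr_bp`, `n_speciation`, `n_extinction`,
#'   `lineage_time_kyr`, `speciation_rate`, `extinction_rate`, `net_rate`.
#' @export
windowed_rates <- function(events, richness, window_kyr = 1,
                           start_kyr_bp = 10, step_years = 100) {
  n_steps <- length(richness) - 1L
  steps_per_kyr <- 1000 / step_years
  wsteps <- as.integer(window_kyr * steps_per_kyr)
  start_steps <- as.integer(start_kyr_bp * steps_per_kyr)
  if (start_steps > n_steps) {
    stop("analysis period longer than the run itself")
  }
  n_win <- start_steps %/% wsteps
  out <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    first <- n_steps - start_steps + (w - 1L) * wsteps + 1L
    last <- first + wsteps - 1L
    in_win <- events$step >= first & events$step <= last
    n_spec <- sum(events$event[in_win] == "speciation")
    n_ext <- sum(events$event[in_win] == "extinction")
    lt <- sum(richness[first:last + 1L]) * (step_years / 1000)
    out[[w]] <- data.frame(
      window_start_kyr_bp = start_kyr_bp - (w - 1) * window_kyr,
      window_end_kyr_bp = start_kyr_bp - w * window_kyr,
      n_speciation = n_spec, n_extinction = n_ext,
      lineage_time_kyr = lt,
      speciation_rate = if (lt > 0) n_spec / lt else NA_real_,
      extinction_rate = if (lt > 0) n_ext / lt else NA_real_)
  }
  out <- do.call(rbind, out)
  out$net_rate <- out$speciation_rate - out$extinction_rate
  out
}

#' Latitudinal diversity gradient with bootstrap confidence intervals
#'
#' Builds richness-by-latitude curves from per-seed simulation outputs by
#' the subsampling scheme used for comparing simulated with empirical
#' gradients: in each bootstrap replicate, `n_per_band` seeds are drawn
#' with replacement from every `band_deg`-degree latitudinal band of seed
#' locations, their descendant species' ranges are overlaid, and richness
#' (number of overlaid species present) is computed per latitudinal band of
#' grid cells. Reported per cell band: the mean and percentile 95% CI of
#' richness across replicates.
#'
#' @param ranges_by_seed List, one element per seed run: a list of cell-id
#'   vectors (one per extant descendant species; empty list if none
#'   survive).
#' @param seed_cells Integer vector of seed cell ids, parallel to
#'   `ranges_by_seed`.
#' @param grid A `nichesim_grid`.
#' @param band_deg Band width in degrees (default 5).
#' @param n_per_band Seeds drawn per seed band per replicate (default 10).
#' @param n_boot Bootstrap replicates (default 100).
#' @param seed RNG seed for the bootstrap.
#' @return Data frame: `band_mid_lat`, `mean_richness`, `ci_lower`,
#'   `ci_upper` (bands of grid cells). Seed bands without any available
#'   seed are skipped with a warning.
#' @export
latitudinal_gradient <- function(ranges_by_seed, seed_cells, grid,
                                 band_deg = 5, n_per_band = 10,
                                 n_boot = 100, seed = 1) {
  stopifnot(length(ranges_by_seed) == length(seed_cells))
  breaks <- seq(-90, 90, by = band_deg)
  band_of <- function(lat) {
    pmin(findInterval(lat, breaks, rightmost.closed = TRUE),
         length(breaks) - 1L)
  }
  n_bands <- length(breaks) - 1L
  cell_band <- band_of(grid$cells$lat)
  # per seed run: number of distinct descendant species present per cell band
  seed_band_counts <- vapply(ranges_by_seed, function(ranges) {
    counts <- integer(n_bands)
    for (cells in ranges) {
      if (length(cells)) {
        bands <- unique(cell_band[cells])
        counts[bands] <- counts[bands] + 1L
      }
    }
    counts
  }, integer(n_bands))  # n_bands x n_seeds
  seed_band <- band_of(grid$cells$lat[seed_cells])
  seeds_in_band <- split(seq_along(seed_cells), factor(seed_band, 1:n_bands))
  occupied_seed_bands <- which(lengths(seeds_in_band) > 0)
  empty <- setdiff(which(tabulate(cell_band, n_bands) > 0 &
                           lengths(seeds_in_band) == 0), integer(0))
  if (length(empty)) {
    warning("no seeds available in ", length(empty),
            " latitudinal band(s); they contribute no sampled seeds")
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  boot <- matrix(0, n_bands, n_boot)
  for (r in seq_len(n_boot)) {
    tot <- numeric(n_bands)
    for (b in occupied_seed_bands) {
      pool <- seeds_in_band[[b]]
      take <- pool[sample.int(length(pool), n_per_band, replace = TRUE)]
      tot <- tot + rowSums(seed_band_counts[, take, drop = FALSE])
    }
    boot[, r] <- tot
  }
  has_cells <- tabulate(cell_band, n_bands) > 0
  data.frame(
    band_mid_lat = (breaks[-length(breaks)] + breaks[-1])[has_cells] / 2,
    mean_richness = rowMeans(boot)[has_cells],
    ci_lower = apply(boot, 1, stats::quantile, 0.025)[has_cells],
    ci_upper = apply(boot, 1, stats::quantile, 0.975)[has_cells])
}

#' Per-step population fragmentation
#'
#' Extracts the per-step number of population components (contiguous,
#' mutually isolated occupied patches) per species from a run recorded with
#' `record_components = TRUE`.
#'
#' @param run A `nichesim_run`.
#' @return Data frame `step`, `species_id`, `n_components`, plus the
#'   per-step mean across extant species as attribute-free summary columns
#'   via [aggregate_fragmentation()].
#' @export
fragmentation_series <- function(run) {
  if (is.null(run$fragmentation)) {
    stop("run was not recorded with record_components = TRUE")
  }
  run$fragmentation
}

#' @description `aggregate_fragmentation()` averages component counts over
#'   species within each step.
#' @rdname fragmentation_series
#' @export
aggregate_fragmentation <- function(run) {
  fr <- fragmentation_series(run)
  out <- stats::aggregate(n_components ~ step, data = fr, FUN = mean)
  names(out)[2] <- "mean_components"
  out
}

#' Final range sizes
#'
#' Sums occupied cell areas per species at the end of a run. Extinct
#' species (empty ranges) are excluded.
#'
#' @param run A `nichesim_run`.
#' @param grid The grid the run used (defaults to the one in the config).
#' @return Data frame `species_id`, `n_cells`, `area_km2`.
#' @export
range_size_summary <- function(run, grid = run$config$grid) {
  extant <- run$species$status == "extant"
  ids <- run$species$species_id[extant]
  cells <- run$occupancy[extant]
  data.frame(
    species_id = ids,
    n_cells = lengths(cells),
    area_km2 = vapply(cells, function(cs) {
      sum(grid$cells$area_km2[cs])
    }, numeric(1)))
}

#' Compare evolutionary rates across niche-evolution scenarios
#'
#' Given a table of windowed rates across runs, tests whether the reference
#' scenario (niche conservatism by default) shows different rates than each
#' other scenario: a one-way ANOVA across scenarios with post-hoc Tukey HSD
#' contrasts against the reference (family-wise error controlled by the
#' HSD), and paired t-tests on seed-matched observations restricted to
#' complete blocks (identical `seed x breadth x dispersal x window`
#' combinations present in both scenarios), Bonferroni-corrected across
#' scenario contrasts.
#'
#' @param rates Data frame with columns `rate`, `scenario`, `seed`, and
#'   optionally `breadth`, `dispersal`, `window` (used for pairing).
#' @param reference Reference scenario (default `"conservatism"`).
#' @return A `scenario_comparison`: list with `anova` (the `aov` fit),
#'   `hsd` (data frame of contrasts vs the reference: `scenario`, `diff`,
#'   `lwr`, `upr`, `p_adj`), and `paired` (data frame: `scenario`,
#'   `mean_diff`, `ci_lower`, `ci_upper`, `p`, `p_adj`, `n_pairs`,
#'   `n_dropped`).
#' @export
compare_scenarios <- function(rates, reference = "conservatism") {
  stopifnot(all(c("rate", "scenario", "seed") %in% names(rates)))
  rates <- rates[!is.na(rates$rate), ]
  rates$scenario <- factor(rates$scenario)
  if (!reference %in% levels(rates$scenario)) {
    stop("reference scenario '", reference, "' not present in the data")
  }
  fit <- stats::aov(rate ~ scenario, data = rates)
  tk <- stats::TukeyHSD(fit)$scenario
  pick <- grepl(paste0("(^|-)", reference, "($|-)"), rownames(tk))
  tk <- tk[pick, , drop = FALSE]
  other <- sub(paste0("-?", reference, "-?"), "", rownames(tk))
  # orient contrasts as other - reference
  flip <- !startsWith(rownames(tk), paste0(reference, "-")) &
    endsWith(rownames(tk), paste0("-", reference))
  sgn <- ifelse(flip, 1, -1)
  hsd <- data.frame(
    scenario = other,
    diff = sgn * tk[, "diff"],
    lwr = ifelse(sgn > 0, tk[, "lwr"], -tk[, "upr"]),
    upr = ifelse(sgn > 0, tk[, "upr"], -tk[, "lwr"]),
    p_adj = tk[, "p adj"],
    row.names = NULL)
  key_cols <- intersect(c("seed", "breadth", "dispersal", "window"),
                        names(rates))
  key <- do.call(paste, c(rates[key_cols], sep = "\r"))
  paired <- lapply(setdiff(levels(rates$scenario), reference), function(s) {
    a <- rates$scenario == reference
    b <- rates$scenario == s
    ka <- key[a]
    kb <- key[b]
    common <- intersect(ka, kb)
    dup <- union(ka[duplicated(ka)], kb[duplicated(kb)])
    common <- setdiff(common, dup)  # ambiguous blocks dropped
    n_dropped <- (length(unique(ka)) - length(common)) +
      (length(unique(kb)) - length(common))
    if (length(common) < 2) {
      return(data.frame(scenario = s, mean_diff = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        p = NA_real_, n_pairs = length(common),
                        n_dropped = n_dropped))
    }
    va <- rates$rate[a][match(common, ka)]
    vb <- rates$rate[b][match(common, kb)]
    d <- vb - va
    if (stats::sd(d) < 1e-10 * max(1, abs(mean(d)))) {
      # constant paired difference: degenerate t statistic
      m <- mean(d)
      return(data.frame(scenario = s, mean_diff = m, ci_lower = m,
                        ci_upper = m, p = if (abs(m) < 1e-12) 1 else 0,
                        n_pairs = length(common), n_dropped = n_dropped))
    }
    tt <- stats::t.test(vb, va, paired = TRUE)
    data.frame(scenario = s, mean_diff = unname(tt$estimate),
               ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
               p = tt$p.value, n_pairs = length(common),
               n_dropped = n_dropped)
  })
  paired <- do.call(rbind, paired)
  paired$p_adj <- stats::p.adjust(paired$p, method = "bonferroni")
  structure(list(anova = fit, hsd = hsd, paired = paired,
                 reference = reference),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("Scenario comparison vs '", x$reference, "'\n", sep = "")
  cat("ANOVA p =",
      format.pval(summary(x$anova)[[1]][["Pr(>F)"]][1], digits = 3), "\n")
  cat("\nTukey HSD contrasts (other - reference):\n")
  print(x$hsd, digits = 3, row.names = FALSE)
  cat("\nPaired t-tests (seed-matched, Bonferroni):\n")
  print(x$paired, digits = 3, row.names = FALSE)
  invisible(x)
}
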