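---
title: "Simulating diversification under climatic-niche evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating diversification under climatic-niche evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichesim)
```

## The model

`nichesim` is a spatially explicit eco-evolutionary simulator. A simulated
species is a set of occupied cells on a global icosahedral grid together
with a climatic-niche envelope: closed tolerance intervals
`[lower, upper]` on three variables — mean monthly maximum temperature
(TMAX, °C), mean monthly minimum temperature (TMIN, °C) and mean monthly
maximum precipitation (PRCP, mm/d). A cell is suitable iff all three
values fall inside the species' envelopes. Time advances in 100-year
steps over (by default) 120 kyr of changing climate, and each step applies,
in fixed order:

1. **Range loss.** Occupied cells whose new climate falls outside the
   envelope are vacated.
2. **Dispersal and colonization.** Every occupied cell draws a reach
   `d` from the species' dispersal kernel; all land cells within `d`
   adjacency hops are tested, and every suitable one is occupied
   immediately. Dispersal is jump dispersal: unsuitable or sea cells in
   between do not block, so remote patches can be colonized without being
   connected.
3. **Extinction.** A species whose occupied set is now empty — it lost
   all suitable habitat and failed to colonize any — is extinct.
4. **Niche evolution.** The envelope is updated under one of ten
   scenarios (below).
5. **Population tracking.** The occupied set is partitioned into
   connected components under grid adjacency (populations). Components are
   matched to the previous step's components by maximal cell overlap, and
   each carries an isolation clock.
6. **Allopatric speciation.** When a population has remained isolated
   for the minimum isolation time (100 steps = 10 kyr by default), the
   species is replaced by its current components, each becoming a daughter
   species with a copy of the parent's envelope, a fresh clock and its own
   random stream. The phylogeny gains one (possibly multifurcating) node.

The order matters and is fixed: extinction is only declared after the
species had its chance to colonize within the same step, and the
range-level climate change used for niche evolution is measured on the
updated range (the current cells, compared with the same cells one step
earlier, unweighted means).

### Isolation clocks and the speciation trigger

A clock belongs to a population component and counts consecutive steps
the component spent as one of two or more mutually isolated components.
Both fragments of a first split therefore start at 0 and reach the
threshold together, 100 steps after the split; a component that merges
with another (reconnection) or newly appears resets to 0; a lone
component is the whole species and carries no isolation. Speciation fires
as soon as *any* component's clock reaches the threshold, and all current
components become daughters, so no occupied cell is ever silently
dropped. We chose the any-component trigger (over requiring every
component to be old) because isolation of one population for the full
threshold is the biological criterion for allopatric speciation; making a
single young splinter veto the event would, perversely, suppress
speciation in exactly the high-fragmentation regimes that are supposed to
produce it.

### The ten niche-evolution scenarios

The temperature and precipitation axes evolve independently; the
temperature-axis delta is applied to the TMAX and TMIN envelopes alike
(it is computed from TMAX). With `dV` the mean change across the range
between consecutive steps and `x` the adaptive rate (0.1 or 0.5):

| scenario id | rule per axis |
|---|---|
| `conservatism` | no change, ever |
| `dir-shift-10/50` | both limits `+= x·dV` (breadth fixed) |
| `dir-expand-10/50` | `dV > 0`: upper `+= x·dV`; `dV < 0`: lower `+= x·dV` |
| `omni-expand-10/50` | upper `+= x·|dV|`, lower `-= x·|dV|` |
| `rand-shift` | both limits `+= Δcentre` |
| `rand-expand-reduce` | lower `+= Δedge`, upper `-= Δedge` |
| `rand-change-shift` | upper `+= Δcentre + Δedge`, lower `+= Δcentre − Δedge` |

`Δcentre` and `Δedge` are redrawn each step, per axis, from
`Uniform(−NB0, NB0) × 0.01`, where NB0 is the species' *initial* niche
breadth on that axis — fixed at the start, inherited unchanged by
daughters. Under random reduction an envelope may invert
(upper < lower); we deliberately do not clamp it: an inverted envelope
admits no cell, which is a legitimate extinction pathway. Note the sign
conventions of `rand-expand-reduce` and `rand-change-shift` differ (a
positive `Δedge` contracts the former and expands the latter); both
follow their stated update rules literally.

Initial breadths are the full tolerance ranges: narrow = 40 °C
(temperature) and 5 mm/d (precipitation); broad = 60 °C and 10 mm/d,
centred on the seed cell's climate at the first time slice.

### Dispersal

Two levels: poor dispersers reach at most 2 cells per step, good
dispersers 4 (about 200 and 400 km at the ~99-km spacing of a
resolution-8 grid). Reach probabilities decay exponentially,
`p(d) ∝ exp(−λ d)` over `d = 1..max` with `λ = log 2` by default;
tabulated kernels can be supplied verbatim. One reach draw is made per
occupied cell per step. Reaches are hops on the adjacency graph, not
kilometres.

### Randomness

Each species draws from its own counter-based substream (splitmix64,
keyed by run seed and species id), so per-run results are independent of
iteration order and any species' draw sequence can be replayed in
isolation. All R-level randomness (seed sampling, synthetic climate,
bootstrap) goes through `set.seed`. A run is a pure function of its
configuration and seed.

## The grid

`build_grid(r)` tessellates the sphere into `10·3^r + 2` cells (aperture-3
icosahedral series): recursive subdivision inserts projected face
centroids and re-triangulates, and cells are the spherical Voronoi regions
of the vertices — 12 pentagons at the icosahedron vertices, hexagons
elsewhere. After each subdivision the vertices are spring-relaxed to
equalize edge lengths (the technique used for icosahedral climate-model
grids), with a fixed gain, target-length factor and displacement
tolerance, so construction is deterministic. At resolution 8 the grid has
65,612 cells of mean area ~7,774 km² (the sphere's area divided exactly,
since Voronoi areas partition it); neighbour spacings vary by less than a
factor of 1.3 and areas by about 1.27. We do not reproduce any particular
DGGS library's cell indexing or the exact equal-area (ISEA) projection —
the model only needs near-equal areas and spacings, plus a deterministic,
exportable indexing.

Graph distances (hops), not kilometres, define dispersal; the two agree
to within the spacing ratio. `neighbors_within()` and the engine's
component search both operate on the adjacency structure; tests verify
both against independent BFS and igraph oracles.

## Climate

`climate_series` objects hold per-cell, per-slice values of the three
variables; slice 1 is the oldest time (120 ka by default) and the last
slice is the present. Two standard transformations are provided:

* `anomaly_combine()` — the anomaly (delta) method: temperature output is
  the observed modern climatology plus the model's change relative to its
  own present; precipitation is the climatology times the model's ratio.
  When the model's present-day precipitation is below 0.01 mm/d the ratio
  is taken as 1; dividing by a near-zero reference would otherwise explode
  arid cells.
* `interpolate_timesteps()` — linear refinement of a coarse (possibly
  irregular) years-BP axis to a regular step; a 120-kyr span at 100-year
  steps yields exactly 1,201 slices, knots preserved exactly. Spans not
  divisible by the target step are rejected rather than silently
  truncated.

## The synthetic world

`synthetic_world()` builds the package's standard test conditions when the
deposited paleoclimate data are not at hand. Its components, and what they
emulate:

* **Compact continents.** Land is one (or more) spherical-cap landmass
  with a noise-modulated coast, covering ~35% of the sphere. Compactness
  is deliberate: at desk-scale resolutions (resolution 4, ~870-km
  spacing), ragged coastlines and satellite islets sit within jump-reach
  of the mainland and act as *permanent vicariance traps* — every lineage
  that straddles the gap re-fragments forever, and exponential
  "speciation pumps" dominate all scenario contrasts. Real continents at
  ~100-km resolution are, relatively, far better connected.
* **Smooth orography.** Static temperature and precipitation anomaly
  fields, smoothed over several cells (sd 5 °C and 2 mm/d). Paleoclimate
  fields at this resolution are typically interpolated down from ~2.5°
  atmospheric models, so their spatial structure is smooth at the cell
  scale; rough cell-scale fields again create pocket-scale traps.
* **A glacial sawtooth.** Slow cooling from an interglacial start to a
  glacial maximum at 21 ka, rapid deglacial warming to 11 ka, then a
  stable interglacial — the shape of the late-Pleistocene record, with
  equatorial amplitude 6 °C growing toward the poles (polar
  amplification) and 2 mm/d of glacial drying. Species are seeded under
  interglacial conditions, so the record ends near where it began.
* **Millennial, spatially coherent variability.** AR(1) anomalies with
  0.995 persistence per century step (decorrelation over millennia) and
  near-continental spatial coherence, sd 2.5 °C — the desk-scale analogue
  of Dansgaard–Oeschger-style variability. Coherent variability matters:
  it does not average out over a species' range, so expansion scenarios
  accumulate breadth (total-variation ratchet) and become cosmopolitan
  and inert at full scale, while fixed envelopes keep an active swept
  edge.

What the synthetic world does *not* emulate: real continental
configurations and their latitudinal asymmetries, orbital-scale spectral
structure, regional monsoon dynamics, and the empirical relationship
between the three climate variables. Passing the direction tests on this
world shows the mechanisms rank the scenarios as under full-scale
conditions; it does not reproduce full-scale magnitudes, which require
real 120-kyr transient paleoclimate fields and cluster-scale replication.

## Analyses

* `windowed_rates()` computes per-capita speciation, extinction and net
  diversification in fixed 1-kyr windows over the last 10 kyr of a run
  (speciation needs time to initiate, so earlier windows are excluded by
  default). The per-capita denominator is lineage-time: extant count
  summed over the window's steps times 0.1 kyr. Windows with zero
  lineage-time give `NA`, not 0. Speciation events count once per event
  regardless of daughter count.
* `latitudinal_gradient()` overlays bootstrap samples of per-seed
  descendant ranges (10 seeds per 5° seed band, 100 replicates by
  default) and reports mean richness per 5° cell band with percentile 95%
  intervals.
* `compare_scenarios()` runs the one-way ANOVA + Tukey HSD contrasts
  against conservatism, and seed-matched paired t-tests on complete
  blocks, Bonferroni-corrected across contrasts. The HSD controls the
  family-wise error within one ANOVA family; when families (breadth ×
  dispersal) are analysed separately, a Bonferroni correction across
  families is the caller's responsibility, as no procedure was prescribed.
* `fragmentation_series()` and `range_size_summary()` expose per-step
  population counts and final range areas.

## Numerical and policy choices

* Suitability intervals are closed; boundary values are suitable.
* Runs abort, flagged, when cumulative species exceed `max_species`
  (default 10,000): the desk-scale stand-in for removing run-away
  simulations by wall-clock or memory. Experiment analyses drop every
  seed with an aborted run (at full scale this removes on the order of 130 of
  1,000 seeds).
* Daughters inherit the parent envelope exactly and evolve independently
  afterwards; NB0 is never re-derived.
* The interpolation, anomaly and rate computations are exact arithmetic;
  the only tolerances in the package are test tolerances.

## Problem sizes used by the test-suite and acceptance runs

The structural checks build grids up to resolution 8 (65,612 cells). The
oracle-equivalence checks replay 200-step runs on a resolution-3 world.
The scenario-contrast experiment runs 50 seeds × 2 breadths × 2 dispersal
levels × 7 scenarios (conservatism, the three 50%-rate adaptive scenarios
and the three random scenarios) for 1,200 steps on a resolution-4
synthetic world with a 4,000-species cap — 1,400 runs, chosen so a full
replication completes in minutes on one core while leaving the
direction tests with ~30–40 usable seeds after runaway removal. At this
scale the extinction contrasts (random > conservatism) and the net
ordering against the shift and omnidirectional scenarios are robust
across worlds; the random-speciation and directional-expansion contrasts
are marginal and can flip with the world seed, which the acceptance
outputs expose rather than hide.
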