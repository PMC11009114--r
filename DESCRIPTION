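Package: nichesim
Title: Spatially Explicit Eco-Evolutionary Simulation of Climatic Niche
    Evolution and Diversification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatially explicit, cellular-automaton style simulator of
    speciation and extinction on an icosahedral global grid. Simulated
    species carry climatic-niche envelopes for temperature and
    precipitation, disperse stochastically over near-equal-area hexagonal
    cells, speciate allopatrically when their ranges stay fragmented for a
    fixed isolation time, and go extinct when all suitable occupied cells
    vanish. Ten niche-evolution scenarios (conservatism, directional and
    omnidirectional adaptive change at two rates, and three random-change
    modes) control how envelopes move each 100-year time step. Includes a
    geodesic grid builder, paleoclimate utilities (anomaly method, linear
    time interpolation, synthetic glacial-interglacial generator), a
    compiled simulation engine with full phylogeny and event bookkeeping,
    and downstream analyses: windowed per-capita diversification rates,
    latitudinal diversity gradients with bootstrap confidence intervals,
    population-fragmentation series and cross-scenario statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    igraph,
    geosphere,
    optparse
Config/testthat/edition: 3
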