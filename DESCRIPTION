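Package: chemforage
Title: Two-Substrate Chemotactic Foraging Simulation with Information Metrics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Agent-based simulation of a population of motile cells foraging
    for two essential substrates on a one-dimensional periodic lattice. Cells
    sense local concentrations through noisy receptor binding (binomial, or
    Gaussian with a tunable noise factor), move by comparing bound-receptor
    counts on their two ends, absorb resources, re-apportion a fixed receptor
    budget between the two substrate types (equal or adaptive strategies),
    divide above a resource threshold and die when a store is exhausted.
    Includes plug-in (histogram) estimators of entropy, conditional entropy
    and mutual information over the sensing channels, the population growth
    rate, and a subjective-information statistic (the time-averaged
    across-population spread of per-cell channel information), together with
    scripted parameter sweeps over cell stress and sensing noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
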