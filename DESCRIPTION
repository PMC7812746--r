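Package: ctcoh
Title: Cortico-Thalamo-Cerebellar Loop Simulation and LFP Coherence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how cerebellar output shapes coherence
    between sensorimotor cortical areas. Provides a laminar firing-rate
    model of the cortico-thalamo-cerebellar loop (trigeminal nuclei,
    thalamic relays, zona incerta, Purkinje cells and cerebellar nuclei,
    plus layered S1 and M1 modules), a surrogate generator for
    multichannel LFP-like trials with known spectral coupling and
    behavioral links, and an analysis pipeline covering event-related
    averaging with Z-scoring, current source density, Morlet
    time-frequency decomposition, trial coherence with
    frequency-dependent windows, line-noise normalization,
    difference-of-coherence testing, spectral Granger causality
    (parametric and nonparametric), and a coherence-based linear
    predictor of whisker protraction amplitude.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
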