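Package: laminarpac
Title: Laminar Neural Mass Modelling and Information-Theoretic
    Cross-Frequency Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a cortical column as a network of coupled neural mass
    oscillators (14 neuronal populations across layers 2/3, 4, 5 and 6, each a
    damped second-order system with sigmoidal rate coupling) driven by random
    external input, and analyses the simulated postsynaptic potentials with an
    information-theoretic cross-frequency coupling framework: band-pass
    filtering and Hilbert decomposition into instantaneous amplitude and phase,
    modulation index and envelope-to-signal correlation, conditional mutual
    information and conditional transfer entropy between phases, amplitudes
    and instantaneous frequencies (PAC, APC, AAC, PPC, PFC and same-frequency
    coupling), circular-shift surrogate significance testing with false
    discovery rate correction, an exact decomposition of indirect couplings
    into cascades of direct couplings, and local weighted-digraph topology
    measures (clustering, efficiency, betweenness) relating anatomical
    structure to effective coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
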