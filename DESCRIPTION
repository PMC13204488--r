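Package: fbnlsm
Title: Brain-Network-Constrained Spiking Reservoirs for Spoken-Digit Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds liquid state machines whose reservoir wiring is constrained
    by functional brain networks inferred from regional BOLD time series.
    Provides Pearson-correlation graph construction with density thresholding,
    Watts-Strogatz and Barabasi-Albert comparison topologies with small-world
    and scale-free characterization, a sparse spike encoder for speech based on
    enhanced MFCC features (static + delta + delta-delta), dynamic time warping
    alignment, layer normalization and Sigma-Delta modulation, a leaky
    integrate-and-fire reservoir with receptor-kinetics synapses, spike-timing
    dependent plasticity and Poisson-distributed conduction delays, a ReSuMe
    (remote supervised method) readout trained on van Rossum spike-train
    distances, firing-pattern separability analysis by one-way ANOVA, weighted
    clustering and shortest-path metrics, and generators for synthetic modular
    BOLD series and class-distinct formant utterances so the whole pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
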