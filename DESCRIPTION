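Package: gammalink
Title: Delay-Coupled Spiking Populations, Gamma Coherence and Information Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two bidirectionally delay-coupled conductance-based
    excitatory-inhibitory neuronal populations, computes local field potential
    (LFP) and multi-unit activity (MUA) observables, quantifies frequency-resolved
    phase coherence and inter-population time shifts as a function of the
    inter-areal conduction delay, and measures stimulus information carried by
    the receiver population's LFP/MUA power spectra using bias-corrected mutual
    information with equipopulated binning and a bootstrap null. Includes
    surrogate-signal generators with analytically known coherence and
    information content for validating the estimators, and an experiment
    harness for delay and stimulus sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    jsonlite,
    yaml,
    signal
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
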