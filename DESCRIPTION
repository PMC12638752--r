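Package: ratstates
Title: EEG Microstate Analysis for Rodent Multichannel Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extraction and characterisation of quasi-stable topographic
    microstates from multichannel rodent EEG. Implements global field power
    (GFP) peak detection, atomize-and-agglomerate hierarchical clustering
    (AAHC) of peak topographies, backfitting of template maps, the classical
    microstate parameters (coverage, occurrence, duration, per-class GFP,
    global explained variance) and occurrence-based expected transition
    matrices; cluster-number selection by Krzanowski-Lai, cross-validation,
    Davies-Bouldin, Dunn, Frey-Van Groenewoud, dispersion and a metacriterion;
    validation against temporally shuffled surrogate recordings; and
    association of microstate time courses with frequency-specific
    band-limited power of source-space signals through a linear model with
    group-level sign-flip permutation testing and threshold-free cluster
    enhancement (TFCE). A synthetic-data module generates recordings, montages
    and source scenes with known ground truth so the whole pipeline is
    testable without animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
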