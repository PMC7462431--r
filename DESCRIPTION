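Package: connsmooth
Title: Structural-Connectome Graph Smoothing of Source-Space EEG
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Smooths source-projected EEG region-of-interest time courses on
    graphs derived from the white-matter structural connectome (one-hop
    low-pass graph filtering) and provides the full validation machinery
    around the operator: power-envelope, coherence and imaginary-coherence
    functional connectivity; search information on weighted connectomes;
    distance-binned group-consensus structural connectomes and
    degree-preserving null graphs; stepwise structure-function regression
    with distance-matched connected-versus-unconnected comparisons;
    fit-versus-reference curves with white-noise controls; and repeated
    Louvain co-assignment community analysis. A synthetic cohort generator
    emulates distance-dependent structural connectivity, SC-coupled
    band-limited sources and instantaneous volume-conduction leakage so the
    whole pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
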