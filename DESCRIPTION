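Package: ranvier
Title: Node of Ranvier Geometry and Myelinated-Axon Conduction Speed
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the geometry of the node of Ranvier
    tunes action potential conduction speed in myelinated central axons.
    Implements a double-cable compartmental model (axonal membrane plus
    periaxonal space under the myelin) with Hodgkin-Huxley-type nodal
    channels (fast and persistent Na+, slow K+), presets for rat optic
    nerve and cortical grey matter axons, in-silico experiments sweeping
    node length, internode length and myelin wrap number under
    constant-channel-density or constant-channel-number assumptions, a
    half-maximum intensity morphometry routine for measuring node length
    from confocal line profiles, and a synthetic-data generator producing
    axon populations and confocal-like line profiles with realistic
    statistical structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
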