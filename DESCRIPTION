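Package: mirsite
Title: Seed-Agnostic MicroRNA Target Site Prediction from Duplex Energy
    Profiles and Boosted Decision Stumps
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts microRNA target sites in 3'UTR sequences without
    requiring a seed match or evolutionary conservation.  Candidate zones
    are discovered by scanning a per-position anchored intermolecular
    duplex free-energy profile computed with a bundled nearest-neighbor
    parameter table; each zone's representative duplex is described by a
    catalogue of pairing, bulge, positional and compositional features
    (including a compactness measure) and scored by a MultiBoost committee
    of decision stumps with false-positive-rate calibrated score
    thresholds.  Seed and conserved-seed post-filters derive the stricter
    prediction classes, and seeded synthetic-data generators emulate every
    input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    Rcpp,
    jsonlite,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
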