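Package: dmcbench
Title: Benchmarking Fungal ITS Metabarcoding Classification with Defined Mock Communities
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates defined mock communities (DMCs) of fungal ITS1/ITS2
    amplicons together with reference databases of known completeness, turns
    paired reads into OTUs (quality trimming, pair merging, marker extraction,
    dereplication, pre-clustering, de novo chimera removal, OptiClust-style
    clustering at 0.03, rare-OTU filtering), classifies OTU representatives
    with a top-hit alignment search, a naive-Bayes bootstrap classifier and a
    nearest-neighbour classifier, and scores classifications against the known
    community composition using strict, loose and two-marker consensus
    adjudication, synonym and subgeneric-rank handling, per-community
    precision/recall/F1, L1 abundance distances, and abundance-filter
    threshold sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
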