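Package: homologyGO
Title: Homology-Based Gene Ontology Prediction from Sequence Search Hits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transfers Gene Ontology (GO) annotations from sequence-search
    hits to query proteins. Parses OBO ontologies, GAF annotation files and
    BLAST/DIAMOND/MMseqs2-style tabular hit files; scores candidate GO terms
    with eleven template-weighting functions, including a bit-score times
    sequence-identity weight; evaluates predictions with the CAFA Fmax and
    information-accretion-weighted wFmax metrics; builds time-elapsed
    benchmarks from two annotation releases; and generates deterministic
    synthetic ontologies, annotation databases and hit tables with
    controllable planted signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
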