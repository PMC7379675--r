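Package: dsbkit
Title: Monte Carlo Quantification of DNA Double-Strand Breaks on PDB Geometries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores radiation-induced single- and double-strand breaks on
    DNA geometries read from Protein Data Bank files or generated as ideal
    B-DNA duplexes. Stochastic energy-deposition events from spectrum-driven,
    isotropically incident electrons are mapped onto sugar-phosphate backbone
    groups; strand breaks are called at a configurable energy threshold (ET)
    and paired into double-strand breaks at a base-pair distance threshold
    (BPT). Includes absolute-dose calibration of primary counts,
    seed-replicated exposure series with binomial statistics, full ET x BPT
    threshold scans, quadratic dose-response fitting, and comparison against
    experimental DNA-dosimeter measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
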