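Package: coidiv
Title: COI Barcode Diversity Assessment, Validation and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing molecular diversity in cytochrome c oxidase
    subunit 1 (COI) DNA-barcode data sets. Implements Kimura 2-parameter
    distances with pairwise deletion, neighbor-joining trees with per-species
    monophyly assessment, taxonomic-rank partitioning of pairwise divergences,
    2%-threshold MOTU clustering, quality control and nuclear-pseudogene
    (numt) screening under the invertebrate mitochondrial code, raw versus
    taxon-weighted sampling-bias diagnostics, GC content analysis by codon
    position, and a hierarchical codon-aware sequence simulator with injected
    taxonomic anomalies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
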