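Package: sortscape
Title: Affinity and Epistasis Landscapes from Sort-Seq Deep Mutational Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sort-seq deep mutational scanning of a
    protein-protein binding interface, modelled on the BPTI-chymotrypsin
    system. Translates and filters sorted-gate sequencing reads, computes
    per-variant enrichment ratios against the pre-sort library, trains
    per-gate ensembles of feed-forward neural regressors on one-hot plus
    embedding features, calibrates predicted log2 enrichment ratios to
    binding free-energy changes with a linear model, and assembles the
    complete single/double-mutant affinity and epistasis landscape with
    ensemble-based uncertainty. Includes a synthetic sort-seq generator
    with a planted affinity landscape so that every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
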