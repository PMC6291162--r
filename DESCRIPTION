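Package: ralascope
Title: De Novo Burden, Binding-Region Clustering and Functional Assay
    Analysis for RALA and Related Small GTPases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical and structural analysis pipeline for evaluating a
    candidate disease gene from trio sequencing cohorts, built around the small
    GTPase RALA. Provides HGVS-lite protein-change parsing and cohort tables
    with monozygotic-twin collapsing; annotation of the GTP/GDP-binding region
    of a protein from a ligand-bound structure by a distance rule; exact
    binomial and Poisson upper-tail tests of de novo mutation burden against a
    per-chromosome mutation-rate null; Fisher exact tests of regional missense
    depletion in population databases; codon-level recurrence summaries;
    residue mapping onto paralogous GTPases by global alignment; normalization
    and group comparison of GTPase-activity and effector-binding plate assays;
    and seeded synthetic-data generators for every input so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
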