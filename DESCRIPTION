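Package: microcensus
Title: Quantifying Rare Ultrasmall Microbes in Size-Fractionated Soil Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for characterizing rare ultrasmall microbes (Candidate
    Phyla Radiation bacteria and DPANN archaea) in paired bulk and 0.2-micron
    size-fraction ("concentrate") soil metagenomes. Computes per-scaffold depth,
    breadth-of-coverage and relative-abundance profiles; concentrate-over-bulk
    enrichment factors with explicit detection-limit handling; an absolute
    cells-per-gram census under parameterized models; single-copy-gene
    completeness and contamination scoring with bin-retention filtering;
    metabolic marker and pathway-completeness profiles; in-silico amplicon
    primer detectability with IUPAC degeneracy and mismatch tolerance; and
    gene-order synteny classification of cytochrome ubiquinol oxidase (cyo)
    operons against a reference. A synthetic-community simulator with Poisson
    (Lander-Waterman) coverage, planted enrichment, planted primer-site
    mutations and planted operon layouts provides ground truth so every stage
    is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
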