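Package: erscan
Title: Selection Scans for Evolve-and-Resequence Pool-Seq Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterizes alleles under selection in replicated
    evolve-and-resequence (E&R) experiments sequenced as pools (Pool-Seq).
    Reads PoPoolation2-style sync allele counts, applies repeat/indel/region
    masks, calls biallelic SNPs with replication and coverage filters, scans
    for consistent allele-frequency change with a Cochran-Mantel-Haenszel
    test, calibrates significance against a coverage-matched Wright-Fisher
    drift null with an empirical false discovery rate, estimates temporal
    effective population size, classifies selected-allele trajectories
    (continuous versus plateauing), and tests genomic-feature and Gene
    Ontology enrichment with a SNP-permutation procedure that corrects for
    gene length. A synthetic experiment generator with ground-truth tables
    makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    methods,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
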