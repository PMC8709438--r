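Package: bacmeth
Title: Bacterial Methylome Motif Analysis for Multi-Replicon Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for nanopore-derived bacterial DNA
    methylation (6mA/4mC/5mC) in multi-replicon genomes such as Rhizobium
    leguminosarum. Scans degenerate IUPAC methylation motifs on both
    strands, aggregates per-site modified-base calls into genome-wide,
    sliding-window and per-motif methylation summaries across conditions
    (free-living culture versus nitrogen-fixing bacteroids), intersects
    motifs with gene promoter regions and tests COG-category enrichment
    (hypergeometric test with FDR control), and estimates relative
    replicon copy number from read coverage. Includes a synthetic-data
    generator with a packaged profile emulating the RCAM1026 study
    conditions so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
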