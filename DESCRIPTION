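Package: cdspirna
Title: Discovery and Characterization of CDS-piRNAs in Testis Small RNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for discovering and characterizing
    piRNAs derived from endogenous protein-coding sequences (CDS-piRNAs) in
    Drosophila testis small-RNA sequencing data. Implements hierarchical read
    classification (non-piRNA, piRNA cluster, transposon, genic), the piRNA
    host-gene screen (small-RNA/mRNA enrichment, size profile, 5' nucleotide
    bias, immunoprecipitation enrichment, region density, strand and junction
    metrics), 5'-to-5' 10-nt complementary-overlap pairing between trigger and
    responder small RNAs, phasing signatures, mutant fold-change comparison,
    degradome cleavage-site pairing, and proximity-labeling spectral-count
    enrichment. A synthetic-data generator with planted ground truth makes
    every stage testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
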