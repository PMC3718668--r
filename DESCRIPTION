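Package: mspjiseq
Title: In Silico MspJI Digestion and Methylation-Dependent Enrichment
    Sequencing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models methylation-dependent restriction digestion by MspJI,
    which recognizes 5-methylcytosine in the mCNNR context (R = A or G) and
    cuts 12 and 16 nucleotides 3' of the methylated base, leaving a
    four-base 5' overhang. Provides IUPAC degenerate-motif scanning of
    genomes on both strands, classification of CG/CHG/CHH methylation
    contexts and of the seven symmetric two-way cleavage categories, a
    cleavage-scenario engine that digests a genome under a methylation
    state and size-selects fragments, a census of recoverable cytosines,
    FASTQ quality filtering and adapter trimming, attribution of mapped
    insert fragments to methylated CNNR loci via the cut-model geometry,
    per-site and per-region methylation quantification, and assessment
    statistics (binomial bisulfite-style calls, specificity and sensitivity
    against peak regions, replicate correlation, metagene profiles). A
    seeded synthetic-data generator produces genomes, methylomes, reads
    and bisulfite-like site counts with known ground truth so that every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Rsamtools,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
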