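Package: occupeak
Title: Differential ChIP-Seq Occupancy, Chromatin-State Enrichment and
    Peak-to-Gene Linkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares the genomic occupancy of two chromatin-bound factors
    from ChIP-seq peak sets and matched signal tracks. Peaks are classified
    as unique to one factor or common to both with a windowed conditional
    binomial count-ratio test; peak sets are annotated against a
    seven-category functional model of the genome (promoter, TTS, UTRs,
    exon, intron, intergenic) and a 15-state chromatin segmentation, with
    one-sided binomial enrichment tests and a product-of-binomials
    cross-set comparison; IUPAC-degenerate motifs (e.g. the TPA-response
    element TGASTCA) are scanned and associated with peak subsets by
    hypergeometric tests; peaks are linked to gene lists with a
    Monte-Carlo random-peak null. A fully seeded synthetic-data generator
    produces genomes, gene models, segmentations, peak sets and signal
    tracks with planted ground truth so every stage can be exercised and
    scored without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
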