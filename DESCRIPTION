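Package: srnascout
Title: Discovery and Classification of Bacterial Small RNAs from
    Strand-Specific RNA-Seq
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A genome-wide small-RNA (sRNA) discovery pipeline for bacteria.
    Builds strand-specific coverage tracks from read alignments, calls
    transcription units with a seed-and-extend coverage rule, determines
    distinct 5'- and 3'-ends and labels transcription start sites as primary
    or processed by comparing a primary-transcript-enriched and a
    processed-transcript-enriched library (dRNA-seq), classifies candidates
    positionally against the annotation (trans-encoded, cis-antisense, mRNA
    leader, sense, ORF-covering), scans upstream of primary 5'-ends with a
    two-box sigma-70 promoter PSSM with exact score P-values, quantifies
    structure well-definedness with abstract-shape probability Z-scores
    against genome-window backgrounds, screens candidates for small ORFs and
    ribosome-binding sites, and applies two-channel (M/A) and tiling-chip
    hybridization candidate filters. A seeded synthetic-data module generates
    genomes, annotations, planted transcripts of every class, and reads with
    the primary/processed end structure, so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
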