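Package: polyamp
Title: CRISPR Editing Outcomes at Polyploid Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes CRISPR/Cas9 editing outcomes at highly heterozygous
    loci of polyploid genomes from paired-end amplicon sequencing. Collapses
    read pairs by overlap, trims fixed flanks, clusters identical sequences,
    calls allelic variants at a prevalence threshold, assigns each variant to a
    reference allele through diagnostic SNP fingerprints computed outside the
    CRISPR target windows (with rescue of PCR-dropout alleles), classifies
    per-site edits including dual-guide deletions, and predicts protein
    consequences (frameshifts, premature termination codons, in-frame
    insertions and deletions) through an exon/intron gene model. Also provides
    dual-sgRNA design checks (seed mismatches across alleles, PAM-to-PAM
    spacing, Hamming off-target scans), protein percent-identity computation,
    and a synthetic-data generator that emulates a five-allele octoploid locus
    with per-allele cleavage efficiency, PCR allele bias and Phred-scaled
    sequencing error, so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    S4Vectors,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    GenomicRanges,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
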