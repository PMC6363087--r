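#' @useDynLib polyamp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames rbinom runif
#' @importFrom utils write.table head
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Validate a nucleotide sequence set
#'
#' Checks the alphabet (A/C/G/T/N only), non-emptiness and id uniqueness of a
#' named character vector of sequences.
#'
#' @param seqs named character vector of upper-case nucleotide sequences.
#' @param what label used in error messages.
#' @return `seqs`, invisibly, after validation.
#' @keywords internal
validate_nucseqs <- function(seqs, what = "sequence") {
  if (length(seqs) == 0) return(invisible(seqs))
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop(what, ": every record needs a non-empty id")
  if (anyDuplicated(names(seqs)))
    stop(what, ": duplicate id '", names(seqs)[duplicated(names(seqs))][1], "'")
  if (any(nchar(seqs) == 0)) stop(what, ": empty sequence not allowed")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    sym <- regmatches(seqs[bad][1], regexpr("[^ACGTN]", seqs[bad][1]))
    stop(what, ": invalid symbol '", sym, "' in record '", names(seqs)[bad][1], "'")
  }
  invisible(seqs)
}

#' Read a FASTA file
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return named character vector of sequences, upper-cased and validated
#'   against the A/C/G/T/N alphabet.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  validate_nucseqs(seqs, what = basename(path))
  seqs
}

#' Write sequences as single-line FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(seqs))
    writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con, sep = "\n")
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Quality strings are decoded at ASCII offset 33 (Sanger / Illumina 1.8
#' convention). Scores outside 0..60 are rejected rather than re-interpreted,
#' so offset-64 files fail validation instead of being silently mis-decoded.
#'
#' @param path path to a FASTQ file.
#' @return a `fastq_reads` data frame with columns `id`, `seq`, `qual`
#'   (quality kept as the raw Phred+33 string; see [qual_ints()]).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ '", path, "': ", conditionMessage(e))
  )
  seqs <- toupper(as.character(x))
  ids <- sub("\\s.*$", "", names(x))
  quals <- as.character(S4Vectors::mcols(x)$qualities)
  out <- fastq_reads(ids, seqs, quals)
  out
}

#' Construct a validated set of quality-scaled reads
#'
#' @param id,seq,qual parallel character vectors (qual is the Phred+33 string).
#' @return data frame of class `fastq_reads`.
#' @export
fastq_reads <- function(id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  df <- data.frame(id = as.character(id), seq = as.character(seq),
                   qual = as.character(qual), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(nchar(df$seq) != nchar(df$qual)))
      stop("sequence/quality length mismatch at record ",
           which(nchar(df$seq) != nchar(df$qual))[1])
    seqs <- setNames(df$seq, make.unique(df$id))
    if (any(nchar(df$seq) == 0)) stop("empty read")
    bad <- grepl("[^ACGTN]", df$seq)
    if (any(bad)) {
      sym <- regmatches(df$seq[bad][1], regexpr("[^ACGTN]", df$seq[bad][1]))
      stop("invalid symbol '", sym, "' in read '", df$id[bad][1], "'")
    }
    allq <- utf8ToInt(paste(df$qual, collapse = "")) - 33L
    if (any(allq < 0L | allq > 60L))
      stop("Phred score out of range 0..60 at offset 33; ",
           "offset-64 encoded input is not supported")
  }
  class(df) <- c("fastq_reads", "data.frame")
  df
}

#' Decode one quality string to integer Phred scores
#' @param qual a Phred+33 quality string.
#' @return integer vector of scores.
#' @export
qual_ints <- function(qual) utf8ToInt(qual) - 33L

#' Write reads to FASTQ (Phred+33), 4 lines per record
#' @param reads a `fastq_reads` data frame.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

# ---- gene models ------------------------------------------------------------

#' Construct a gene model
#'
#' Exon intervals are 0-based half-open on the coordinates of the sequence the
#' model annotates. The CDS starts `cds_start_offset` bases into the first
#' exon and runs to the end of the last exon; translation downstream stops at
#' the first stop codon.
#'
#' @param exons integer matrix (or list of length-2 vectors) of `[start, end)`
#'   intervals, sorted, non-overlapping.
#' @param strand `"+"` or `"-"` (only `"+"` models are produced by the
#'   simulator; `"-"` is accepted for completeness).
#' @param cds_start_offset bases into the first exon where the CDS begins.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(exons, strand = "+", cds_start_offset = 0L) {
  if (is.list(exons)) exons <- do.call(rbind, lapply(exons, as.integer))
  exons <- matrix(as.integer(exons), ncol = 2)
  colnames(exons) <- c("start", "end")
  if (nrow(exons) < 1) stop("gene model needs at least one exon")
  if (any(exons[, 2] <= exons[, 1])) stop("empty or inverted exon interval")
  if (is.unsorted(exons[, 1], strictly = TRUE) && nrow(exons) > 1)
    stop("exons must be sorted by start")
  if (nrow(exons) > 1 && any(exons[-nrow(exons), 2] > exons[-1, 1]))
    stop("exon intervals overlap")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  cds_start_offset <- as.integer(cds_start_offset)
  spliced_len <- sum(exons[, 2] - exons[, 1])
  if (cds_start_offset < 0 || cds_start_offset >= spliced_len)
    stop("cds_start_offset outside spliced transcript")
  structure(list(exons = exons, strand = strand,
                 cds_start_offset = cds_start_offset),
            class = "gene_model")
}

#' Intron intervals of a gene model
#' @param gm a `gene_model`.
#' @return integer matrix of `[start, end)` intron intervals (0 rows if
#'   single-exon).
#' @export
introns <- function(gm) {
  ex <- gm$exons
  if (nrow(ex) < 2) return(matrix(integer(), ncol = 2,
                                  dimnames = list(NULL, c("start", "end"))))
  matrix(c(ex[-nrow(ex), 2], ex[-1, 1]), ncol = 2,
         dimnames = list(NULL, c("start", "end")))
}

#' Spliced transcript and CDS of an allele
#' @param seq allele sequence (character scalar).
#' @param gm its `gene_model`.
#' @return list with `transcript` and `cds` character scalars.
#' @export
spliced_seq <- function(seq, gm) {
  parts <- substring(seq, gm$exons[, 1] + 1L, gm$exons[, 2])
  tx <- paste(parts, collapse = "")
  list(transcript = tx, cds = substring(tx, gm$cds_start_offset + 1L))
}

#' Load a gene model from a GFF3 file
#'
#' Takes the `exon` features of the requested sequence id and converts them to
#' the package's 0-based half-open convention. The CDS start offset is derived
#' from the first `CDS` feature when present, else 0.
#'
#' @param path GFF3 file.
#' @param seqid sequence id whose exons to load.
#' @return a `gene_model`.
#' @export
gene_model_from_gff3 <- function(path, seqid) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 gene models requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == seqid]
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) stop("no exon features for '", seqid, "' in ", path)
  ex <- ex[order(GenomicRanges::start(ex))]
  exons <- cbind(GenomicRanges::start(ex) - 1L, GenomicRanges::end(ex))
  strand <- as.character(GenomicRanges::strand(ex))[1]
  if (strand == "*") strand <- "+"
  cds <- gr[gr$type == "CDS"]
  off <- 0L
  if (length(cds)) {
    cds_start <- min(GenomicRanges::start(cds)) - 1L
    off <- as.integer(cds_start - exons[1, 1])
    if (off < 0) off <- 0L
  }
  gene_model(exons, strand = strand, cds_start_offset = off)
}

# ---- guide specs and allele sets -------------------------------------------

#' Define an sgRNA
#'
#' @param name guide label.
#' @param protospacer the 20-nt protospacer, 5'->3' (PAM-distal first).
#' @param pam IUPAC PAM pattern (default `"NGG"` for SpCas9).
#' @param seed_len number of PAM-proximal protospacer bases treated as the
#'   seed (default 12).
#' @return object of class `guide_spec`.
#' @export
guide_spec <- function(name, protospacer, pam = "NGG", seed_len = 12L) {
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) != 20L) stop("protospacer must be 20 nt")
  if (grepl("[^ACGT]", protospacer)) stop("protospacer must be A/C/G/T")
  pam <- toupper(pam)
  if (grepl(sprintf("[^%s]", paste(names(IUPAC_SETS), collapse = "")), pam))
    stop("PAM pattern must be IUPAC")
  structure(list(name = name, protospacer = protospacer, pam = pam,
                 seed_len = as.integer(seed_len)), class = "guide_spec")
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Assemble the reference allele set of one locus
#'
#' The central container: the reference haplotypes of one locus in one
#' genotype, each with a gene model, plus the sgRNAs aimed at the locus.
#'
#' @param locus_id locus label.
#' @param alleles named character vector of allele sequences.
#' @param gene_models named list of [gene_model()]s, one per allele.
#' @param guides list of [guide_spec()]s.
#' @param anchor id of the allele used as alignment anchor (default: first).
#' @return object of class `allele_set`.
#' @export
allele_set <- function(locus_id, alleles, gene_models, guides = list(),
                       anchor = names(alleles)[1]) {
  validate_nucseqs(alleles, what = "allele")
  if (length(alleles) < 1) stop("need at least one allele")
  if (!setequal(names(gene_models), names(alleles)))
    stop("every allele needs a gene model (ids must match)")
  for (id in names(alleles)) {
    gm <- gene_models[[id]]
    if (!inherits(gm, "gene_model")) stop("gene_models[['", id, "']] is not a gene_model")
    if (max(gm$exons[, 2]) > nchar(alleles[[id]]))
      stop("exon interval outside allele '", id, "' length")
  }
  if (!anchor %in% names(alleles)) stop("anchor allele not in set")
  structure(list(locus_id = locus_id, alleles = alleles,
                 gene_models = gene_models[names(alleles)], guides = guides,
                 anchor = anchor),
            class = "allele_set")
}

#' @export
print.allele_set <- function(x, ...) {
  cat("<allele_set> locus", x$locus_id, "-", length(x$alleles), "allele(s),",
      length(x$guides), "guide(s)\n")
  for (id in names(x$alleles))
    cat(sprintf("  %-6s %5d nt, %d exon(s)\n", id, nchar(x$alleles[[id]]),
                nrow(x$gene_models[[id]]$exons)))
  invisible(x)
}

#' Load a locus specification from JSON
#'
#' The locus spec is a JSON document with fields `locus_id`, `alleles` (list
#' of objects with `id`, `seq` or `fasta`+`fasta_id`, and `gene_model` with
#' `exons` (0-based half-open pairs), `strand`, `cds_start_offset` — or
#' `gff3`+`seqid`), and `guides` (objects with `name`, `protospacer`, `pam`,
#' `seed_len`). Relative file references are resolved against the JSON file's
#' directory.
#'
#' @param path path to the JSON locus spec.
#' @return an [allele_set()].
#' @export
load_locus_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- jsonlite::read_json(path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  if (is.null(js$alleles) || !length(js$alleles)) stop("locus spec has no alleles")
  ids <- vapply(js$alleles, function(a) a$id %||% stop("allele without id"), "")
  if (anyDuplicated(ids)) stop("duplicate allele id '", ids[duplicated(ids)][1], "'")
  seqs <- character(0); gms <- list()
  for (a in js$alleles) {
    s <- if (!is.null(a$seq)) toupper(a$seq) else {
      fa <- read_fasta(resolve(a$fasta))
      fa[[a$fasta_id %||% a$id]]
    }
    if (is.null(s)) stop("no sequence for allele '", a$id, "'")
    seqs[[a$id]] <- s
    gms[[a$id]] <- if (!is.null(a$gene_model)) {
      g <- a$gene_model
      gene_model(lapply(g$exons, function(e) as.integer(unlist(e))),
                 strand = g$strand %||% "+",
                 cds_start_offset = g$cds_start_offset %||% 0L)
    } else if (!is.null(a$gff3)) {
      gene_model_from_gff3(resolve(a$gff3), a$seqid %||% a$id)
    } else stop("no gene model for allele '", a$id, "'")
  }
  guides <- lapply(js$guides %||% list(), function(g)
    guide_spec(g$name %||% "guide", g$protospacer, g$pam %||% "NGG",
               g$seed_len %||% 12L))
  allele_set(js$locus_id %||% "locus", seqs, gms, guides,
             anchor = js$anchor %||% ids[1])
}

#' Write a locus specification to JSON
#' @param aset an [allele_set()].
#' @param path output path.
#' @export
write_locus_spec <- function(aset, path) {
  js <- list(
    locus_id = aset$locus_id, anchor = aset$anchor,
    alleles = lapply(names(aset$alleles), function(id) {
      gm <- aset$gene_models[[id]]
      list(id = id, seq = unname(aset$alleles[[id]]),
           gene_model = list(
             exons = lapply(seq_len(nrow(gm$exons)),
                            function(i) as.integer(gm$exons[i, ])),
             strand = gm$strand, cds_start_offset = gm$cds_start_offset))
    }),
    guides = lapply(aset$guides, function(g)
      list(name = g$name, protospacer = g$protospacer, pam = g$pam,
           seed_len = g$seed_len)))
  jsonlite::write_json(js, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement
#' @param seq character vector of sequences.
#' @return reverse-complemented sequences.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
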