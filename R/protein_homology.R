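# Translation and pairwise protein percent identity (BLASTP-like scoring).

#' Translate a CDS with the standard genetic code
#'
#' Frame 0; translation stops at (and includes) the first stop codon,
#' rendered `*`. Codons containing N or other non-ACGT symbols translate to
#' `X`. A trailing partial codon is ignored with a warning.
#'
#' @param cds nucleotide sequence (length >= 3).
#' @param require_start if `TRUE`, error unless the first codon is ATG.
#' @param quiet suppress the partial-codon warning.
#' @return amino-acid sequence (character scalar), possibly ending in `*`.
#' @export
translate_cds <- function(cds, require_start = FALSE, quiet = FALSE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 3L) stop("CDS shorter than one codon")
  if (n %% 3L != 0L && !quiet)
    warning("trailing partial codon (", n %% 3L, " nt) ignored")
  codons <- substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  if (require_start && codons[1] != "ATG") stop("CDS does not start with ATG")
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1])]
  paste(aa, collapse = "")
}

#' Pairwise protein percent identity
#'
#' BLASTP-like scoring: BLOSUM62, gap open -11, gap extend -1. In local mode
#' the best-scoring local alignment is reported; in global mode the end-to-end
#' alignment. Percent identity is identical columns divided by aligned
#' columns (including gap columns of the reported span) times 100 — the
#' BLASTP convention; reported identities depend on this denominator.
#'
#' @param a,b amino-acid sequences (character scalars; terminal `*` is
#'   stripped before alignment).
#' @param mode `"local"` (default) or `"global"`.
#' @param gap_open,gap_extend gap penalties (negative).
#' @return list with `identity` (percent), `aligned_length`, `n_identical`,
#'   `score`, and the aligned strings `a_aln`, `b_aln`.
#' @export
pairwise_identity <- function(a, b, mode = c("local", "global"),
                              gap_open = -11, gap_extend = -1) {
  mode <- match.arg(mode)
  a <- sub("\\*+$", "", toupper(a))
  b <- sub("\\*+$", "", toupper(b))
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  # identity is a symmetric measure, but tie-broken tracebacks depend on the
  # argument order; canonicalize so identity(a, b) == identity(b, a) exactly
  swapped <- a > b
  if (swapped) { tmp <- a; a <- b; b <- tmp }
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a), subject = Biostrings::AAString(b),
    type = mode, substitutionMatrix = data_env$BLOSUM62,
    gapOpening = -gap_open, gapExtension = -gap_extend)
  pa <- as.character(Biostrings::alignedPattern(al))
  pb <- as.character(Biostrings::alignedSubject(al))
  if (swapped) { tmp <- pa; pa <- pb; pb <- tmp }
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(pb, "")[[1]]
  n_id <- sum(ca == cb & ca != "-")
  len <- length(ca)
  list(identity = 100 * n_id / len, aligned_length = len, n_identical = n_id,
       score = Biostrings::score(al), a_aln = pa, b_aln = pb)
}

#' Read a single protein sequence from FASTA
#' @param path FASTA file; the first record is returned.
#' @return amino-acid sequence (character scalar).
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readAAStringSet(path)
  if (length(x) == 0) stop("no sequences in ", path)
  toupper(as.character(x[[1]]))
}

#' Percent identity table for many sequence pairs
#'
#' @param queries,subjects named character vectors of protein sequences; all
#'   query x subject pairs are aligned.
#' @param mode `"local"` or `"global"`.
#' @return data frame: `query`, `subject`, `mode`, `identity`,
#'   `aligned_length`, `score`.
#' @export
identity_table <- function(queries, subjects, mode = "local") {
  rows <- list()
  for (q in names(queries)) for (s in names(subjects)) {
    r <- pairwise_identity(queries[[q]], subjects[[s]], mode = mode)
    rows[[paste(q, s)]] <- data.frame(
      query = q, subject = s, mode = mode, identity = r$identity,
      aligned_length = r$aligned_length, score = r$score,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
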