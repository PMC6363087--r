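# Global alignment of observed amplicon sequences to reference alleles and
# extraction of normalized (left-aligned) variants.

#' Alignment scoring parameters
#'
#' Affine-gap scoring chosen to favour one long deletion over scattered gaps,
#' matching dual-cut biology: a length-k gap costs `gap_open + k * gap_extend`.
#'
#' @param match,mismatch,gap_open,gap_extend scoring terms (penalties
#'   negative).
#' @return list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = -6,
                          gap_extend = -1) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_scoring")
}

#' Globally align a sequence to a reference and extract variants
#'
#' Optimal global alignment under affine-gap scoring (Needleman-Wunsch with
#' Gotoh gaps, via [Biostrings::pairwiseAlignment()]), followed by variant
#' extraction. Adjacent gap columns are fused into single indel events and
#' every indel is left-aligned: shifted to the lowest reference position that
#' produces an identical edited sequence, so placement inside homopolymers
#' and repeats is canonical regardless of traceback.
#'
#' @param seq observed sequence (character scalar).
#' @param ref reference sequence (character scalar).
#' @param scoring an [align_scoring()].
#' @return data frame of class `variant_table` with columns `pos` (0-based on
#'   `ref`), `ref`, `alt`, `type` (`substitution`/`insertion`/`deletion`).
#'   Attribute `score` carries the alignment score. Insertions have `ref = ""`
#'   and `pos` = reference position before which the bases are inserted;
#'   deletions have `alt = ""`.
#' @export
align_global <- function(seq, ref, scoring = align_scoring()) {
  stopifnot(nchar(seq) > 0, nchar(ref) > 0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    pattern = seq, subject = ref, type = "global",
    substitutionMatrix = mat,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  out <- variants_from_alignment(
    as.character(Biostrings::alignedPattern(al)),
    as.character(Biostrings::alignedSubject(al)), ref)
  attr(out, "score") <- Biostrings::score(al)
  out
}

empty_variants <- function() {
  out <- data.frame(pos = integer(), ref = character(), alt = character(),
                    type = character(), stringsAsFactors = FALSE)
  class(out) <- c("variant_table", "data.frame")
  out
}

# Walk aligned strings (equal length, '-' for gaps), emit left-aligned events.
variants_from_alignment <- function(aln_seq, aln_ref, ref) {
  p <- strsplit(aln_seq, "")[[1]]
  s <- strsplit(aln_ref, "")[[1]]
  n <- length(p)
  pos <- integer(0); refs <- character(0); alts <- character(0); types <- character(0)
  rpos <- 0L   # bases of ref consumed
  bound <- 0L  # indels never left-shift past the previous variant
  i <- 1L
  while (i <= n) {
    if (s[i] != "-" && p[i] != "-") {
      if (s[i] != p[i]) {
        pos <- c(pos, rpos); refs <- c(refs, s[i]); alts <- c(alts, p[i])
        types <- c(types, "substitution")
        bound <- rpos + 1L
      }
      rpos <- rpos + 1L
      i <- i + 1L
    } else if (p[i] == "-") {             # deletion from ref
      j <- i
      while (j <= n && p[j] == "-") j <- j + 1L
      del <- paste(s[i:(j - 1L)], collapse = "")
      la <- left_align_del(ref, rpos, nchar(del), bound)
      pos <- c(pos, la$pos); refs <- c(refs, la$ref); alts <- c(alts, "")
      types <- c(types, "deletion")
      rpos <- rpos + nchar(del)
      bound <- la$pos + nchar(del)
      i <- j
    } else {                              # insertion into ref
      j <- i
      while (j <= n && s[j] == "-") j <- j + 1L
      ins <- paste(p[i:(j - 1L)], collapse = "")
      la <- left_align_ins(ref, rpos, ins, bound)
      pos <- c(pos, la$pos); refs <- c(refs, ""); alts <- c(alts, la$alt)
      types <- c(types, "insertion")
      bound <- la$pos
      i <- j
    }
  }
  out <- data.frame(pos = pos, ref = refs, alt = alts, type = types,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos, out$type), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  out
}

# Shift a deletion of k bases at 0-based pos to its leftmost equivalent spot,
# never crossing `bound` (the end of the previous variant).
left_align_del <- function(ref, pos, k, bound = 0L) {
  rc <- strsplit(ref, "")[[1]]
  while (pos > bound && rc[pos] == rc[pos + k]) pos <- pos - 1L
  list(pos = pos, ref = paste(rc[(pos + 1L):(pos + k)], collapse = ""))
}

# Shift an insertion (before ref position pos) to its leftmost equivalent.
left_align_ins <- function(ref, pos, ins, bound = 0L) {
  rc <- strsplit(ref, "")[[1]]
  ic <- strsplit(ins, "")[[1]]
  k <- length(ic)
  while (pos > bound && ic[k] == rc[pos]) {
    ic <- c(rc[pos], ic[-k])
    pos <- pos - 1L
  }
  list(pos = pos, alt = paste(ic, collapse = ""))
}

#' Apply variants to a reference sequence
#'
#' Reconstructs the edited sequence from a reference and a `variant_table`
#' (the inverse of [align_global()]: applying the variants extracted from an
#' alignment of `seq` to `ref` yields `seq` exactly).
#'
#' @param ref reference sequence.
#' @param variants a `variant_table`.
#' @return edited sequence (character scalar).
#' @export
apply_variants <- function(ref, variants) {
  if (nrow(variants) == 0) return(ref)
  # right to left; at equal positions substitutions/deletions act on the
  # reference base before an insertion lands in front of it
  v <- variants[order(-variants$pos, variants$type == "insertion"), , drop = FALSE]
  out <- ref
  for (i in seq_len(nrow(v))) {
    pos <- v$pos[i]
    if (v$type[i] == "insertion") {
      out <- paste0(substr(out, 1L, pos), v$alt[i],
                    substr(out, pos + 1L, nchar(out)))
    } else {
      out <- paste0(substr(out, 1L, pos), v$alt[i],
                    substr(out, pos + nchar(v$ref[i]) + 1L, nchar(out)))
    }
  }
  out
}

#' Reference interval touched by each variant
#' @param variants a `variant_table`.
#' @return matrix with columns `start`, `end` (0-based half-open; insertions
#'   give zero-width intervals at their insertion point).
#' @keywords internal
variant_intervals <- function(variants) {
  cbind(start = variants$pos,
        end = variants$pos + nchar(variants$ref))
}

#' Equivalent-placement interval of each variant
#'
#' For an indel inside a repeat, every placement between its left-most and
#' right-most admissible position describes the same edited molecule. This
#' returns, per variant, the reference interval covered by the union of all
#' equivalent placements (substitutions are single positions; insertions
#' of zero width at either extreme give `[pmin, pmax]`).
#'
#' @param ref reference sequence the variants are placed on.
#' @param variants a `variant_table`.
#' @return matrix with columns `start`, `end` (0-based; half-open for
#'   deletions/substitutions, inclusive point range for insertions, which are
#'   zero-width when `pmin == pmax`).
#' @keywords internal
variant_placement_range <- function(ref, variants) {
  rc <- strsplit(ref, "")[[1]]
  n <- length(rc)
  out <- matrix(0L, nrow = nrow(variants), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
  for (i in seq_len(nrow(variants))) {
    p <- variants$pos[i]
    if (variants$type[i] == "substitution") {
      out[i, ] <- c(p, p + 1L)
    } else if (variants$type[i] == "deletion") {
      k <- nchar(variants$ref[i])
      pmin <- p
      while (pmin > 0L && rc[pmin] == rc[pmin + k]) pmin <- pmin - 1L
      pmax <- p
      while (pmax + k < n && rc[pmax + 1L] == rc[pmax + k + 1L])
        pmax <- pmax + 1L
      out[i, ] <- c(pmin, pmax + k)
    } else {
      ic <- strsplit(variants$alt[i], "")[[1]]
      k <- length(ic)
      pmin <- p; icl <- ic
      while (pmin > 0L && icl[k] == rc[pmin]) {
        icl <- c(rc[pmin], icl[-k])
        pmin <- pmin - 1L
      }
      pmax <- p; icr <- ic
      while (pmax < n && icr[1] == rc[pmax + 1L]) {
        icr <- c(icr[-1], rc[pmax + 1L])
        pmax <- pmax + 1L
      }
      out[i, ] <- c(pmin, pmax)
    }
  }
  out
}

#' Export variants as a minimal VCF
#'
#' Left-aligned variants, 1-based positions; indels use the usual anchored
#' representation (previous reference base prepended to REF and ALT).
#'
#' @param variants a `variant_table` on `ref` coordinates.
#' @param ref reference sequence.
#' @param path output path.
#' @param chrom contig name for column 1.
#' @export
write_vcf <- function(variants, ref, path, chrom = "amplicon") {
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", chrom, nchar(ref)),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(variants)) {
    rows <- vapply(seq_len(nrow(variants)), function(i) {
      v <- variants[i, ]
      if (v$type == "substitution") {
        sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", chrom, v$pos + 1L, v$ref, v$alt)
      } else if (v$pos > 0L) {
        anchor <- substr(ref, v$pos, v$pos)
        sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", chrom, v$pos,
                paste0(anchor, v$ref), paste0(anchor, v$alt))
      } else {  # indel at position 0: anchor on the following base
        anchor <- substr(ref, v$pos + nchar(v$ref) + 1L, v$pos + nchar(v$ref) + 1L)
        sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", chrom, 1L,
                paste0(v$ref, anchor), paste0(v$alt, anchor))
      }
    }, "")
    lines <- c(lines, rows)
  }
  writeLines(lines, path)
  invisible(path)
}
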