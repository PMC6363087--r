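# Read preprocessing: pair merging by overlap, fixed-length flank trimming,
# exact sequence clustering with prevalences.

#' Merge configuration
#'
#' Parameters of overlap-based read-pair collapse. Defaults follow FLASH's
#' published defaults (min overlap 10 nt, up to 25% of the overlap allowed to
#' mismatch). Quality offset is fixed at 33.
#'
#' @param min_overlap minimum admissible overlap, >= 4.
#' @param max_mismatch_frac maximum mismatching fraction of the overlap,
#'   in `[0, 0.5)`.
#' @return object of class `merge_config`.
#' @export
merge_config <- function(min_overlap = 10L, max_mismatch_frac = 0.25) {
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 4L) stop("min_overlap must be >= 4")
  if (max_mismatch_frac < 0 || max_mismatch_frac >= 0.5)
    stop("max_mismatch_frac must be in [0, 0.5)")
  structure(list(min_overlap = min_overlap,
                 max_mismatch_frac = max_mismatch_frac,
                 quality_offset = 33L),
            class = "merge_config")
}

#' Merge one read pair by overlap
#'
#' `r2` is expected in sequencer orientation (reverse strand) and is
#' reverse-complemented internally. Among all innie overlaps of length
#' `>= min_overlap` whose mismatch fraction is `<= max_mismatch_frac`, the
#' longest is chosen. At overlap mismatches the base with the higher Phred
#' score is kept; on quality ties the r1 base is kept with quality
#' `min(q1, q2)`; agreeing bases keep `max(q1, q2)`.
#'
#' @param r1,r2 single-row `fastq_reads` (or lists with `seq`/`qual`).
#' @param cfg a [merge_config()].
#' @return a one-row `fastq_reads` with attributes `overlap` and
#'   `mismatches`, or `NULL` if no admissible overlap exists.
#' @export
merge_pair <- function(r1, r2, cfg = merge_config()) {
  res <- .merge_pairs_cpp(r1$seq, r1$qual, r2$seq, r2$qual,
                          cfg$min_overlap, cfg$max_mismatch_frac)
  if (!res$merged[1]) return(NULL)
  out <- fastq_reads(r1$id[1], res$seq[1], res$qual[1])
  attr(out, "overlap") <- res$overlap[1]
  attr(out, "mismatches") <- res$mismatches[1]
  out
}

#' Merge all read pairs of a sample
#'
#' Vectorized pair collapse. Pairs without an admissible overlap are dropped
#' and counted; the amplicon designs this pipeline targets are shorter than
#' the summed read length, so outie/adapter-readthrough pairs are not
#' searched for.
#'
#' @param r1,r2 `fastq_reads` of equal length, pairs in file order.
#' @param cfg a [merge_config()].
#' @return a `fastq_reads` of merged reads; attribute `n_unmerged` counts
#'   dropped pairs, attribute `overlap` the per-read overlap lengths.
#' @export
merge_pairs <- function(r1, r2, cfg = merge_config()) {
  if (nrow(r1) != nrow(r2)) stop("r1/r2 must have the same number of reads")
  if (nrow(r1) == 0) {
    out <- fastq_reads(character(), character(), character())
    attr(out, "n_unmerged") <- 0L
    return(out)
  }
  res <- .merge_pairs_cpp(r1$seq, r1$qual, r2$seq, r2$qual,
                          cfg$min_overlap, cfg$max_mismatch_frac)
  keep <- res$merged
  out <- fastq_reads(r1$id[keep], res$seq[keep], res$qual[keep])
  attr(out, "n_unmerged") <- sum(!keep)
  attr(out, "overlap") <- res$overlap[keep]
  out
}

#' Trim fixed-length flanks from reads
#'
#' Removes `n5` bases from the 5' end and `n3` from the 3' end of every read
#' (the noise-reduction step applied to merged amplicon reads). Reads not
#' longer than `n5 + n3` are discarded, not errored; their count is recorded
#' in attribute `n_discarded`.
#'
#' @param reads a `fastq_reads`.
#' @param n5,n3 bases to trim from each end (default 35).
#' @return trimmed `fastq_reads`.
#' @export
trim_fixed <- function(reads, n5 = 35L, n3 = 35L) {
  n5 <- as.integer(n5); n3 <- as.integer(n3)
  if (n5 < 0 || n3 < 0) stop("trim lengths must be >= 0")
  len <- nchar(reads$seq)
  keep <- len > n5 + n3
  out <- fastq_reads(reads$id[keep],
                     substr(reads$seq[keep], n5 + 1L, len[keep] - n3),
                     substr(reads$qual[keep], n5 + 1L, len[keep] - n3))
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Cluster identical sequences
#'
#' One cluster per distinct sequence string: no similarity threshold is
#' applied, so sequences differing by a single base form distinct clusters.
#' Clusters are sorted by count descending, ties broken lexicographically by
#' sequence, and prevalence is computed over the input total.
#'
#' @param seqs character vector of merged, trimmed read sequences (a
#'   `fastq_reads` is also accepted).
#' @return data frame of class `cluster_table` with columns `rank`, `seq`,
#'   `count`, `prevalence`.
#' @export
cluster_exact <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  if (length(seqs) == 0) {
    out <- data.frame(rank = integer(), seq = character(), count = integer(),
                      prevalence = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("cluster_table", "data.frame")
    return(out)
  }
  tab <- table(seqs)
  cnt <- as.integer(tab)
  sq <- names(tab)
  ord <- order(-cnt, sq, method = "radix")
  out <- data.frame(rank = seq_along(ord), seq = sq[ord], count = cnt[ord],
                    prevalence = cnt[ord] / length(seqs),
                    stringsAsFactors = FALSE)
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Drop reads below a mean-quality threshold
#'
#' Optional filter; the pipeline default applies no quality threshold beyond
#' the Phred-33 decoding itself.
#'
#' @param reads a `fastq_reads`.
#' @param min_mean_qual minimum mean Phred score.
#' @return filtered `fastq_reads` with attribute `n_dropped`.
#' @export
filter_mean_quality <- function(reads, min_mean_qual) {
  if (nrow(reads) == 0) return(reads)
  mq <- vapply(reads$qual, function(q) mean(qual_ints(q)), numeric(1),
               USE.NAMES = FALSE)
  out <- reads[mq >= min_mean_qual, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(mq < min_mean_qual)
  class(out) <- c("fastq_reads", "data.frame")
  out
}

#' Write a cluster table as TSV
#' @param clusters a `cluster_table`.
#' @param path output path.
#' @export
write_clusters <- function(clusters, path) {
  write.table(clusters, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
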