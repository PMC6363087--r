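# Allele disambiguation: diagnostic SNP fingerprints computed outside the
# CRISPR target windows, prevalence-threshold variant calling, best-match
# assignment of observed clusters to reference alleles, and rescue of
# PCR-dropout alleles by their exclusive SNPs.

#' Select variant clusters above the prevalence threshold
#'
#' Keeps clusters with prevalence `>= min_prev` (inclusive: "at least 1%").
#' Dropped clusters are retained in attribute `below_threshold` for dropout
#' rescue.
#'
#' @param clusters a `cluster_table` from [cluster_exact()].
#' @param min_prev prevalence threshold (default 0.01).
#' @return the kept subset of `clusters`; attribute `below_threshold` holds
#'   the rest.
#' @export
call_variant_clusters <- function(clusters, min_prev = 0.01) {
  keep <- clusters$prevalence >= min_prev
  out <- clusters[keep, , drop = FALSE]
  rownames(out) <- NULL
  below <- clusters[!keep, , drop = FALSE]
  rownames(below) <- NULL
  attr(out, "below_threshold") <- below
  class(out) <- class(clusters)
  out
}

# ---- induced alignment frame ------------------------------------------------

# Align every allele to the anchor allele and induce a common column frame:
# one column per anchor position ("p<pos>") plus columns for bases inserted
# relative to the anchor ("i<pos>.<k>", inserted before anchor position
# <pos>). For each allele the frame records the base in each column ("-" if
# absent) and the allele's own 0-based coordinate of that base.
induced_frame <- function(aset, scoring = align_scoring()) {
  anchor_id <- aset$anchor
  anchor <- aset$alleles[[anchor_id]]
  ids <- names(aset$alleles)
  per <- list()
  ins_keys <- character(0)
  for (id in ids) {
    if (id == anchor_id) {
      n <- nchar(anchor)
      per[[id]] <- list(
        base = setNames(strsplit(anchor, "")[[1]], paste0("p", 0:(n - 1L))),
        pos = setNames(0:(n - 1L), paste0("p", 0:(n - 1L))))
      next
    }
    al <- Biostrings::pairwiseAlignment(
      pattern = aset$alleles[[id]], subject = anchor, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE),
      gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
    p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    keys <- character(length(p)); bases <- character(length(p))
    poss <- integer(length(p))
    apos <- 0L; ppos <- 0L; ins_k <- 0L
    for (i in seq_along(p)) {
      if (s[i] != "-") {
        keys[i] <- paste0("p", apos)
        apos <- apos + 1L
        ins_k <- 0L
      } else {
        keys[i] <- paste0("i", apos, ".", ins_k)
        ins_k <- ins_k + 1L
        ins_keys <- union(ins_keys, keys[i])
      }
      if (p[i] != "-") {
        bases[i] <- p[i]; poss[i] <- ppos; ppos <- ppos + 1L
      } else {
        bases[i] <- "-"; poss[i] <- NA_integer_
      }
    }
    per[[id]] <- list(base = setNames(bases, keys), pos = setNames(poss, keys))
  }
  n <- nchar(anchor)
  all_keys <- paste0("p", 0:(n - 1L))
  if (length(ins_keys)) {
    # interleave: an insertion column "i<x>.<k>" sits just before column "p<x>"
    ip <- as.integer(sub("^i([0-9]+)\\..*$", "\\1", ins_keys))
    ik <- as.integer(sub("^i[0-9]+\\.([0-9]+)$", "\\1", ins_keys))
    keys <- c(all_keys, ins_keys)
    kpos <- c(0:(n - 1L), ip)
    ktype <- c(rep(1L, n), rep(0L, length(ins_keys)))
    ksub <- c(rep(0L, n), ik)
    all_keys <- keys[order(kpos, ktype, ksub)]
  }
  frame <- list(keys = all_keys, anchor = anchor_id, alleles = list())
  for (id in ids) {
    b <- per[[id]]$base[all_keys]
    b[is.na(b)] <- "-"
    names(b) <- all_keys
    po <- per[[id]]$pos[all_keys]
    names(po) <- all_keys
    frame$alleles[[id]] <- list(base = b, pos = po)
  }
  # anchor coordinate of every column (insertion columns take the position
  # they precede), for masking/visibility arithmetic
  frame$col_anchor_pos <- as.integer(sub("^[pi]([0-9]+).*$", "\\1", all_keys))
  frame
}

#' Default masked windows around guide target sites
#'
#' Protospacer + PAM extended by `flank` bases on each side, per allele, to
#' absorb the NHEJ indel smear around each cut.
#'
#' @param aset an [allele_set()] with guides.
#' @param flank extension in bases (default 10).
#' @return named list (per allele) of `[start, end)` interval matrices.
#' @export
default_masked_windows <- function(aset, flank = 10L) {
  out <- list()
  for (id in names(aset$alleles)) {
    rows <- list()
    for (g in aset$guides) {
      gs <- locate_guide(g, aset$alleles[[id]])
      if (!gs$found) next
      lo <- min(gs$protospacer_interval[1], gs$pam_interval[1]) - flank
      hi <- max(gs$protospacer_interval[2], gs$pam_interval[2]) + flank
      rows[[length(rows) + 1L]] <- c(max(0L, lo), min(nchar(aset$alleles[[id]]), hi))
    }
    out[[id]] <- if (length(rows)) do.call(rbind, rows)
                 else matrix(integer(), ncol = 2)
  }
  out
}

#' Build per-allele diagnostic SNP fingerprints
#'
#' Alleles are aligned to the anchor allele, inducing a common column frame.
#' Alleles whose visible (unmasked, in-window) aligned sequences are
#' identical are grouped into one shared class (e.g. a pair of alleles
#' indistinguishable within the sequenced region). For every class the
#' fingerprint records: `diagnostic` — the columns where the class carries a
#' base that differs from every other class (the exclusive SNPs used for
#' dropout rescue); and `profile` — all discriminative columns (where at
#' least two classes disagree) with this class's base, used for best-match
#' assignment. Masked target windows never contribute columns.
#'
#' @param aset an [allele_set()].
#' @param masked_windows per-allele list of `[start, end)` interval matrices;
#'   default [default_masked_windows()] around the guide sites.
#' @param trim `c(n5, n3)`: bases trimmed from the amplicon ends; columns
#'   whose allele coordinate falls outside the surviving window on any allele
#'   are invisible to the fingerprint (default `c(0, 0)`).
#' @param flank mask flank passed to [default_masked_windows()].
#' @param scoring an [align_scoring()].
#' @return object of class `fingerprint_set`: list of per-class fingerprints
#'   plus the frame metadata.
#' @export
build_fingerprints <- function(aset, masked_windows = NULL, trim = c(0L, 0L),
                               flank = 10L, scoring = align_scoring()) {
  if (is.null(masked_windows)) masked_windows <- default_masked_windows(aset, flank)
  ids <- names(aset$alleles)
  frame <- induced_frame(aset, scoring)
  nk <- length(frame$keys)

  # column visibility: a column is usable if, for every allele carrying a
  # base there, that base lies outside the allele's masks and inside its
  # trimmed window
  usable <- rep(TRUE, nk)
  for (id in ids) {
    po <- frame$alleles[[id]]$pos
    len <- nchar(aset$alleles[[id]])
    lo <- trim[1]; hi <- len - trim[2]
    bad <- !is.na(po) & (po < lo | po >= hi)
    mw <- masked_windows[[id]]
    if (!is.null(mw) && nrow(mw)) {
      for (j in seq_len(nrow(mw)))
        bad <- bad | (!is.na(po) & po >= mw[j, 1] & po < mw[j, 2])
    }
    usable <- usable & !bad
  }

  base_mat <- do.call(rbind, lapply(ids, function(id) frame$alleles[[id]]$base))
  rownames(base_mat) <- ids

  # group alleles into classes by identical visible sequence
  vis_sig <- apply(base_mat[, usable, drop = FALSE], 1, paste, collapse = "")
  class_of <- match(vis_sig, unique(vis_sig))
  classes <- split(ids, class_of)
  class_ids <- vapply(classes, function(m) paste(m, collapse = "/"), "")

  # class-level base per column (members are identical on usable columns)
  cls_mat <- do.call(rbind, lapply(classes, function(m) base_mat[m[1], , drop = TRUE]))
  rownames(cls_mat) <- class_ids
  ncls <- nrow(cls_mat)

  discriminative <- usable & apply(cls_mat, 2, function(col) length(unique(col)) > 1)

  fps <- list()
  for (ci in seq_len(ncls)) {
    members <- classes[[ci]]
    rep_id <- members[1]
    pos_rep <- frame$alleles[[rep_id]]$pos
    mine <- cls_mat[ci, ]
    if (ncls > 1) {
      others <- cls_mat[-ci, , drop = FALSE]
      exclusive <- discriminative & mine != "-" &
        vapply(seq_along(mine), function(j) all(others[, j] != mine[j]),
               logical(1))
    } else {
      exclusive <- rep(FALSE, nk)
    }
    prof_cols <- which(discriminative & mine != "-" & !is.na(pos_rep))
    profile <- data.frame(col = frame$keys[prof_cols],
                          allele_pos = unname(pos_rep[prof_cols]),
                          base = unname(mine[prof_cols]),
                          stringsAsFactors = FALSE)
    diag_cols <- which(exclusive & !is.na(pos_rep))
    diagnostic <- data.frame(col = frame$keys[diag_cols],
                             allele_pos = unname(pos_rep[diag_cols]),
                             base = unname(mine[diag_cols]),
                             stringsAsFactors = FALSE)
    fps[[class_ids[ci]]] <- list(class_id = class_ids[ci], members = members,
                                 representative = rep_id,
                                 diagnostic = diagnostic, profile = profile)
  }
  structure(list(classes = fps, trim = as.integer(trim),
                 anchor = frame$anchor,
                 n_discriminative = sum(discriminative)),
            class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat("<fingerprint_set>", length(x$classes), "allele class(es),",
      x$n_discriminative, "discriminative column(s)\n")
  for (fp in x$classes)
    cat(sprintf("  %-10s %d exclusive, %d profile position(s)\n",
                fp$class_id, nrow(fp$diagnostic), nrow(fp$profile)))
  invisible(x)
}

# Aligned cluster base at every reference position, for one cluster/ref pair
# (batched over clusters). Returns a list of character vectors, each of
# length nchar(ref_window), "-" where the cluster has a gap.
aligned_bases_batch <- function(seqs, ref_window, scoring = align_scoring()) {
  if (length(seqs) == 0) return(list())
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(seqs), subject = ref_window,
    type = "global", substitutionMatrix = mat,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  # pattern bases in the subject frame: mismatches keep the pattern base,
  # deletions appear as "-", insertions are invisible (they sit between
  # reference positions and never carry diagnostic columns of the reference)
  strsplit(as.character(Biostrings::aligned(al)), "")
}

#' Assign a cluster sequence to a reference allele class
#'
#' The cluster is aligned globally to each class representative (within the
#' trimmed amplicon window recorded in the fingerprints) and scored by the
#' fraction of the class's profile positions whose aligned base matches.
#' Positions deleted in the cluster (alignment gaps) are excluded from the
#' denominator so that large dual-cut deletions do not mask the surviving
#' diagnostics. The cluster is assigned to the class with the uniquely
#' maximal score if that score is at least `min_score`; ties or lower scores
#' give `"unassigned"`. With a single class every cluster assigns to it.
#'
#' @param cluster_seq the cluster's sequence (trimmed amplicon frame).
#' @param fingerprints a `fingerprint_set` built with the matching `trim`.
#' @param aset the [allele_set()].
#' @param min_score assignment threshold (default 0.8, tolerating one
#'   sequencing error over small diagnostic sets).
#' @param scoring an [align_scoring()].
#' @return list with `assigned` (class id or `"unassigned"`), `score`,
#'   `match_detail` (per-class matched/scorable counts).
#' @export
assign_allele <- function(cluster_seq, fingerprints, aset, min_score = 0.8,
                          scoring = align_scoring()) {
  detail <- score_clusters(cluster_seq, fingerprints, aset, scoring)[[1]]
  pick_assignment(detail, min_score)
}

# batch scoring: one alignment per (cluster, class)
score_clusters <- function(cluster_seqs, fingerprints, aset,
                           scoring = align_scoring()) {
  trim <- fingerprints$trim
  per_class <- list()
  for (fp in fingerprints$classes) {
    ref <- aset$alleles[[fp$representative]]
    len <- nchar(ref)
    win <- substr(ref, trim[1] + 1L, len - trim[2])
    ab <- aligned_bases_batch(cluster_seqs, win, scoring)
    wpos <- fp$profile$allele_pos - trim[1]
    ok <- wpos >= 0L & wpos < nchar(win)
    dpos <- fp$diagnostic$allele_pos - trim[1]
    dok <- dpos >= 0L & dpos < nchar(win)
    per_class[[fp$class_id]] <- lapply(ab, function(b) {
      obs <- b[wpos[ok] + 1L]
      scorable <- obs != "-"
      dobs <- b[dpos[dok] + 1L]
      list(matched = sum(obs[scorable] == fp$profile$base[ok][scorable]),
           scorable = sum(scorable),
           diag_matched = sum(dobs == fp$diagnostic$base[dok]),
           diag_total = sum(dok))
    })
  }
  lapply(seq_along(cluster_seqs), function(i) {
    det <- lapply(per_class, `[[`, i)
    det
  })
}

pick_assignment <- function(detail, min_score) {
  nclass <- length(detail)
  if (nclass == 1) {
    sc <- detail[[1]]
    s <- if (sc$scorable > 0) sc$matched / sc$scorable else 1
    return(list(assigned = names(detail)[1], score = s, match_detail = detail))
  }
  scores <- vapply(detail, function(d)
    if (d$scorable > 0) d$matched / d$scorable else NA_real_, numeric(1))
  if (all(is.na(scores)))
    return(list(assigned = "unassigned", score = NA_real_, match_detail = detail))
  best <- max(scores, na.rm = TRUE)
  winners <- names(scores)[!is.na(scores) & scores == best]
  if (length(winners) != 1 || best < min_score)
    return(list(assigned = "unassigned", score = best, match_detail = detail))
  list(assigned = winners, score = best, match_detail = detail)
}

#' Rescue a PCR-dropout allele from sub-threshold clusters
#'
#' When an expected allele class is absent from the main (>= min_prev) call
#' set, sub-threshold clusters whose aligned bases match *all* of the class's
#' exclusive diagnostic positions are returned as rescued calls — differences
#' inside the masked target windows (i.e. edits) are irrelevant by
#' construction, since diagnostics exclude those windows.
#'
#' @param below_clusters `cluster_table` of sub-threshold clusters (attribute
#'   `below_threshold` of [call_variant_clusters()]).
#' @param missing_fp the fingerprint of the missing class (an element of
#'   `fingerprint_set$classes`).
#' @param fingerprints the full `fingerprint_set` (for the trim window).
#' @param aset the [allele_set()].
#' @param scoring an [align_scoring()].
#' @return the matching subset of `below_clusters` with columns `assigned`,
#'   `rescued = TRUE`, `diag_matched`, `diag_total`; zero rows if the allele
#'   is not detected.
#' @export
rescue_missing <- function(below_clusters, missing_fp, fingerprints, aset,
                           scoring = align_scoring()) {
  out <- below_clusters[integer(0), , drop = FALSE]
  if (nrow(below_clusters) == 0 || nrow(missing_fp$diagnostic) == 0) {
    out$assigned <- character(0); out$rescued <- logical(0)
    out$diag_matched <- integer(0); out$diag_total <- integer(0)
    return(out)
  }
  trim <- fingerprints$trim
  ref <- aset$alleles[[missing_fp$representative]]
  win <- substr(ref, trim[1] + 1L, nchar(ref) - trim[2])
  dpos <- missing_fp$diagnostic$allele_pos - trim[1]
  ok <- dpos >= 0L & dpos < nchar(win)
  dpos <- dpos[ok]
  dbase <- missing_fp$diagnostic$base[ok]
  if (length(dpos) == 0) {
    out$assigned <- character(0); out$rescued <- logical(0)
    out$diag_matched <- integer(0); out$diag_total <- integer(0)
    return(out)
  }
  ab <- aligned_bases_batch(below_clusters$seq, win, scoring)
  matched <- vapply(ab, function(b) sum(b[dpos + 1L] == dbase), integer(1))
  hit <- matched == length(dpos)
  out <- below_clusters[hit, , drop = FALSE]
  out$assigned <- rep(missing_fp$class_id, nrow(out))
  out$rescued <- rep(TRUE, nrow(out))
  out$diag_matched <- matched[hit]
  out$diag_total <- rep(length(dpos), nrow(out))
  rownames(out) <- NULL
  out
}
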