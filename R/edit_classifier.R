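# Classification of editing outcomes: per-guide-site edit status, dual-cut
# deletions, and predicted protein consequence through the gene model.

#' Per-site edit status and dual-cut detection
#'
#' A guide site counts as edited iff some variant's reference interval
#' intersects the window `[cut - flank, cut + flank)` around its blunt cut
#' position; a dual cut is a single deletion whose interval contains both cut
#' positions (boundary-inclusive).
#'
#' Indel placement within repeats is ambiguous (a left-aligned deletion and
#' its right-shifted equivalents describe the same molecule), so when `ref`
#' is supplied each indel is tested by its whole equivalent-placement range —
#' from its left-most to its right-most admissible position — making the
#' calls placement-invariant.
#'
#' @param variants a `variant_table` on allele coordinates.
#' @param guide_sites list of `guide_site` objects (see
#'   [check_allele_compatibility()]); sites with `found = FALSE` are reported
#'   `"not_assessable"`.
#' @param flank half-width of the edit window around each cut (default 10).
#' @param ref the allele sequence; enables placement-range testing.
#' @return list with `site_status` (named character,
#'   `"wild-type"`/`"edited"`/`"not_assessable"`) and `dual_cut` flag.
#' @export
call_site_edits <- function(variants, guide_sites, flank = 10L, ref = NULL) {
  iv <- variant_intervals(variants)
  if (!is.null(ref) && nrow(variants)) {
    rng <- variant_placement_range(ref, variants)
    iv <- cbind(start = rng[, 1], end = rng[, 2])
  }
  status <- character(0)
  cuts <- integer(0)
  for (gs in guide_sites) {
    nm <- gs$guide
    if (isFALSE(gs$found)) {
      status[nm] <- "not_assessable"
      next
    }
    cut <- gs$cut
    cuts <- c(cuts, cut)
    hit <- FALSE
    if (nrow(variants)) {
      lo <- cut - flank; hi <- cut + flank
      # interval [s,e) intersects window; insertions are points s==e
      hit <- any(ifelse(iv[, 1] == iv[, 2],
                        iv[, 1] >= lo & iv[, 1] <= hi,
                        iv[, 2] > lo & iv[, 1] < hi))
    }
    status[nm] <- if (hit) "edited" else "wild-type"
  }
  dual <- FALSE
  if (length(cuts) >= 2 && nrow(variants)) {
    del <- variants$type == "deletion"
    if (any(del)) {
      s <- iv[del, 1]; e <- iv[del, 2]
      c1 <- min(cuts); c2 <- max(cuts)
      dual <- any(s <= c1 & e >= c2)
    }
  }
  list(site_status = status, dual_cut = dual)
}

#' Predict the coding consequence of a set of variants
#'
#' Applies the variants to the genomic allele sequence, rebuilds the
#' transcript from the surviving exonic bases (a deletion removing a whole
#' intron together with flanking exon ends fuses the remaining exon parts),
#' translates the reconstructed CDS with the standard genetic code, and
#' classifies by net CDS length change and first stop codon.
#'
#' Classification levels: `none`, `silent`, `missense`,
#' `in_frame_deletion`/`in_frame_insertion` (with `n_aa`), `premature_stop`
#' (an in-frame edit that introduces a stop), `frameshift`,
#' `frameshift_with_PTC` (with the stop position in aa), `splice_disrupted`,
#' `start_lost`. A frameshift is called iff the net CDS length change mod 3
#' is non-zero. Any deletion removing >= 1 base of a canonical GT donor or AG
#' acceptor dinucleotide without deleting its full intron is
#' `splice_disrupted` and no translation is attempted.
#'
#' @param variants a `variant_table` on the allele's genomic coordinates.
#' @param gm the allele's [gene_model()].
#' @param ref the allele's genomic sequence.
#' @return one-row data frame with columns `effect`, `n_aa` (aa gained/lost
#'   for in-frame events), `ptc_aa` (1-based aa position of a premature
#'   stop), `cds_delta` (net CDS length change in nt).
#' @export
predict_coding_effect <- function(variants, gm, ref) {
  res <- function(effect, n_aa = NA_integer_, ptc_aa = NA_integer_,
                  cds_delta = NA_integer_) {
    data.frame(effect = effect, n_aa = n_aa, ptc_aa = ptc_aa,
               cds_delta = cds_delta, stringsAsFactors = FALSE)
  }
  if (nrow(variants) == 0) return(res("none", cds_delta = 0L))

  # splice-disruption screen (deletion-based rule)
  intr <- introns(gm)
  if (nrow(intr)) {
    del <- variants[variants$type == "deletion", , drop = FALSE]
    for (i in seq_len(nrow(del))) {
      s <- del$pos[i]; e <- s + nchar(del$ref[i])
      for (j in seq_len(nrow(intr))) {
        donor <- c(intr[j, 1], intr[j, 1] + 2L)
        accep <- c(intr[j, 2] - 2L, intr[j, 2])
        hits_site <- (e > donor[1] && s < donor[2]) ||
                     (e > accep[1] && s < accep[2])
        whole_intron <- s <= intr[j, 1] && e >= intr[j, 2]
        if (hits_site && !whole_intron) return(res("splice_disrupted"))
      }
    }
  }

  # per-base CDS annotation of the reference, then carried through the edit
  L <- nchar(ref)
  cds_flag <- logical(L)
  spliced_i <- 0L
  for (j in seq_len(nrow(gm$exons))) {
    idx <- (gm$exons[j, 1] + 1L):gm$exons[j, 2]
    flags <- (spliced_i + seq_along(idx) - 1L) >= gm$cds_start_offset
    cds_flag[idx] <- flags
    spliced_i <- spliced_i + length(idx)
  }
  bases <- strsplit(ref, "")[[1]]
  keep <- rep(TRUE, L)
  ins_at <- vector("list", L + 1L)  # insertions before 0-based position p
  for (i in seq_len(nrow(variants))) {
    p <- variants$pos[i]
    if (variants$type[i] == "substitution") {
      bases[p + 1L] <- variants$alt[i]
    } else if (variants$type[i] == "deletion") {
      keep[(p + 1L):(p + nchar(variants$ref[i]))] <- FALSE
    } else {
      ins_at[[p + 1L]] <- c(ins_at[[p + 1L]], variants$alt[i])
    }
  }
  # inserted bases inherit the CDS flag of the base they precede (or, at the
  # end of the sequence, of the base before)
  out_bases <- character(0); out_flags <- logical(0)
  for (p in 0:L) {
    if (!is.null(ins_at[[p + 1L]])) {
      ins <- paste(ins_at[[p + 1L]], collapse = "")
      fl <- if (p < L) cds_flag[p + 1L] else cds_flag[L]
      out_bases <- c(out_bases, strsplit(ins, "")[[1]])
      out_flags <- c(out_flags, rep(fl, nchar(ins)))
    }
    if (p < L && keep[p + 1L]) {
      out_bases <- c(out_bases, bases[p + 1L])
      out_flags <- c(out_flags, cds_flag[p + 1L])
    }
  }
  ref_cds <- paste(strsplit(ref, "")[[1]][cds_flag], collapse = "")
  new_cds <- paste(out_bases[out_flags], collapse = "")
  delta <- nchar(new_cds) - nchar(ref_cds)

  if (new_cds == ref_cds) return(res("none", cds_delta = 0L))

  # CDS start destroyed by a deletion?
  cds_positions <- which(cds_flag) - 1L
  start_pos <- cds_positions[seq_len(min(3L, length(cds_positions)))]
  del <- variants[variants$type == "deletion", , drop = FALSE]
  if (nrow(del)) {
    ds <- del$pos; de <- del$pos + nchar(del$ref)
    if (any(vapply(seq_along(ds), function(i)
      any(start_pos >= ds[i] & start_pos < de[i]), logical(1))))
      return(res("start_lost", ptc_aa = 0L, cds_delta = as.integer(delta)))
  }

  ref_prot <- translate_cds(ref_cds, quiet = TRUE)
  new_prot <- translate_cds(new_cds, quiet = TRUE)
  ref_aa <- sub("\\*$", "", ref_prot)
  new_aa <- sub("\\*$", "", new_prot)
  new_has_ptc <- grepl("\\*$", new_prot) &&
    nchar(new_aa) < (nchar(new_cds) %/% 3L - 1L)

  if (delta %% 3L != 0L) {
    if (new_has_ptc)
      return(res("frameshift_with_PTC", ptc_aa = nchar(new_aa) + 1L,
                 cds_delta = as.integer(delta)))
    return(res("frameshift", cds_delta = as.integer(delta)))
  }
  if (new_has_ptc)
    return(res("premature_stop", ptc_aa = nchar(new_aa) + 1L,
               cds_delta = as.integer(delta)))
  if (delta == 0L) {
    if (new_aa == ref_aa) return(res("silent", cds_delta = 0L))
    return(res("missense", cds_delta = 0L))
  }
  if (delta > 0L)
    return(res("in_frame_insertion", n_aa = delta %/% 3L,
               cds_delta = as.integer(delta)))
  res("in_frame_deletion", n_aa = (-delta) %/% 3L, cds_delta = as.integer(delta))
}

#' Classify Sanger clone sequences against a reference
#'
#' Transient-assay mode: each clone is a single sequence (no prevalence
#' logic). Clones aligning to the reference at under 50% identity are flagged
#' foreign and not classified.
#'
#' @param clone_seqs named character vector (e.g. from [read_fasta()]).
#' @param ref reference sequence.
#' @param guide_sites guide sites on `ref` (see
#'   [check_allele_compatibility()]).
#' @param gm optional [gene_model()] for coding-effect prediction.
#' @param scoring an [align_scoring()].
#' @param flank edit-window half-width.
#' @return data frame with one row per clone: `clone`, `n_variants`,
#'   `deletion_size` (largest deletion, 0 if none), `dual_cut`, per-site
#'   status columns, `effect`, `foreign`.
#' @export
classify_clones <- function(clone_seqs, ref, guide_sites, gm = NULL,
                            scoring = align_scoring(), flank = 10L) {
  rows <- lapply(names(clone_seqs), function(id) {
    seq <- clone_seqs[[id]]
    vars <- align_global(seq, ref, scoring)
    aligned_cols <- max(nchar(seq), nchar(ref))
    ident <- 1 - (nrow(vars[vars$type == "substitution", , drop = FALSE]) +
                  sum(nchar(vars$ref[vars$type == "deletion"])) +
                  sum(nchar(vars$alt[vars$type == "insertion"]))) / aligned_cols
    if (ident < 0.5) {
      row <- data.frame(clone = id, n_variants = NA_integer_,
                        deletion_size = NA_integer_, dual_cut = NA,
                        effect = NA_character_, foreign = TRUE,
                        stringsAsFactors = FALSE)
      for (gs in guide_sites) row[[paste0("site_", gs$guide)]] <- NA_character_
      return(row)
    }
    se <- call_site_edits(vars, guide_sites, flank = flank, ref = ref)
    dels <- nchar(vars$ref[vars$type == "deletion"])
    eff <- if (!is.null(gm)) predict_coding_effect(vars, gm, ref)$effect
           else NA_character_
    row <- data.frame(clone = id, n_variants = nrow(vars),
                      deletion_size = if (length(dels)) max(dels) else 0L,
                      dual_cut = se$dual_cut, effect = eff, foreign = FALSE,
                      stringsAsFactors = FALSE)
    for (nm in names(se$site_status)) row[[paste0("site_", nm)]] <- se$site_status[[nm]]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "deletion_histogram") <-
    table(out$deletion_size[!out$foreign & out$deletion_size > 0])
  out
}

#' Summarize a sample into variant groups
#'
#' One row per variant group — a distinct (assigned allele class, edit)
#' combination — with summed prevalence, per-site status, dual-cut flag and
#' coding effect. The number of distinct groups is the sample's
#' figure-of-merit (the "alignment groups" of an amplicon experiment).
#' Grouping is invariant to read order and depth scaling.
#'
#' @param edit_calls data frame from [classify_sample()] /
#'   [run_amplicon()] with columns `assigned`, `variant_sig`, `prevalence`,
#'   site-status columns, `dual_cut`, `effect`.
#' @return data frame of groups, sorted by prevalence descending; attribute
#'   `n_groups` gives the count.
#' @export
summarize_sample <- function(edit_calls) {
  if (nrow(edit_calls) == 0) {
    out <- edit_calls
    attr(out, "n_groups") <- 0L
    return(out)
  }
  key <- paste(edit_calls$assigned, edit_calls$variant_sig, sep = "|")
  rows <- lapply(split(seq_len(nrow(edit_calls)), key), function(idx) {
    first <- edit_calls[idx[1], , drop = FALSE]
    first$prevalence <- sum(edit_calls$prevalence[idx])
    first$count <- sum(edit_calls$count[idx])
    first
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$prevalence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_groups") <- nrow(out)
  out
}
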