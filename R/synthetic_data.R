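# Synthetic five-allele locus generator: haplotypes differing by intronic
# indels and coding SNPs (one allele carrying a seed mismatch under guide 1),
# CRISPR editing outcomes at two cut sites including dual-cut deletions, PCR
# allele bias, and Phred-scaled paired-end reads with truth labels.

#' Simulation configuration
#'
#' Defaults emulate a highly heterozygous octoploid locus sequenced as a
#' ~440-bp amplicon: five allele haplotypes (two of them identical within the
#' amplicon), intronic indels, four synonymous plus eight non-synonymous
#' coding SNPs, a dual-guide design with the two cuts 198 bp apart
#' (PAM-to-PAM), one allele with a seed mismatch under guide 1 (never cut
#' there), 2 x 250 nt read pairs at depth 5000 and flat Q30 error.
#'
#' @param seed RNG seed; every random draw flows from it.
#' @param depth number of molecules = read pairs.
#' @param read_len read length (default 250).
#' @param phred flat Phred quality of simulated bases (default 30).
#' @param pcr_weights per-allele amplification weights (need not sum to 1);
#'   set one near 0 to emulate PCR dropout.
#' @param efficiency per-guide cleavage probability on cleavable alleles.
#' @param dual_cut_prob probability that a molecule with both sites cleavable
#'   carries a single cut-to-cut deletion.
#' @param indel_geom_p geometric parameter of the NHEJ indel size spectrum.
#' @param indel_max indel size cap (default 30).
#' @param del_frac fraction of NHEJ events that are deletions (default 0.7).
#' @param dual_jitter maximum extra resection (bases, per side) of dual-cut
#'   deletions.
#' @param error_rate per-base substitution error probability; default derived
#'   from `phred` (`10^(-phred/10)`); set 0 for noise-free reads.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, depth = 5000L, read_len = 250L, phred = 30L,
                       pcr_weights = c(a1 = 0.22, a2 = 0.22, a3 = 0.20,
                                       a4 = 0.19, a5 = 0.17),
                       efficiency = c(g1 = 0.9, g2 = 0.8),
                       dual_cut_prob = 0.35, indel_geom_p = 0.3,
                       indel_max = 30L, del_frac = 0.7, dual_jitter = 6L,
                       error_rate = NULL) {
  stopifnot(all(pcr_weights >= 0), sum(pcr_weights) > 0,
            all(efficiency >= 0 & efficiency <= 1),
            dual_cut_prob >= 0, dual_cut_prob <= 1)
  if (is.null(error_rate)) error_rate <- 10^(-phred / 10)
  stopifnot(error_rate >= 0, error_rate < 1)
  structure(list(seed = as.integer(seed), depth = as.integer(depth),
                 read_len = as.integer(read_len), phred = as.integer(phred),
                 pcr_weights = pcr_weights, efficiency = efficiency,
                 dual_cut_prob = dual_cut_prob, indel_geom_p = indel_geom_p,
                 indel_max = as.integer(indel_max), del_frac = del_frac,
                 dual_jitter = as.integer(dual_jitter),
                 error_rate = error_rate),
            class = "sim_config")
}

# Fixed architecture of the simulated locus (0-based half-open):
# flank5 [0,40) | exon1 [40,160) | intron1 [160,266), 106 nt | exon2
# [266,336) | intron2 [336,376) | exon3 [376,399) | flank3 [399,439).
# CDS starts 12 nt into exon1 and ends with a TAA at the end of exon3.
# Guide 1: protospacer [93,113), PAM [113,116), cut 110 (exon 1).
# Guide 2: protospacer [291,311), PAM [311,314), cut 308 (exon 2).
# PAM-to-PAM spacing 198 bp; the 106-nt intron 1 sits between the cuts.
sim_arch <- function() {
  list(len = 439L,
       exons = rbind(c(40L, 160L), c(266L, 336L), c(376L, 399L)),
       cds_start_offset = 12L,
       g1 = list(proto = c(93L, 113L), pam = c(113L, 116L), cut = 110L),
       g2 = list(proto = c(291L, 311L), pam = c(311L, 314L), cut = 308L),
       # masked target windows (protospacer+PAM +/- 10) on the base allele
       masks = rbind(c(83L, 126L), c(281L, 324L)),
       # coding regions outside the masks, grouped by whether they survive
       # the widest dual-cut deletion [cut1 - jitter, cut2 + jitter)
       snp_regions_safe = rbind(c(52L, 83L), c(324L, 336L), c(390L, 396L)),
       snp_regions_span = rbind(c(126L, 160L), c(266L, 281L)))
}

sim_gene_model <- function(exons = sim_arch()$exons) {
  gene_model(exons, strand = "+", cds_start_offset = sim_arch()$cds_start_offset)
}

# genomic position (0-based) -> CDS index (0-based) or NA
cds_index_of <- function(gpos, gm) {
  spliced <- 0L
  for (j in seq_len(nrow(gm$exons))) {
    if (gpos >= gm$exons[j, 1] && gpos < gm$exons[j, 2]) {
      tx <- spliced + (gpos - gm$exons[j, 1])
      cd <- tx - gm$cds_start_offset
      return(if (cd >= 0) cd else NA_integer_)
    }
    spliced <- spliced + gm$exons[j, 2] - gm$exons[j, 1]
  }
  NA_integer_
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE != "*"], character(0))

#' Simulate the reference allele set of a polymorphic locus
#'
#' Builds a 439-nt three-exon base haplotype (intron 1 fixed at 106 nt) and
#' derives five alleles: two identical within the amplicon (a shared,
#' indistinguishable class), and three carrying intron-2 indels plus coding
#' SNPs (4 synonymous + 8 non-synonymous in total). Allele `a5` additionally
#' carries a substitution in the seed of guide 1, abolishing its cleavage
#' there. Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return an [allele_set()] with attributes `snp_table` (planted SNPs:
#'   `allele`, `pos`, `ref`, `alt`, `synonymous`, `in_seed`) and
#'   `base_masks` (the target-window masks on the base allele).
#' @export
simulate_locus <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  arch <- sim_arch()
  gm <- sim_gene_model()
  L <- arch$len
  ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  # CDS as sense codons, terminal TAA
  cds_pos <- integer(0)
  spliced <- 0L
  for (j in seq_len(nrow(gm$exons))) {
    idx <- gm$exons[j, 1]:(gm$exons[j, 2] - 1L)
    keep <- (spliced + seq_along(idx) - 1L) >= gm$cds_start_offset
    cds_pos <- c(cds_pos, idx[keep])
    spliced <- spliced + length(idx)
  }
  n_codons <- length(cds_pos) %/% 3L
  codons <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  codons[n_codons] <- "TAA"
  ch[cds_pos + 1L] <- strsplit(paste(codons, collapse = ""), "")[[1]]

  # canonical splice dinucleotides
  intr <- introns(gm)
  for (j in seq_len(nrow(intr))) {
    ch[intr[j, 1] + 1L] <- "G"; ch[intr[j, 1] + 2L] <- "T"
    ch[intr[j, 2] - 1L] <- "A"; ch[intr[j, 2]] <- "G"
  }

  # impose NGG PAMs; repair any stop codon this creates (never at the real
  # terminal codon, which lies far from both PAMs)
  for (g in list(arch$g1, arch$g2)) {
    ch[g$pam[1] + 2L] <- "G"
    ch[g$pam[1] + 3L] <- "G"
  }
  repeat {
    fixed <- TRUE
    for (ci in seq_len(n_codons - 1L)) {
      cp <- cds_pos[(3L * (ci - 1L) + 1L):(3L * ci)]
      if (paste(ch[cp + 1L], collapse = "") %in% c("TAA", "TAG", "TGA")) {
        ch[cp[1] + 1L] <- "C"
        fixed <- FALSE
      }
    }
    if (fixed) break
  }
  # terminal-exon codons 61-64 are fixed to CTA-ACC-CCT-AAC: sense in frame
  # 0 but stop-containing in both shifted frames, so any upstream frameshift
  # reaching exon 3 meets a premature termination codon (real 3' sequence
  # context is stop-rich in shifted frames; a short random CDS need not be)
  ch[cds_pos[181:192] + 1L] <- strsplit("CTAACCCCTAAC", "")[[1]]
  base <- paste(ch, collapse = "")

  # helper: is ref->alt at genomic pos synonymous on the base sequence?
  is_syn <- function(pos, alt) {
    cd <- cds_index_of(pos, gm)
    ci <- cd %/% 3L
    cp <- cds_pos[(3L * ci + 1L):(3L * ci + 3L)]
    cod <- ch[cp + 1L]
    new <- cod
    new[which(cp == pos)] <- alt
    aa0 <- Biostrings::GENETIC_CODE[[paste(cod, collapse = "")]]
    aa1 <- Biostrings::GENETIC_CODE[[paste(new, collapse = "")]]
    if (aa1 == "*") return(NA)           # never plant stops
    identical(aa0, aa1)
  }
  pick_snp <- function(region_rows, want_syn, used) {
    pool <- unlist(lapply(seq_len(nrow(region_rows)), function(j)
      region_rows[j, 1]:(region_rows[j, 2] - 1L)))
    pool <- setdiff(pool, used)
    for (pos in sample(pool)) {
      alts <- sample(setdiff(c("A", "C", "G", "T"), ch[pos + 1L]))
      for (alt in alts) {
        syn <- is_syn(pos, alt)
        if (!is.na(syn) && syn == want_syn)
          return(list(pos = pos, ref = ch[pos + 1L], alt = alt))
      }
    }
    stop("could not place a ", if (want_syn) "synonymous" else "non-synonymous",
         " SNP; widen the regions")
  }

  # per-allele SNP plan: (n_safe-region SNPs syn?, n_span-region SNPs syn?)
  plan <- list(
    a3 = c(FALSE, TRUE, FALSE, TRUE),    # 2 non-syn + 2 syn
    a4 = c(FALSE, FALSE, FALSE, TRUE),   # 3 non-syn + 1 syn
    a5 = c(FALSE, TRUE, FALSE))          # + seed SNP => 3 non-syn + 1 syn
  used <- integer(0)
  snp_rows <- list()
  alleles <- c(a1 = base, a2 = base)
  gms <- list(a1 = gm, a2 = gm)
  for (id in names(plan)) {
    muts <- list()
    for (k in seq_along(plan[[id]])) {
      # first two SNPs of each allele go to dual-deletion-surviving regions
      rg <- if (k <= 2) arch$snp_regions_safe else arch$snp_regions_span
      sp <- pick_snp(rg, plan[[id]][k], used)
      used <- c(used, sp$pos)
      muts[[k]] <- sp
      snp_rows[[paste(id, k)]] <- data.frame(
        allele = id, pos = sp$pos, ref = sp$ref, alt = sp$alt,
        synonymous = plan[[id]][k], in_seed = FALSE, stringsAsFactors = FALSE)
    }
    ac <- ch
    for (m in muts) ac[m$pos + 1L] <- m$alt
    if (id == "a5") {
      # seed mismatch under guide 1 (PAM-proximal protospacer base),
      # non-synonymous by construction (second codon position)
      pos <- 107L
      alt <- NULL
      for (a in sample(setdiff(c("A", "C", "G", "T"), ch[pos + 1L]))) {
        syn <- is_syn(pos, a)
        if (!is.na(syn) && !syn) { alt <- a; break }
      }
      ac[pos + 1L] <- alt
      snp_rows[["a5 seed"]] <- data.frame(
        allele = "a5", pos = pos, ref = ch[pos + 1L], alt = alt,
        synonymous = FALSE, in_seed = TRUE, stringsAsFactors = FALSE)
    }
    seq_id <- paste(ac, collapse = "")
    # intron-2 indels (outside masks and splice dinucleotides)
    if (id == "a3") {
      seq_id <- paste0(substr(seq_id, 1, 350), substr(seq_id, 356, L))
      gms[[id]] <- gene_model(rbind(gm$exons[1:2, ], gm$exons[3, ] - 5L),
                              cds_start_offset = gm$cds_start_offset)
    } else if (id == "a4") {
      ins <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                   collapse = "")
      seq_id <- paste0(substr(seq_id, 1, 355), ins, substr(seq_id, 356, L))
      gms[[id]] <- gene_model(rbind(gm$exons[1:2, ], gm$exons[3, ] + 6L),
                              cds_start_offset = gm$cds_start_offset)
    } else {
      seq_id <- paste0(substr(seq_id, 1, 345), substr(seq_id, 349, L))
      gms[[id]] <- gene_model(rbind(gm$exons[1:2, ], gm$exons[3, ] - 3L),
                              cds_start_offset = gm$cds_start_offset)
    }
    alleles[[id]] <- seq_id
  }

  guides <- list(
    guide_spec("g1", substr(base, arch$g1$proto[1] + 1L, arch$g1$proto[2]),
               "NGG", 12L),
    guide_spec("g2", substr(base, arch$g2$proto[1] + 1L, arch$g2$proto[2]),
               "NGG", 12L))
  aset <- allele_set("simlocus", alleles, gms, guides, anchor = "a1")
  snp_table <- do.call(rbind, snp_rows)
  rownames(snp_table) <- NULL
  # allele-frame coordinate of each SNP (positions downstream of the
  # intron-2 indels shift with them; `pos` stays on the base haplotype)
  shift <- c(a1 = 0L, a2 = 0L, a3 = -5L, a4 = 6L, a5 = -3L)
  brk <- c(a1 = Inf, a2 = Inf, a3 = 350, a4 = 355, a5 = 345)
  snp_table$allele_pos <- snp_table$pos +
    ifelse(snp_table$pos >= brk[snp_table$allele], shift[snp_table$allele], 0L)
  attr(aset, "snp_table") <- snp_table
  attr(aset, "base_masks") <- arch$masks
  aset
}

# one NHEJ indel at a cut site, as a variant_table row
draw_nhej_indel <- function(cut, cfg) {
  size <- min(stats::rgeom(1, cfg$indel_geom_p) + 1L, cfg$indel_max)
  if (runif(1) < cfg$del_frac) {
    start <- cut - sample.int(size + 1L, 1L) + 1L   # uniform in [cut-size, cut]
    list(type = "deletion", pos = start, size = size)
  } else {
    list(type = "insertion", pos = cut,
         ins = paste(sample(c("A", "C", "G", "T"), size, replace = TRUE),
                     collapse = ""))
  }
}

indel_to_variants <- function(ind, ref) {
  if (ind$type == "deletion") {
    v <- data.frame(pos = ind$pos,
                    ref = substr(ref, ind$pos + 1L, ind$pos + ind$size),
                    alt = "", type = "deletion", stringsAsFactors = FALSE)
  } else {
    v <- data.frame(pos = ind$pos, ref = "", alt = ind$ins,
                    type = "insertion", stringsAsFactors = FALSE)
  }
  class(v) <- c("variant_table", "data.frame")
  v
}

#' Simulate CRISPR editing of a molecule pool
#'
#' Each molecule draws its allele from the PCR weights, then its editing
#' outcome: on alleles where both guides are predicted to cleave, a dual-cut
#' deletion (cut to cut, with up to `dual_jitter` extra bases per side) with
#' probability `dual_cut_prob`; otherwise independent per-site NHEJ indels at
#' the cut positions with the per-guide efficiencies. The seed-mismatched
#' allele draws no guide-1 edits. The NHEJ outcome at each (allele, site) is
#' drawn once per simulation, so repair products recur across molecules as
#' they do in clonally propagated tissue. Deterministic under `cfg$seed`.
#'
#' @param aset an [allele_set()] from [simulate_locus()].
#' @param cfg a [sim_config()].
#' @return list with `seqs` (molecule sequences, length `cfg$depth`),
#'   `type_id` (per molecule), and `types`: the truth table, one row per
#'   distinct (allele, edit) molecule type with `allele`, `class`,
#'   `n_molecules`, `prevalence`, `site_g1`, `site_g2`, `dual_cut`, `effect`,
#'   `n_aa`, `edit_desc`.
#' @export
simulate_editing <- function(aset, cfg = sim_config()) {
  set.seed(cfg$seed + 1L)
  ids <- names(aset$alleles)
  # identical alleles form one truth class (indistinguishable in any read)
  seqsig <- match(unname(aset$alleles), unique(unname(aset$alleles)))
  class_of <- vapply(seq_along(ids), function(i)
    paste(ids[seqsig == seqsig[i]], collapse = "/"), "")
  names(class_of) <- ids

  sites <- lapply(aset$guides, function(g) check_allele_compatibility(g, aset))
  names(sites) <- vapply(aset$guides, `[[`, "", "name")
  cleavable <- vapply(ids, function(id) vapply(sites, function(s)
    isTRUE(s[[id]]$found) && isTRUE(s[[id]]$predicted_cleavage), logical(1)),
    logical(length(sites)))

  # fixed NHEJ repertoire and dual-deletion geometry per allele x site
  repertoire <- list()
  for (id in ids) {
    rep_id <- list()
    for (g in names(sites)) {
      if (cleavable[g, id])
        rep_id[[g]] <- draw_nhej_indel(sites[[g]][[id]]$cut, cfg)
    }
    if (all(cleavable[, id])) {
      cuts <- sort(vapply(names(sites), function(g) sites[[g]][[id]]$cut, 0L))
      j1 <- sample.int(cfg$dual_jitter + 1L, 1L) - 1L
      j2 <- sample.int(cfg$dual_jitter + 1L, 1L) - 1L
      rep_id$dual <- list(type = "deletion", pos = cuts[1] - j1,
                          size = (cuts[2] + j2) - (cuts[1] - j1))
    }
    repertoire[[id]] <- rep_id
  }

  w <- cfg$pcr_weights[ids]
  allele_draw <- sample(ids, cfg$depth, replace = TRUE, prob = w / sum(w))
  u_dual <- runif(cfg$depth)
  u_g <- matrix(runif(cfg$depth * length(sites)), ncol = length(sites),
                dimnames = list(NULL, names(sites)))
  outcome <- character(cfg$depth)
  for (i in seq_len(cfg$depth)) {
    id <- allele_draw[i]
    if (all(cleavable[, id]) && u_dual[i] < cfg$dual_cut_prob) {
      outcome[i] <- "dual"
    } else {
      hit <- names(sites)[cleavable[, id] &
                            u_g[i, ] < cfg$efficiency[seq_along(sites)]]
      outcome[i] <- if (length(hit)) paste(hit, collapse = "+") else "wt"
    }
  }
  type_key <- paste(allele_draw, outcome, sep = ":")

  types <- unique(data.frame(allele = allele_draw, outcome = outcome,
                             key = type_key, stringsAsFactors = FALSE))
  types <- types[order(types$key), , drop = FALSE]
  type_seqs <- character(nrow(types))
  rows <- list()
  for (t in seq_len(nrow(types))) {
    id <- types$allele[t]
    ref <- aset$alleles[[id]]
    gm <- aset$gene_models[[id]]
    vars <- empty_variants()
    if (types$outcome[t] == "dual") {
      vars <- indel_to_variants(repertoire[[id]]$dual, ref)
    } else if (types$outcome[t] != "wt") {
      for (g in strsplit(types$outcome[t], "+", fixed = TRUE)[[1]])
        vars <- rbind(vars, indel_to_variants(repertoire[[id]][[g]], ref))
      class(vars) <- c("variant_table", "data.frame")
    }
    type_seqs[t] <- apply_variants(ref, vars)
    gsites <- lapply(names(sites), function(g) sites[[g]][[id]])
    se <- call_site_edits(vars, gsites, ref = ref)
    eff <- predict_coding_effect(vars, gm, ref)
    rows[[t]] <- data.frame(
      type_id = types$key[t], allele = id, class = class_of[[id]],
      site_g1 = se$site_status[["g1"]], site_g2 = se$site_status[["g2"]],
      dual_cut = se$dual_cut, effect = eff$effect, n_aa = eff$n_aa,
      edit_desc = if (nrow(vars)) paste(sprintf("%d%s>%s", vars$pos, vars$ref,
                                                vars$alt), collapse = ";")
                  else "WT",
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  truth$n_molecules <- as.integer(table(type_key)[truth$type_id])
  truth$prevalence <- truth$n_molecules / cfg$depth
  truth$seq <- type_seqs
  # collapse types identical in class and sequence (alleles a1/a2 drawing
  # the same outcome label produce distinct keys but identical molecules)
  dedup_key <- paste(truth$class, truth$seq)
  if (anyDuplicated(dedup_key)) {
    keep <- !duplicated(dedup_key)
    remap <- setNames(truth$type_id[keep][match(dedup_key, dedup_key[keep])],
                      truth$type_id)
    type_key <- unname(remap[type_key])
    agg <- tapply(truth$n_molecules, dedup_key, sum)
    truth <- truth[keep, , drop = FALSE]
    truth$n_molecules <- as.integer(agg[paste(truth$class, truth$seq)])
    truth$prevalence <- truth$n_molecules / cfg$depth
  }
  rownames(truth) <- NULL
  list(seqs = truth$seq[match(type_key, truth$type_id)],
       type_id = type_key, types = truth)
}

#' Simulate paired-end reads from a molecule pool
#'
#' R1 reads the first `read_len` bases of each molecule; R2 the
#' reverse-complement of the last `read_len` (molecules shorter than the read
#' length are read end-to-end by both mates). Substitution errors are drawn
#' per base at the rate implied by `cfg$phred`; qualities are written flat at
#' that Phred score, offset 33. Deterministic under `cfg$seed`.
#'
#' @param molecules character vector of molecule sequences (from
#'   [simulate_editing()]).
#' @param cfg a [sim_config()].
#' @return list with `r1`, `r2` (`fastq_reads`; ids `m<i>` match molecule
#'   order).
#' @export
simulate_reads <- function(molecules, cfg = sim_config()) {
  set.seed(cfg$seed + 2L)
  n <- length(molecules)
  len <- nchar(molecules)
  rl <- pmin(len, cfg$read_len)
  r1 <- substr(molecules, 1L, rl)
  r2 <- revcomp(substr(molecules, len - rl + 1L, len))
  err <- cfg$error_rate %||% 10^(-cfg$phred / 10)
  add_errors <- function(seqs) {
    n_err <- rbinom(length(seqs), nchar(seqs), err)
    for (i in which(n_err > 0L)) {
      pos <- sample.int(nchar(seqs[i]), n_err[i])
      for (p in pos) {
        old <- substr(seqs[i], p, p)
        substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
    }
    seqs
  }
  r1 <- add_errors(r1)
  r2 <- add_errors(r2)
  qc <- intToUtf8(33L + cfg$phred)
  quals <- strrep(qc, rl)
  ids <- paste0("m", seq_len(n))
  list(r1 = fastq_reads(ids, r1, quals), r2 = fastq_reads(ids, r2, quals))
}

#' Simulate a complete sequencing run and write it to disk
#'
#' Convenience wrapper: locus, editing, reads; writes `R1.fastq`,
#' `R2.fastq`, `locus_spec.json` and `truth.tsv` into `out_dir`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `aset`, `edit` (editing truth) and file
#'   paths.
#' @export
simulate_run <- function(cfg = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aset <- simulate_locus(cfg)
  ed <- simulate_editing(aset, cfg)
  rd <- simulate_reads(ed$seqs, cfg)
  paths <- list(r1 = file.path(out_dir, "R1.fastq"),
                r2 = file.path(out_dir, "R2.fastq"),
                locus = file.path(out_dir, "locus_spec.json"),
                truth = file.path(out_dir, "truth.tsv"))
  write_fastq(rd$r1, paths$r1)
  write_fastq(rd$r2, paths$r2)
  write_locus_spec(aset, paths$locus)
  truth <- ed$types[, setdiff(names(ed$types), "seq")]
  write.table(truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(aset = aset, edit = ed, paths = paths))
}

#' Compare pipeline output with simulation truth
#'
#' For every truth molecule type at or above `min_prev`, checks whether the
#' pipeline reported a variant group with the same allele class, the same
#' per-site edit statuses, the same dual-cut flag and the same coding effect.
#'
#' @param run an `amplicon_run`.
#' @param truth the `types` truth table from [simulate_editing()].
#' @param min_prev truth-prevalence cutoff for evaluated groups (default
#'   0.02).
#' @return data frame, one row per evaluated truth group, with `recovered`;
#'   attribute `recovery` gives the fraction recovered.
#' @export
compare_to_truth <- function(run, truth, min_prev = 0.02) {
  tr <- truth[truth$prevalence >= min_prev, , drop = FALSE]
  g <- run$groups
  tr$recovered <- vapply(seq_len(nrow(tr)), function(i) {
    any(g$assigned == tr$class[i] &
        g$site_g1 == tr$site_g1[i] & g$site_g2 == tr$site_g2[i] &
        g$dual_cut == tr$dual_cut[i] & g$effect == tr$effect[i])
  }, logical(1))
  attr(tr, "recovery") <- mean(tr$recovered)
  tr
}
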