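test_that("identical sequences align with no variants", {
  s <- rand_dna(50)
  expect_equal(nrow(align_global(s, s)), 0)
})

test_that("indels inside repeats are reported left-aligned", {
  ref <- "ACGTAAAAAACGT"          # A6 homopolymer at 0-based 4..9
  alt <- "ACGTAAACGT"             # 3-base deletion somewhere in it
  v <- align_global(alt, ref)
  expect_equal(v$type, "deletion")
  expect_equal(v$pos, 4L)          # leftmost admissible placement
  # every admissible placement reconstructs the same string
  for (p in 4:7) {
    vv <- v; vv$pos <- p; vv$ref <- substr(ref, p + 1, p + 3)
    expect_equal(apply_variants(ref, vv), alt)
  }
  # insertion flavour
  vi <- align_global("ACGTAAAAAAAACGT", ref)
  expect_equal(vi$type, "insertion")
  expect_equal(vi$pos, 4L)
})

test_that("alignment score equals the exhaustive enumeration oracle", {
  set.seed(33)
  for (rep in 1:25) {
    a <- rand_dna(sample(3:8, 1))
    b <- rand_dna(sample(3:8, 1))
    got <- attr(align_global(a, b), "score")
    expect_equal(got, oracle_global_score(a, b), info = paste(a, b))
  }
})

test_that("applying extracted variants reconstructs the query exactly", {
  set.seed(99)
  for (rep in 1:200) {
    ref <- rand_dna(sample(60:120, 1))
    seq <- ref
    for (k in seq_len(sample(1:3, 1))) {      # random edits
      op <- sample(c("sub", "del", "ins"), 1)
      p <- sample(nchar(seq) - 10, 1) + 4
      if (op == "sub") {
        substr(seq, p, p) <- sample(c("A", "C", "G", "T"), 1)
      } else if (op == "del") {
        n <- sample(1:8, 1)
        seq <- paste0(substr(seq, 1, p), substr(seq, p + n + 1, nchar(seq)))
      } else {
        seq <- paste0(substr(seq, 1, p), rand_dna(sample(1:8, 1)),
                      substr(seq, p + 1, nchar(seq)))
      }
    }
    v <- align_global(seq, ref)
    expect_equal(apply_variants(ref, v), seq)
  }
})

# gene model used throughout: 106-nt intron 1 between the two target exons
sim_gm <- function() gene_model(rbind(c(40L, 160L), c(266L, 336L),
                                      c(376L, 399L)),
                                cds_start_offset = 12L)

test_that("site edits and dual cuts are called from variant intervals", {
  sites <- list(list(guide = "g1", found = TRUE, cut = 110L),
                list(guide = "g2", found = TRUE, cut = 308L))
  # no variants
  se <- call_site_edits(empty_var_tbl(), sites)
  expect_equal(unname(se$site_status), c("wild-type", "wild-type"))
  expect_false(se$dual_cut)
  # one 210-nt deletion spanning both cuts (cut-to-cut distance is 198)
  del <- var_tbl(pos = 105L, ref = strrep("A", 210), alt = "",
                 type = "deletion")
  se <- call_site_edits(del, sites)
  expect_equal(unname(se$site_status), c("edited", "edited"))
  expect_true(se$dual_cut)
  # 1-base insertion exactly at cut2
  ins <- var_tbl(pos = 308L, ref = "", alt = "T", type = "insertion")
  se <- call_site_edits(ins, sites)
  expect_equal(unname(se$site_status), c("wild-type", "edited"))
  expect_false(se$dual_cut)
  # absent site is not assessable
  sites2 <- list(list(guide = "g1", found = FALSE), sites[[2]])
  se <- call_site_edits(ins, sites2)
  expect_equal(se$site_status[["g1"]], "not_assessable")
})

test_that("dual-cut deletions of 187/193/188 nt give 27 aa, 29 aa and a PTC", {
  aset <- simulate_locus(sim_config(seed = 3))
  ref <- aset$alleles[["a1"]]
  gm <- aset$gene_models[["a1"]]
  mkdel <- function(start, size)
    var_tbl(pos = start, ref = substr(ref, start + 1, start + size), alt = "",
            type = "deletion")
  # deletions spanning the 106-nt intron 1: CDS loses size - 106 nt
  e187 <- predict_coding_effect(mkdel(100L, 187L), gm, ref)
  expect_equal(e187$effect, "in_frame_deletion")
  expect_equal(e187$n_aa, 27L)
  e193 <- predict_coding_effect(mkdel(100L, 193L), gm, ref)
  expect_equal(e193$effect, "in_frame_deletion")
  expect_equal(e193$n_aa, 29L)
  e188 <- predict_coding_effect(mkdel(100L, 188L), gm, ref)
  expect_equal(e188$effect, "frameshift_with_PTC")
})

test_that("small coding edits classify by length arithmetic", {
  aset <- simulate_locus(sim_config(seed = 3))
  ref <- aset$alleles[["a1"]]
  gm <- aset$gene_models[["a1"]]
  # 3-nt exonic deletion not creating a stop -> 1 aa lost
  for (start in c(60L, 130L, 290L)) {
    v <- var_tbl(pos = start, ref = substr(ref, start + 1, start + 3),
                 alt = "", type = "deletion")
    e <- predict_coding_effect(v, gm, ref)
    expect_true(e$effect %in% c("in_frame_deletion", "premature_stop"))
    if (e$effect == "in_frame_deletion") expect_equal(e$n_aa, 1L)
  }
  # synonymous substitution -> silent; no variants -> none
  expect_equal(predict_coding_effect(empty_var_tbl(), gm, ref)$effect, "none")
})

test_that("frameshift is equivalent to net CDS change not divisible by 3", {
  set.seed(55)
  aset <- simulate_locus(sim_config(seed = 3))
  ref <- aset$alleles[["a1"]]
  gm <- aset$gene_models[["a1"]]
  n_checked <- 0
  for (rep in 1:300) {
    # random exonic indel clear of splice sites
    exonic <- c(55:150, 270:330, 380:390)
    p <- sample(exonic, 1)
    if (runif(1) < 0.5) {
      n <- sample(1:12, 1)
      if (p + n > 395) next
      v <- var_tbl(pos = p, ref = substr(ref, p + 1, p + n), alt = "",
                   type = "deletion")
    } else {
      v <- var_tbl(pos = p, ref = "", alt = rand_dna(sample(1:12, 1)),
                   type = "insertion")
    }
    e <- predict_coding_effect(v, gm, ref)
    if (e$effect %in% c("splice_disrupted", "start_lost")) next
    n_checked <- n_checked + 1
    fs <- e$effect %in% c("frameshift", "frameshift_with_PTC")
    expect_equal(fs, e$cds_delta %% 3 != 0,
                 info = sprintf("pos %d delta %d effect %s", p, e$cds_delta,
                                e$effect))
  }
  expect_gt(n_checked, 200)
})

test_that("breaking one splice site without removing the intron disrupts splicing", {
  aset <- simulate_locus(sim_config(seed = 3))
  ref <- aset$alleles[["a1"]]
  gm <- aset$gene_models[["a1"]]
  # deletion over the intron-1 donor (GT at 160), intron retained
  v <- var_tbl(pos = 158L, ref = substr(ref, 159, 164), alt = "",
               type = "deletion")
  expect_equal(predict_coding_effect(v, gm, ref)$effect, "splice_disrupted")
  # deletion of the entire intron plus flanking exon ends fuses exons instead
  v2 <- var_tbl(pos = 155L, ref = substr(ref, 156, 270), alt = "",
                type = "deletion")  # 115 nt: 5 exon1 + 106 intron + 4 exon2
  e2 <- predict_coding_effect(v2, gm, ref)
  expect_false(e2$effect == "splice_disrupted")
  expect_equal(e2$cds_delta, -9L)
  expect_equal(e2$effect, "in_frame_deletion")
})

test_that("clone classification handles wild-type, dual-cut and foreign clones", {
  aset <- simulate_locus(sim_config(seed = 3))
  ref <- aset$alleles[["a1"]]
  g1 <- locate_guide(aset$guides[[1]], ref)
  g2 <- locate_guide(aset$guides[[2]], ref)
  dual205 <- apply_variants(ref, var_tbl(pos = 105L,
                                         ref = substr(ref, 106, 310),
                                         alt = "", type = "deletion"))
  del5 <- apply_variants(ref, var_tbl(pos = 306L, ref = substr(ref, 307, 311),
                                      alt = "", type = "deletion"))
  clones <- c(wt = ref, dual = dual205, site2 = del5, foreign = rand_dna(400))
  tab <- classify_clones(clones, ref, list(g1, g2), gm = aset$gene_models[["a1"]])
  expect_equal(tab$n_variants[tab$clone == "wt"], 0L)
  expect_true(tab$dual_cut[tab$clone == "dual"])
  expect_equal(tab$deletion_size[tab$clone == "dual"], 205L)
  expect_equal(tab$site_g1[tab$clone == "site2"], "wild-type")
  expect_equal(tab$site_g2[tab$clone == "site2"], "edited")
  expect_equal(tab$deletion_size[tab$clone == "site2"], 5L)
  expect_true(tab$foreign[tab$clone == "foreign"])
})

test_that("variant groups are invariant to read order and depth scaling", {
  calls <- data.frame(
    assigned = c("a1/a2", "a1/a2", "a3", "a3", "a4"),
    variant_sig = c("WT", "110A>", "WT", "110A>", "200>TT"),
    prevalence = c(0.3, 0.2, 0.2, 0.2, 0.1),
    count = c(30L, 20L, 20L, 20L, 10L),
    site_g1 = "wild-type", site_g2 = "wild-type", dual_cut = FALSE,
    effect = "none", stringsAsFactors = FALSE)
  g <- summarize_sample(calls)
  expect_equal(attr(g, "n_groups"), 5L)
  # shuffle rows: same groups
  set.seed(1)
  g2 <- summarize_sample(calls[sample(nrow(calls)), ])
  expect_equal(attr(g2, "n_groups"), 5L)
  expect_equal(g$variant_sig, g2$variant_sig)
  # depth scaling: duplicate rows with same signatures, halve prevalences
  calls3 <- rbind(calls, calls)
  calls3$prevalence <- calls3$prevalence / 2
  g3 <- summarize_sample(calls3)
  expect_equal(attr(g3, "n_groups"), 5L)
  expect_equal(sort(g3$prevalence), sort(g$prevalence))
})

test_that("VCF export writes anchored, 1-based records", {
  ref <- "ACGTACGTAA"
  v <- rbind(var_tbl(2L, "G", "C", "substitution"),
             var_tbl(4L, "AC", "", "deletion"),
             var_tbl(7L, "", "TT", "insertion"))
  class(v) <- c("variant_table", "data.frame")
  f <- tempfile(fileext = ".vcf")
  write_vcf(v, ref, f)
  lines <- grep("^[^#]", readLines(f), value = TRUE)
  expect_equal(length(lines), 3)
  flds <- do.call(rbind, strsplit(lines, "\t"))
  expect_equal(flds[1, 2], "3"); expect_equal(flds[1, 4], "G")
  expect_equal(flds[2, 2], "4"); expect_equal(flds[2, 4], "TAC")
  expect_equal(flds[2, 5], "T")
  expect_equal(flds[3, 2], "7"); expect_equal(flds[3, 5], "GTT")
})
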