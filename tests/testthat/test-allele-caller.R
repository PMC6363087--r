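test_that("prevalence threshold is inclusive at exactly 1%", {
  cl <- data.frame(rank = 1:3, seq = c("AA", "AT", "AG"),
                   count = c(981L, 10L, 9L),
                   prevalence = c(0.981, 0.010, 0.009))
  class(cl) <- c("cluster_table", "data.frame")
  kept <- call_variant_clusters(cl, min_prev = 0.01)
  expect_equal(kept$seq, c("AA", "AT"))              # 1.0% kept, 0.9% dropped
  expect_equal(attr(kept, "below_threshold")$seq, "AG")
  # a single cluster (prevalence 1) is kept
  one <- cluster_exact("ACGT")
  expect_equal(nrow(call_variant_clusters(one)), 1)
})

test_that("fingerprints match the exhaustive column-scan oracle on toy alleles", {
  aset <- toy_allele_set()
  masks <- rbind(c(40L, 50L))
  mw <- list(a1 = masks, a2 = masks, a3 = masks)
  fps <- build_fingerprints(aset, masked_windows = mw)
  oracle <- oracle_exclusive_positions(aset$alleles, masks)
  for (id in names(aset$alleles)) {
    got <- sort(fps$classes[[id]]$diagnostic$allele_pos)
    expect_equal(got, sort(oracle[[id]]), info = id)
  }
  # hand-placed SNPs: a2 exclusive at 10 and 30, a3 exclusive at 20
  expect_setequal(fps$classes[["a2"]]$diagnostic$allele_pos, c(10L, 30L))
  expect_setequal(fps$classes[["a3"]]$diagnostic$allele_pos, 20L)
})

test_that("fingerprints respect masked windows", {
  aset <- toy_allele_set()
  # mask covering a3's only SNP: a3 becomes indistinguishable from a1
  masks <- rbind(c(15L, 25L))
  mw <- list(a1 = masks, a2 = masks, a3 = masks)
  fps <- build_fingerprints(aset, masked_windows = mw)
  expect_equal(length(fps$classes), 2)
  expect_true("a1/a3" %in% names(fps$classes))
  expect_equal(sort(fps$classes[["a1/a3"]]$members), c("a1", "a3"))
})

test_that("identical alleles form a shared ambiguity class", {
  fps <- build_fingerprints(simulate_locus(sim_config(seed = 2)),
                            trim = c(35L, 35L))
  expect_true("a1/a2" %in% names(fps$classes))
  expect_equal(fps$classes[["a1/a2"]]$members, c("a1", "a2"))
  # diagnostic positions never intersect masked windows (checked on the
  # representative's own coordinates against its guide-site masks)
  aset <- simulate_locus(sim_config(seed = 2))
  mw <- default_masked_windows(aset)
  for (fp in fps$classes) {
    m <- mw[[fp$representative]]
    for (j in seq_len(nrow(m)))
      expect_false(any(fp$diagnostic$allele_pos >= m[j, 1] &
                       fp$diagnostic$allele_pos < m[j, 2]),
                   info = fp$class_id)
  }
})

test_that("a single-allele genotype assigns every cluster to it", {
  seq <- rand_dna(80)
  gm <- gene_model(rbind(c(0L, 80L)))
  aset <- allele_set("solo", c(only = seq), list(only = gm))
  fps <- build_fingerprints(aset)
  expect_equal(nrow(fps$classes[["only"]]$diagnostic), 0)
  a <- assign_allele(seq, fps, aset)
  expect_equal(a$assigned, "only")
})

test_that("clusters assign to their source allele, tolerating masked edits", {
  cfg <- sim_config(seed = 4)
  aset <- simulate_locus(cfg)
  fps <- build_fingerprints(aset, trim = c(35L, 35L))
  trim_win <- function(s) substr(s, 36, nchar(s) - 35)
  # verbatim allele -> its class, score 1
  for (id in names(aset$alleles)) {
    a <- assign_allele(trim_win(aset$alleles[[id]]), fps, aset)
    expect_true(grepl(id, a$assigned))
    expect_equal(a$score, 1.0)
  }
  # a4 with a 5-base deletion inside the guide-2 masked window still assigns
  ref <- aset$alleles[["a4"]]
  cut2 <- locate_guide(aset$guides[[2]], ref)$cut
  edited <- apply_variants(ref, var_tbl(cut2 - 2L,
                                        substr(ref, cut2 - 1, cut2 + 3), "",
                                        "deletion"))
  a <- assign_allele(trim_win(edited), fps, aset)
  expect_equal(a$assigned, "a4")
})

test_that("edits strictly inside masked windows never change the assignment", {
  cfg <- sim_config(seed = 6)
  aset <- simulate_locus(cfg)
  fps <- build_fingerprints(aset, trim = c(35L, 35L))
  trim_win <- function(s) substr(s, 36, nchar(s) - 35)
  mw <- default_masked_windows(aset)
  set.seed(60)
  for (id in c("a3", "a4", "a5")) {
    ref <- aset$alleles[[id]]
    base_call <- assign_allele(trim_win(ref), fps, aset)$assigned
    for (rep in 1:10) {
      m <- mw[[id]][sample(nrow(mw[[id]]), 1), ]
      p <- sample((m[1] + 3L):(m[2] - 8L), 1)
      v <- switch(sample(c("sub", "del", "ins"), 1),
        sub = var_tbl(p, substr(ref, p + 1, p + 1),
                      sample(setdiff(c("A", "C", "G", "T"),
                                     substr(ref, p + 1, p + 1)), 1),
                      "substitution"),
        del = var_tbl(p, substr(ref, p + 1, p + 4), "", "deletion"),
        ins = var_tbl(p, "", rand_dna(3), "insertion"))
      got <- assign_allele(trim_win(apply_variants(ref, v)), fps, aset)$assigned
      expect_equal(got, base_call, info = paste(id, v$type, p))
    }
  }
})

test_that("rescue recovers a dropout allele only from matching clusters", {
  cfg <- sim_config(seed = 8, depth = 3000,
                    pcr_weights = c(a1 = 0.25, a2 = 0.25, a3 = 0.24,
                                    a4 = 0.004, a5 = 0.256))
  aset <- simulate_locus(cfg)
  ed <- simulate_editing(aset, cfg)
  rd <- simulate_reads(ed$seqs, cfg)
  run <- run_amplicon(rd$r1, rd$r2, aset)
  # a4 absent from the main >= 1% call set, recovered by rescue
  expect_false(any(run$edit_calls$assigned == "a4" & !run$edit_calls$rescued))
  resc <- run$edit_calls[run$edit_calls$rescued, , drop = FALSE]
  expect_gt(nrow(resc), 0)
  expect_true(all(resc$assigned == "a4"))
  expect_true(all(resc$prevalence < 0.01))
  # rescue never fires for classes already present at >= 1%
  expect_false(any(run$edit_calls$rescued &
                   run$edit_calls$assigned %in%
                     c("a1/a2", "a3", "a5")))
})

test_that("rescue returns nothing when no reads carry the exclusive SNPs", {
  aset <- simulate_locus(sim_config(seed = 8))
  fps <- build_fingerprints(aset, trim = c(35L, 35L))
  # sub-threshold clusters from a different allele only
  other <- substr(aset$alleles[["a1"]], 36, nchar(aset$alleles[["a1"]]) - 35)
  below <- data.frame(rank = 1L, seq = other, count = 2L, prevalence = 0.002)
  class(below) <- c("cluster_table", "data.frame")
  res <- rescue_missing(below, fps$classes[["a4"]], fps, aset)
  expect_equal(nrow(res), 0)
})
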