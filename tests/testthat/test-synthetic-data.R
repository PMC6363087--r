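test_that("the simulated locus carries the designed polymorphism structure", {
  aset <- simulate_locus(sim_config(seed = 13))
  snp <- attr(aset, "snp_table")
  # four synonymous and eight non-synonymous coding SNPs
  expect_equal(sum(snp$synonymous), 4)
  expect_equal(sum(!snp$synonymous), 8)
  # exactly one allele has a guide-1 seed mismatch
  cc <- check_allele_compatibility(aset$guides[[1]], aset)
  seedless <- names(cc)[!vapply(cc, `[[`, TRUE, "predicted_cleavage")]
  expect_equal(seedless, "a5")
  # guide 2 is polymorphism-free on every allele
  cc2 <- check_allele_compatibility(aset$guides[[2]], aset)
  expect_true(all(vapply(cc2, `[[`, TRUE, "predicted_cleavage")))
  # two alleles identical within the amplicon; intron-2 indels elsewhere
  expect_equal(aset$alleles[["a1"]], aset$alleles[["a2"]])
  expect_equal(nchar(aset$alleles[["a3"]]), 439 - 5)
  expect_equal(nchar(aset$alleles[["a4"]]), 439 + 6)
  expect_equal(nchar(aset$alleles[["a5"]]), 439 - 3)
  # intron 1 is 106 nt on every allele
  for (id in names(aset$alleles))
    expect_equal(unname(introns(aset$gene_models[[id]])[1, 2] -
                        introns(aset$gene_models[[id]])[1, 1]), 106L)
  # reference CDSs translate without premature stops
  for (id in names(aset$alleles)) {
    p <- translate_cds(spliced_seq(aset$alleles[[id]],
                                   aset$gene_models[[id]])$cds, quiet = TRUE)
    expect_equal(nchar(p), 67L)  # 66 aa + terminal stop
    expect_equal(substr(p, 67, 67), "*")
  }
})

test_that("planted SNP count equals the table and positions are real", {
  aset <- simulate_locus(sim_config(seed = 14))
  snp <- attr(aset, "snp_table")
  base <- aset$alleles[["a1"]]
  for (i in seq_len(nrow(snp))) {
    al <- aset$alleles[[snp$allele[i]]]
    expect_equal(substr(base, snp$pos[i] + 1, snp$pos[i] + 1), snp$ref[i])
    expect_equal(substr(al, snp$allele_pos[i] + 1, snp$allele_pos[i] + 1),
                 snp$alt[i])
  }
})

test_that("editing respects efficiencies and the seed mismatch", {
  aset <- simulate_locus(sim_config(seed = 15))
  # zero efficiency -> all wild-type molecules
  ed0 <- simulate_editing(aset, sim_config(seed = 15, depth = 300,
                                           efficiency = c(g1 = 0, g2 = 0),
                                           dual_cut_prob = 0))
  expect_true(all(ed0$types$effect == "none"))
  expect_true(all(ed0$types$site_g1 == "wild-type"))
  # full efficiency + certain dual cut -> every cleavable molecule dual
  ed1 <- simulate_editing(aset, sim_config(seed = 15, depth = 300,
                                           efficiency = c(g1 = 1, g2 = 1),
                                           dual_cut_prob = 1))
  t1 <- ed1$types
  expect_true(all(t1$dual_cut[t1$class != "a5"]))
  # the seed-mismatched allele never shows a guide-1 edit
  for (s in 1:4) {
    ed <- simulate_editing(aset, sim_config(seed = s, depth = 500))
    expect_true(all(ed$types$site_g1[ed$types$class == "a5"] == "wild-type"))
    expect_false(any(ed$types$dual_cut[ed$types$class == "a5"]))
  }
})

test_that("the dual-cut fraction is binomially consistent with its probability", {
  aset <- simulate_locus(sim_config(seed = 16))
  p <- 0.35
  cfg <- sim_config(seed = 16, depth = 10000, dual_cut_prob = p)
  ed <- simulate_editing(aset, cfg)
  # restrict to molecules of dual-capable classes
  capable <- ed$types$class != "a5"
  n_capable <- sum(ed$types$n_molecules[capable])
  n_dual <- sum(ed$types$n_molecules[capable & ed$types$dual_cut])
  se <- sqrt(p * (1 - p) / n_capable)
  expect_lt(abs(n_dual / n_capable - p), 3 * se)
})

test_that("reads mirror their molecules and carry the configured error rate", {
  aset <- simulate_locus(sim_config(seed = 17))
  cfg0 <- sim_config(seed = 17, depth = 300, error_rate = 0)
  ed <- simulate_editing(aset, cfg0)
  rd <- simulate_reads(ed$seqs, cfg0)
  # noise-free: merged reads reconstruct molecules exactly
  m <- merge_pairs(rd$r1, rd$r2)
  expect_equal(nrow(m), 300)
  expect_equal(m$seq, ed$seqs)
  # error rate within 3 sigma of the Phred expectation over >= 1e5 bases
  cfg30 <- sim_config(seed = 18, depth = 300, phred = 30)
  rd30 <- simulate_reads(ed$seqs[1:300], cfg30)
  n_mm <- 0; n_bases <- 0
  for (i in 1:300) {
    truth <- substr(ed$seqs[i], 1, nchar(rd30$r1$seq[i]))
    n_mm <- n_mm + sum(strsplit(rd30$r1$seq[i], "")[[1]] !=
                       strsplit(truth, "")[[1]])
    n_bases <- n_bases + nchar(truth)
  }
  expect_gt(n_bases, 6e4)
  p <- 0.001
  expect_lt(abs(n_mm / n_bases - p), 3 * sqrt(p * (1 - p) / n_bases))
})

test_that("simulation output is byte-identical under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  simulate_run(sim_config(seed = 19, depth = 50), d1)
  simulate_run(sim_config(seed = 19, depth = 50), d2)
  for (f in c("R1.fastq", "R2.fastq", "locus_spec.json", "truth.tsv")) {
    a <- file.path(d1, f); b <- file.path(d2, f)
    expect_identical(readBin(a, "raw", file.size(a)),
                     readBin(b, "raw", file.size(b)), info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
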