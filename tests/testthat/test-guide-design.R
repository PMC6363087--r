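test_that("site enumeration matches the sliding-window oracle", {
  set.seed(21)
  for (rep in 1:5) {
    seq <- rand_dna(200)
    got <- find_sites(seq)
    exp <- oracle_find_sites(seq)
    expect_equal(nrow(got), nrow(exp))
    expect_equal(got$start, exp$start)
    expect_equal(got$strand, exp$strand)
    expect_equal(got$protospacer, exp$protospacer)
  }
})

test_that("sequences without a PAM give no sites", {
  expect_equal(nrow(find_sites(strrep("AT", 40))), 0)
})

test_that("a site planted on both strands is reported once per strand", {
  set.seed(22)
  core <- rand_dna(20)
  seq <- paste0("TTTT", core, "TGG", "TTTT", "CCA", rc_chr(core), "TTTT")
  hits <- find_sites(seq)
  mine <- hits[hits$protospacer == core, ]
  expect_equal(nrow(mine), 2)
  expect_setequal(mine$strand, c("+", "-"))
})

test_that("guide cut positions sit 3 bp 5' of the PAM on both strands", {
  seq <- rand_dna(100)
  proto <- substr(seq, 21, 40)
  g <- guide_spec("g", proto, "NNN")   # permissive PAM so the site is found
  gs <- locate_guide(g, seq)
  expect_equal(gs$strand, "+")
  expect_equal(gs$protospacer_interval, c(20L, 40L))
  expect_equal(gs$cut, 40L - 3L)
  expect_equal(gs$pam_interval, c(40L, 43L))
  gs_rc <- locate_guide(g, rc_chr(seq))
  expect_equal(gs_rc$strand, "-")
  expect_equal(gs_rc$cut, 100L - 40L + 3L)
})

test_that("seed and PAM mismatches abolish predicted cleavage, distal ones do not", {
  cfg <- sim_config(seed = 9)
  aset <- simulate_locus(cfg)
  g1 <- aset$guides[[1]]
  cc <- check_allele_compatibility(g1, aset)
  # perfect match on a1-a4
  for (id in c("a1", "a2", "a3", "a4")) {
    expect_true(cc[[id]]$predicted_cleavage, info = id)
    expect_equal(nrow(cc[[id]]$mismatches), 0, info = id)
  }
  # the PAM-proximal substitution on a5 kills cleavage
  expect_false(cc[["a5"]]$predicted_cleavage)
  expect_true(all(cc[["a5"]]$mismatches$in_seed))
  # a PAM-distal mismatch (protospacer position 1) only warns
  ref <- aset$alleles[["a1"]]
  gs <- locate_guide(g1, ref)
  p <- gs$protospacer_interval[1]
  distal <- apply_variants(ref, var_tbl(p, substr(ref, p + 1, p + 1),
    setdiff(c("A", "C", "G", "T"), substr(ref, p + 1, p + 1))[1],
    "substitution"))
  aset2 <- allele_set("x", c(mut = distal),
                      list(mut = aset$gene_models[["a1"]]), aset$guides)
  cc2 <- check_allele_compatibility(g1, aset2)
  expect_true(cc2[["mut"]]$predicted_cleavage)
  expect_length(cc2[["mut"]]$warnings, 1)
  expect_false(cc2[["mut"]]$mismatches$in_seed)
  # monotonicity: adding a seed mismatch on top never restores cleavage
  sp <- gs$protospacer_interval[2] - 2L
  both <- apply_variants(distal, var_tbl(sp, substr(distal, sp + 1, sp + 1),
    setdiff(c("A", "C", "G", "T"), substr(distal, sp + 1, sp + 1))[1],
    "substitution"))
  aset3 <- allele_set("x", c(mut = both),
                      list(mut = aset$gene_models[["a1"]]), aset$guides)
  expect_false(check_allele_compatibility(g1, aset3)[["mut"]]$predicted_cleavage)
})

test_that("guides absent beyond the mismatch tolerance report no site", {
  g <- guide_spec("g", strrep("A", 20))
  gs <- locate_guide(g, rand_dna(100))
  if (gs$found) expect_lte(nrow(gs$mismatches), 4)
  gs2 <- locate_guide(g, paste(rep("CGT", 40), collapse = ""))
  expect_false(gs2$found)
})

test_that("PAM-to-PAM spacing is 198 in the simulated design and 0 for self", {
  aset <- simulate_locus(sim_config(seed = 10))
  s1 <- locate_guide(aset$guides[[1]], aset$alleles[["a1"]])
  s2 <- locate_guide(aset$guides[[2]], aset$alleles[["a1"]])
  expect_equal(pair_spacing(s1, s2), 198L)
  expect_equal(pair_spacing(s1, s1), 0L)
  # hand arithmetic on a constructed pair
  seq <- paste0(rand_dna(10), rand_dna(20), "AGG", rand_dna(37),
                rand_dna(20), "TGG", rand_dna(10))
  ga <- guide_spec("a", substr(seq, 11, 30))
  gb <- guide_spec("b", substr(seq, 71, 90))
  sa <- locate_guide(ga, seq); sb <- locate_guide(gb, seq)
  expect_equal(pair_spacing(sa, sb), 60L)   # PAM starts at 30 and 90 (0-based)
  s1$allele_id <- "a1"; s2$allele_id <- "a2"
  expect_error(pair_spacing(s1, s2), "different alleles")
})

test_that("off-target scan equals the exhaustive Hamming oracle", {
  set.seed(31)
  proto <- rand_dna(20)
  db <- c(chr1 = paste0(rand_dna(100), proto, "AGG", rand_dna(2877)),
          chr2 = rand_dna(2000))
  g <- guide_spec("g", proto)
  got <- off_target_scan(g, db, max_mismatches = 5)
  exp <- oracle_offtargets(g$protospacer, db, 5)
  key <- function(d) sort(paste(d$seqid, d$strand, d$start, d$mismatches))
  expect_equal(key(got), key(exp))
  # zero tolerance on the source sequence returns exactly the on-target site
  got0 <- off_target_scan(g, db["chr1"], max_mismatches = 0)
  expect_equal(nrow(got0), 1)
  expect_equal(got0$start, 100L)
  expect_equal(got0$mismatches, 0L)
})

test_that("off-target scanning is strand-symmetric", {
  set.seed(32)
  db <- c(s = rand_dna(1500))
  g <- guide_spec("g", rand_dna(20))
  fwd <- off_target_scan(g, db, max_mismatches = 6)
  rev <- off_target_scan(g, c(s = rc_chr(db[["s"]])), max_mismatches = 6)
  expect_equal(nrow(fwd), nrow(rev))
  # positions mirror: start' = L - end
  expect_setequal(1500L - fwd$end, rev$start)
  expect_equal(sort(fwd$mismatches), sort(rev$mismatches))
})

test_that("planted CDS off-targets carry mismatch counts and the CDS flag", {
  set.seed(33)
  g <- guide_spec("g", rand_dna(20))
  make_site <- function(mm) {
    s <- g$protospacer
    pos <- sample(20, mm)
    for (p in pos) substr(s, p, p) <- setdiff(c("A", "C", "G", "T"),
                                              substr(s, p, p))[1]
    s
  }
  genome <- paste0(rand_dna(500), make_site(4), "TGG", rand_dna(300),
                   make_site(5), "AAG", rand_dna(200))
  db <- c(chr = genome)
  cds <- list(chr = rbind(c(480L, 560L), c(800L, 900L)))
  hits <- off_target_scan(g, db, max_mismatches = 5, cds_intervals = cds)
  planted <- hits[hits$start %in% c(500L, 823L), ]
  expect_equal(nrow(planted), 2)
  expect_setequal(planted$mismatches, c(4L, 5L))
  expect_true(all(planted$cds_overlap))
  # ranking is by (mismatches, seed mismatches)
  expect_true(all(diff(hits$mismatches) >= 0))
})
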