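# Independent brute-force oracles and small fixture builders used across the
# suite. Each oracle re-derives the expected result by direct enumeration,
# never by calling the code path it checks.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rand_qual <- function(n, lo = 2L, hi = 40L)
  intToUtf8(33L + sample(lo:hi, n, replace = TRUE))

rc_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# ---- read-merge oracle ------------------------------------------------------
# Enumerates every innie overlap length, applies the admissibility rule and
# the consensus rules directly.
oracle_merge <- function(s1, q1, s2raw, q2raw, min_overlap, max_frac) {
  s2 <- rc_chr(s2raw)
  q2 <- paste(rev(strsplit(q2raw, "")[[1]]), collapse = "")
  l1 <- nchar(s1); l2 <- nchar(s2)
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  qi1 <- utf8ToInt(q1) - 33L;  qi2 <- utf8ToInt(q2) - 33L
  best <- NULL
  if (min(l1, l2) < min_overlap) return(NULL)
  for (o in seq(min(l1, l2), min_overlap, by = -1L)) {
    off <- l1 - o
    mm <- sum(c1[off + seq_len(o)] != c2[seq_len(o)])
    if (mm > floor(max_frac * o)) next
    cons_b <- character(o); cons_q <- integer(o)
    for (i in seq_len(o)) {
      b1 <- c1[off + i]; b2 <- c2[i]; x1 <- qi1[off + i]; x2 <- qi2[i]
      if (b1 == b2) { cons_b[i] <- b1; cons_q[i] <- max(x1, x2) }
      else if (x1 > x2) { cons_b[i] <- b1; cons_q[i] <- x1 }
      else if (x2 > x1) { cons_b[i] <- b2; cons_q[i] <- x2 }
      else { cons_b[i] <- b1; cons_q[i] <- min(x1, x2) }
    }
    best <- list(
      seq = paste0(substr(s1, 1, off), paste(cons_b, collapse = ""),
                   substr(s2, o + 1, l2)),
      qual = paste0(substr(q1, 1, off), intToUtf8(33L + cons_q),
                    substr(q2, o + 1, l2)),
      overlap = o)
    break  # longest admissible wins
  }
  best
}

# ---- fingerprint column-scan oracle ----------------------------------------
# For equal-length alleles (no indels): positions outside the masks where an
# allele's base differs from every other allele's base.
oracle_exclusive_positions <- function(seqs, masks) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  n <- ncol(mat)
  masked <- rep(FALSE, n)
  if (!is.null(masks) && nrow(masks))
    for (j in seq_len(nrow(masks)))
      masked[(masks[j, 1] + 1L):masks[j, 2]] <- TRUE
  out <- list()
  for (id in names(seqs)) {
    others <- mat[setdiff(names(seqs), id), , drop = FALSE]
    excl <- which(!masked & vapply(seq_len(n), function(p)
      all(others[, p] != mat[id, p]), logical(1)))
    out[[id]] <- excl - 1L  # 0-based
  }
  out
}

# ---- PAM-site enumeration oracle -------------------------------------------
iupac_ok <- function(base, code) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  base %in% sets[[code]]
}

oracle_find_sites <- function(seq, pam = "NGG") {
  k <- nchar(pam)
  pc <- strsplit(pam, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc_chr(seq)
    cs <- strsplit(s, "")[[1]]
    L <- length(cs)
    for (i in seq_len(max(0, L - 19L - k))) {
      pam_seq <- cs[(i + 20L):(i + 19L + k)]
      if (all(mapply(iupac_ok, pam_seq, pc))) {
        start0 <- if (strand == "+") i - 1L else L - (i + 19L)
        hits[[length(hits) + 1L]] <- data.frame(
          strand = strand, start = start0,
          protospacer = paste(cs[i:(i + 19L)], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) return(data.frame(strand = character(), start = integer(),
                                      protospacer = character()))
  out[order(out$start, out$strand), , drop = FALSE]
}

# ---- off-target Hamming oracle ---------------------------------------------
oracle_offtargets <- function(proto, db, max_mm, pams = c("NGG", "NAG")) {
  gb <- strsplit(proto, "")[[1]]
  hits <- list()
  for (sid in names(db)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") db[[sid]] else rc_chr(db[[sid]])
      cs <- strsplit(s, "")[[1]]
      L <- length(cs)
      for (i in seq_len(max(0, L - 22L))) {
        mm <- sum(cs[i:(i + 19L)] != gb)
        if (mm > max_mm) next
        pam <- paste(cs[(i + 20L):(i + 22L)], collapse = "")
        if (!any(vapply(pams, function(p)
          all(mapply(iupac_ok, strsplit(pam, "")[[1]], strsplit(p, "")[[1]])),
          logical(1)))) next
        start0 <- if (strand == "+") i - 1L else L - (i + 19L)
        hits[[length(hits) + 1L]] <- data.frame(
          seqid = sid, strand = strand, start = start0, mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) return(data.frame(seqid = character(), strand = character(),
                                      start = integer(), mismatches = integer()))
  rownames(out) <- NULL
  out[order(out$seqid, out$strand, out$start), , drop = FALSE]
}

# ---- exhaustive alignment-score oracle -------------------------------------
# Maximum global alignment score by plain recursion over all monotone edit
# scripts with affine gaps (exponential; only for very short sequences).
oracle_global_score <- function(a, b, match = 2, mismatch = -3, open = -6,
                                extend = -1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      sc <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, sc + rec(i + 1L, j + 1L, "m"))
    }
    if (i <= length(ca)) {  # gap in b (insertion into a)
      cost <- extend + if (state == "ga") 0 else open
      best <- max(best, cost + rec(i + 1L, j, "ga"))
    }
    if (j <= length(cb)) {  # gap in a (deletion from a)
      cost <- extend + if (state == "gb") 0 else open
      best <- max(best, cost + rec(i, j + 1L, "gb"))
    }
    best
  }
  rec(1L, 1L, "m")
}

# protein flavour of the same recursion, BLOSUM62 substitution scores
oracle_protein_global_score <- function(a, b, open = -11, extend = -1) {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  B <- data_env$BLOSUM62
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb))
      best <- max(best, B[ca[i], cb[j]] + rec(i + 1L, j + 1L, "m"))
    if (i <= length(ca))
      best <- max(best, extend + (if (state == "ga") 0 else open) +
                    rec(i + 1L, j, "ga"))
    if (j <= length(cb))
      best <- max(best, extend + (if (state == "gb") 0 else open) +
                    rec(i, j + 1L, "gb"))
    best
  }
  rec(1L, 1L, "m")
}

# ---- small hand-built fixtures ---------------------------------------------
# Three equal-length toy alleles with SNPs at fixed columns, one guide whose
# target window is masked.
toy_allele_set <- function() {
  base <- paste0("ATGGCTACCT", "GATTACAGGA", "TTTGGCCAAT",  # 0..29
                 "CCGGAATTCA", "GGCTTAGCAT", "AACCGGTTAA")  # 30..59
  a1 <- base
  a2 <- base; substr(a2, 11, 11) <- "C"   # SNP at 0-based 10
  a3 <- base; substr(a3, 21, 21) <- "A"   # SNP at 0-based 20
  substr(a2, 31, 31) <- "T"               # second a2 SNP at 0-based 30
  gm <- gene_model(rbind(c(0L, 60L)), cds_start_offset = 0L)
  allele_set("toy", c(a1 = a1, a2 = a2, a3 = a3),
             list(a1 = gm, a2 = gm, a3 = gm), guides = list())
}

# Fast noise-free mini simulation for pipeline determinism tests
mini_sim <- function(seed = 11, depth = 400) {
  cfg <- sim_config(seed = seed, depth = depth, error_rate = 0)
  aset <- simulate_locus(cfg)
  ed <- simulate_editing(aset, cfg)
  rd <- simulate_reads(ed$seqs, cfg)
  list(cfg = cfg, aset = aset, ed = ed, rd = rd)
}

# variant-table literals for tests
var_tbl <- function(pos, ref, alt, type) {
  v <- data.frame(pos = as.integer(pos), ref = ref, alt = alt, type = type,
                  stringsAsFactors = FALSE)
  class(v) <- c("variant_table", "data.frame")
  v
}
empty_var_tbl <- function() var_tbl(integer(0), character(0), character(0),
                                    character(0))
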