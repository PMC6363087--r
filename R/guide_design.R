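# Dual-sgRNA design checks: site enumeration, per-allele compatibility with
# seed-mismatch calls, PAM-to-PAM spacing, and mismatch-counted off-target
# scans.

iupac_match_matrix <- function(pattern) {
  # logical matrix [pattern position x base ACGTN]: TRUE if base admissible
  pc <- strsplit(pattern, "")[[1]]
  t(vapply(pc, function(ch) {
    adm <- IUPAC_SETS[[ch]]
    c(A = "A" %in% adm, C = "C" %in% adm, G = "G" %in% adm,
      T = "T" %in% adm, N = FALSE)
  }, logical(5)))
}

# vectorized: does the k-mer starting at each position match the IUPAC pattern
pam_match_vec <- function(chars, starts, pattern) {
  mm <- iupac_match_matrix(pattern)
  k <- nchar(pattern)
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(k)) {
    b <- chars[starts + j - 1L]
    ok <- ok & mm[j, ][match(b, c("A", "C", "G", "T", "N"))]
  }
  ok
}

#' Enumerate candidate protospacer sites
#'
#' Every window of 20 protospacer bases followed by a PAM matching
#' `pam_pattern`, on both strands, in deterministic (position, strand) order.
#' Intervals are 0-based half-open on the forward strand of `seq`.
#'
#' @param seq sequence to scan (character scalar, length >= 23).
#' @param pam_pattern IUPAC PAM (default `"NGG"`).
#' @return data frame with columns `protospacer`, `pam`, `strand`, `start`,
#'   `end` (protospacer interval), `pam_start`, `pam_end`, `cut` (blunt cut
#'   position, 3 bp 5' of the PAM).
#' @export
find_sites <- function(seq, pam_pattern = "NGG") {
  seq <- toupper(seq)
  L <- nchar(seq)
  k <- nchar(pam_pattern)
  empty <- data.frame(protospacer = character(), pam = character(),
                      strand = character(), start = integer(), end = integer(),
                      pam_start = integer(), pam_end = integer(),
                      cut = integer(), stringsAsFactors = FALSE)
  if (L < 20L + k) return(empty)
  chars <- strsplit(seq, "")[[1]]
  rows <- list()
  # forward: protospacer [i, i+20), PAM [i+20, i+20+k)
  starts <- seq_len(L - 19L - k)            # 1-based protospacer starts
  ok <- pam_match_vec(chars, starts + 20L, pam_pattern)
  if (any(ok)) {
    i <- starts[ok]
    rows$fwd <- data.frame(
      protospacer = substring(seq, i, i + 19L),
      pam = substring(seq, i + 20L, i + 19L + k),
      strand = "+", start = i - 1L, end = i + 19L,
      pam_start = i + 19L, pam_end = i + 19L + k,
      cut = i + 16L, stringsAsFactors = FALSE)
  }
  # reverse: site on the minus strand; forward-coordinate layout is
  # [pam_start, pam_end) [start, end) with the cut 3 bp into the protospacer
  rc <- revcomp(seq)
  rchars <- strsplit(rc, "")[[1]]
  ok <- pam_match_vec(rchars, starts + 20L, pam_pattern)
  if (any(ok)) {
    i <- starts[ok]                          # 1-based on the rc sequence
    fstart <- L - (i + 19L) + 1L             # 1-based forward start of protospacer
    rows$rev <- data.frame(
      protospacer = substring(rc, i, i + 19L),
      pam = substring(rc, i + 20L, i + 19L + k),
      strand = "-", start = fstart - 1L, end = fstart + 19L,
      pam_start = fstart - 1L - k, pam_end = fstart - 1L,
      cut = fstart - 1L + 3L, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate one guide on one allele
#'
#' Finds the window (either strand) minimizing protospacer mismatches; more
#' than `max_mismatches` everywhere means the site is absent.
#'
#' @param guide a [guide_spec()].
#' @param seq allele sequence.
#' @param max_mismatches search tolerance (default 4).
#' @return a `guide_site` list: `guide`, `found`, `strand`,
#'   `protospacer_interval`, `pam_interval`, `cut` (0-based, 3 bp 5' of PAM),
#'   `mismatches` (data frame: `proto_pos` 1-20 from the PAM-distal end,
#'   `allele_base`, `guide_base`, `in_seed`), `pam_seq`, `pam_ok`.
#' @export
locate_guide <- function(guide, seq, max_mismatches = 4L) {
  seq <- toupper(seq)
  L <- nchar(seq)
  k <- nchar(guide$pam)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    n_win <- L - 19L - k
    if (n_win < 1) next
    protos <- substring(s, seq_len(n_win), seq_len(n_win) + 19L)
    gb <- strsplit(guide$protospacer, "")[[1]]
    mm <- rep(0L, n_win)
    pm <- strsplit(protos, "")
    mmv <- vapply(pm, function(w) sum(w != gb), integer(1))
    pams <- substring(s, seq_len(n_win) + 20L, seq_len(n_win) + 19L + k)
    mmat <- iupac_match_matrix(guide$pam)
    pam_mm <- vapply(strsplit(pams, ""), function(w)
      sum(!mmat[cbind(seq_len(k), match(w, c("A", "C", "G", "T", "N")))]),
      integer(1))
    tot <- mmv + pam_mm
    i <- which.min(tot)
    cand <- list(strand = strand, i = i, proto_mm = mmv[i], pam_mm = pam_mm[i],
                 proto = protos[i], pam = pams[i])
    if (is.null(best) || cand$proto_mm + cand$pam_mm < best$proto_mm + best$pam_mm)
      best <- cand
  }
  if (is.null(best) || best$proto_mm > max_mismatches) {
    return(list(guide = guide$name, found = FALSE))
  }
  i <- best$i
  gb <- strsplit(guide$protospacer, "")[[1]]
  ab <- strsplit(best$proto, "")[[1]]
  mmpos <- which(ab != gb)
  mismatches <- data.frame(
    proto_pos = mmpos, allele_base = ab[mmpos], guide_base = gb[mmpos],
    in_seed = mmpos > (20L - guide$seed_len), stringsAsFactors = FALSE)
  if (best$strand == "+") {
    ps <- c(i - 1L, i + 19L)
    pam_iv <- c(i + 19L, i + 19L + k)
    cut <- i + 16L
  } else {
    fstart <- L - (i + 19L)                  # 0-based forward start
    ps <- c(fstart, fstart + 20L)
    pam_iv <- c(fstart - k, fstart)
    cut <- fstart + 3L
  }
  list(guide = guide$name, found = TRUE, strand = best$strand,
       protospacer_interval = ps, pam_interval = pam_iv, cut = cut,
       mismatches = mismatches, pam_seq = best$pam,
       pam_ok = best$pam_mm == 0L)
}

#' Evaluate a guide's compatibility with every allele
#'
#' Per allele, the best-matching site with its mismatch map and a binary
#' cleavage prediction: `predicted_cleavage` is `FALSE` iff any mismatch
#' falls in the seed (the PAM-proximal `seed_len` bases) or the PAM itself;
#' PAM-distal mismatches leave it `TRUE` (with a warning flag). This is a
#' binary rule, not an efficiency model: the usable signal in dual-guide
#' designs at heterozygous loci is the all-or-nothing seed-mismatch outcome.
#'
#' @param guide a [guide_spec()].
#' @param aset an [allele_set()].
#' @param max_mismatches tolerance of the site search (default 4).
#' @return named list of `guide_site`s (one per allele), each with
#'   `predicted_cleavage` and `warnings` added; absent sites have
#'   `found = FALSE`.
#' @export
check_allele_compatibility <- function(guide, aset, max_mismatches = 4L) {
  out <- list()
  for (id in names(aset$alleles)) {
    gs <- locate_guide(guide, aset$alleles[[id]], max_mismatches)
    gs$allele_id <- id
    if (gs$found) {
      seed_or_pam <- (!gs$pam_ok) ||
        (nrow(gs$mismatches) > 0 && any(gs$mismatches$in_seed))
      gs$predicted_cleavage <- !seed_or_pam
      gs$warnings <- if (nrow(gs$mismatches) > 0 && any(!gs$mismatches$in_seed))
        "PAM-distal mismatch; cleavage may be reduced" else character(0)
    }
    out[[id]] <- gs
  }
  out
}

#' PAM-to-PAM spacing of a guide pair
#'
#' Distance in bases between the PAM-proximal boundaries of the two PAMs,
#' measured on the shared allele, orientation-normalized.
#'
#' @param site1,site2 `guide_site`s on the same allele.
#' @return integer distance.
#' @export
pair_spacing <- function(site1, site2) {
  if (!is.null(site1$allele_id) && !is.null(site2$allele_id) &&
      site1$allele_id != site2$allele_id)
    stop("guide sites lie on different alleles")
  bnd <- function(s) if (s$strand == "+") s$pam_interval[1] else s$pam_interval[2]
  abs(bnd(site2) - bnd(site1))
}

#' Mismatch-counted off-target scan
#'
#' Every PAM-adjacent 20-mer within Hamming distance `max_mismatches` of the
#' protospacer, on both strands of each database sequence. Pure Hamming on
#' the 20-mer (no bulges); PAMs NGG and NAG by default. Hits carry mismatch
#' and seed-mismatch counts and, when CDS intervals are supplied, a
#' CDS-overlap flag; they are ranked by (mismatch count, seed mismatches).
#'
#' @param guide a [guide_spec()].
#' @param db named character vector of database sequences.
#' @param max_mismatches Hamming tolerance (default 5).
#' @param pam_patterns admissible PAMs (default `c("NGG", "NAG")`).
#' @param cds_intervals optional named list (per database sequence) of
#'   `[start, end)` CDS interval matrices for the overlap flag.
#' @return data frame: `seqid`, `strand`, `start`, `end` (protospacer
#'   interval, forward coordinates), `site`, `pam`, `mismatches`,
#'   `seed_mismatches`, `cds_overlap`.
#' @export
off_target_scan <- function(guide, db, max_mismatches = 5L,
                            pam_patterns = c("NGG", "NAG"),
                            cds_intervals = NULL) {
  gb <- strsplit(guide$protospacer, "")[[1]]
  seed_from <- 20L - guide$seed_len + 1L
  rows <- list()
  for (sid in names(db)) {
    seq <- toupper(db[[sid]])
    L <- nchar(seq)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else revcomp(seq)
      k <- nchar(pam_patterns[1])
      n_win <- L - 19L - k
      if (n_win < 1) next
      chars <- strsplit(s, "")[[1]]
      # mismatches of every window against the protospacer, vectorized over
      # the 20 protospacer positions
      mm <- integer(n_win)
      seed_mm <- integer(n_win)
      for (j in 1:20) {
        neq <- chars[seq_len(n_win) + j - 1L] != gb[j]
        mm <- mm + neq
        if (j >= seed_from) seed_mm <- seed_mm + neq
      }
      pam_ok <- rep(FALSE, n_win)
      for (pp in pam_patterns)
        pam_ok <- pam_ok | pam_match_vec(chars, seq_len(n_win) + 20L, pp)
      hit <- which(mm <= max_mismatches & pam_ok)
      if (!length(hit)) next
      if (strand == "+") {
        start <- hit - 1L
      } else {
        start <- L - (hit + 19L)
      }
      rows[[paste(sid, strand)]] <- data.frame(
        seqid = sid, strand = strand, start = start, end = start + 20L,
        site = substring(s, hit, hit + 19L),
        pam = substring(s, hit + 20L, hit + 19L + k),
        mismatches = mm[hit], seed_mismatches = seed_mm[hit],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(seqid = character(), strand = character(),
                      start = integer(), end = integer(), site = character(),
                      pam = character(), mismatches = integer(),
                      seed_mismatches = integer(), cds_overlap = logical(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out$cds_overlap <- FALSE
  if (!is.null(cds_intervals)) {
    for (i in seq_len(nrow(out))) {
      iv <- cds_intervals[[out$seqid[i]]]
      if (!is.null(iv) && nrow(iv))
        out$cds_overlap[i] <- any(out$end[i] > iv[, 1] & out$start[i] < iv[, 2])
    }
  }
  out <- out[order(out$mismatches, out$seed_mismatches, out$seqid, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
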