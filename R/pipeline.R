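# End-to-end orchestration: prep -> call -> assign -> classify -> report.

#' Run configuration for the amplicon pipeline
#'
#' Aggregates the analysis parameters: Phred-33 decoding, merge settings,
#' fixed 35-nt flank trims, the 1% prevalence threshold, the mask flank
#' around cut sites, alignment scoring and the assignment threshold.
#'
#' @param merge a [merge_config()].
#' @param trim5,trim3 flank trim lengths (default 35).
#' @param min_prev variant-calling prevalence threshold, in `(0, 0.5]`.
#' @param mask_flank half-width added around protospacer+PAM when masking
#'   target windows (default 10).
#' @param min_score allele-assignment threshold (default 0.8).
#' @param scoring an [align_scoring()].
#' @return object of class `run_config`.
#' @export
run_config <- function(merge = merge_config(), trim5 = 35L, trim3 = 35L,
                       min_prev = 0.01, mask_flank = 10L, min_score = 0.8,
                       scoring = align_scoring()) {
  if (min_prev <= 0 || min_prev > 0.5) stop("min_prev must be in (0, 0.5]")
  structure(list(merge = merge, trim5 = as.integer(trim5),
                 trim3 = as.integer(trim3), min_prev = min_prev,
                 mask_flank = as.integer(mask_flank), min_score = min_score,
                 scoring = scoring),
            class = "run_config")
}

#' Assign and classify called clusters
#'
#' For every kept cluster: best-match allele-class assignment via the
#' fingerprints, global alignment to the assigned class representative,
#' variant extraction (left-aligned, on full allele coordinates), per-site
#' edit status, dual-cut detection and coding-effect prediction.
#'
#' @param called `cluster_table` of clusters at or above the prevalence
#'   threshold (from [call_variant_clusters()]).
#' @param fingerprints a `fingerprint_set` built with the run's trim.
#' @param aset the [allele_set()].
#' @param cfg a [run_config()].
#' @return data frame `edit_calls`: one row per cluster with `rank`, `count`,
#'   `prevalence`, `assigned`, `score`, `rescued`, `n_variants`,
#'   `variant_sig`, `site_*` columns, `dual_cut`, `effect`, `n_aa`, `ptc_aa`.
#'   Attribute `variants` holds the per-cluster `variant_table`s.
#' @export
classify_sample <- function(called, fingerprints, aset, cfg = run_config()) {
  gnames <- vapply(aset$guides, `[[`, "", "name")
  gsites <- lapply(aset$guides, function(g) check_allele_compatibility(g, aset))
  names(gsites) <- gnames
  trim <- fingerprints$trim
  scores <- if (nrow(called)) score_clusters(called$seq, fingerprints, aset,
                                             cfg$scoring) else list()
  rows <- list()
  var_list <- list()
  for (i in seq_len(nrow(called))) {
    asg <- pick_assignment(scores[[i]], cfg$min_score)
    row <- data.frame(rank = called$rank[i], count = called$count[i],
                      prevalence = called$prevalence[i],
                      assigned = asg$assigned, score = asg$score,
                      rescued = FALSE, stringsAsFactors = FALSE)
    if (asg$assigned != "unassigned") {
      rep_id <- fingerprints$classes[[asg$assigned]]$representative
      ref <- aset$alleles[[rep_id]]
      win <- substr(ref, trim[1] + 1L, nchar(ref) - trim[2])
      vars <- align_global(called$seq[i], win, cfg$scoring)
      vars$pos <- vars$pos + trim[1]
      # re-left-align against the full allele (the trim boundary is
      # arbitrary), never shifting an indel past the preceding variant
      bound <- 0L
      for (k in seq_len(nrow(vars))) {
        if (vars$type[k] == "deletion") {
          la <- left_align_del(ref, vars$pos[k], nchar(vars$ref[k]), bound)
          vars$pos[k] <- la$pos; vars$ref[k] <- la$ref
        } else if (vars$type[k] == "insertion") {
          la <- left_align_ins(ref, vars$pos[k], vars$alt[k], bound)
          vars$pos[k] <- la$pos; vars$alt[k] <- la$alt
        }
        bound <- vars$pos[k] + nchar(vars$ref[k])
      }
      se <- call_site_edits(vars, lapply(gnames, function(g) gsites[[g]][[rep_id]]),
                            flank = cfg$mask_flank, ref = ref)
      eff <- predict_coding_effect(vars, aset$gene_models[[rep_id]], ref)
      row$n_variants <- nrow(vars)
      row$variant_sig <- if (nrow(vars))
        paste(sprintf("%d%s>%s", vars$pos, vars$ref, vars$alt), collapse = ";")
        else "WT"
      for (g in gnames) row[[paste0("site_", g)]] <- se$site_status[[g]]
      row$dual_cut <- se$dual_cut
      row$effect <- eff$effect; row$n_aa <- eff$n_aa; row$ptc_aa <- eff$ptc_aa
      var_list[[as.character(i)]] <- vars
    } else {
      row$n_variants <- NA_integer_; row$variant_sig <- NA_character_
      for (g in gnames) row[[paste0("site_", g)]] <- NA_character_
      row$dual_cut <- NA; row$effect <- NA_character_
      row$n_aa <- NA_integer_; row$ptc_aa <- NA_integer_
    }
    rows[[i]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rank = integer(), count = integer(), prevalence = numeric(),
               assigned = character(), score = numeric(), rescued = logical(),
               n_variants = integer(), variant_sig = character(),
               dual_cut = logical(), effect = character(), n_aa = integer(),
               ptc_aa = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "variants") <- var_list
  out
}

#' Run the full amplicon analysis
#'
#' prep (merge, trim, cluster) -> call (prevalence threshold) -> assign
#' (fingerprints) -> classify (alignment, site edits, coding effect) ->
#' rescue of expected-but-missing allele classes -> per-sample variant-group
#' summary. Deterministic: the same inputs and configuration reproduce the
#' same outputs byte for byte.
#'
#' @param r1,r2 paths to FASTQ files, or `fastq_reads` objects.
#' @param locus an [allele_set()] or path to a locus-spec JSON.
#' @param cfg a [run_config()].
#' @param out_dir if non-NULL, report files are written here:
#'   `clusters.tsv`, `edit_calls.tsv`, `variants.vcf`, `summary.json`,
#'   `run_manifest.json`.
#' @param sample_id label used in reports.
#' @return list of class `amplicon_run` with elements `clusters`, `called`,
#'   `edit_calls` (incl. rescued rows), `groups` (variant-group summary),
#'   `fingerprints`, `accounting` (read-count bookkeeping), `config`.
#' @export
run_amplicon <- function(r1, r2, locus, cfg = run_config(), out_dir = NULL,
                         sample_id = "sample") {
  aset <- if (inherits(locus, "allele_set")) locus else load_locus_spec(locus)
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  n_pairs <- nrow(r1)

  merged <- merge_pairs(r1, r2, cfg$merge)
  trimmed <- trim_fixed(merged, cfg$trim5, cfg$trim3)
  clusters <- cluster_exact(trimmed)
  called <- call_variant_clusters(clusters, cfg$min_prev)
  below <- attr(called, "below_threshold")

  fps <- build_fingerprints(aset, trim = c(cfg$trim5, cfg$trim3),
                            flank = cfg$mask_flank, scoring = cfg$scoring)
  edit_calls <- classify_sample(called, fps, aset, cfg)

  # dropout rescue: expected classes absent from the main call set
  seen <- unique(edit_calls$assigned[edit_calls$assigned != "unassigned"])
  missing <- setdiff(names(fps$classes), seen)
  rescued_rows <- list()
  for (cls in missing) {
    res <- rescue_missing(below, fps$classes[[cls]], fps, aset, cfg$scoring)
    if (nrow(res)) {
      res$score <- NA_real_
      res$n_variants <- NA_integer_; res$variant_sig <- NA_character_
      for (g in vapply(aset$guides, `[[`, "", "name"))
        res[[paste0("site_", g)]] <- NA_character_
      res$dual_cut <- NA; res$effect <- NA_character_
      res$n_aa <- NA_integer_; res$ptc_aa <- NA_integer_
      rescued_rows[[cls]] <- res[, c("rank", "count", "prevalence", "assigned",
                                     "score", "rescued", "n_variants",
                                     "variant_sig",
                                     paste0("site_", vapply(aset$guides, `[[`,
                                                            "", "name")),
                                     "dual_cut", "effect", "n_aa", "ptc_aa")]
    }
  }
  if (length(rescued_rows))
    edit_calls <- rbind(edit_calls, do.call(rbind, rescued_rows))
  rownames(edit_calls) <- NULL

  groups <- summarize_sample(
    edit_calls[!is.na(edit_calls$variant_sig), , drop = FALSE])

  accounting <- list(pairs_in = n_pairs,
                     merged = nrow(merged),
                     unmerged = attr(merged, "n_unmerged"),
                     trimmed_kept = nrow(trimmed),
                     trim_discarded = attr(trimmed, "n_discarded"),
                     clusters = nrow(clusters),
                     called = nrow(called),
                     below_threshold = nrow(below),
                     rescued = sum(edit_calls$rescued))

  out <- structure(list(sample_id = sample_id, clusters = clusters,
                        called = called, edit_calls = edit_calls,
                        groups = groups, fingerprints = fps,
                        accounting = accounting, config = cfg),
                   class = "amplicon_run")
  if (!is.null(out_dir)) write_run_reports(out, aset, out_dir)
  out
}

#' @export
print.amplicon_run <- function(x, ...) {
  a <- x$accounting
  cat("<amplicon_run>", x$sample_id, "\n")
  cat(sprintf("  pairs %d | merged %d (unmerged %d) | trimmed %d\n",
              a$pairs_in, a$merged, a$unmerged, a$trimmed_kept))
  cat(sprintf("  clusters %d | called >= %.2g%%: %d | rescued: %d\n",
              a$clusters, 100 * x$config$min_prev, a$called, a$rescued))
  cat(sprintf("  variant groups: %d\n", attr(x$groups, "n_groups")))
  invisible(x)
}

write_run_reports <- function(run, aset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_clusters(run$clusters, file.path(out_dir, "clusters.tsv"))
  write.table(run$edit_calls[, c("rank", "count", "prevalence", "assigned",
                                 "score", "rescued")],
              file.path(out_dir, "variant_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(run$edit_calls, file.path(out_dir, "edit_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(run$groups, file.path(out_dir, "groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  # one VCF over the anchor allele: variants of clusters assigned to classes
  # containing the anchor, else per representative noted in the record id
  vars <- attr(run$edit_calls, "variants")
  anchor_seq <- aset$alleles[[aset$anchor]]
  if (length(vars)) {
    merged_vars <- do.call(rbind, vars)
    merged_vars <- merged_vars[!duplicated(merged_vars), , drop = FALSE]
    class(merged_vars) <- c("variant_table", "data.frame")
    write_vcf(merged_vars, anchor_seq, file.path(out_dir, "variants.vcf"),
              chrom = aset$locus_id)
  } else {
    write_vcf(empty_variants(), anchor_seq, file.path(out_dir, "variants.vcf"),
              chrom = aset$locus_id)
  }
  summary_js <- list(sample = run$sample_id,
                     n_groups = attr(run$groups, "n_groups"),
                     accounting = run$accounting)
  jsonlite::write_json(summary_js, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- list(package = "polyamp",
                   version = as.character(utils::packageVersion("polyamp")),
                   sample = run$sample_id,
                   parameters = list(
                     min_overlap = run$config$merge$min_overlap,
                     max_mismatch_frac = run$config$merge$max_mismatch_frac,
                     quality_offset = run$config$merge$quality_offset,
                     trim5 = run$config$trim5, trim3 = run$config$trim3,
                     min_prev = run$config$min_prev,
                     mask_flank = run$config$mask_flank,
                     min_score = run$config$min_score,
                     scoring = unclass(run$config$scoring)),
                   accounting = run$accounting)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
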