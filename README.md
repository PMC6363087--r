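# polyamp

Quantifying CRISPR/Cas9 editing outcomes at highly heterozygous loci of
polyploid genomes from paired-end amplicon sequencing.

## The problem

In a polyploid such as octoploid cultivated strawberry (*Fragaria* ×
*ananassa*, up to eight homoeologous copies per locus), a single "gene" is a
family of allele haplotypes that differ by intronic indels and coding SNPs.
After Cas9 mutagenesis with a dual-sgRNA construct, an amplicon sequencing
library over the target region is a mixture of (allele haplotype × induced
edit) molecules. Making sense of it requires answering, for every distinct
read sequence: *which allele did this come from, what was edited at each
guide site, and what does that do to the protein?* Two complications make
this harder than diploid amplicon analysis:

* the edits themselves (NHEJ indels, large dual-cut deletions) destroy parts
  of the sequence you would otherwise use to recognize the allele, and
* PCR bias can drop an entire allele below any sensible prevalence
  threshold.

`polyamp` implements the full workflow:

1. **Read preparation** — read pairs are collapsed by overlap (FLASH-style:
   longest overlap whose mismatch fraction is within budget; per-base
   consensus keeps the higher-quality base), 35 nt of each flank are trimmed,
   and identical sequences are clustered exactly — no similarity threshold,
   so one base of difference means a distinct cluster. Prevalence is the
   cluster's fraction of merged, trimmed reads.
2. **Variant calling** — clusters at ≥ 1% prevalence are candidate allelic
   variants.
3. **Allele assignment by SNP fingerprints** — alleles are aligned to an
   anchor haplotype, and every allele class (alleles indistinguishable
   within the amplicon form one class) gets a fingerprint of diagnostic
   positions computed *outside* masked windows around the guide target sites
   (protospacer + PAM ± 10 nt), so edits never obscure the assignment.
   Clusters are assigned to the best-matching class (≥ 0.8 of scorable
   diagnostic positions; positions deleted by a dual-cut deletion are
   excluded from the denominator).
4. **Dropout rescue** — if an expected allele class is missing from the main
   call set, sub-threshold clusters matching *all* of its exclusive SNPs are
   rescued, regardless of what happened inside the target windows.
5. **Edit classification** — each cluster is aligned globally (affine gaps:
   match +2, mismatch −3, gap open −6, extend −1) to its assigned allele;
   variants are extracted and left-aligned; a guide site is "edited" if a
   variant touches ± 10 nt around its cut (3 bp 5′ of the PAM); a dual cut is
   one deletion containing both cut positions.
6. **Protein consequence** — variants are applied to the genomic allele, the
   transcript is rebuilt through the exon/intron model (a deletion removing a
   whole intron plus flanking exon ends fuses the remaining exon parts), and
   the CDS is translated: `silent`, `missense`, `in_frame_deletion(n aa)`,
   `in_frame_insertion(n aa)`, `premature_stop`, `frameshift`,
   `frameshift_with_PTC(aa)`, `splice_disrupted`, `start_lost`.

Around the core pipeline the package provides dual-sgRNA design checks
(per-allele seed/PAM mismatch calls — one seed mismatch is treated as
abolishing cleavage; PAM-to-PAM spacing; Hamming off-target scans with NGG
and NAG PAMs and CDS-overlap flags), protein translation and BLASTP-like
percent identity (BLOSUM62, gap open −11 / extend −1, local or global), and
a synthetic-data generator that emulates the five-allele situation end to
end: intronic indels, 4 synonymous + 8 non-synonymous coding SNPs, one
allele with a guide-seed mismatch, a 198-bp PAM-to-PAM dual-guide design
over a 106-nt intron, PCR allele weights (including dropout), and
Phred-scaled 2 × 250 nt read pairs with full truth labels.

## Worked example

```r
library(polyamp)

cfg  <- sim_config(seed = 7, depth = 5000)   # the default study conditions
aset <- simulate_locus(cfg)                  # 5 alleles, 2 guides
ed   <- simulate_editing(aset, cfg)          # molecule pool + truth table
rd   <- simulate_reads(ed$seqs, cfg)         # 2 x 250 nt pairs, Q30

run <- run_amplicon(rd$r1, rd$r2, aset)
run
#> <amplicon_run> sample
#>   pairs 5000 | merged 5000 (unmerged 0) | trimmed 5000
#>   clusters 1263 | called >= 1%: 15 | rescued: 0
#>   variant groups: 15

head(run$groups[, c("prevalence", "assigned", "site_g1", "site_g2",
                    "dual_cut", "effect", "n_aa")], 4)
#>   prevalence assigned   site_g1 site_g2 dual_cut              effect n_aa
#> 1     0.0954       a5 wild-type  edited    FALSE frameshift_with_PTC   NA
#> 2     0.0698    a1/a2    edited  edited    FALSE frameshift_with_PTC   NA
#> 3     0.0674    a1/a2    edited  edited     TRUE   in_frame_deletion   33
#> 4     0.0670       a4    edited  edited    FALSE frameshift_with_PTC   NA
```

Reading the output: 1263 distinct sequences were observed (most are
singleton error clusters), 15 passed the 1% threshold. Each group is one
(allele class, edit) combination: e.g. row 3 is a dual-cut deletion on the
`a1/a2` class — those two alleles are identical within the amplicon, so the
pipeline reports the ambiguity class rather than guessing — removing 33
amino acids in frame. The seed-mismatched allele `a5` is only ever edited at
guide 2, never at guide 1. Comparing against the generator's truth:

```r
cmp <- compare_to_truth(run, ed$types)       # groups planted at >= 2%
attr(cmp, "recovery")
#> [1] 1
```

`run_amplicon(..., out_dir = "results/")` writes `clusters.tsv`,
`variant_calls.tsv`, `edit_calls.tsv`, `groups.tsv`, `variants.vcf`
(left-aligned, 1-based, anchored indels), `summary.json` and
`run_manifest.json` (all parameters, for exact re-runs). The same pipeline
runs from FASTQ files plus a locus-spec JSON; see
`vignettes/polyploid-amplicon-editing.Rmd` for the format and for the Sanger
clone mode (`classify_clones()`) used with transient assays.

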