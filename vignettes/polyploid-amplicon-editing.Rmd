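---
title: "Calling CRISPR editing outcomes at a heterozygous polyploid locus"
author: "polyamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling CRISPR editing outcomes at a heterozygous polyploid locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyamp)
```

# The analysis model

An amplicon library over a CRISPR target region of a polyploid locus is a
mixture over molecules $m = (\text{allele } a, \text{edit } e)$. After
merging read pairs and trimming fixed flanks, the observed data are exact
sequence clusters with prevalences $p_c$ (cluster reads / total merged,
trimmed reads). The pipeline's job is the inverse map $c \mapsto (a, e,
\text{protein consequence})$, under two adversities it is explicitly built
for: the edit $e$ can delete the very positions that identify $a$, and PCR
bias can push an entire allele below the calling threshold.

## Read preparation

Pairs are collapsed by overlap. Among all "innie" overlaps of length
$\geq$ `min_overlap` whose mismatch fraction is $\leq$ `max_mismatch_frac`,
the longest wins; within the overlap, agreeing bases keep the maximum
quality, disagreeing bases keep the higher-quality base, and quality ties
keep the forward-read base with the minimum quality. Defaults (`min_overlap
= 10`, `max_mismatch_frac = 0.25`) are FLASH's published defaults; the
merge rule itself is verified against an exhaustive-overlap oracle in the
test suite. Only the overlapping orientation is searched: the supported
amplicon designs are shorter than the summed read length, so a real pair
always overlaps, and unmergeable pairs are counted and excluded from the
prevalence denominator. 35 nt are then trimmed from each end (noise
reduction at the primer/adapter margins; reads not longer than 70 nt are
discarded, not errored). Quality strings are Phred+33; scores outside 0–60
are rejected outright rather than re-interpreted, so offset-64 input fails
loudly. An optional mean-quality read filter exists
(`filter_mean_quality()`) but defaults off — the only quality use the core
pipeline makes is the merge consensus.

Clustering is exact: one cluster per distinct string, no similarity
threshold, sorted by count with lexicographic tie-break for determinism.

## Variant calling and the 1% threshold

Clusters at prevalence $\geq$ 1% (inclusive) are candidate allelic
variants. The threshold is applied per sample with the merged-and-trimmed
read total as denominator. Everything below the threshold is kept in a side
list, because of the rescue step below.

## Fingerprints and allele assignment

All alleles are pairwise-aligned to an anchor allele, inducing a common
column frame (anchor positions plus insertion columns). Columns are dropped
if they fall inside a **masked window** on any allele — protospacer + PAM
± `mask_flank` (default 10 nt) around each guide site, where NHEJ indels
concentrate — or outside the trimmed amplicon window. Alleles identical on
the remaining visible columns form one **class** and are never told apart
(they are reported as an ambiguity class such as `a1/a2`).

Each class gets two column sets:

* `profile` — all discriminative columns (where at least two classes
  disagree), used for assignment;
* `diagnostic` — the exclusive subset where this class differs from *every*
  other class, used for dropout rescue.

A cluster is aligned to each class representative and scored by the
fraction of profile positions whose aligned base matches. Positions deleted
in the cluster are excluded from the denominator: a dual-cut deletion
removes every profile column between the cuts, and scoring those columns as
mismatches would unassign precisely the most prevalent outcome class. The
cluster is assigned to the unique best class if its score is at least
`min_score = 0.8` — lenient enough to tolerate a sequencing error on a
small diagnostic set, strict enough to prevent cross-assignment (the
default synthetic locus separates classes by 3–10 diagnostic positions, so
a wrong class scores at most ~0.86 while the right one scores 1.0). Ties or
low scores give `unassigned`, which is a reported outcome, not an error.
With a single allele every cluster assigns to it trivially.

The synthetic-data generator deliberately places, for every distinguishable
allele, at least one private SNP outside the widest possible dual-cut
deletion, mirroring a design reality: if an allele's only distinguishing
positions sit between the two cuts, its dual-deletion products are
unassignable in principle, and no pipeline can fix that.

## Dropout rescue

If an expected class is absent from the $\geq$ 1% call set, sub-threshold
clusters whose aligned bases match **all** of the class's exclusive
diagnostic positions are returned as rescued calls. Differences inside the
masked target windows are irrelevant by construction, so edited molecules
of the dropped allele are rescued too. "All exclusive positions" is the
strictest reading of a fingerprint match; a laxer fraction would risk
counting error-halo clusters of abundant alleles as evidence for the
missing one. Rescued calls carry `rescued = TRUE` and are never assigned a
coding effect (their per-molecule evidence is too thin); the claim they
support is presence of the allele, not a specific edit.

## Edit classification

Assigned clusters are aligned globally to their class representative under
affine-gap scoring (match +2, mismatch −3, gap open −6, gap extend −1 —
chosen so one long deletion outscores scattered gaps, which matches
dual-cut biology). Variants are extracted and left-aligned (lowest
reference position producing the identical edited sequence, never shifting
an indel across a neighbouring variant), making placement canonical across
tracebacks; a round-trip property (apply variants to reference, recover the
cluster exactly) is fuzz-tested over thousands of random edits.

A guide site is **edited** iff a variant interval intersects
$[\text{cut} - 10, \text{cut} + 10)$; the cut is fixed 3 bp 5′ of the PAM
(blunt SpCas9 cut). A **dual cut** is a single deletion whose interval
contains both cut positions. Because an indel inside a repeat has several
equivalent placements describing the same molecule, these interval tests
use the variant's whole equivalent-placement range (left-most to right-most
shift), so the calls do not depend on which placement an aligner happened
to report — without this, a cut-to-cut deletion left-shifted by one base
through a repeated flanking base would lose its dual-cut status. A site
that cannot be located on the assigned allele (more than 4 mismatches) is
`not_assessable`.

## Protein consequence

Variants are applied to the genomic allele and each surviving base keeps
its exon/CDS annotation; inserted bases inherit the annotation of the base
they precede. The surviving CDS bases are concatenated — so a deletion that
removes an entire intron together with flanking exon ends fuses the
remaining exon parts — and translated with the standard genetic code.
Classification is by net CDS length change $\Delta$ and first stop:
frameshift iff $\Delta \bmod 3 \neq 0$ (with `frameshift_with_PTC` and the
stop's aa position when translation meets a premature stop); otherwise
in-frame insertion/deletion of $|\Delta|/3$ aa, `missense`, or `silent`.
Two further levels are honest edge cases: `premature_stop` for an in-frame
edit that introduces a stop codon (e.g. an inserted TAA) — the frameshift
labels are reserved for actual frameshifts so that the $\Delta \bmod 3$
equivalence stays exact — and `start_lost` when a deletion removes the CDS
start. Any deletion removing $\geq 1$ base of a canonical GT donor or AG
acceptor without deleting the whole intron is `splice_disrupted` and not
translated (the spliced product would be speculation). Substitutions inside
the splice dinucleotides are *not* flagged — a known limitation of the
deletion-based rule.

Deletion sizes are reported in the coordinates of the analyzed molecule:
genomic for genomic-DNA amplicons, spliced for cDNA amplicons. Both are
supported by giving the allele the matching gene model (for cDNA, a single
exon spanning the sequence); which one a run used is a property of its
locus spec.

## Guide design checks

`check_allele_compatibility()` reports, per allele, the best-matching site
with its mismatch map, and a binary `predicted_cleavage`: `FALSE` iff any
mismatch falls in the seed (the 12 PAM-proximal protospacer bases — a
common convention; configurable) or in the PAM. This is deliberately not a
quantitative efficiency model: the reliable, reproducible signal at a
heterozygous locus is the all-or-nothing seed-mismatch outcome, and that is
what the synthetic generator emulates (its `a5` allele carries a
PAM-proximal substitution under guide 1 and is never cut there).
`pair_spacing()` measures PAM-to-PAM distance between the PAM-proximal PAM
boundaries. `off_target_scan()` is a pure Hamming scan of PAM-adjacent
20-mers (NGG and NAG, both strands, no bulges), ranked by (mismatch count,
seed mismatches), with optional CDS-overlap flags — candidate enumeration,
not activity scoring; activity models (MIT/CFD-style) are out of scope.

## Protein homology

`translate_cds()` implements the standard code with first-stop truncation
and `X` for fuzzy codons. `pairwise_identity()` aligns two proteins under
BLOSUM62 with gap open −11 / extend −1 (BLASTP-like), local or global, and
reports identical columns / aligned columns × 100 — the aligned-span
denominator *includes* gap columns, which is the convention published
identities usually assume; results are sensitive to this choice, so it is
stated here prominently. Because tie-broken tracebacks depend on argument
order, the implementation canonicalizes the pair internally so that
identity is exactly symmetric.

# The synthetic data generator

`simulate_locus()` builds a 439-nt, three-exon amplicon haplotype and five
alleles from it. The fixed architecture encodes the features the analysis
must cope with, at realistic scale:

* intron 1 is 106 nt and sits between the two guide sites — this length is
  *derived*: with dual-cut genomic deletions of 187 and 193 nt removing 27
  and 29 aa, the deleted span must contain 106 nt of intron
  ($187 - 81 = 193 - 87 = 106$); the regression test pins exactly this
  arithmetic, flagged as derived;
* guides in exon 1 and exon 2, 198 bp PAM to PAM;
* alleles `a1`/`a2` identical within the amplicon (an ambiguity class);
  `a3`/`a4`/`a5` carry intron-2 indels (−5, +6, −3 nt) and coding SNPs — 4
  synonymous + 8 non-synonymous in total, verified per allele by
  translation at generation time; `a5` additionally carries a
  non-synonymous substitution in the guide-1 seed;
* terminal-exon codons 61–64 are fixed to a sense sequence that contains
  stop codons in both shifted reading frames, so every upstream frameshift
  reaching exon 3 meets a PTC — real 3′ sequence context is stop-rich in
  shifted frames, whereas a 201-nt random CDS need not be.

`simulate_editing()` draws, per molecule: the allele (PCR weights; default
0.22/0.22/0.20/0.19/0.17 — mild bias, no dropout; the dropout scenario
weights one allele to 0.004), then a dual-cut deletion with probability
0.35 when both guides can cleave, else independent per-site NHEJ edits with
efficiencies 0.9 (guide 1) and 0.8 (guide 2). NHEJ indel sizes are
geometric ($p = 0.3$, capped at 30 nt), 70% deletions — chosen to produce
the small-indel spectra typical of plant NHEJ; no published spectrum is
being fitted. Crucially, the NHEJ outcome at each (allele, site) is drawn
*once per simulation*, so repair products recur across molecules — the
regime of clonally propagated T0 tissue, where a handful of variant groups
dominate, rather than an infinite-diversity repair model.

`simulate_reads()` reads 250 nt from each molecule end (molecules shorter
than the read length are read end-to-end), adds substitution errors at the
Phred-implied rate (flat Q30 by default; indel errors are off — negligible
for the platform class emulated) and writes matching flat quality strings.
All randomness in all three stages flows from `cfg$seed`; the same seed
reproduces byte-identical FASTQ.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: PCR chimeras between alleles (a known
amplicon artifact, explicitly out of scope), cycle-dependent quality decay,
indel sequencing errors, primer-site mutations, and any unknown additional
alleles beyond the configured set. The generator defines the study
conditions; its parameters are not tuned per test.

# Problem sizes and numerical choices

The acceptance-level checks run the full pipeline on 20 simulated datasets
of 5 000 read pairs each (both the default and the dropout conditions) — a
scale a desk machine handles in a few minutes while leaving binomial noise
small relative to the thresholds being exercised. Unit tests use depths of
150–600. Alignment is exact dynamic programming throughout (no heuristics);
the only approximation anywhere is the binary cleavage rule discussed
above. Degenerate inputs are defined behaviour: empty FASTQ yields empty,
well-formed reports; clusters failing assignment are reported
`unassigned`; reads at or below the summed trim length are dropped and
counted.

# Known limitations

* Allele dosage is not estimated: a class's prevalence conflates copy
  number, PCR bias and editing; the package reports composition, not
  genotype dosage.
* Chimera detection is out of scope; chimeric clusters will usually end up
  `unassigned` (mixed fingerprints) but are not flagged as chimeras.
* The homology identities depend on alignment mode and the aligned-span
  denominator; both modes are provided and the convention is documented,
  but reproducing a published value requires the same database sequences.
* `predicted_cleavage` is binary; partial efficiency reduction from
  PAM-distal mismatches is reported only as a warning.
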