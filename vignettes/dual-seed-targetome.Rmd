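---
title: "Dual-seed targetome analysis of canonical miRNAs and their 5'-isomiRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-seed targetome analysis of canonical miRNAs and their 5'-isomiRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoTargetome)
```

## The biological question

A mature miRNA represses mRNAs whose sequence contains a Watson–Crick
match to its *seed region*: nucleotides 2–7 (a "6mer" site) or 2–8 (a
"7mer-m8" site) counted from the miRNA's 5′ end. During biogenesis,
imprecise Drosha/Dicer cleavage produces *5′-isomiRs*: variants trimmed
by *k* nucleotides at the 5′ end. Because the seed is defined
positionally, a 5′ shift moves the seed register by *k* nucleotides, so
an isomiR should, in general, recognise a different set of mRNAs than
its canonical form.

The interesting exception is a *dual-seed architecture*: when an mRNA
carries a contiguous match to miRNA nucleotides 2 through *k*+8, that
single stretch simultaneously contains the canonical 6mer site (its last
six bases) and the +*k* isomiR 7mer-m8 site (its first seven bases). For
*k* = 4 this is an 11-nt match. miRNAs whose target sites are frequently
"extendable" in this sense keep regulating largely the same mRNA set
even when processing shifts their 5′ end — seed shifting then reinforces
rather than rewires repression. hsa-miR-93-5p, whose +3/+4 5′-isomiRs
arise readily from shRNA-encoded hairpins and in tumor tissue, is the
motivating case, and its canonical sequence
(`CAAAGUGCUGUUCGUGCAGGUAG`) ships as the package fixture `mir93_5p()`.

This package quantifies that architecture. Given mature miRNA sequences
with isomiR annotations, transcript sequences with 3′-UTR annotation,
and paired miRNA/mRNA expression matrices, it computes:

* per-miRNA canonical (6mer) and isomiR (7mer-m8) targetomes and their
  **Jaccard index** |A∩B| / |A∪B|;
* the proportion of canonical 6mer sites that are **extendable** to the
  full (*k*+7)-nt dual site, at site and at gene granularity;
* **anticorrelation screening**: Spearman correlation of each gene with
  the canonical miRNA across samples, BH-adjusted, with "significantly
  anticorrelated" defined as ρ < 0 and adjusted p < α;
* **enrichment statistics** (sample odds ratio (a·d)/(b·c) with a
  two-sided Fisher exact p-value) of a focal gene list — e.g.
  experimentally downregulated genes — among anticorrelated genes or
  among seed-carrying genes;
* a **Mann–Whitney** comparison of the correlation distributions of
  genes with versus without the canonical seed.

## Sequence conventions

miRNAs are stored in the RNA alphabet; transcripts in DNA. All matching
happens in DNA space: a seed is converted to the mRNA-sense *site motif*
by reverse complement and U→T transliteration (`makeSiteMotif`), and
exact string matching is then performed on the sense-strand spliced
sequence. Lowercase input is uppercased; any non-ACGT character
(including N) in a window makes that window a non-match, which handles
ambiguity codes deterministically. Negative 5′ shifts (5′ extensions)
are rejected rather than ignored — deriving them would require genomic
context that a mature-miRNA FASTA does not carry — and seeds are derived
purely by positional shift of the canonical sequence; possible
non-templated first-nucleotide variants of real isomiRs are out of
scope.

Seed positions are 1-based in all definitions and outputs (matching the
field's "nucleotides 2–7" convention); internally, coordinates are
0-based half-open. Transcript loading (`loadTranscripts`) accepts a
genome FASTA plus a GENCODE-style GTF (exons are spliced; minus-strand
transcripts reverse-complemented; the 3′-UTR is the spliced region 3′ of
the stop codon, inferred from `stop_codon` or `CDS` features) or a
pre-spliced transcript FASTA. Because the annotation does not pin one
isoform per gene, a representative-transcript policy is explicit:
`longest_spliced` (default, deterministic, common practice),
`longest_utr3`, or `all_union` (a gene is a target if any of its
transcripts carries a site). Ties break on the lexicographically
smallest transcript id. Which policy the original cohort analyses used
is unknowable from published summaries, so none is claimed to reproduce
them exactly.

## Worked geometry example

```{r geometry}
m93 <- mir93_5p()
siteSequence(seedMotif(m93, "6mer"))               # CACTTT
siteSequence(seedMotif(isomiR(m93, 4), "7mer-m8")) # AACAGCA
siteSequence(makeExtendedMotif(m93, 4))            # AACAGCACTTT
frag <- "CTACCTGCACGAACAGCACTTTGTT"  # hairpin sense fragment
scanSites(frag, "CACTTT")       # 17
scanSites(frag, "AACAGCA")      # 12
scanSites(frag, "AACAGCACTTT")  # 12
```

The 6mer site at position 17 is *extendable*: positions 12–22 hold the
full 11-nt dual site, whose first seven characters are the +4 isomiR's
7mer-m8 site.

## Expression model and thresholds

Count matrices move through an explicit scale state machine
(`raw_counts → size_normalized → fpkm/rpm → log2p1`); each transition
validates its input scale, so a matrix can never be normalized twice.

* **Size factors** are median-of-ratios: for sample *j*, the median over
  reference genes of count/geometric-mean, the reference set being the
  rows positive in every sample (geometric means in log space). This is
  the standard bulk RNA-seq estimator; `DESeq2`'s implementation is used
  as a cross-check oracle in the test suite, not as the implementation.
* **FPKM** = normalized × 10⁹ / (length × column total) for mRNA (gene
  length = the representative transcript's spliced length); **RPM** =
  normalized × 10⁶ / column total for miRNA, where length normalization
  is meaningless. Both are then log2(1 + x) transformed.
* **Abundance filter** (default fraction 0.99): rows ranked by median
  expression descending, cumulative sum formed, and the minimal prefix
  reaching 99% of the total kept — the low-abundance tail is dropped.
  Medians are taken on the *linear* scale (FPKM/RPM), because a fraction
  of total expression is only meaningful additively; ties at the cut are
  kept together, and ranking ties break on row id so the filter is
  deterministic. Applied to the miRNA matrix, the same filter selects
  the "most abundant miRNAs" analyzed in the Jaccard ranking.
* **Expressed** (default threshold 1.0): a gene counts as expressed when
  its median log2(1+FPKM) is ≥ 1 (closed bound — a boundary gene is
  kept). The summary statistic is the median across samples; the
  published analyses state only the threshold, so the median is this
  package's choice, made for robustness.

Samples are paired between the mRNA and miRNA matrices by shared sample
id (never column order), optionally restricted to
`sample_type == "Primary Tumor"` via a sample sheet.

## Statistical choices

* **Spearman ρ** is the Pearson correlation of mid-ranks. Its two-sided
  zero-correlation p-value is exact (full permutation enumeration) for
  n < 10 and uses the t-approximation t = ρ√((n−2)/(1−ρ²)) otherwise;
  with cohort-scale n the approximation error is negligible (the test
  suite bounds the KS distance of null p-values from uniform at 0.05
  with n = 50). Constant genes are flagged `NA` and excluded from the
  BH family, which by default is all genes surviving the abundance
  filter.
* **BH adjustment** delegates to `stats::p.adjust(method = "BH")`; the
  test suite checks it against a hand-written step-up oracle.
* **Fisher's exact test** is computed in-package: the reported odds
  ratio is the *sample* estimate (a·d)/(b·c) — not the conditional MLE
  that `stats::fisher.test` returns, which differs noticeably in small
  tables — and the two-sided p sums hypergeometric point probabilities
  no larger than the observed one (the point-probability rule, which
  matches `fisher.test`'s p-value; both equivalences are asserted in
  tests). A zero cell makes the sample OR infinite and is flagged
  rather than corrected.
* **Mann–Whitney** wraps `stats::wilcox.test`, exact when both groups
  have ≤ 8 untied values, otherwise the tie-corrected normal
  approximation with continuity correction.
* **Jaccard** over an empty union and extension ratios over an empty
  canonical set are `NA`, never 0.

## The synthetic study generator

Real inputs for this analysis are multi-gigabyte cohort downloads, so
the package carries a generator (`simulateStudy`) that emulates their
*statistical structure* end to end. Its defaults are the package's
reference study conditions and are not tuned per analysis:

* 2,000 genes; spliced lengths lognormal (meanlog = log 1200,
  sdlog = 0.6, clamped to [300, 15000]), ~40% 3′-UTR, GC 0.45 — a
  deliberately coarse sketch of a human transcriptome; about half the
  genes get an intron and half sit on the minus strand, so the
  FASTA/GTF loader's splicing logic is exercised, not bypassed.
* Planting rates (p_can_only, p_iso_only, p_both) = (0.1, 0.1, 0.3) per
  gene for the focal miRNA (default hsa-miR-93-5p, +4 primary shift,
  +3 secondary), sites inserted at uniform positions in the 3′-UTR.
  Planting is by insertion, not rejection sampling; ground truth is
  corrected by rescanning the final sequences, so labels stay truthful
  even when background sequence collides with a motif. A
  `background = "clean"` mode scrubs accidental occurrences of the
  focal motifs before planting, giving site-free backgrounds for
  calibration checks where the planted overlap (0.3/0.5 = 0.6) must be
  recovered exactly.
* Expression: 200 samples; the focal miRNA's per-sample log2 abundance
  is Normal(10, 1); its isomiR rows are fixed small fractions of the
  canonical mean (2% for +4, 1.5% for +3) plus noise, mirroring the
  printed isomiR shares; mRNA counts are negative binomial (dispersion
  0.1) with mean μ₀ · library factor · exp(−β·z̃), where z̃ is the
  standardized focal log-abundance and β = 1 (jittered ±20%) only for
  planted targets. Multiplicative repression via exp(−β·z̃) is the
  simplest monotone model producing negative Spearman correlation — the
  only property the downstream analysis uses — and claims no
  biophysical realism.
* The emulated "experimentally downregulated" list is the 54 planted
  isomiR-target genes with the largest β.

All randomness flows from the single config seed; two runs with the same
seed are byte-identical. What passing tests on this generator do *not*
show: behaviour under real-data features it omits — 3′ supplementary
pairing and site-context effects, shared miRNA co-regulation,
batch/copy-number confounding of correlations, isoform switching, or
sequencing-depth artefacts beyond a lognormal library factor.

## Problem sizes used in checks

The packaged checks run the generator at its reference conditions:
2,000 genes for the overlap-recovery and null-calibration runs (100
samples, β = 0, for the null; BH discovery fraction bounded by
0.05 + 3·MC-SE), 800 genes × 200 samples × 20 replicates for repression
recovery (planted-target enrichment OR > 2 required in ≥ 95% of
replicates), and exhaustive Fisher-vs-enumeration comparison over all
2×2 tables with total ≤ 40. These sizes were chosen as the smallest at
which the binomial/Monte-Carlo error bands quoted above are meaningful.

## Orchestration

`simulateStudy(config, dir)` writes, and `loadStudy(paths)` reads, the
full input bundle as plain-text files (FASTA, GTF, TSV matrices, sample
sheet, gene list). `runStudy()` is the single entry point for the whole
analysis and returns the per-gene association table (with seed flags
per shift), the per-miRNA Jaccard tables for +4 and +3, the extension
table, both enrichment tests, the Mann–Whitney comparison, and a run
manifest (package version, parameter hash, problem sizes); with
`outDir` set, everything is written as tab-delimited UTF-8 tables with
`NA` for undefined values. The R functions are the interface; there is
deliberately no shell wrapper, since every consumer of this analysis
works in R.

## Known limitations

Only exact Watson–Crick 6mer/7mer-m8 matching is implemented: no
8mer/7mer-A1 classes, no G:U wobble, no centered sites, no site-context
scoring or conservation filtering. Gene length for FPKM is the
representative transcript's spliced length, not the union-exon length.
The Jaccard ranking is reported raw, without multiple-testing
correction across miRNAs or bootstrap intervals. Differential
expression is consumed as an input list, never recomputed.
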