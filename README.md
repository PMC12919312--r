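# isoTargetome

Dual-seed targetome analysis of canonical miRNAs and their 5′-isomiRs.

## What this solves

A miRNA's targets are defined by its **seed**: nucleotides 2–7 ("6mer")
or 2–8 ("7mer-m8") from the 5′ end, whose Watson–Crick complement is
searched in mRNA sequences. A **5′-isomiR** — a processing variant
trimmed by *k* nucleotides at the 5′ end — shifts that seed register, so
in general it should target different mRNAs. But when an mRNA carries a
contiguous match to miRNA nucleotides 2…*k*+8 (an **extended site**,
*k*+7 nt long; 11 nt for *k* = 4), that one stretch contains both the
canonical 6mer site (its last 6 bases) and the +*k* isomiR 7mer-m8 site
(its first 7 bases) — the isomiR then reinforces, rather than rewires,
repression of the same genes.

For researchers studying isomiR function in transcriptomic cohorts,
this package quantifies that architecture per miRNA:

* canonical (6mer) vs isomiR (7mer-m8) targetomes and their **Jaccard
  index** |A∩B|/|A∪B|, with percentile ranks across the abundant miRNAs;
* the proportion of canonical sites **extendable** to the full dual
  site (site- and gene-level);
* **anticorrelation screening** of genes against the canonical miRNA
  across samples (Spearman ρ, Benjamini–Hochberg adjustment; significant
  anticorrelation = ρ < 0 and adjusted p < 0.05);
* **enrichment** of a focal gene list among anticorrelated or
  seed-carrying genes (sample odds ratio (a·d)/(b·c), two-sided Fisher
  exact test) and a **Mann–Whitney** comparison of correlations for
  genes with vs without the canonical seed.

Expression matrices follow the standard bulk pipeline: median-of-ratios
size factors, FPKM (mRNA) or RPM (miRNA), log2(1+x), a 99%
cumulative-abundance filter, and an expressed/not-expressed call at
median log2(1+FPKM) ≥ 1. A synthetic-study generator (`simulateStudy`)
emulates the whole input bundle — transcriptome with planted seed sites,
paired negative-binomial count matrices with planted repression — so
every stage is testable without cohort downloads.

## Worked example

The seed geometry of hsa-miR-93-5p, checked against the hairpin
fragment that encodes it:

```r
library(isoTargetome)
m93 <- mir93_5p()
seedMotif(m93, "6mer")
#> SeedMotif 6mer seed AAAGUG -> site CACTTT
seedMotif(isomiR(m93, 4), "7mer-m8")
#> SeedMotif 7mer-m8 seed UGCUGUU -> site AACAGCA
makeExtendedMotif(m93, 4)
#> ExtendedMotif shift +4 site AACAGCACTTT (11 nt)

frag <- "CTACCTGCACGAACAGCACTTTGTT"
scanSites(frag, "CACTTT")       # canonical 6mer site starts at 17
scanSites(frag, "AACAGCACTTT")  # 11-nt extended dual site at 12
```

The 6mer at 17 sits inside the extended site at 12–22, i.e. it is
*extendable*: the +4 isomiR recognises the same place.

A full synthetic study (dual sites planted in 30% of genes,
canonical-only and isomiR-only in 10% each, repression β = 1):

```r
bundle <- simulateStudy(simulationConfig(seed = 42, nGenes = 500,
                                         nSamples = 60, nMirnas = 5))
res <- runStudy(bundle)

head(res$jaccardTables[["+4"]], 3)
#>           mirna 6mer 7mer-m8 intersection union    jaccard
#> 2 hsa-miR-93-5p  242     180          143   279 0.51254480
#> 3    sim-miR-02   76      42           10   108 0.09259259
#> 1    sim-miR-01  108      22            8   122 0.06557377

res$focalProfile[, c("jaccard", "extension_ratio_site", "extension_ratio_gene")]
#>     jaccard extension_ratio_site extension_ratio_gene
#> 1 0.5125448            0.3785489            0.4958678

length(res$expressedCheck$expressed)   # 54 of 54 planted targets expressed
res$enrichmentSeed$oddsRatio           # 4.653465
res$enrichmentSeed$p                   # 2.23592e-05
res$groupComparison$p                  # 1.199992e-28
```

Read: the dual-seed focal miRNA dominates the Jaccard ranking (0.51 vs
≤ 0.09 for background miRNAs, reflecting the planted 30%/50% overlap
plus random background sites); ~38% of its canonical sites are
extendable; the planted downregulated list is strongly enriched for the
canonical seed (OR 4.65) and genes carrying that seed are markedly more
anticorrelated with the miRNA (Mann–Whitney p ≈ 1e-28).

`runStudy(..., outDir = "out")` writes every table as TSV (per-gene
association table with `Correlation_canonical`, `Padj` and per-shift
seed flags; Jaccard tables with `6mer`, `7mer-m8`, `intersection`,
`union`, `jaccard` columns; the extension table; enrichment summary; a
run manifest). Real data enter through `loadStudy()` — genome FASTA +
GENCODE-style GTF, miRBase-style mature FASTA, isomiR labels in pipe
notation (`hsa-miR-93-5p|+4`), TSV count matrices, a sample sheet, and
a gene list.

See `vignettes/dual-seed-targetome.Rmd` for the model, parameter and
calibration details.

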