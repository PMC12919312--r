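# Independent oracles and shared fixtures, kept deliberately naive.

MIR93_SEQ <- "CAAAGUGCUGUUCGUGCAGGUAG"
# prefix of the shRNA sense fragment that encodes the hairpin
SHRNA_FRAG <- "CTACCTGCACGAACAGCACTTTGTT"

# O(L*m) sliding-window scan
naiveScan <- function(sequence, motif) {
  m <- nchar(motif); L <- nchar(sequence)
  if (L < m) return(integer(0))
  which(vapply(seq_len(L - m + 1L),
               function(i) substr(sequence, i, i + m - 1L) == motif,
               logical(1)))
}

# step-up BH by hand
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# two-sided Fisher p by direct enumeration with lchoose arithmetic
fisherEnumOracle <- function(a, b, c, d) {
  N <- a + b + c + d; r <- a + b; k <- a + c
  support <- max(0L, r + k - N):min(r, k)
  logp <- lchoose(k, support) + lchoose(N - k, r - support) - lchoose(N, r)
  probs <- exp(logp)
  pObs <- probs[support == a]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# random DNA / RNA strings
randomDNA <- function(n, gc = 0.5) {
  paste0(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
         collapse = "")
}
randomRNA <- function(n) {
  paste0(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

revcompOracle <- function(dna) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", dna), "")[[1]]),
        collapse = "")
}

# Toy two-exon annotation on a 60-bp contig: exon1 = [5,20] (16 bp),
# exon2 = [31,50] (20 bp); spliced length 36. On the plus strand the
# CDS is [7,20]+[31,37] and the stop codon [38,40], i.e. spliced
# positions 24-26 (1-based), so the 3'-UTR is the 0-based half-open
# interval [26, 36).
toyAnnotation <- function(strand = "+") {
  GenomicRanges::GRanges(
    seqnames = "chrT",
    ranges = IRanges::IRanges(start = c(1, 5, 31, 7, 31, 38),
                              end = c(60, 20, 50, 20, 37, 40)),
    strand = strand,
    type = c("gene", "exon", "exon", "CDS", "CDS", "stop_codon"),
    gene_id = "gT",
    transcript_id = c(NA, rep("txT", 5)),
    gene_name = "geneT")
}

quietly <- function(expr) suppressWarnings(suppressMessages(expr))
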