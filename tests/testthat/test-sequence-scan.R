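.toyGenome <- function(seq60) {
  Biostrings::DNAStringSet(setNames(seq60, "chrT"))
}

test_that("transcripts are spliced from exons and the 3'-UTR placed after the stop", {
  set.seed(50)
  g <- randomDNA(60)
  genome <- .toyGenome(g)

  rec <- loadTranscripts(genome, toyAnnotation("+"))
  expect_equal(nrow(rec), 1L)
  expected <- paste0(substr(g, 5, 20), substr(g, 31, 50))
  expect_equal(rec$sequence, expected)
  expect_equal(nchar(rec$sequence), 36L)
  # stop codon at spliced 0-based offset 23 -> utr3 = [26, 36)
  expect_equal(rec$utr3_start, 26L)
  expect_equal(rec$utr3_end, 36L)
  expect_equal(utr3Sequence(rec), substr(expected, 27, 36))
})

test_that("minus-strand transcripts are reverse-complemented", {
  set.seed(51)
  g <- randomDNA(60)
  exonsOnly <- toyAnnotation("-")
  rec <- loadTranscripts(.toyGenome(g), exonsOnly)
  plusConcat <- paste0(substr(g, 5, 20), substr(g, 31, 50))
  expect_equal(rec$sequence, revcompOracle(plusConcat))

  # minus-strand stop codon: genomic [9,11]; its 3'-most base (start 9)
  # sits at spliced 0-based offset 20 + (20 - 9) = 31 -> utr3 = [32, 36)
  ann <- GenomicRanges::GRanges(
    seqnames = "chrT",
    ranges = IRanges::IRanges(start = c(5, 31, 12, 31, 9),
                              end = c(20, 50, 20, 45, 11)),
    strand = "-",
    type = c("exon", "exon", "CDS", "CDS", "stop_codon"),
    gene_id = "gT", transcript_id = "txT", gene_name = "geneT")
  rec <- loadTranscripts(.toyGenome(g), ann)
  expect_equal(rec$utr3_start, 32L)
  expect_equal(rec$utr3_end, 36L)
})

test_that("CDS without a stop_codon feature implies utr3 three bases later", {
  set.seed(52)
  g <- randomDNA(60)
  ann <- GenomicRanges::GRanges(
    seqnames = "chrT",
    ranges = IRanges::IRanges(start = c(5, 31, 7, 31),
                              end = c(20, 50, 20, 37)),
    strand = "+",
    type = c("exon", "exon", "CDS", "CDS"),
    gene_id = "gT", transcript_id = "txT", gene_name = "geneT")
  rec <- loadTranscripts(.toyGenome(g), ann)
  # CDS ends at spliced 0-based offset 22; stop assumed at 23-25
  expect_equal(rec$utr3_start, 26L)
})

test_that("non-coding transcripts have an empty 3'-UTR interval", {
  set.seed(53)
  g <- randomDNA(60)
  ann <- GenomicRanges::GRanges(
    seqnames = "chrT", ranges = IRanges::IRanges(5, 50), strand = "+",
    type = "exon", gene_id = "gT", transcript_id = "txT",
    gene_name = "geneT")
  rec <- loadTranscripts(.toyGenome(g), ann)
  expect_true(is.na(rec$utr3_start))
  expect_equal(utr3Sequence(rec), "")
})

test_that("id mismatches between FASTA and GTF are skipped with a warning", {
  set.seed(54)
  genome <- Biostrings::DNAStringSet(setNames(randomDNA(60), "chrOther"))
  expect_warning(expect_error(loadTranscripts(genome, toyAnnotation("+")),
                              "no transcripts"),
                 "not found in FASTA")
  # version suffixes are tolerated when stripping is on
  genome2 <- Biostrings::DNAStringSet(setNames(randomDNA(60), "chrT.2"))
  rec <- loadTranscripts(genome2, toyAnnotation("+"), stripVersions = TRUE)
  expect_equal(nrow(rec), 1L)
})

test_that("representative selection is deterministic with lexicographic ties", {
  recs <- data.frame(
    transcript_id = c("tx2", "tx1", "tx3"),
    gene_id = "g1", gene_name = "g1",
    sequence = c(strrep("A", 1200), strrep("C", 900), strrep("G", 1200)),
    utr3_start = c(NA, 100L, 1000L), utr3_end = c(NA, 900L, 1200L),
    stringsAsFactors = FALSE)
  # longest spliced, tie 1200/1200 broken by smaller transcript id
  expect_equal(selectRepresentative(recs, "longest_spliced")$transcript_id,
               "tx2")
  expect_equal(selectRepresentative(recs, "longest_utr3")$transcript_id,
               "tx1")  # 800 beats 200 and NA
  expect_equal(nrow(selectRepresentative(recs, "all_union")), 3L)
})

test_that("scanSites reports all overlapping matches in ascending order", {
  expect_equal(scanSites(SHRNA_FRAG, "CACTTT"), 17L)
  expect_equal(scanSites(SHRNA_FRAG, "AACAGCA"), 12L)
  expect_equal(scanSites(SHRNA_FRAG, "AACAGCACTTT"), 12L)
  expect_equal(scanSites("AAAA", "AAA"), c(1L, 2L))
  expect_equal(scanSites("AA", "AAA"), integer(0))
  expect_equal(scanSites("", "AAA"), integer(0))
  # N windows never match
  expect_equal(scanSites("CANTTTCACTTT", "CACTTT"), 7L)
})

test_that("scanSites agrees with the naive sliding-window oracle", {
  set.seed(55)
  for (i in 1:1000) {
    L <- sample(20:150, 1)
    seq <- randomDNA(L, gc = runif(1, 0.3, 0.7))
    motif <- if (i %% 3 == 0) randomDNA(sample(6:11, 1), 0.5)
             else substr(seq, sample(L - 11, 1), 0) # force some matches
    if (!nzchar(motif)) {
      p <- sample(L - 11, 1)
      motif <- substr(seq, p, p + sample(5:10, 1))
    }
    expect_identical(scanSites(seq, motif), as.integer(naiveScan(seq, motif)))
  }
})

test_that("extendable flags require the full extended window", {
  ext <- makeExtendedMotif(mir93_5p(), 4)  # AACAGCACTTT, length 11
  # window 12-22 of the fragment matches the full extended site
  expect_true(annotateExtendable(17L, SHRNA_FRAG, ext))
  # too close to the 5' boundary: window would start before position 1
  expect_false(annotateExtendable(3L, "GGCACTTTGG", ext))
  # 6mer present but not embedded in the extended site
  expect_false(annotateExtendable(5L, "TTTTCACTTTGG", ext))
})

test_that("every extendable 6mer co-occurs with an isomiR 7mer-m8 site", {
  set.seed(56)
  m93 <- mir93_5p()
  for (k in c(3L, 4L)) {
    ext <- makeExtendedMotif(m93, k)
    site6 <- siteSequence(seedMotif(m93, "6mer"))
    site7 <- siteSequence(seedMotif(isomiR(m93, k), "7mer-m8"))
    off <- nchar(siteSequence(ext)) - 6L
    for (i in 1:40) {
      seq <- randomDNA(300)
      # plant one extended site and one bare 6mer
      substr(seq, 50, 49 + nchar(siteSequence(ext))) <- siteSequence(ext)
      starts6 <- scanSites(seq, site6)
      flags <- annotateExtendable(starts6, seq, ext)
      for (j in seq_along(starts6)) {
        if (flags[j])
          expect_true((starts6[j] - off) %in% scanSites(seq, site7))
      }
      expect_true(any(flags))
    }
  }
})

test_that("target sets respect regions and the utr3 set is nested in full_mrna", {
  set.seed(57)
  m93 <- mir93_5p()
  can6 <- seedMotif(m93, "6mer")
  # gene with the motif only in the CDS part
  sq <- randomDNA(200)
  sq <- paste0(substr(sq, 1, 20), "CACTTT", substr(sq, 27, 200))
  sq <- paste0(substr(sq, 1, 150), strrep("G", 50))  # clean 3'UTR
  recs <- data.frame(transcript_id = "t1", gene_id = "g1",
                     gene_name = "g1", sequence = sq,
                     utr3_start = 150L, utr3_end = 200L,
                     stringsAsFactors = FALSE)
  expect_equal(targetGenes(buildTargetSet("m", recs, can6, "full_mrna")),
               "g1")
  expect_equal(targetGenes(buildTargetSet("m", recs, can6, "utr3")),
               character(0))
  expect_error(buildTargetSet("m", recs[0, ], can6), "empty gene universe")

  # nesting on random records
  recs <- do.call(rbind, lapply(1:60, function(i) {
    L <- sample(150:400, 1)
    data.frame(transcript_id = paste0("t", i), gene_id = paste0("g", i),
               gene_name = paste0("g", i), sequence = randomDNA(L),
               utr3_start = as.integer(round(L * 0.6)), utr3_end = L,
               stringsAsFactors = FALSE)
  }))
  for (motif in list(can6, seedMotif(isomiR(m93, 4), "7mer-m8"))) {
    utr3Set <- targetGenes(buildTargetSet("m", recs, motif, "utr3"))
    fullSet <- targetGenes(buildTargetSet("m", recs, motif, "full_mrna"))
    expect_true(all(utr3Set %in% fullSet))
  }
})

test_that("all_union marks a gene as a target if any transcript has a site", {
  sq1 <- paste0(strrep("G", 50), "CACTTT", strrep("G", 50))
  sq2 <- strrep("A", 120)
  recs <- data.frame(transcript_id = c("t1", "t2"), gene_id = "g1",
                     gene_name = "g1", sequence = c(sq1, sq2),
                     utr3_start = NA_integer_, utr3_end = NA_integer_,
                     stringsAsFactors = FALSE)
  can6 <- seedMotif(mir93_5p(), "6mer")
  # the longer transcript (t2, 120 nt) lacks the site
  expect_equal(targetGenes(buildTargetSet(
    "m", selectRepresentative(recs, "longest_spliced"), can6)),
    character(0))
  expect_equal(targetGenes(buildTargetSet(
    "m", selectRepresentative(recs, "all_union"), can6)), "g1")
})
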