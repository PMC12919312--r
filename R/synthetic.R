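#' Simulation configuration
#'
#' Bundles every knob of the synthetic study generator. The defaults
#' describe the study conditions the rest of the package is exercised
#' under: 2,000 genes, planting rates (0.1, 0.1, 0.3) for
#' canonical-only / isomiR-only / dual sites of the focal miRNA,
#' repression coefficient beta = 1 acting on planted targets, and 200
#' samples.
#'
#' @param seed RNG seed; all randomness flows from it.
#' @param nGenes number of genes.
#' @param lengthMeanLog,lengthSdLog lognormal parameters of spliced
#'   transcript length (bp); lengths are clamped to [300, 15000].
#' @param utr3Fraction fraction of the transcript assigned to the
#'   3'-UTR.
#' @param gcContent background GC content.
#' @param nMirnas number of decoy mature miRNAs (beyond the focal one).
#' @param focal the focal \linkS4class{MatureMiRNA}; default
#'   hsa-miR-93-5p.
#' @param shifts isomiR 5' shifts carried by the focal miRNA; the first
#'   is the primary one used for planting.
#' @param pCanOnly,pIsoOnly,pBoth per-gene probabilities of planting a
#'   canonical-only 6mer site, an isomiR-only 7mer-m8 site, or the
#'   overlapping extended dual site (must sum to <= 1).
#' @param plantRegion where sites are planted (\code{"utr3"} or
#'   \code{"full_mrna"}).
#' @param background \code{"random"} (realistic: accidental motif
#'   occurrences are left in place and ground truth is corrected by
#'   rescanning) or \code{"clean"} (accidental occurrences of the focal
#'   motifs are scrubbed before planting, so class frequencies are
#'   exactly the planting rates).
#' @param intronProb probability a gene gets two exons.
#' @param minusStrandProb probability a gene sits on the minus strand.
#' @param nSamples number of samples.
#' @param mirMeanLog2,mirSdLog2 the focal miRNA's per-sample log2
#'   abundance is Normal(mirMeanLog2, mirSdLog2).
#' @param isomirFractions named fractions of the canonical row's
#'   abundance carried by each isomiR (names = shifts); defaults 1.5%
#'   (+3) and 2% (+4).
#' @param beta repression coefficient: planted targets' negative-
#'   binomial mean is multiplied by exp(-beta_i * z) with z the
#'   standardized focal log-abundance; per-gene beta_i is jittered
#'   uniformly within 20% of \code{beta}.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param baseMeanLog,baseSdLog lognormal parameters of per-gene base
#'   expression.
#' @param librarySdLog lognormal sigma of per-sample library-size
#'   factors.
#' @param normalFraction fraction of samples labelled as non-tumor in
#'   the sample sheet (they still receive the same generative model).
#' @param nDownregulated size of the emulated experimentally
#'   downregulated gene list (planted isomiR targets with the largest
#'   beta).
#' @return A validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L,
                             nGenes = 2000L,
                             lengthMeanLog = log(1200), lengthSdLog = 0.6,
                             utr3Fraction = 0.4,
                             gcContent = 0.45,
                             nMirnas = 10L,
                             focal = mir93_5p(),
                             shifts = c(4L, 3L),
                             pCanOnly = 0.1, pIsoOnly = 0.1, pBoth = 0.3,
                             plantRegion = c("utr3", "full_mrna"),
                             background = c("random", "clean"),
                             intronProb = 0.5,
                             minusStrandProb = 0.5,
                             nSamples = 200L,
                             mirMeanLog2 = 10, mirSdLog2 = 1,
                             isomirFractions = c("3" = 0.015, "4" = 0.02),
                             beta = 1,
                             dispersion = 0.1,
                             baseMeanLog = log(200), baseSdLog = 1,
                             librarySdLog = 0.2,
                             normalFraction = 0,
                             nDownregulated = 54L) {
  plantRegion <- match.arg(plantRegion)
  background <- match.arg(background)
  stopifnot(pCanOnly >= 0, pIsoOnly >= 0, pBoth >= 0,
            pCanOnly + pIsoOnly + pBoth <= 1,
            dispersion > 0, nGenes >= 1, nSamples >= 5,
            gcContent > 0, gcContent < 1, beta >= 0,
            all(shifts >= 1), is(focal, "MatureMiRNA"))
  cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
              lengthMeanLog = lengthMeanLog, lengthSdLog = lengthSdLog,
              utr3Fraction = utr3Fraction, gcContent = gcContent,
              nMirnas = as.integer(nMirnas), focal = focal,
              shifts = as.integer(shifts),
              pCanOnly = pCanOnly, pIsoOnly = pIsoOnly, pBoth = pBoth,
              plantRegion = plantRegion, background = background,
              intronProb = intronProb, minusStrandProb = minusStrandProb,
              nSamples = as.integer(nSamples),
              mirMeanLog2 = mirMeanLog2, mirSdLog2 = mirSdLog2,
              isomirFractions = isomirFractions, beta = beta,
              dispersion = dispersion, baseMeanLog = baseMeanLog,
              baseSdLog = baseSdLog, librarySdLog = librarySdLog,
              normalFraction = normalFraction,
              nDownregulated = as.integer(nDownregulated))
  class(cfg) <- "SimulationConfig"
  cfg
}

.randomSeq <- function(n, gc) {
  paste0(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
         collapse = "")
}

# Replace every occurrence of any motif by fresh random bases until none
# remains (used by background = "clean").
.scrubMotifs <- function(seq, motifs, gc) {
  repeat {
    hit <- FALSE
    for (m in motifs) {
      starts <- scanSites(seq, m)
      if (length(starts) > 0) {
        hit <- TRUE
        for (p in starts)
          substr(seq, p, p + nchar(m) - 1L) <- .randomSeq(nchar(m), gc)
      }
    }
    if (!hit) return(seq)
  }
}

.hasMotif <- function(seq, m) length(scanSites(seq, m)) > 0

#' Simulate a synthetic transcriptome with planted seed sites
#'
#' Generates, per gene, a random spliced transcript at the configured GC
#' content (5'-UTR, CDS, stop codon, 3'-UTR layout; roughly half the
#' genes get an intron and half sit on the minus strand), plants the
#' focal miRNA's canonical 6mer site, isomiR 7mer-m8 site, or the
#' overlapping extended dual site according to the planting rates, and
#' assembles per-gene genomic contigs plus a GENCODE-style annotation.
#' Ground-truth labels are taken from a rescan of the final sequences,
#' so accidental background matches are labelled truthfully.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return A list: \code{genome} (DNAStringSet of contigs), \code{gtf}
#'   (GRanges with gene/transcript/exon/CDS/stop_codon features),
#'   \code{records} (transcript data.frame in
#'   \code{\link{loadTranscripts}} layout), \code{truth} (per-gene
#'   data.frame: intended class, rescanned has_6mer / has_7mer /
#'   extendable flags, lengths), \code{motifs} (the planted site
#'   strings), and \code{matures} (focal + decoy miRNAs).
#' @export
simulateTranscriptome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  focal <- config$focal
  primaryShift <- config$shifts[1]
  site6 <- siteSequence(seedMotif(focal, "6mer"))
  iso <- isomiR(focal, primaryShift)
  site7 <- siteSequence(seedMotif(iso, "7mer-m8"))
  ext <- makeExtendedMotif(focal, primaryShift)
  siteExt <- siteSequence(ext)
  motifs <- c(canonical_6mer = site6, isomir_7mer = site7,
              extended = siteExt)

  classes <- sample(c("both", "can_only", "iso_only", "none"),
                    config$nGenes, replace = TRUE,
                    prob = c(config$pBoth, config$pCanOnly,
                             config$pIsoOnly,
                             1 - config$pBoth - config$pCanOnly -
                               config$pIsoOnly))
  plantSite <- c(both = siteExt, can_only = site6, iso_only = site7,
                 none = "")

  genomeSeqs <- character(config$nGenes)
  contigNames <- character(config$nGenes)
  gtfRows <- vector("list", config$nGenes)
  recRows <- vector("list", config$nGenes)
  truthRows <- vector("list", config$nGenes)

  for (i in seq_len(config$nGenes)) {
    gid <- sprintf("GENE%05d", i)
    tid <- sprintf("TX%05d.1", i)
    contig <- sprintf("ctg%05d", i)
    L <- round(rlnorm(1, config$lengthMeanLog, config$lengthSdLog))
    L <- max(300L, min(15000L, as.integer(L)))
    utr5 <- 50L
    utr3Len <- max(80L, as.integer(round(L * config$utr3Fraction)))
    cdsLen <- L - utr5 - 3L - utr3Len
    cdsLen <- (cdsLen %/% 3L) * 3L
    utr3Len <- L - utr5 - 3L - cdsLen
    utr3Start0 <- L - utr3Len          # 0-based half-open [utr3Start0, L)

    intended <- classes[i]
    site <- plantSite[[intended]]
    for (attempt in 1:50) {
      spliced <- .randomSeq(L, config$gcContent)
      if (config$background == "clean")
        spliced <- .scrubMotifs(spliced, motifs, config$gcContent)
      if (nzchar(site)) {
        lo <- if (config$plantRegion == "utr3") utr3Start0 + 1L else 1L
        hi <- L - nchar(site) + 1L
        pos <- if (hi > lo) sample(lo:hi, 1) else lo
        substr(spliced, pos, pos + nchar(site) - 1L) <- site
      }
      if (config$background == "random") break
      ok <- (.hasMotif(spliced, site6) ==
               (intended %in% c("both", "can_only"))) &&
            (.hasMotif(spliced, site7) ==
               (intended %in% c("both", "iso_only")))
      if (ok) break
    }

    # genomic layout: optional intron inside the CDS
    strand <- if (runif(1) < config$minusStrandProb) "-" else "+"
    twoExons <- runif(1) < config$intronProb && cdsLen > 60L
    if (twoExons) {
      cutAfter <- sample((utr5 + 10L):(utr5 + cdsLen - 10L), 1)
      intronLen <- sample(100:500, 1)
      intron <- .randomSeq(intronLen, config$gcContent)
      pre <- paste0(substr(spliced, 1, cutAfter), intron,
                    substr(spliced, cutAfter + 1L, L))
      exonsPre <- rbind(c(1L, cutAfter),
                        c(cutAfter + intronLen + 1L, L + intronLen))
    } else {
      pre <- spliced
      exonsPre <- rbind(c(1L, L))
    }
    preLen <- nchar(pre)
    # spliced 1-based intervals of CDS and stop codon
    cdsSpliced <- c(utr5 + 1L, utr5 + cdsLen)
    stopSpliced <- c(utr5 + cdsLen + 1L, utr5 + cdsLen + 3L)
    # map a spliced interval to pre-mRNA (insert intron offset), then to
    # the contig (reverse-complement flip for minus strand); may split
    # across the junction for the CDS
    toPre <- function(p) {
      if (twoExons && p > exonsPre[1, 2]) p + (exonsPre[2, 1] - 1L -
                                                 exonsPre[1, 2]) else p
    }
    mapIval <- function(s, e) {
      sP <- toPre(s); eP <- toPre(e)
      parts <- if (twoExons && s <= exonsPre[1, 2] &&
                   eP >= exonsPre[2, 1])
        rbind(c(sP, exonsPre[1, 2]), c(exonsPre[2, 1], eP))
      else rbind(c(sP, eP))
      if (strand == "-")
        parts <- cbind(preLen - parts[, 2] + 1L, preLen - parts[, 1] + 1L)
      parts[order(parts[, 1]), , drop = FALSE]
    }
    contigSeq <- if (strand == "-") .revcompDNA(pre) else pre
    genomeSeqs[i] <- contigSeq
    contigNames[i] <- contig

    exonParts <- mapIval(1L, L)
    cdsParts <- mapIval(cdsSpliced[1], cdsSpliced[2])
    stopParts <- mapIval(stopSpliced[1], stopSpliced[2])
    mk <- function(type, parts) data.frame(
      chrom = contig, start = parts[, 1], end = parts[, 2],
      strand = strand, type = type, gene_id = gid, transcript_id = tid,
      gene_name = gid, stringsAsFactors = FALSE)
    gtfRows[[i]] <- rbind(
      mk("gene", rbind(c(1L, preLen))), mk("transcript",
                                           rbind(c(1L, preLen))),
      mk("exon", exonParts), mk("CDS", cdsParts),
      mk("stop_codon", stopParts))

    recRows[[i]] <- data.frame(
      transcript_id = tid, gene_id = gid, gene_name = gid,
      sequence = spliced, utr3_start = utr3Start0, utr3_end = L,
      stringsAsFactors = FALSE)

    regionSeq <- if (config$plantRegion == "utr3")
      substr(spliced, utr3Start0 + 1L, L) else spliced
    starts6 <- scanSites(regionSeq, site6)
    offset <- if (config$plantRegion == "utr3") utr3Start0 else 0L
    extendable <- if (length(starts6) > 0)
      any(annotateExtendable(starts6 + offset, spliced, ext)) else FALSE
    truthRows[[i]] <- data.frame(
      gene_id = gid, class_intended = intended,
      has_6mer = length(starts6) > 0,
      has_7mer = .hasMotif(regionSeq, site7),
      extendable = extendable,
      length = L, utr3_length = utr3Len, strand = strand,
      stringsAsFactors = FALSE)
  }

  genome <- Biostrings::DNAStringSet(setNames(genomeSeqs, contigNames))
  gtfDf <- do.call(rbind, gtfRows)
  gtf <- GenomicRanges::GRanges(
    seqnames = gtfDf$chrom,
    ranges = IRanges::IRanges(gtfDf$start, gtfDf$end),
    strand = gtfDf$strand,
    type = gtfDf$type, gene_id = gtfDf$gene_id,
    transcript_id = gtfDf$transcript_id, gene_name = gtfDf$gene_name,
    source = "isoTargetome_sim",
    phase = ifelse(gtfDf$type == "CDS", 0L, NA_integer_))

  decoys <- list()
  if (config$nMirnas > 0) {
    for (k in seq_len(config$nMirnas)) {
      nm <- sprintf("sim-miR-%02d", k)
      decoys[[nm]] <- matureMiRNA(
        nm, chartr("T", "U", .randomSeq(22L, 0.5)))
    }
  }
  matures <- c(setNames(list(focal), focal@name), decoys)

  list(genome = genome, gtf = gtf,
       records = do.call(rbind, recRows),
       truth = do.call(rbind, truthRows),
       motifs = motifs, matures = matures)
}

#' Simulate paired miRNA / mRNA count matrices
#'
#' Per sample j the focal miRNA's log2 abundance is Normal; isomiR rows
#' are fixed small fractions of the canonical mean (plus negative-
#' binomial noise); mRNA counts are NegBin with mean
#' mu_i0 * L_j * exp(-beta_i * z_j) where z is the standardized focal
#' log-abundance, L_j a lognormal library factor, and beta_i > 0 only
#' for planted targets.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param sim output of \code{\link{simulateTranscriptome}} (for the
#'   ground-truth labels and decoy miRNAs).
#' @return A list: \code{mrnaCounts} and \code{mirCounts}
#'   (\linkS4class{ExpressionMatrix}, raw counts), \code{sampleSheet}
#'   (data.frame with \code{sample_id}, \code{sample_type}),
#'   \code{downregulated} (character vector emulating the experimentally
#'   downregulated gene list), and \code{truth} with a \code{beta}
#'   column added.
#' @export
simulateExpression <- function(config, sim) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  truth <- sim$truth
  n <- config$nSamples
  samples <- sprintf("S%03d", seq_len(n))
  sizeNB <- 1 / config$dispersion

  z <- rnorm(n, config$mirMeanLog2, config$mirSdLog2)
  zt <- as.numeric(scale(z))
  lib <- rlnorm(n, 0, config$librarySdLog)

  # miRNA matrix: focal canonical + isomiR rows + decoys
  focalName <- config$focal@name
  muFocal <- 2^z
  mirRows <- list()
  mirRows[[focalName]] <- rnbinom(n, mu = muFocal * lib, size = sizeNB)
  for (s in config$shifts) {
    frac <- config$isomirFractions[[as.character(s)]]
    if (is.null(frac)) frac <- 0.02
    lab <- paste0(focalName, "|+", s)
    mirRows[[lab]] <- rnbinom(n, mu = frac * muFocal * lib, size = sizeNB)
  }
  for (nm in setdiff(names(sim$matures), focalName)) {
    base <- 2^rnorm(1, config$mirMeanLog2 - 2, 2)
    mirRows[[nm]] <- rnbinom(n, mu = base * lib, size = sizeNB)
  }
  mirMat <- do.call(rbind, mirRows)
  dimnames(mirMat) <- list(names(mirRows), samples)

  planted <- truth$class_intended != "none"
  beta <- ifelse(planted, config$beta * runif(nrow(truth), 0.8, 1.2), 0)
  mu0 <- rlnorm(nrow(truth), config$baseMeanLog, config$baseSdLog)
  mu <- outer(mu0, lib) * exp(-beta %o% zt)
  mrnaMat <- matrix(rnbinom(length(mu), mu = mu, size = sizeNB),
                    nrow = nrow(mu),
                    dimnames = list(truth$gene_id, samples))

  nNormal <- round(config$normalFraction * n)
  sampleType <- c(rep("Solid Tissue Normal", nNormal),
                  rep("Primary Tumor", n - nNormal))
  sampleSheet <- data.frame(sample_id = samples,
                            sample_type = sample(sampleType),
                            stringsAsFactors = FALSE)

  isoTargets <- truth$gene_id[truth$has_7mer]
  ord <- order(-beta[match(isoTargets, truth$gene_id)])
  down <- head(isoTargets[ord], config$nDownregulated)
  truth$beta <- beta

  list(mrnaCounts = expressionMatrix(mrnaMat, "raw_counts"),
       mirCounts = expressionMatrix(mirMat, "raw_counts"),
       sampleSheet = sampleSheet, downregulated = down, truth = truth)
}

#' Simulate a full synthetic study bundle
#'
#' One call produces everything the analysis pipeline consumes:
#' transcriptome (genome contigs + GTF), mature miRNA FASTA with isomiR
#' labels, paired count matrices, a sample sheet, the emulated
#' downregulated-gene list, and the ground truth. With \code{dir} set,
#' all files are written in the dialects the loaders read.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param dir optional output directory (created if needed).
#' @return The bundle list (components of
#'   \code{\link{simulateTranscriptome}} and
#'   \code{\link{simulateExpression}}, plus \code{config} and, when
#'   written, \code{paths}).
#' @export
simulateStudy <- function(config = simulationConfig(), dir = NULL) {
  sim <- simulateTranscriptome(config)
  expr <- simulateExpression(config, sim)
  bundle <- c(sim[c("genome", "gtf", "records", "motifs", "matures")],
              expr, list(config = config))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      genomeFasta = file.path(dir, "genome.fa"),
      gtf = file.path(dir, "annotation.gtf"),
      mirnaFasta = file.path(dir, "mirnas.fa"),
      isomirs = file.path(dir, "isomirs.tsv"),
      mrnaCounts = file.path(dir, "mrna_counts.tsv"),
      mirnaCounts = file.path(dir, "mirna_counts.tsv"),
      sampleSheet = file.path(dir, "samples.tsv"),
      downregulated = file.path(dir, "downregulated.tsv"),
      truth = file.path(dir, "ground_truth.tsv"))
    Biostrings::writeXStringSet(bundle$genome, paths$genomeFasta)
    rtracklayer::export(bundle$gtf, paths$gtf, format = "gtf")
    mat <- Biostrings::BStringSet(vapply(bundle$matures,
                                         function(m) m@sequence,
                                         character(1)))
    names(mat) <- names(bundle$matures)
    Biostrings::writeXStringSet(mat, paths$mirnaFasta)
    write.table(
      data.frame(label = paste0(config$focal@name, "|+", config$shifts)),
      paths$isomirs, sep = "\t", quote = FALSE, row.names = FALSE)
    writeCountsTSV(bundle$mrnaCounts, paths$mrnaCounts, "gene_id")
    writeCountsTSV(bundle$mirCounts, paths$mirnaCounts, "mirna_label")
    write.table(bundle$sampleSheet, paths$sampleSheet, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene_id = bundle$downregulated),
                paths$downregulated, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(bundle$truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    bundle$paths <- paths
  }
  bundle
}
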