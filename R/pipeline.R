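#' Load a study bundle from files
#'
#' Reads the file set emitted by \code{\link{simulateStudy}} (or
#' equivalently structured real data): genome FASTA + GTF, mature miRNA
#' FASTA, isomiR label TSV, two count TSVs, sample sheet, and a
#' downregulated-gene list.
#'
#' @param paths named list of file paths: \code{genomeFasta},
#'   \code{gtf}, \code{mirnaFasta}, \code{isomirs}, \code{mrnaCounts},
#'   \code{mirnaCounts}, \code{sampleSheet}, \code{downregulated}.
#' @param fastaType forwarded to \code{\link{loadTranscripts}}.
#' @return A bundle list as consumed by \code{\link{runStudy}}.
#' @export
loadStudy <- function(paths, fastaType = "genome") {
  need <- c("genomeFasta", "gtf", "mirnaFasta", "mrnaCounts",
            "mirnaCounts", "sampleSheet", "downregulated")
  missing <- setdiff(need, names(paths))
  if (length(missing) > 0)
    stop("missing input path(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  absent <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
  if (length(absent) > 0)
    stop("input file(s) not found: ", paste(absent, collapse = ", "),
         call. = FALSE)
  matures <- readMatureFasta(paths$mirnaFasta)
  list(records = loadTranscripts(paths$genomeFasta, paths$gtf,
                                 fastaType = fastaType),
       matures = matures,
       isomirs = if (!is.null(paths$isomirs) && file.exists(paths$isomirs))
         readIsomirTable(paths$isomirs, matures) else NULL,
       mrnaCounts = readCountsTSV(paths$mrnaCounts),
       mirCounts = readCountsTSV(paths$mirnaCounts),
       sampleSheet = read.delim(paths$sampleSheet,
                                stringsAsFactors = FALSE),
       downregulated = read.delim(paths$downregulated,
                                  stringsAsFactors = FALSE)[[1]])
}

#' Scan a transcript universe for a miRNA's dual-seed sites
#'
#' Builds the canonical 6mer target set, the per-shift isomiR 7mer-m8
#' target sets, and the canonical site table with extendable flags for
#' the primary (first) shift.
#'
#' @param records transcript records (already reduced to representatives
#'   unless the all-union policy is wanted).
#' @param mirna a \linkS4class{MatureMiRNA}.
#' @param shifts isomiR 5' shifts to derive.
#' @param region \code{"full_mrna"} or \code{"utr3"}.
#' @return A list: \code{canonicalSet} (TargetSet), \code{isomirSets}
#'   (named list of TargetSets, one per shift), \code{canonicalSites}
#'   (site data.frame with extendable flags), \code{extended} (the
#'   ExtendedMotif of the primary shift).
#' @export
runScan <- function(records, mirna, shifts = c(4L, 3L),
                    region = c("full_mrna", "utr3")) {
  region <- match.arg(region)
  if (nrow(records) == 0)
    stop("scan stage: empty transcript universe", call. = FALSE)
  can6 <- seedMotif(mirna, "6mer")
  ext <- makeExtendedMotif(mirna, shifts[1])
  canonicalSet <- buildTargetSet(mirna@name, records, can6, region)
  isomirSets <- lapply(shifts, function(s) {
    iso <- isomiR(mirna, s)
    buildTargetSet(isomirLabel(iso), records,
                   seedMotif(iso, "7mer-m8"), region)
  })
  names(isomirSets) <- paste0("+", shifts)
  sites <- scanTranscripts(records, can6, region = region,
                           extended = ext, motifId = "canonical_6mer")
  list(canonicalSet = canonicalSet, isomirSets = isomirSets,
       canonicalSites = sites, extended = ext)
}

.md5OfObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(x, file = f)
  unname(tools::md5sum(f))
}

#' Run the full dual-seed targetome analysis
#'
#' Orchestrates every stage on a study bundle: representative-transcript
#' selection; mRNA normalization (median-of-ratios size factors, FPKM,
#' log2(1+FPKM)) with the cumulative-abundance filter; miRNA
#' normalization (RPM, log2(1+RPM)) with the same 99% filter to select
#' the abundant miRNAs; Spearman anticorrelation screening of the focal
#' canonical miRNA against all expressed genes with BH adjustment; seed
#' scanning over the expressed universe; expression check and
#' anticorrelation/seed enrichment of the downregulated gene list;
#' Mann-Whitney comparison of correlations with vs without the canonical
#' 6mer seed; and per-miRNA Jaccard and extension tables across the
#' abundant miRNAs.
#'
#' @param bundle a study bundle (from \code{\link{simulateStudy}} or
#'   \code{\link{loadStudy}}).
#' @param focalName name of the focal miRNA; default the first entry of
#'   \code{bundle$matures}.
#' @param shifts isomiR shifts for the focal miRNA (first = primary).
#' @param region scan region, \code{"full_mrna"} (default) or
#'   \code{"utr3"}.
#' @param policy representative-transcript policy.
#' @param abundanceFraction cumulative-abundance filter fraction
#'   (default 0.99).
#' @param exprThreshold expressed/not-expressed cut on the log2(1+FPKM)
#'   median (default 1.0).
#' @param alpha significance level for anticorrelation calls (on the BH-
#'   adjusted p; default 0.05).
#' @param tumorOnly restrict samples to \code{sample_type ==
#'   "Primary Tumor"} via the sample sheet (default TRUE).
#' @param outDir optional directory; when set, all result tables plus a
#'   run manifest are written as TSV/JSON-like text.
#' @return A list of results: \code{associationTable} (per expressed
#'   gene: expression summary, rho, padj, seed flags),
#'   \code{expressedCheck}, \code{enrichmentAnticorr},
#'   \code{enrichmentSeed}, \code{groupComparison}, \code{jaccardTables}
#'   (one per shift), \code{extensionTable}, \code{focalProfile},
#'   \code{percentile} (focal Jaccard percentile per shift),
#'   \code{universe}, \code{manifest}.
#' @export
runStudy <- function(bundle, focalName = NULL, shifts = c(4L, 3L),
                     region = c("full_mrna", "utr3"),
                     policy = "longest_spliced",
                     abundanceFraction = 0.99, exprThreshold = 1.0,
                     alpha = 0.05, tumorOnly = TRUE, outDir = NULL) {
  region <- match.arg(region)
  stopifnot(abundanceFraction > 0, abundanceFraction <= 1,
            exprThreshold >= 0, alpha > 0, alpha < 1)
  if (is.null(focalName)) focalName <- names(bundle$matures)[1]
  if (!focalName %in% names(bundle$matures))
    stop("focal miRNA '", focalName, "' not among the mature sequences",
         call. = FALSE)
  focal <- bundle$matures[[focalName]]

  # --- sample selection ---------------------------------------------
  mrnaV <- exprValues(bundle$mrnaCounts)
  mirV <- exprValues(bundle$mirCounts)
  keepSamples <- intersect(colnames(mrnaV), colnames(mirV))
  if (tumorOnly && !is.null(bundle$sampleSheet)) {
    tumor <- bundle$sampleSheet$sample_id[
      bundle$sampleSheet$sample_type == "Primary Tumor"]
    keepSamples <- intersect(keepSamples, tumor)
  }
  if (length(keepSamples) < 5)
    stop("sample selection left fewer than 5 paired samples",
         call. = FALSE)

  # --- transcripts & gene lengths -----------------------------------
  reps <- selectRepresentative(bundle$records, policy)
  lengths <- setNames(nchar(reps$sequence), reps$gene_id)
  # representative spliced length stands in for union-exon gene length
  sharedGenes <- intersect(rownames(mrnaV), names(lengths))
  if (length(sharedGenes) == 0)
    stop("no genes shared between the count matrix and the annotation",
         call. = FALSE)

  # --- mRNA normalization chain -------------------------------------
  mrnaRaw <- expressionMatrix(mrnaV[sharedGenes, keepSamples,
                                    drop = FALSE],
                              "raw_counts",
                              geneLengths = lengths[sharedGenes])
  mrnaNorm <- normalizeCounts(mrnaRaw)
  mrnaFpkm <- toFPKM(mrnaNorm)
  filt <- cumulativeAbundanceFilter(mrnaFpkm, abundanceFraction)
  universe <- filt$keptIds
  if (length(universe) == 0)
    stop("abundance filter removed every gene", call. = FALSE)
  mrnaLog <- log2p1(mrnaFpkm)

  # --- miRNA normalization chain ------------------------------------
  mirRaw <- expressionMatrix(mirV[, keepSamples, drop = FALSE],
                             "raw_counts")
  mirRpm <- toRPM(normalizeCounts(mirRaw))
  mirFilt <- cumulativeAbundanceFilter(mirRpm, abundanceFraction)
  mirLog <- log2p1(mirRpm)
  if (!focalName %in% rownames(exprValues(mirLog)))
    stop("focal miRNA '", focalName, "' absent from the miRNA counts",
         call. = FALSE)
  mirVec <- exprValues(mirLog)[focalName, ]
  # abundant mature miRNAs (isomiR rows carry '|' and are not rescanned)
  abundantMirnas <- intersect(
    mirFilt$keptIds[!grepl("|", mirFilt$keptIds, fixed = TRUE)],
    names(bundle$matures))

  # --- association screening ----------------------------------------
  assoc <- spearmanTable(
    new("ExpressionMatrix",
        values = exprValues(mrnaLog)[universe, , drop = FALSE],
        scale = "log2p1", geneLengths = numeric(0)),
    mirVec)

  # --- seed scanning over the expressed universe --------------------
  expressedRecords <- reps[reps$gene_id %in% universe, , drop = FALSE]
  if (policy == "all_union")
    expressedRecords <- bundle$records[
      bundle$records$gene_id %in% universe, , drop = FALSE]
  scan <- runScan(expressedRecords, focal, shifts, region)
  seedFlags <- data.frame(
    gene_id = assoc$gene_id,
    Seed_canonical = assoc$gene_id %in% targetGenes(scan$canonicalSet),
    stringsAsFactors = FALSE)
  for (s in shifts)
    seedFlags[[paste0("Seed_iso_", s)]] <-
      assoc$gene_id %in% targetGenes(scan$isomirSets[[paste0("+", s)]])

  medianExpr <- apply(exprValues(mrnaLog)[assoc$gene_id, , drop = FALSE],
                      1, median)
  associationTable <- cbind(
    data.frame(gene_id = assoc$gene_id,
               median_log2_fpkm = unname(medianExpr),
               Correlation_canonical = assoc$rho,
               Padj = assoc$padj, stringsAsFactors = FALSE),
    seedFlags[, -1, drop = FALSE])

  # --- downregulated list: expression check + enrichment ------------
  expressedCheck <- NULL
  enrichmentAnticorr <- NULL
  enrichmentSeed <- NULL
  antiGenes <- assoc$gene_id[!is.na(assoc$padj) & assoc$rho < 0 &
                               assoc$padj < alpha]
  if (!is.null(bundle$downregulated)) {
    expressedCheck <- expressedAbove(mrnaLog, bundle$downregulated,
                                     exprThreshold)
    downExpr <- intersect(expressedCheck$expressed, universe)
    if (length(downExpr) > 0) {
      tabA <- buildEnrichmentTable(downExpr, antiGenes, universe)
      enrichmentAnticorr <- c(as.list(oddsRatioFisher(tabA)),
                              list(table = tabA))
      tabS <- buildEnrichmentTable(downExpr,
                                   targetGenes(scan$canonicalSet),
                                   universe)
      enrichmentSeed <- c(as.list(oddsRatioFisher(tabS)),
                          list(table = tabS,
                               nWithSeed = tabS[["a"]],
                               nExpressed = length(downExpr)))
    }
  }

  # --- Mann-Whitney: rho with vs without the canonical 6mer seed ----
  withSeed <- associationTable$Seed_canonical &
    !is.na(associationTable$Correlation_canonical)
  groupComparison <- NULL
  if (any(withSeed) && any(!withSeed))
    groupComparison <- compareGroups(
      associationTable$Correlation_canonical[withSeed],
      associationTable$Correlation_canonical[!withSeed])

  # --- Jaccard & extension tables across abundant miRNAs ------------
  jaccardTables <- list()
  extensionRows <- list()
  for (s in shifts) {
    rows <- lapply(abundantMirnas, function(nm) {
      m <- bundle$matures[[nm]]
      if (nchar(m@sequence) < s + 8) return(NULL)
      sc <- runScan(expressedRecords, m, shifts = s, region = region)
      prof <- overlapProfile(nm, s, sc$canonicalSet,
                             sc$isomirSets[[paste0("+", s)]],
                             sc$canonicalSites)
      if (s == shifts[1]) extensionRows[[nm]] <<- prof
      prof
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    tab <- do.call(rbind, rows)
    jac <- data.frame(mirna = tab$mirna_label, check.names = FALSE,
                      stringsAsFactors = FALSE)
    jac[["6mer"]] <- tab$n_6mer
    jac[["7mer-m8"]] <- tab$n_7mer_m8
    jac$intersection <- tab$n_intersection
    jac$union <- tab$n_union
    jac$jaccard <- tab$jaccard
    jaccardTables[[paste0("+", s)]] <- jac[order(-jac$jaccard), ]
  }
  extTab <- do.call(rbind, extensionRows)
  extensionTable <- data.frame(
    mirna = extTab$mirna_label, check.names = FALSE,
    stringsAsFactors = FALSE)
  extensionTable[["6mer_sites"]] <- extTab$n_sites
  extensionTable$extended_sites <- extTab$n_extended_sites
  extensionTable$ratio_site <- extTab$extension_ratio_site
  extensionTable$ratio_gene <- extTab$extension_ratio_gene
  extensionTable <- extensionTable[order(-extensionTable$ratio_site), ]

  percentile <- vapply(shifts, function(s) {
    jac <- jaccardTables[[paste0("+", s)]]
    ref <- jac$jaccard[jac$mirna != focalName]
    val <- jac$jaccard[jac$mirna == focalName]
    if (length(val) == 0 || length(ref) == 0) return(NA_real_)
    percentileRank(val, ref)
  }, numeric(1))
  names(percentile) <- paste0("+", shifts)

  focalProfile <- overlapProfile(
    focalName, shifts[1], scan$canonicalSet,
    scan$isomirSets[[paste0("+", shifts[1])]], scan$canonicalSites)

  params <- list(focalName = focalName, shifts = shifts, region = region,
                 policy = policy, abundanceFraction = abundanceFraction,
                 exprThreshold = exprThreshold, alpha = alpha,
                 tumorOnly = tumorOnly)
  manifest <- list(
    package = "isoTargetome",
    version = as.character(utils::packageVersion("isoTargetome")),
    parameters = params,
    configHash = .md5OfObject(params),
    nSamples = length(keepSamples),
    nGenesUniverse = length(universe),
    nAbundantMirnas = length(abundantMirnas))

  res <- list(associationTable = associationTable,
              expressedCheck = expressedCheck,
              enrichmentAnticorr = enrichmentAnticorr,
              enrichmentSeed = enrichmentSeed,
              groupComparison = groupComparison,
              jaccardTables = jaccardTables,
              extensionTable = extensionTable,
              focalProfile = focalProfile,
              percentile = percentile,
              anticorrelated = antiGenes,
              universe = universe,
              sizeFactors = sizeFactors(mrnaRaw),
              manifest = manifest)
  if (!is.null(outDir)) writeStudyOutputs(res, outDir)
  res
}

#' Write the result tables of a study run
#'
#' Emits UTF-8 tab-delimited tables ("." decimal separator, NA for
#' undefined values): the per-gene association table, one Jaccard table
#' per shift, the extension table, an enrichment summary, and a run
#' manifest.
#'
#' @param res result list from \code{\link{runStudy}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeStudyOutputs <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(association = file.path(dir, "association.tsv"))
  write.table(res$associationTable, paths["association"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (s in names(res$jaccardTables)) {
    p <- file.path(dir, paste0("jaccard_", sub("\\+", "plus", s), ".tsv"))
    write.table(res$jaccardTables[[s]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths[paste0("jaccard_", s)] <- p
  }
  paths["extension"] <- file.path(dir, "extension.tsv")
  write.table(res$extensionTable, paths["extension"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  enr <- data.frame(
    analysis = c("downregulated_vs_anticorrelated",
                 "downregulated_vs_canonical_seed"),
    odds_ratio = c(
      if (is.null(res$enrichmentAnticorr)) NA
      else res$enrichmentAnticorr$oddsRatio,
      if (is.null(res$enrichmentSeed)) NA else res$enrichmentSeed$oddsRatio),
    p = c(if (is.null(res$enrichmentAnticorr)) NA
          else res$enrichmentAnticorr$p,
          if (is.null(res$enrichmentSeed)) NA else res$enrichmentSeed$p))
  paths["enrichment"] <- file.path(dir, "enrichment.tsv")
  write.table(enr, paths["enrichment"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths["manifest"] <- file.path(dir, "manifest.txt")
  mf <- res$manifest
  lines <- c(paste0("package: ", mf$package, " ", mf$version),
             paste0("config_hash: ", mf$configHash),
             paste0("n_samples: ", mf$nSamples),
             paste0("n_genes_universe: ", mf$nGenesUniverse),
             paste0("n_abundant_mirnas: ", mf$nAbundantMirnas),
             paste0("parameters: ",
                    paste(names(mf$parameters),
                          vapply(mf$parameters, function(x)
                            paste(x, collapse = ","), character(1)),
                          sep = "=", collapse = "; ")))
  writeLines(lines, paths["manifest"])
  invisible(paths)
}
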