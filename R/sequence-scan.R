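DNA_ALPHABET <- c("A", "C", "G", "T")

.stripVersion <- function(ids) sub("\\.[0-9]+$", "", ids)

# Map a genomic position to a 0-based spliced offset given exon ranges
# (data.frame with start/end, genomic coordinates, 1-based closed) and a
# strand. Exons must already be sorted in transcription (5'->3') order.
.genomicToSpliced <- function(pos, exons, strand) {
  off <- 0L
  for (i in seq_len(nrow(exons))) {
    w <- exons$end[i] - exons$start[i] + 1L
    if (pos >= exons$start[i] && pos <= exons$end[i]) {
      within <- if (strand == "+") pos - exons$start[i] else exons$end[i] - pos
      return(off + within)
    }
    off <- off + w
  }
  NA_integer_
}

#' Load transcript records from FASTA + GTF
#'
#' Builds one record per transcript: spliced sense-strand sequence and
#' the 3'-UTR sub-interval (the portion of the spliced sequence 3' of
#' the stop codon; empty for non-coding or UTR-less transcripts).
#'
#' With \code{fastaType = "genome"} the FASTA holds chromosome/contig
#' sequences and exons are spliced from it (minus-strand transcripts are
#' reverse-complemented). With \code{fastaType = "transcript"} the FASTA
#' already holds spliced transcript sequences, matched to the GTF by
#' transcript id; the GTF is still used to place the 3'-UTR.
#'
#' @param fasta path to a FASTA file (genome slices or spliced
#'   transcripts), or a \code{DNAStringSet}.
#' @param annotation path to a GENCODE-style GTF (attributes
#'   \code{gene_id}, \code{transcript_id}, \code{gene_name}; features
#'   \code{exon}, \code{CDS}, \code{stop_codon}), or a \code{GRanges}.
#' @param fastaType \code{"genome"} or \code{"transcript"}.
#' @param stripVersions compare FASTA/GTF ids after dropping trailing
#'   \code{".N"} version suffixes (default TRUE).
#' @return A data.frame with columns \code{transcript_id},
#'   \code{gene_id}, \code{gene_name}, \code{sequence},
#'   \code{utr3_start}, \code{utr3_end} (0-based half-open interval in
#'   spliced coordinates; \code{NA} when the transcript has no annotated
#'   3'-UTR).
#' @export
loadTranscripts <- function(fasta, annotation,
                            fastaType = c("genome", "transcript"),
                            stripVersions = TRUE) {
  fastaType <- match.arg(fastaType)
  seqs <- if (is(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- if (is(annotation, "GRanges")) annotation
        else rtracklayer::import(annotation, format = "gtf")
  m <- S4Vectors::mcols(gr)
  if (!all(c("type", "transcript_id") %in% names(m)))
    stop("GTF must carry 'type' and 'transcript_id' attributes",
         call. = FALSE)
  keep <- m$type %in% c("exon", "CDS", "stop_codon")
  gr <- gr[keep]
  m <- S4Vectors::mcols(gr)
  feat <- data.frame(
    type = as.character(m$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = as.character(m$transcript_id),
    gene_id = if ("gene_id" %in% names(m)) as.character(m$gene_id)
              else NA_character_,
    gene_name = if ("gene_name" %in% names(m)) as.character(m$gene_name)
                else NA_character_,
    stringsAsFactors = FALSE)
  feat <- feat[!is.na(feat$transcript_id), , drop = FALSE]

  fastaKey <- if (stripVersions) .stripVersion(names(seqs)) else names(seqs)
  out <- vector("list", length(unique(feat$transcript_id)))
  i <- 0L
  for (tx in unique(feat$transcript_id)) {
    ft <- feat[feat$transcript_id == tx, , drop = FALSE]
    exons <- ft[ft$type == "exon", , drop = FALSE]
    if (nrow(exons) == 0) next
    strand <- exons$strand[1]
    exons <- exons[order(exons$start), , drop = FALSE]
    if (strand == "-")
      exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]

    txKey <- if (stripVersions) .stripVersion(tx) else tx
    if (fastaType == "transcript") {
      hit <- which(fastaKey == txKey)
      if (length(hit) == 0) {
        warning("transcript '", tx, "' not found in FASTA; skipped",
                call. = FALSE)
        next
      }
      spliced <- toupper(as.character(seqs[[hit[1]]]))
    } else {
      chrom <- exons$chrom[1]
      chromKey <- if (stripVersions) .stripVersion(chrom) else chrom
      hit <- which(fastaKey == chromKey)
      if (length(hit) == 0) {
        warning("sequence '", chrom, "' for transcript '", tx,
                "' not found in FASTA; skipped", call. = FALSE)
        next
      }
      chromSeq <- seqs[[hit[1]]]
      pieces <- vapply(seq_len(nrow(exons)), function(k) {
        ex <- Biostrings::subseq(chromSeq, exons$start[k], exons$end[k])
        if (strand == "-") ex <- Biostrings::reverseComplement(ex)
        as.character(ex)
      }, character(1))
      spliced <- toupper(paste0(pieces, collapse = ""))
    }

    L <- nchar(spliced)
    utr3_start <- NA_integer_; utr3_end <- NA_integer_
    stops <- ft[ft$type == "stop_codon", , drop = FALSE]
    cds <- ft[ft$type == "CDS", , drop = FALSE]
    # 0-based spliced offset of the base immediately after translation end
    after <- NA_integer_
    if (nrow(stops) > 0) {
      lastBase <- if (strand == "+") max(stops$end) else min(stops$start)
      sp <- .genomicToSpliced(lastBase, exons, strand)
      if (!is.na(sp)) after <- sp + 1L
    } else if (nrow(cds) > 0) {
      lastBase <- if (strand == "+") max(cds$end) else min(cds$start)
      sp <- .genomicToSpliced(lastBase, exons, strand)
      if (!is.na(sp)) after <- sp + 1L + 3L  # skip the (unannotated) stop
    }
    if (!is.na(after) && after < L) {
      utr3_start <- after
      utr3_end <- L
    }
    i <- i + 1L
    out[[i]] <- data.frame(
      transcript_id = tx,
      gene_id = ft$gene_id[1],
      gene_name = ft$gene_name[1],
      sequence = spliced,
      utr3_start = utr3_start,
      utr3_end = utr3_end,
      stringsAsFactors = FALSE)
  }
  if (i == 0L)
    stop("no transcripts could be assembled from the inputs", call. = FALSE)
  do.call(rbind, out[seq_len(i)])
}

#' 3'-UTR subsequence of a transcript record
#'
#' @param record one row of the data.frame returned by
#'   \code{\link{loadTranscripts}}.
#' @return The 3'-UTR sequence, or \code{""} if none is annotated.
#' @export
utr3Sequence <- function(record) {
  if (is.na(record$utr3_start[1])) return("")
  substr(record$sequence[1], record$utr3_start[1] + 1L, record$utr3_end[1])
}

#' Pick one representative transcript per gene
#'
#' @param records transcript data.frame from \code{\link{loadTranscripts}}.
#' @param policy \code{"longest_spliced"} (default),
#'   \code{"longest_utr3"}, or \code{"all_union"} (keep every transcript;
#'   a gene is then a target if any transcript carries a site). Ties are
#'   broken by lexicographically smallest transcript id.
#' @return A data.frame with the same columns, one row per gene (or all
#'   rows for \code{"all_union"}).
#' @export
selectRepresentative <- function(records,
    policy = c("longest_spliced", "longest_utr3", "all_union")) {
  policy <- match.arg(policy)
  if (policy == "all_union") return(records)
  key <- switch(policy,
    longest_spliced = nchar(records$sequence),
    longest_utr3 = ifelse(is.na(records$utr3_start), 0L,
                          records$utr3_end - records$utr3_start))
  ord <- order(records$gene_id, -key, records$transcript_id)
  r <- records[ord, , drop = FALSE]
  r[!duplicated(r$gene_id), , drop = FALSE]
}

#' Scan a sequence for exact motif occurrences
#'
#' Finds all exact, possibly overlapping occurrences of the motif's DNA
#' site string. Windows containing any non-ACGT character (including N)
#' never match.
#'
#' @param sequence DNA string to scan (sense strand).
#' @param motif a \linkS4class{SeedMotif}, \linkS4class{ExtendedMotif},
#'   or plain DNA string.
#' @return Integer vector of 1-based start positions, ascending (empty
#'   when there is no match or the sequence is shorter than the motif).
#' @examples
#' scanSites("CTACCTGCACGAACAGCACTTTGTT", "CACTTT")   # 17
#' @export
scanSites <- function(sequence, motif) {
  site <- if (is.character(motif)) toupper(motif) else siteSequence(motif)
  sequence <- toupper(sequence)
  if (nchar(sequence) < nchar(site) || nchar(site) == 0) return(integer(0))
  hits <- Biostrings::matchPattern(Biostrings::DNAString(site),
                                   Biostrings::DNAString(sequence),
                                   fixed = TRUE)
  sort(Biostrings::start(hits))
}

#' Flag extendable canonical 6mer sites
#'
#' A canonical 6mer site at 1-based start \code{p} is extendable when the
#' surrounding window matches the extended dual-seed motif, i.e. the
#' 6mer occupies the last 6 positions of a full (shift5+7)-nt match.
#' Sites too close to the 5' boundary are non-extendable by definition.
#'
#' @param starts 1-based starts of canonical 6mer sites.
#' @param sequence the scanned DNA sequence.
#' @param extended an \linkS4class{ExtendedMotif} built from the same
#'   canonical miRNA.
#' @return Logical vector parallel to \code{starts}.
#' @export
annotateExtendable <- function(starts, sequence, extended) {
  stopifnot(is(extended, "ExtendedMotif"))
  ext <- siteSequence(extended)
  off <- nchar(ext) - 6L
  sequence <- toupper(sequence)
  vapply(starts, function(p) {
    p > off && substr(sequence, p - off, p + 5L) == ext
  }, logical(1))
}

#' Target set of a motif over a gene universe
#'
#' @slot mirnaLabel miRNA/isomiR label the motif belongs to.
#' @slot seedType seed class of the motif.
#' @slot region \code{"full_mrna"} or \code{"utr3"}.
#' @slot genes sorted gene ids with at least one site.
#' @export
setClass("TargetSet",
  representation(mirnaLabel = "character", seedType = "character",
                 region = "character", genes = "character"),
  validity = function(object) {
    if (!object@region %in% c("full_mrna", "utr3"))
      return("region must be 'full_mrna' or 'utr3'")
    TRUE
  })

setMethod("show", "TargetSet", function(object) {
  cat("TargetSet:", object@mirnaLabel, object@seedType, "in",
      object@region, "-", length(object@genes), "genes\n")
})

#' @describeIn buildTargetSet gene ids in a \code{TargetSet}.
#' @param x a \code{TargetSet}.
#' @export
targetGenes <- function(x) {
  stopifnot(is(x, "TargetSet"))
  x@genes
}

#' Scan transcripts and tabulate seed sites
#'
#' @param records transcript data.frame (typically after
#'   \code{\link{selectRepresentative}}).
#' @param motif a \linkS4class{SeedMotif} or \linkS4class{ExtendedMotif}.
#' @param region scan the full spliced mRNA or only the 3'-UTR.
#' @param extended optional \linkS4class{ExtendedMotif}; when supplied
#'   and \code{motif} is a canonical 6mer, each site gains an
#'   \code{extendable} flag (tested against the full spliced sequence so
#'   boundary context is not lost for 3'-UTR scans).
#' @param motifId label stored in the \code{motif_id} column.
#' @return A data.frame of sites: \code{gene_id}, \code{transcript_id},
#'   \code{motif_id}, \code{region}, \code{start} (1-based within the
#'   scanned region), \code{extendable}.
#' @export
scanTranscripts <- function(records, motif,
                            region = c("full_mrna", "utr3"),
                            extended = NULL, motifId = NULL) {
  region <- match.arg(region)
  site <- if (is.character(motif)) toupper(motif) else siteSequence(motif)
  if (is.null(motifId))
    motifId <- if (is.character(motif)) motif else site
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    seq <- if (region == "utr3") utr3Sequence(rec) else rec$sequence
    if (!nzchar(seq)) next
    starts <- scanSites(seq, site)
    if (length(starts) == 0) next
    extendable <- if (!is.null(extended)) {
      # evaluate the extension window on the full spliced sequence
      offset <- if (region == "utr3") rec$utr3_start else 0L
      annotateExtendable(starts + offset, rec$sequence, extended)
    } else rep(NA, length(starts))
    rows[[i]] <- data.frame(
      gene_id = rec$gene_id, transcript_id = rec$transcript_id,
      motif_id = motifId, region = region, start = starts,
      extendable = extendable, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(gene_id = character(), transcript_id = character(),
                      motif_id = character(), region = character(),
                      start = integer(), extendable = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a gene-level target set
#'
#' A gene is a target when at least one site for the motif occurs in the
#' chosen region of its representative transcript(s).
#'
#' @param mirnaLabel label for bookkeeping (e.g.
#'   \code{"hsa-miR-93-5p|+4"}).
#' @param records transcript data.frame (pass the output of
#'   \code{\link{selectRepresentative}}, or all transcripts for the
#'   \code{all_union} policy).
#' @param motif a \linkS4class{SeedMotif}.
#' @param region \code{"full_mrna"} (default) or \code{"utr3"}.
#' @return A \linkS4class{TargetSet}.
#' @export
buildTargetSet <- function(mirnaLabel, records, motif,
                           region = c("full_mrna", "utr3")) {
  region <- match.arg(region)
  if (nrow(records) == 0)
    stop("empty gene universe: no transcript records supplied",
         call. = FALSE)
  sites <- scanTranscripts(records, motif, region = region)
  seedType <- if (is(motif, "SeedMotif")) motif@seedType else "custom"
  new("TargetSet", mirnaLabel = mirnaLabel, seedType = seedType,
      region = region, genes = sort(unique(sites$gene_id)))
}
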