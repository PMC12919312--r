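#' @import methods
#' @importFrom stats median cor pt rnorm runif rlnorm rnbinom setNames
#' @importFrom utils head read.delim write.table
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")

.normalizeRNA <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- chartr("T", "U", x)
  bad <- setdiff(unique(strsplit(x, "")[[1]]), RNA_ALPHABET)
  if (length(bad) > 0)
    stop("invalid RNA character(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  x
}

#' Mature miRNA
#'
#' Holds a mature miRNA name and its canonical sequence in the RNA
#' alphabet (A/C/G/U, 5'->3'). Sequences shorter than 16 nt are rejected:
#' anything shorter cannot carry a shifted seed register.
#'
#' @slot name miRNA identifier, e.g. \code{"hsa-miR-93-5p"}.
#' @slot sequence RNA string, uppercased on construction.
#' @export
setClass("MatureMiRNA",
  representation(name = "character", sequence = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1 || !nzchar(object@name))
      msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@sequence) != 1)
      msg <- c(msg, "'sequence' must be a single string")
    else {
      chars <- unique(strsplit(object@sequence, "")[[1]])
      if (!all(chars %in% RNA_ALPHABET))
        msg <- c(msg, "sequence must contain only A/C/G/U")
      if (nchar(object@sequence) < 16)
        msg <- c(msg, "mature miRNA sequence must be >= 16 nt")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a MatureMiRNA
#'
#' @param name miRNA identifier.
#' @param sequence mature sequence; lowercase and T are normalized to
#'   uppercase RNA.
#' @return A \linkS4class{MatureMiRNA} object.
#' @examples
#' matureMiRNA("hsa-miR-93-5p", "CAAAGUGCUGUUCGUGCAGGUAG")
#' @export
matureMiRNA <- function(name, sequence) {
  new("MatureMiRNA", name = name,
      sequence = .normalizeRNA(sequence, paste0("miRNA ", name)))
}

#' A 5'-isomiR of a mature miRNA
#'
#' A 5'-isomiR is described by its parent miRNA, a non-negative 5' shift
#' (number of nucleotides trimmed from the canonical 5' end, in the
#' 5'->3' direction) and an optional string of non-templated 3'
#' nucleotides. 5' extensions (negative shifts) are rejected: deriving
#' them would need genomic context a mature FASTA does not carry.
#'
#' @slot parent the canonical \linkS4class{MatureMiRNA}.
#' @slot shift5 integer 5' shift, \code{0 <= shift5 <= length - 10}.
#' @slot mod3 appended 3' nucleotides (RNA alphabet; may be empty).
#' @export
setClass("IsomiR",
  representation(parent = "MatureMiRNA", shift5 = "integer",
                 mod3 = "character"),
  validity = function(object) {
    msg <- character()
    L <- nchar(object@parent@sequence)
    if (length(object@shift5) != 1 || is.na(object@shift5))
      msg <- c(msg, "'shift5' must be a single integer")
    else {
      if (object@shift5 < 0)
        msg <- c(msg, "negative 5' shifts (5' extensions) are not supported")
      if (object@shift5 > L - 10)
        msg <- c(msg, sprintf(
          "shift5 = %d leaves fewer than 10 nt of a %d-nt parent",
          object@shift5, L))
    }
    if (length(object@mod3) != 1)
      msg <- c(msg, "'mod3' must be a single (possibly empty) string")
    else if (nzchar(object@mod3)) {
      chars <- unique(strsplit(object@mod3, "")[[1]])
      if (!all(chars %in% RNA_ALPHABET))
        msg <- c(msg, "mod3 must contain only A/C/G/U")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct an IsomiR
#'
#' @param parent a \linkS4class{MatureMiRNA}.
#' @param shift5 non-negative integer 5' shift.
#' @param mod3 appended 3' nucleotides, default none.
#' @return An \linkS4class{IsomiR} object.
#' @examples
#' mir93 <- matureMiRNA("hsa-miR-93-5p", "CAAAGUGCUGUUCGUGCAGGUAG")
#' isomiR(mir93, 4)
#' @export
isomiR <- function(parent, shift5, mod3 = "") {
  new("IsomiR", parent = parent, shift5 = as.integer(shift5),
      mod3 = if (nzchar(mod3)) .normalizeRNA(mod3, "mod3") else "")
}

#' @describeIn isomiR full label in pipe notation, e.g.
#'   \code{"hsa-miR-93-5p|+4"}.
#' @param x an \code{IsomiR}.
#' @export
isomirLabel <- function(x) {
  stopifnot(is(x, "IsomiR"))
  lab <- x@parent@name
  if (x@shift5 > 0 || nzchar(x@mod3))
    lab <- paste0(lab, "|", if (x@shift5 > 0) paste0("+", x@shift5) else "0")
  if (nzchar(x@mod3)) {
    r <- rle(strsplit(x@mod3, "")[[1]])
    lab <- paste0(lab, "|", paste0("+", r$lengths, r$values, collapse = ""))
  }
  lab
}

setMethod("show", "MatureMiRNA", function(object) {
  cat("MatureMiRNA", object@name, "(", nchar(object@sequence), "nt )\n")
  cat(" ", object@sequence, "\n")
})

setMethod("show", "IsomiR", function(object) {
  cat("IsomiR", isomirLabel(object), "\n")
  cat("  derived:", isomirSequence(object), "\n")
})

#' Parse an isomiR label in pipe notation
#'
#' Labels take the forms \code{"name"}, \code{"name|+k"} (or
#' \code{"name|0"}), and \code{"name|+k|+nX"} where \code{n} is a count
#' and \code{X} a nucleotide, e.g. \code{"hsa-miR-95-5p|0|+2U"} for two
#' appended uracils. A trailing \code{"|0"} in the third field denotes no
#' 3' modification.
#'
#' @param label notation string.
#' @return A list with elements \code{name}, \code{shift5} (integer) and
#'   \code{mod3} (expanded nucleotide string, e.g. \code{"UU"}).
#' @examples
#' parseIsomirNotation("hsa-miR-93-5p|+4")
#' parseIsomirNotation("hsa-miR-95-5p|0|+2U")
#' @export
parseIsomirNotation <- function(label) {
  stopifnot(is.character(label), length(label) == 1)
  parts <- strsplit(label, "|", fixed = TRUE)[[1]]
  if (length(parts) < 1 || !nzchar(parts[1]))
    stop("empty miRNA name in label '", label, "'", call. = FALSE)
  if (length(parts) > 3)
    stop("too many '|' fields in label '", label, "'", call. = FALSE)
  name <- parts[1]
  shift5 <- 0L
  mod3 <- ""
  if (length(parts) >= 2) {
    tok <- parts[2]
    if (!grepl("^[+-]?[0-9]+$", tok))
      stop("malformed shift token '", tok, "' in label '", label, "'",
           call. = FALSE)
    shift5 <- as.integer(tok)
  }
  if (length(parts) == 3) {
    tok <- parts[3]
    if (tok != "0") {
      m <- regmatches(tok, regexec("^\\+([0-9]+)([ACGUTacgut])$", tok))[[1]]
      if (length(m) == 0)
        stop("malformed 3' modification token '", tok, "' in label '",
             label, "'", call. = FALSE)
      nt <- chartr("T", "U", toupper(m[3]))
      mod3 <- strrep(nt, as.integer(m[2]))
    }
  }
  list(name = name, shift5 = shift5, mod3 = mod3)
}

#' Derive the isomiR sequence from its parent
#'
#' Removes the first \code{shift5} nucleotides of the parent sequence and
#' appends \code{mod3}. The derived sequence must keep at least 10 nt.
#'
#' @param parent a \linkS4class{MatureMiRNA} or a plain RNA string.
#' @param shift5 non-negative integer 5' shift.
#' @param mod3 appended 3' nucleotides, default none.
#' @return The derived RNA sequence.
#' @examples
#' applyShift("CAAAGUGCUGUUCGUGCAGGUAG", 4, "UU")
#' @export
applyShift <- function(parent, shift5, mod3 = "") {
  seq <- if (is(parent, "MatureMiRNA")) parent@sequence
         else .normalizeRNA(parent)
  shift5 <- as.integer(shift5)
  if (is.na(shift5) || shift5 < 0)
    stop("shift5 must be a non-negative integer", call. = FALSE)
  if (nchar(seq) - shift5 < 10)
    stop("shift5 = ", shift5, " leaves fewer than 10 nt of a ",
         nchar(seq), "-nt sequence", call. = FALSE)
  if (nzchar(mod3)) mod3 <- .normalizeRNA(mod3, "mod3")
  paste0(substr(seq, shift5 + 1L, nchar(seq)), mod3)
}

#' @describeIn applyShift derived sequence of an \linkS4class{IsomiR}.
#' @param x an \code{IsomiR}.
#' @export
isomirSequence <- function(x) {
  stopifnot(is(x, "IsomiR"))
  applyShift(x@parent, x@shift5, x@mod3)
}

#' Extract a seed subsequence
#'
#' Seeds are defined positionally on the mature (or isomiR-derived)
#' sequence: nucleotides 2-7 for a 6mer seed, 2-8 for a 7mer-m8 seed
#' (1-based, from the 5' end).
#'
#' @param sequence RNA string of length >= 8.
#' @param seedType \code{"6mer"} or \code{"7mer-m8"}.
#' @return The seed subsequence (RNA).
#' @examples
#' extractSeed("CAAAGUGCUGUUCGUGCAGGUAG", "6mer")     # "AAAGUG"
#' extractSeed("GUGCUGUUCGUGCAGGUAG", "7mer-m8")      # "UGCUGUU"
#' @export
extractSeed <- function(sequence, seedType = c("6mer", "7mer-m8")) {
  seedType <- match.arg(seedType)
  sequence <- .normalizeRNA(sequence)
  if (nchar(sequence) < 8)
    stop("sequence too short for seed extraction (need >= 8 nt)",
         call. = FALSE)
  substr(sequence, 2L, if (seedType == "6mer") 7L else 8L)
}

.revcompDNA <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' mRNA-sense site motif for a seed
#'
#' The motif actually searched in transcript sequences is the
#' Watson-Crick reverse complement of the seed, transliterated to the
#' DNA alphabet (U pairs with A; the output uses T).
#'
#' @param seedSeq seed subsequence (RNA).
#' @return DNA string of the same length.
#' @examples
#' makeSiteMotif("AAAGUG")   # "CACTTT"
#' @export
makeSiteMotif <- function(seedSeq) {
  seedSeq <- .normalizeRNA(seedSeq, "seed")
  .revcompDNA(chartr("U", "T", seedSeq))
}

#' Seed motif (seed + searchable site string)
#'
#' @slot seedType \code{"6mer"} or \code{"7mer-m8"}.
#' @slot seedSeq RNA seed subsequence (6 or 7 nt).
#' @slot siteSeq DNA site string scanned in mRNA sequences.
#' @export
setClass("SeedMotif",
  representation(seedType = "character", seedSeq = "character",
                 siteSeq = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@seedType %in% c("6mer", "7mer-m8"))
      msg <- c(msg, "seedType must be '6mer' or '7mer-m8'")
    want <- if (object@seedType == "6mer") 6L else 7L
    if (nchar(object@seedSeq) != want)
      msg <- c(msg, sprintf("seedSeq must be %d nt for %s", want,
                            object@seedType))
    if (nchar(object@siteSeq) != nchar(object@seedSeq))
      msg <- c(msg, "siteSeq and seedSeq lengths differ")
    if (nzchar(object@seedSeq) &&
        object@siteSeq != makeSiteMotif(object@seedSeq))
      msg <- c(msg, "siteSeq is not the DNA reverse complement of seedSeq")
    if (length(msg)) msg else TRUE
  })

#' Build a SeedMotif from a mature or isomiR sequence
#'
#' @param sequence mature/isomiR-derived RNA sequence, a
#'   \linkS4class{MatureMiRNA}, or an \linkS4class{IsomiR}.
#' @param seedType \code{"6mer"} or \code{"7mer-m8"}.
#' @return A \linkS4class{SeedMotif}.
#' @examples
#' seedMotif("CAAAGUGCUGUUCGUGCAGGUAG", "6mer")
#' @export
seedMotif <- function(sequence, seedType = c("6mer", "7mer-m8")) {
  seedType <- match.arg(seedType)
  if (is(sequence, "IsomiR")) sequence <- isomirSequence(sequence)
  if (is(sequence, "MatureMiRNA")) sequence <- sequence@sequence
  seed <- extractSeed(sequence, seedType)
  new("SeedMotif", seedType = seedType, seedSeq = seed,
      siteSeq = makeSiteMotif(seed))
}

setMethod("show", "SeedMotif", function(object) {
  cat("SeedMotif", object@seedType, "seed", object@seedSeq,
      "-> site", object@siteSeq, "\n")
})

#' Extended dual-seed motif
#'
#' For a canonical miRNA and a positive shift k, the extended motif spans
#' miRNA nucleotides 2 through k+8 of the canonical sequence; its mRNA
#' site is k+7 nt long (11 nt for k = 4) and simultaneously contains the
#' canonical 6mer site (as its last 6 characters) and the +k isomiR
#' 7mer-m8 site (as its first 7 characters).
#'
#' @slot shift5 positive integer shift.
#' @slot spanSeq canonical nucleotides 2..(shift5+8), RNA.
#' @slot siteSeq DNA reverse complement of \code{spanSeq}.
#' @export
setClass("ExtendedMotif",
  representation(shift5 = "integer", spanSeq = "character",
                 siteSeq = "character"),
  validity = function(object) {
    msg <- character()
    if (object@shift5 < 1) msg <- c(msg, "shift5 must be >= 1")
    if (nchar(object@siteSeq) != object@shift5 + 7L)
      msg <- c(msg, "siteSeq length must equal shift5 + 7")
    if (nchar(object@spanSeq) != nchar(object@siteSeq))
      msg <- c(msg, "spanSeq and siteSeq lengths differ")
    canonical6 <- makeSiteMotif(substr(object@spanSeq, 1L, 6L))
    if (substr(object@siteSeq, nchar(object@siteSeq) - 5L,
               nchar(object@siteSeq)) != canonical6)
      msg <- c(msg, "last 6 characters of siteSeq must be the canonical 6mer site")
    if (length(msg)) msg else TRUE
  })

#' Build an extended dual-seed motif
#'
#' @param parent canonical \linkS4class{MatureMiRNA} (or RNA string).
#' @param shift5 positive integer isomiR shift.
#' @return An \linkS4class{ExtendedMotif}.
#' @examples
#' mir93 <- matureMiRNA("hsa-miR-93-5p", "CAAAGUGCUGUUCGUGCAGGUAG")
#' makeExtendedMotif(mir93, 4)   # site "AACAGCACTTT"
#' @export
makeExtendedMotif <- function(parent, shift5) {
  seq <- if (is(parent, "MatureMiRNA")) parent@sequence
         else .normalizeRNA(parent)
  shift5 <- as.integer(shift5)
  if (is.na(shift5) || shift5 < 1)
    stop("shift5 must be a positive integer for an extended motif",
         call. = FALSE)
  if (nchar(seq) < shift5 + 8L)
    stop("parent sequence too short for shift5 = ", shift5, call. = FALSE)
  span <- substr(seq, 2L, shift5 + 8L)
  new("ExtendedMotif", shift5 = shift5, spanSeq = span,
      siteSeq = makeSiteMotif(span))
}

setMethod("show", "ExtendedMotif", function(object) {
  cat("ExtendedMotif shift +", object@shift5, " site ", object@siteSeq,
      " (", nchar(object@siteSeq), " nt)\n", sep = "")
})

#' @describeIn seedMotif DNA site string of a motif object.
#' @param motif a \code{SeedMotif} or \code{ExtendedMotif}.
#' @export
siteSequence <- function(motif) {
  stopifnot(is(motif, "SeedMotif") || is(motif, "ExtendedMotif"))
  motif@siteSeq
}

#' Read a miRBase-style mature miRNA FASTA
#'
#' The miRNA name is the header token before the first whitespace.
#' Sequences are normalized to the RNA alphabet.
#'
#' @param path FASTA file of mature sequences.
#' @return A named list of \linkS4class{MatureMiRNA} objects.
#' @export
readMatureFasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  out <- lapply(seq_along(ss), function(i)
    matureMiRNA(nm[i], as.character(ss[[i]])))
  names(out) <- nm
  out
}

#' Read a TSV of isomiR labels
#'
#' One label per line (column \code{label} if a header is present),
#' parsed with \code{\link{parseIsomirNotation}} and resolved against a
#' list of mature miRNAs.
#'
#' @param path TSV/one-column text file of pipe-notation labels.
#' @param matures named list of \linkS4class{MatureMiRNA} (e.g. from
#'   \code{\link{readMatureFasta}}).
#' @return A named list of \linkS4class{IsomiR} objects.
#' @export
readIsomirTable <- function(path, matures) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  labels <- if ("label" %in% names(df)) df$label else df[[1]]
  out <- lapply(labels, function(lab) {
    p <- parseIsomirNotation(lab)
    if (!p$name %in% names(matures))
      stop("isomiR label '", lab, "' references unknown miRNA '", p$name,
           "'", call. = FALSE)
    isomiR(matures[[p$name]], p$shift5, p$mod3)
  })
  names(out) <- labels
  out
}

#' Canonical hsa-miR-93-5p fixture
#'
#' The mature hsa-miR-93-5p sequence used throughout examples and the
#' synthetic generator's default focal miRNA.
#'
#' @return A \linkS4class{MatureMiRNA}.
#' @export
mir93_5p <- function() {
  matureMiRNA("hsa-miR-93-5p", "CAAAGUGCUGUUCGUGCAGGUAG")
}
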