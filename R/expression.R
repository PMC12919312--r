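EXPR_SCALES <- c("raw_counts", "size_normalized", "fpkm", "rpm", "log2p1")

#' Expression matrix with an explicit scale tag
#'
#' A features-by-samples matrix of non-negative values tagged with the
#' scale it is on. Scale transitions happen only through the defined
#' operations (\code{\link{normalizeCounts}}, \code{\link{toFPKM}},
#' \code{\link{toRPM}}, \code{\link{log2p1}}), which refuse to run on
#' the wrong input scale — re-applying a transition is an error, not a
#' silent double transform.
#'
#' @slot values numeric matrix, rownames = feature ids, colnames =
#'   sample ids.
#' @slot scale one of \code{raw_counts}, \code{size_normalized},
#'   \code{fpkm}, \code{rpm}, \code{log2p1}.
#' @slot geneLengths per-row lengths in bp (empty when not applicable;
#'   required before FPKM, forbidden on the miRNA RPM path).
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", scale = "character",
                 geneLengths = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@values))
      msg <- c(msg, "values must be numeric")
    if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
      msg <- c(msg, "values must have row and column names")
    if (any(!is.finite(object@values)) || any(object@values < 0))
      msg <- c(msg, "values must be finite and non-negative")
    if (!object@scale %in% EXPR_SCALES)
      msg <- c(msg, paste("scale must be one of:",
                          paste(EXPR_SCALES, collapse = ", ")))
    if (length(object@geneLengths) > 0) {
      if (length(object@geneLengths) != nrow(object@values))
        msg <- c(msg, "geneLengths length must match the number of rows")
      else if (any(object@geneLengths <= 0))
        msg <- c(msg, "geneLengths must be positive")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix with dimnames.
#' @param scale scale tag, default \code{"raw_counts"}.
#' @param geneLengths optional per-row lengths in bp (named or in row
#'   order).
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
expressionMatrix <- function(values, scale = "raw_counts",
                             geneLengths = NULL) {
  values <- as.matrix(values)
  gl <- numeric(0)
  if (!is.null(geneLengths)) {
    if (!is.null(names(geneLengths)))
      geneLengths <- geneLengths[rownames(values)]
    gl <- as.numeric(geneLengths)
  }
  new("ExpressionMatrix", values = values, scale = scale, geneLengths = gl)
}

#' @describeIn expressionMatrix the underlying values matrix.
#' @param x an \code{ExpressionMatrix}.
#' @export
exprValues <- function(x) { stopifnot(is(x, "ExpressionMatrix")); x@values }

#' @describeIn expressionMatrix the scale tag.
#' @export
exprScale <- function(x) { stopifnot(is(x, "ExpressionMatrix")); x@scale }

#' @describeIn expressionMatrix per-row gene lengths (may be empty).
#' @export
geneLengths <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  x@geneLengths
}

setMethod("show", "ExpressionMatrix", function(object) {
  cat("ExpressionMatrix:", nrow(object@values), "features x",
      ncol(object@values), "samples, scale =", object@scale, "\n")
})

setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

.requireScale <- function(x, wanted, op) {
  if (!exprScale(x) %in% wanted)
    stop(op, " expects scale ", paste(wanted, collapse = "/"),
         ", got '", exprScale(x), "'", call. = FALSE)
}

#' Median-of-ratios size factors
#'
#' For sample j, the size factor is the median over reference genes i of
#' counts[i,j] / geomean_i, where geomean_i is the geometric mean of row
#' i across samples and the reference set is the rows with all counts
#' positive (geometric means computed by log-space summation).
#'
#' @param counts raw count matrix or an \linkS4class{ExpressionMatrix}
#'   on the \code{raw_counts} scale.
#' @return Named numeric vector of positive per-sample factors.
#' @examples
#' sizeFactors(matrix(c(2, 4, 4, 8, 8, 16), nrow = 3, byrow = TRUE,
#'                    dimnames = list(paste0("g", 1:3), c("s1", "s2"))))
#' @export
sizeFactors <- function(counts) {
  if (is(counts, "ExpressionMatrix")) {
    .requireScale(counts, "raw_counts", "sizeFactors")
    counts <- exprValues(counts)
  }
  counts <- as.matrix(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene has positive counts in every sample; pre-filter the ",
         "matrix before computing size factors", call. = FALSE)
  logc <- log(counts[ref, , drop = FALSE])
  logGeo <- rowMeans(logc)
  sf <- apply(exp(logc - logGeo), 2, median)
  names(sf) <- colnames(counts)
  sf
}

#' Divide counts by per-sample size factors
#'
#' @param x raw-count \linkS4class{ExpressionMatrix} (or matrix).
#' @param factors positive per-sample factors, default
#'   \code{\link{sizeFactors}(x)}.
#' @return An \code{ExpressionMatrix} on the \code{size_normalized}
#'   scale.
#' @export
normalizeCounts <- function(x, factors = NULL) {
  wasMatrix <- !is(x, "ExpressionMatrix")
  if (wasMatrix) x <- expressionMatrix(as.matrix(x), "raw_counts")
  .requireScale(x, "raw_counts", "normalizeCounts")
  if (is.null(factors)) factors <- sizeFactors(x)
  v <- exprValues(x)
  if (length(factors) != ncol(v))
    stop("length(factors) must equal the number of samples", call. = FALSE)
  if (any(factors <= 0)) stop("size factors must be positive", call. = FALSE)
  out <- sweep(v, 2, factors, "/")
  new("ExpressionMatrix", values = out, scale = "size_normalized",
      geneLengths = x@geneLengths)
}

#' Length-normalize to FPKM
#'
#' fpkm[i,j] = normalized[i,j] * 1e9 / (length_i * T_j), with T_j the
#' column total of the size-normalized matrix.
#'
#' @param x size-normalized \linkS4class{ExpressionMatrix}.
#' @param lengths per-row lengths in bp; defaults to the lengths stored
#'   in the object.
#' @return An \code{ExpressionMatrix} on the \code{fpkm} scale.
#' @export
toFPKM <- function(x, lengths = NULL) {
  .requireScale(x, "size_normalized", "toFPKM")
  if (is.null(lengths)) lengths <- x@geneLengths
  if (length(lengths) == 0)
    stop("gene lengths are required for FPKM", call. = FALSE)
  if (!is.null(names(lengths))) lengths <- lengths[rownames(exprValues(x))]
  if (length(lengths) != nrow(exprValues(x)) || any(is.na(lengths)) ||
      any(lengths <= 0))
    stop("lengths must be positive and cover every row", call. = FALSE)
  v <- exprValues(x)
  total <- colSums(v)
  if (any(total <= 0)) stop("zero column total; cannot compute FPKM",
                            call. = FALSE)
  out <- sweep(v / lengths, 2, total, "/") * 1e9
  new("ExpressionMatrix", values = out, scale = "fpkm",
      geneLengths = as.numeric(lengths))
}

#' Normalize to reads per million
#'
#' rpm[i,j] = normalized[i,j] * 1e6 / T_j. Gene lengths are deliberately
#' not part of this path (miRNA quantification); supplying an object
#' that carries lengths is an error to keep the two pipelines distinct.
#'
#' @param x size-normalized \linkS4class{ExpressionMatrix}.
#' @return An \code{ExpressionMatrix} on the \code{rpm} scale.
#' @export
toRPM <- function(x) {
  .requireScale(x, "size_normalized", "toRPM")
  if (length(x@geneLengths) > 0)
    stop("gene lengths are not applicable on the RPM path; drop them",
         call. = FALSE)
  v <- exprValues(x)
  total <- colSums(v)
  if (any(total <= 0)) stop("zero column total; cannot compute RPM",
                            call. = FALSE)
  out <- sweep(v, 2, total, "/") * 1e6
  new("ExpressionMatrix", values = out, scale = "rpm",
      geneLengths = numeric(0))
}

#' log2(1 + x) transform
#'
#' @param x \linkS4class{ExpressionMatrix} on the \code{fpkm} or
#'   \code{rpm} scale.
#' @return An \code{ExpressionMatrix} on the \code{log2p1} scale.
#' @export
log2p1 <- function(x) {
  .requireScale(x, c("fpkm", "rpm"), "log2p1")
  new("ExpressionMatrix", values = log2(1 + exprValues(x)),
      scale = "log2p1", geneLengths = x@geneLengths)
}

#' Cumulative-abundance filter
#'
#' Rows are ranked by median expression in descending order (ties broken
#' by row id, ascending) and the cumulative sum of medians computed; the
#' minimal prefix reaching \code{fraction} of the total is kept, plus
#' any further rows tied in median with the row at the cut. Rows past
#' the cut (the low-abundance tail) are dropped. Medians must be on a
#' linear scale — a fraction of total expression is only meaningful
#' additively.
#'
#' @param x \linkS4class{ExpressionMatrix} on a linear scale
#'   (\code{size_normalized}, \code{fpkm} or \code{rpm}).
#' @param fraction cumulative fraction to retain, in (0, 1]; default
#'   0.99.
#' @return A list (\code{FilterReport}): \code{keptIds},
#'   \code{droppedIds}, \code{cumulativeFractionAtCut},
#'   \code{threshold}.
#' @export
cumulativeAbundanceFilter <- function(x, fraction = 0.99) {
  .requireScale(x, c("size_normalized", "fpkm", "rpm"),
                "cumulativeAbundanceFilter")
  stopifnot(fraction > 0, fraction <= 1)
  v <- exprValues(x)
  med <- apply(v, 1, median)
  if (all(med == 0) && sum(v) == 0)
    stop("all-zero matrix: nothing to filter", call. = FALSE)
  ord <- order(-med, rownames(v))
  med <- med[ord]
  ids <- rownames(v)[ord]
  cum <- cumsum(med)
  total <- sum(med)
  cut <- which(cum >= fraction * total - 1e-12)[1]
  # keep ties at the cut together
  while (cut < length(med) && med[cut + 1] == med[cut] && med[cut] > 0)
    cut <- cut + 1L
  kept <- ids[seq_len(cut)]
  list(keptIds = kept,
       droppedIds = setdiff(rownames(v), kept),
       cumulativeFractionAtCut = unname(cum[cut] / total),
       threshold = fraction)
}

#' Partition a gene list by an expression threshold
#'
#' A gene counts as expressed when its median value across samples is at
#' or above the threshold (closed bound). Genes absent from the matrix
#' are reported as not expressed.
#'
#' @param x \linkS4class{ExpressionMatrix} on the \code{log2p1} scale.
#' @param geneList genes to classify.
#' @param threshold default 1.0 on the log2(1+x) scale.
#' @return A list with \code{expressed}, \code{notExpressed} and a named
#'   vector \code{medians} over the genes found in the matrix.
#' @export
expressedAbove <- function(x, geneList, threshold = 1.0) {
  .requireScale(x, "log2p1", "expressedAbove")
  v <- exprValues(x)
  present <- intersect(geneList, rownames(v))
  med <- apply(v[present, , drop = FALSE], 1, median)
  expressed <- present[med >= threshold]
  list(expressed = expressed,
       notExpressed = setdiff(geneList, expressed),
       medians = med)
}

#' Read a TSV count matrix
#'
#' Rows are features (first column = id), columns samples (header).
#'
#' @param path TSV file.
#' @param scale scale tag to attach, default \code{"raw_counts"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readCountsTSV <- function(path, scale = "raw_counts") {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  expressionMatrix(m, scale)
}

#' Write an expression matrix as TSV
#'
#' @param x \linkS4class{ExpressionMatrix} or matrix.
#' @param path output file.
#' @param idColumn name of the first (id) column.
#' @export
writeCountsTSV <- function(x, path, idColumn = "feature_id") {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else x
  df <- data.frame(id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
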