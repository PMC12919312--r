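#' Jaccard index of two gene sets
#'
#' |A n B| / |A u B|. Returns \code{NA} (undefined) when both sets are
#' empty.
#'
#' @param setA,setB character vectors (duplicates ignored).
#' @return Numeric in [0, 1], or \code{NA}.
#' @export
jaccardIndex <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  u <- length(union(setA, setB))
  if (u == 0) return(NA_real_)
  length(intersect(setA, setB)) / u
}

#' 2x2 contingency table over an explicit gene universe
#'
#' Rows: in the focal set / not; columns: has the property / not.
#'
#' @param focal,property subsets of \code{universe}.
#' @param universe the full gene universe.
#' @return Named integer vector \code{c(a, b, c, d)} with
#'   \code{a = |focal n property|}, \code{b = |focal \\ property|},
#'   \code{c = |property \\ focal|}, \code{d} the remainder;
#'   \code{a + b + c + d = |universe|}.
#' @export
buildEnrichmentTable <- function(focal, property, universe) {
  focal <- unique(focal); property <- unique(property)
  universe <- unique(universe)
  bad <- setdiff(focal, universe)
  if (length(bad) > 0)
    stop("focal genes outside the universe: ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  bad <- setdiff(property, universe)
  if (length(bad) > 0)
    stop("property genes outside the universe: ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  a <- length(intersect(focal, property))
  b <- length(setdiff(focal, property))
  cc <- length(setdiff(property, focal))
  d <- length(universe) - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' Sample odds ratio and two-sided Fisher exact p-value
#'
#' The odds ratio is the sample estimate (a*d)/(b*c) — \code{Inf} when
#' b*c = 0 with a*d > 0, \code{NA} when both products are zero. The
#' two-sided p-value sums, over the hypergeometric support at the
#' table's margins, the probabilities of all tables no more likely than
#' the observed one (point-probability rule).
#'
#' @param a,b,c,d the four cells (row 1 = focal set, column 1 =
#'   property), or a 2x2 matrix as \code{a}.
#' @return A list with \code{oddsRatio} and \code{p}.
#' @export
oddsRatioFisher <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  } else if (length(a) == 4 && is.null(b)) {
    d <- a[4]; c <- a[3]; b <- a[2]; a <- a[1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers", call. = FALSE)
  or <- if (b * c > 0) (a * d) / (b * c)
        else if (a * d > 0) Inf
        else NA_real_
  N <- a + b + c + d
  r <- a + b      # focal-set size
  k <- a + c      # property size
  lo <- max(0L, r + k - N)
  hi <- min(r, k)
  support <- lo:hi
  probs <- stats::dhyper(support, k, N - k, r)
  pObs <- stats::dhyper(a, k, N - k, r)
  p <- sum(probs[probs <= pObs * (1 + 1e-7)])
  list(oddsRatio = unname(or), p = min(unname(p), 1))
}

#' Percentile rank of a value within reference values
#'
#' 100 times the fraction of reference values less than or equal to the
#' value.
#'
#' @param value a number.
#' @param reference non-empty numeric vector.
#' @return Percentile in [0, 100].
#' @export
percentileRank <- function(value, reference) {
  reference <- reference[is.finite(reference)]
  if (length(reference) == 0)
    stop("reference values must be non-empty", call. = FALSE)
  100 * mean(reference <= value)
}

#' Canonical-vs-isomiR targetome overlap profile
#'
#' Summarizes, for one miRNA and one 5' shift, the overlap between its
#' canonical 6mer targetome and the isomiR 7mer-m8 targetome, and the
#' proportion of canonical 6mer sites extendable to the full
#' (shift5+7)-nt dual-seed match. The extension ratio is reported at
#' both granularities: site level (extendable sites / all canonical
#' sites) and gene level (genes with >= 1 extendable site / genes with
#' >= 1 canonical site).
#'
#' @param mirnaLabel miRNA name.
#' @param shift5 isomiR shift.
#' @param canonicalSet,isomirSet \linkS4class{TargetSet} objects or
#'   plain gene-id vectors.
#' @param canonicalSites optional site data.frame from
#'   \code{\link{scanTranscripts}} with an \code{extendable} column.
#' @return One-row data.frame: \code{mirna_label}, \code{shift5},
#'   \code{n_6mer}, \code{n_7mer_m8}, \code{n_intersection},
#'   \code{n_union}, \code{jaccard}, \code{n_sites},
#'   \code{n_extended_sites}, \code{extension_ratio_site},
#'   \code{extension_ratio_gene}.
#' @export
overlapProfile <- function(mirnaLabel, shift5, canonicalSet, isomirSet,
                           canonicalSites = NULL) {
  gA <- if (is(canonicalSet, "TargetSet")) targetGenes(canonicalSet)
        else unique(canonicalSet)
  gB <- if (is(isomirSet, "TargetSet")) targetGenes(isomirSet)
        else unique(isomirSet)
  inter <- length(intersect(gA, gB))
  uni <- length(union(gA, gB))
  nSites <- NA_integer_; nExt <- NA_integer_
  ratioSite <- NA_real_; ratioGene <- NA_real_
  if (!is.null(canonicalSites)) {
    nSites <- nrow(canonicalSites)
    nExt <- sum(canonicalSites$extendable, na.rm = TRUE)
    ratioSite <- if (nSites > 0) nExt / nSites else NA_real_
    geneHas <- tapply(canonicalSites$extendable, canonicalSites$gene_id,
                      any)
    nGenes <- length(geneHas)
    ratioGene <- if (nGenes > 0) sum(geneHas, na.rm = TRUE) / nGenes
                 else NA_real_
  }
  data.frame(
    mirna_label = mirnaLabel, shift5 = as.integer(shift5),
    n_6mer = length(gA), n_7mer_m8 = length(gB),
    n_intersection = inter, n_union = uni,
    jaccard = if (uni == 0) NA_real_ else inter / uni,
    n_sites = nSites, n_extended_sites = nExt,
    extension_ratio_site = ratioSite, extension_ratio_gene = ratioGene,
    stringsAsFactors = FALSE)
}
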