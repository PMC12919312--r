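# All permutations of 1..n as a matrix (n! rows); used only for the
# exact small-sample Spearman p-value, so n is capped at 9.
.allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Spearman correlation with a two-sided zero-correlation p-value
#'
#' rho is the Pearson correlation of average ranks (so ties are handled
#' by mid-ranks). The p-value is exact by full permutation enumeration
#' for n < 10 and uses the t-approximation
#' t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom otherwise.
#'
#' @param x,y numeric vectors of equal length (n >= 5).
#' @return A list with \code{rho}, \code{p} and \code{n}. \code{rho} is
#'   \code{NA} (with \code{p = NA}) when either vector is constant.
#' @export
spearmanCor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 paired observations", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n < 10) {
    perms <- .allPermutations(n)
    # correlation of rx with every permutation of ry
    rmat <- matrix(ry[perms], nrow(perms), n)
    rhoAll <- as.vector(cor(rx, t(rmat)))
    p <- mean(abs(rhoAll) >= abs(rho) - 1e-12)
  } else {
    r2 <- min(rho^2, 1 - 1e-12)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = min(p, 1), n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control: sort p ascending, q_(i) = min over j >= i of
#' p_(j) * m / j capped at 1, returned in input order.
#'
#' @param p p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Gene-by-gene Spearman association with a miRNA
#'
#' Correlates each gene's expression with the miRNA across the samples
#' shared between the two inputs; samples are paired by id, never by
#' column order. Genes whose expression is constant get \code{NA} rho
#' and are excluded from the BH family.
#'
#' @param mrna \linkS4class{ExpressionMatrix} on the \code{log2p1}
#'   scale.
#' @param mirna named numeric vector: the miRNA's log2(1+RPM) values,
#'   names = sample ids (or a 1-row \code{ExpressionMatrix}).
#' @param genes genes to test; default all rows of \code{mrna}.
#' @return A data.frame with columns \code{gene_id}, \code{rho},
#'   \code{p}, \code{padj}, \code{n}.
#' @export
spearmanTable <- function(mrna, mirna, genes = NULL) {
  .requireScale(mrna, "log2p1", "spearmanTable")
  if (is(mirna, "ExpressionMatrix")) {
    stopifnot(nrow(exprValues(mirna)) == 1)
    mirna <- exprValues(mirna)[1, ]
  }
  if (is.null(names(mirna)))
    stop("the miRNA vector must be named by sample id", call. = FALSE)
  v <- exprValues(mrna)
  shared <- intersect(colnames(v), names(mirna))
  if (length(shared) < 5)
    stop("fewer than 5 shared samples between mRNA and miRNA data",
         call. = FALSE)
  if (is.null(genes)) genes <- rownames(v)
  missing <- setdiff(genes, rownames(v))
  if (length(missing) > 0)
    warning(length(missing), " gene(s) absent from the mRNA matrix were",
            " dropped", call. = FALSE)
  genes <- intersect(genes, rownames(v))
  mv <- mirna[shared]
  sub <- v[genes, shared, drop = FALSE]
  n <- length(shared)
  if (length(unique(mv)) < 2)
    stop("the miRNA vector is constant across the shared samples",
         call. = FALSE)
  if (n >= 10) {
    # vectorized: rank everything once, Pearson on ranks
    rmir <- rank(mv)
    rmat <- t(apply(sub, 1, rank))
    constant <- apply(sub, 1, function(z) length(unique(z)) < 2)
    rho <- suppressWarnings(as.vector(cor(t(rmat), rmir)))
    rho[constant] <- NA_real_
    r2 <- pmin(rho^2, 1 - 1e-12)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  } else {
    res <- lapply(genes, function(g) spearmanCor(sub[g, ], mv))
    rho <- vapply(res, `[[`, numeric(1), "rho")
    p <- vapply(res, `[[`, numeric(1), "p")
  }
  padj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  padj[ok] <- bhAdjust(p[ok])
  data.frame(gene_id = genes, rho = rho, p = p, padj = padj, n = n,
             stringsAsFactors = FALSE)
}

#' Mann-Whitney comparison of two correlation distributions
#'
#' Two-sided test whether the correlation coefficients of genes carrying
#' a seed differ in distribution from those lacking it. Exact when both
#' groups have at most 8 untied values, otherwise the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param valuesWith correlation values for genes with the seed.
#' @param valuesWithout values for genes without the seed.
#' @return A list (\code{GroupComparison}): \code{uStatistic} (U of the
#'   "with" group), \code{p} (two-sided), \code{nWith}, \code{nWithout},
#'   and \code{smallerGroup} — which group is stochastically smaller
#'   (lower values), \code{"with"}, \code{"without"} or \code{"none"}.
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
#' @export
compareGroups <- function(valuesWith, valuesWithout) {
  valuesWith <- valuesWith[is.finite(valuesWith)]
  valuesWithout <- valuesWithout[is.finite(valuesWithout)]
  if (length(valuesWith) == 0 || length(valuesWithout) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  ties <- any(duplicated(c(valuesWith, valuesWithout)))
  exact <- !ties && length(valuesWith) <= 8 && length(valuesWithout) <= 8
  wt <- suppressWarnings(
    stats::wilcox.test(valuesWith, valuesWithout, exact = exact,
                       correct = TRUE))
  u <- unname(wt$statistic)
  mid <- length(valuesWith) * length(valuesWithout) / 2
  list(uStatistic = u, p = wt$p.value,
       nWith = length(valuesWith), nWithout = length(valuesWithout),
       smallerGroup = if (u < mid) "with" else if (u > mid) "without"
                      else "none")
}
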