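.mkMat <- function(v, nrow, scale = "raw_counts", lengths = NULL) {
  m <- matrix(v, nrow = nrow, byrow = TRUE,
              dimnames = list(paste0("g", seq_len(nrow)),
                              paste0("s", seq_len(length(v) / nrow))))
  expressionMatrix(m, scale, geneLengths = lengths)
}

test_that("size factors match the worked median-of-ratios example", {
  em <- .mkMat(c(2, 4, 4, 8, 8, 16), 3)
  sf <- sizeFactors(em)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  expect_equal(unname(sf[1]), 0.7071, tolerance = 1e-4)

  # identical columns -> equal factors
  em2 <- .mkMat(c(5, 5, 1, 1, 9, 9), 3)
  expect_equal(unname(diff(sizeFactors(em2))), 0)

  expect_error(sizeFactors(.mkMat(c(0, 1, 1, 0), 2)),
               "pre-filter")
})

test_that("size factors are scale-equivariant and gene-permutation invariant", {
  set.seed(60)
  for (i in 1:20) {
    m <- matrix(rpois(60, 50) + 1, nrow = 10,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    sf <- sizeFactors(m)
    # direct-formula oracle
    gm <- exp(rowMeans(log(m)))
    oracle <- apply(m / gm, 2, median)
    expect_equal(unname(sf), unname(oracle))
    # rescaling one sample's column by c rescales its factor relative to
    # the others by c (the geometric-mean reference absorbs c^(1/n))
    c3 <- m; c3[, 3] <- c3[, 3] * 5
    sf3 <- sizeFactors(c3)
    expect_equal(unname(sf3[3]), unname(sf[3] * 5^(5 / 6)),
                 tolerance = 1e-12)
    expect_equal(unname(sf3[-3]), unname(sf[-3] * 5^(-1 / 6)),
                 tolerance = 1e-12)
    expect_equal(unname(sf3[3] / sf3[1]), unname(5 * sf[3] / sf[1]),
                 tolerance = 1e-12)
    # permuting genes changes nothing
    expect_equal(sizeFactors(m[sample(10), ]), sf)
  }
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(61)
  # odd row count: DESeq2 takes the median in log space, which matches
  # the linear-space median of ratios only for an odd reference set
  m <- matrix(rnbinom(306, mu = 100, size = 5) + 1, nrow = 51,
              dimnames = list(paste0("g", 1:51), paste0("s", 1:6)))
  expect_equal(unname(sizeFactors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("normalizeCounts divides by factors and round-trips", {
  em <- .mkMat(c(2, 4), 1)
  norm <- normalizeCounts(em, c(1, 2))
  expect_equal(unname(exprValues(norm)), matrix(c(2, 2), 1))
  expect_equal(exprScale(norm), "size_normalized")
  # factors of 1 are the identity
  expect_equal(exprValues(normalizeCounts(em, c(1, 1))), exprValues(em))
  # round trip
  set.seed(62)
  m <- matrix(rpois(40, 30) + 1, nrow = 8,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  sf <- sizeFactors(m)
  back <- sweep(exprValues(normalizeCounts(m, sf)), 2, sf, "*")
  expect_equal(back, m + 0)
  expect_error(normalizeCounts(em, c(1, 2, 3)), "number of samples")
})

test_that("the scale state machine refuses wrong-scale transitions", {
  em <- .mkMat(c(2, 4, 4, 8), 2, lengths = c(1000, 2000))
  norm <- normalizeCounts(em)
  expect_error(normalizeCounts(norm), "expects scale raw_counts")
  fpkm <- toFPKM(norm)
  expect_error(toFPKM(fpkm), "expects scale size_normalized")
  lg <- log2p1(fpkm)
  expect_error(log2p1(lg), "expects scale fpkm/rpm")
  expect_error(cumulativeAbundanceFilter(lg), "expects scale")
  expect_error(expressedAbove(fpkm, "g1"), "expects scale log2p1")
  # lengths are forbidden on the RPM path
  expect_error(toRPM(norm), "not applicable")
})

test_that("FPKM follows the length/depth formula", {
  # one gene of 1000 bp holding all 1e6 normalized fragments
  em <- expressionMatrix(matrix(1e6, 1, 1, dimnames = list("g1", "s1")),
                         "size_normalized", geneLengths = 1000)
  fpkm <- toFPKM(em)
  expect_equal(unname(exprValues(fpkm)[1, 1]), 1e6)
  expect_equal(unname(exprValues(log2p1(fpkm))[1, 1]), log2(1 + 1e6))
  expect_equal(log2(1 + 1e6), 19.93, tolerance = 1e-3)

  # equal counts, lengths 1000 vs 2000 -> FPKM ratio 2:1
  em <- expressionMatrix(
    matrix(c(100, 100), 2, 1, dimnames = list(c("g1", "g2"), "s1")),
    "size_normalized", geneLengths = c(1000, 2000))
  v <- exprValues(toFPKM(em))
  expect_equal(unname(v[1, 1] / v[2, 1]), 2)

  # brute-force formula oracle on random matrices
  set.seed(63)
  m <- matrix(runif(60, 1, 500), nrow = 12,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:5)))
  lens <- runif(12, 300, 5000)
  v <- exprValues(toFPKM(expressionMatrix(m, "size_normalized",
                                          geneLengths = lens)))
  oracle <- m * 1e9 / outer(lens, colSums(m))
  expect_equal(v, oracle)
})

test_that("RPM columns sum to one million", {
  set.seed(64)
  m <- matrix(runif(50, 0, 100), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  rpm <- toRPM(expressionMatrix(m, "size_normalized"))
  expect_equal(unname(colSums(exprValues(rpm))), rep(1e6, 5))
  expect_equal(exprValues(rpm), m * 1e6 / rep(colSums(m), each = 10))
  # a column already summing to 1e6 is unchanged
  m2 <- matrix(c(4e5, 6e5), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(exprValues(toRPM(expressionMatrix(m2, "size_normalized"))),
               m2)
})

test_that("the cumulative-abundance filter keeps the top of the ranking", {
  m <- matrix(rep(c(50, 30, 15, 4, 1), 3), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  em <- expressionMatrix(m, "fpkm")
  rep99 <- cumulativeAbundanceFilter(em, 0.99)
  expect_setequal(rep99$keptIds, c("g1", "g2", "g3", "g4"))
  expect_equal(rep99$droppedIds, "g5")
  expect_equal(rep99$cumulativeFractionAtCut, 0.99)

  # fraction 1.0 keeps every row with positive median
  m2 <- rbind(m, g6 = 0)
  all1 <- cumulativeAbundanceFilter(expressionMatrix(m2, "fpkm"), 1.0)
  expect_setequal(all1$keptIds, paste0("g", 1:5))
  # single row always kept
  one <- cumulativeAbundanceFilter(
    expressionMatrix(m[1, , drop = FALSE], "fpkm"), 0.5)
  expect_equal(one$keptIds, "g1")
  expect_error(cumulativeAbundanceFilter(
    expressionMatrix(matrix(0, 1, 2, dimnames = list("g", c("a", "b"))),
                     "fpkm")), "all-zero")
})

test_that("ties at the filter cut are kept together and fraction is monotone", {
  m <- matrix(rep(c(10, 5, 5, 5, 1), 2), nrow = 5,
              dimnames = list(paste0("g", 1:5), c("s1", "s2")))
  em <- expressionMatrix(m, "rpm")
  # 0.7 of 26 = 18.2; prefix 10+5+5 = 20 >= 18.2, but g4 ties at 5
  rep <- cumulativeAbundanceFilter(em, 0.7)
  expect_setequal(rep$keptIds, c("g1", "g2", "g3", "g4"))

  set.seed(65)
  m <- matrix(runif(80, 0, 100), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
  em <- expressionMatrix(m, "rpm")
  prev <- character(0)
  for (f in c(0.3, 0.6, 0.9, 0.99, 1.0)) {
    kept <- cumulativeAbundanceFilter(em, f)$keptIds
    expect_true(all(prev %in% kept))  # monotone in fraction
    prev <- kept
  }
})

test_that("expressedAbove partitions by median with a closed bound", {
  m <- matrix(c(0, 0, 0, 1, 1, 1, 3, 4, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("zero", "boundary", "high"),
                              paste0("s", 1:3)))
  em <- expressionMatrix(m, "log2p1")
  res <- expressedAbove(em, c("zero", "boundary", "high", "absent"))
  expect_setequal(res$expressed, c("boundary", "high"))  # >= 1 kept
  expect_setequal(res$notExpressed, c("zero", "absent"))

  # planted: exactly k genes above threshold
  set.seed(66)
  k <- 7
  m <- rbind(matrix(runif(15 * 4, 1.2, 8), nrow = 15),
             matrix(runif(10 * 4, 0, 0.8), nrow = 10))
  rownames(m) <- paste0("g", 1:25); colnames(m) <- paste0("s", 1:4)
  m <- m[sample(25), ]
  planted <- rownames(m)[apply(m, 1, median) >= 1][1:k]
  res <- expressedAbove(expressionMatrix(m, "log2p1"),
                        c(planted, "gX1", "gX2"))
  expect_setequal(res$expressed, planted)
})

test_that("count matrices round-trip through TSV", {
  set.seed(67)
  m <- matrix(rpois(20, 10), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  f <- tempfile(fileext = ".tsv")
  writeCountsTSV(expressionMatrix(m, "raw_counts"), f, "gene_id")
  back <- readCountsTSV(f)
  expect_equal(exprValues(back), m + 0)
  expect_equal(exprScale(back), "raw_counts")
})
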