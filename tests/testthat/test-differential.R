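mkCounts <- function(mat, groups, sf = NULL) {
  mat <- as.matrix(mat)
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  RegionCounts(GRanges("chr1", IRanges(seq_len(nrow(mat)) * 1000,
                                       width = 500)),
               mat, sampleData = data.frame(group = groups),
               sizeFactors = sf)
}

test_that("size factors equal a direct median-of-ratios oracle", {
  x <- withr::with_seed(21, matrix(rnbinom(400, mu = 50, size = 10), 100))
  f <- computeSizeFactors(x)
  ## independent oracle
  ok <- rowSums(x == 0) == 0
  gm <- exp(rowMeans(log(x[ok, ])))
  raw <- apply(x[ok, ] / gm, 2, median)
  expect_equal(unname(f), unname(raw / exp(mean(log(raw)))),
               tolerance = 1e-12)
  ## identical samples: unit factors
  expect_equal(computeSizeFactors(cbind(x[, 1], x[, 1])), c(1, 1))
  ## scaling identity: doubling one sample doubles its factor
  f2 <- computeSizeFactors(cbind(x[, 1], 2 * x[, 1]))
  expect_equal(f2[2] / f2[1], 2)
  expect_error(computeSizeFactors(cbind(x[, 1], 0 * x[, 1])), "all-zero")
})

test_that("size factors agree with the canonical estimator", {
  skip_if_not_installed("DESeq2")
  x <- withr::with_seed(22, matrix(rnbinom(600, mu = 80, size = 5), 150))
  f <- computeSizeFactors(x)
  ref <- DESeq2::estimateSizeFactorsForMatrix(x)
  ## conventions differ in the median scale (ratio vs log-ratio), which
  ## only matters for even region counts: agreement to ~1%
  expect_equal(unname(f / exp(mean(log(f)))),
               unname(ref / exp(mean(log(ref)))), tolerance = 0.01)
})

test_that("the dispersion-0 mode equals the conditional binomial oracle", {
  ## spec closed form: 1 vs 1, equal factors, 100 vs 200
  rc <- mkCounts(cbind(100, 200), c("a", "b"), sf = c(1, 1))
  res <- differentialTest(rc, c("a", "b"), dispersion = 0)
  expect_equal(res$raw_p, enumBinomTwoSided(200, 300, 0.5),
               tolerance = 1e-12)
  ## 100 random fixtures against the oracle, including unequal factors
  withr::with_seed(30, {
    for (i in 1:100) {
      k <- rpois(4, 60)
      sf <- runif(4, 0.5, 2)
      rc <- mkCounts(matrix(k, 1), c("a", "a", "b", "b"), sf = sf)
      res <- differentialTest(rc, c("a", "b"), dispersion = 0)
      p0 <- sum(sf[3:4]) / sum(sf)
      expect_equal(res$raw_p,
                   min(1, enumBinomTwoSided(k[3] + k[4], sum(k), p0)),
                   tolerance = 1e-10)
    }
  })
})

test_that("identical groups give zero fold-change and non-significant p", {
  x <- withr::with_seed(31, matrix(rnbinom(50, mu = 100, size = 20), 25))
  rc <- mkCounts(cbind(x, x), rep(c("a", "b"), each = 2), sf = rep(1, 4))
  res <- differentialTest(rc, c("a", "b"), dispersion = 0.05)
  expect_equal(res$log2FC, rep(0, 25))
  expect_true(all(res$raw_p >= 0.5))
})

test_that("direction always matches the sign of the recomputed group means", {
  withr::with_seed(32, {
    x <- matrix(rnbinom(600, mu = 40, size = 4), 100)
    sf <- computeSizeFactors(x)
    rc <- mkCounts(x, rep(c("a", "b"), each = 3), sf = sf)
    res <- differentialTest(rc, c("a", "b"))
    m1 <- rowMeans(sweep(x[, 1:3], 2, sf[1:3], "/"))
    m2 <- rowMeans(sweep(x[, 4:6], 2, sf[4:6], "/"))
    nz <- m1 != m2
    expect_equal(res$direction[nz],
                 ifelse(m2[nz] > m1[nz], "up", "down"))
    expect_true(all(res$adj_p >= res$raw_p - 1e-15))
  })
})

test_that("declared sample rescaling leaves Wald p-values unchanged", {
  x <- withr::with_seed(33, matrix(rnbinom(800, mu = 60, size = 10), 200))
  rc1 <- mkCounts(x, rep(c("a", "b"), each = 2), sf = rep(1, 4))
  x2 <- x; x2[, 3] <- x[, 3] * 4
  rc2 <- mkCounts(x2, rep(c("a", "b"), each = 2), sf = c(1, 1, 4, 1))
  r1 <- differentialTest(rc1, c("a", "b"), dispersion = 0.05)
  r2 <- differentialTest(rc2, c("a", "b"), dispersion = 0.05)
  expect_equal(r1$raw_p, r2$raw_p, tolerance = 1e-12)
  expect_equal(r1$log2FC, r2$log2FC, tolerance = 1e-12)
})

test_that("null type-I error is calibrated and planted effects are detected", {
  withr::with_seed(40, {
    n <- 4000
    mu <- pmin(pmax(rlnorm(n, log(100), 0.5), 10), 2000)
    cnt <- cbind(matrix(rnbinom(n * 4, mu = mu, size = 20), n),
                 matrix(rnbinom(n * 4, mu = mu, size = 20), n))
    rc <- mkCounts(cnt, rep(c("a", "b"), each = 4), sf = rep(1, 8))
    res <- differentialTest(rc, c("a", "b"))
    expect_gt(mean(res$raw_p < 0.05), 0.035)
    expect_lt(mean(res$raw_p < 0.05), 0.065)
    ## planted 2x effect at 3 vs 3: high power at BH 0.05
    np <- 400
    cp <- cbind(matrix(rnbinom(np * 3, mu = 100, size = 20), np),
                matrix(rnbinom(np * 3, mu = 200, size = 20), np))
    rcp <- mkCounts(cp, rep(c("a", "b"), each = 3), sf = rep(1, 6))
    resp <- differentialTest(rcp, c("a", "b"))
    expect_gte(mean(resp$adj_p < 0.05), 0.85)
  })
})

test_that("the NB engine broadly agrees with the reference implementation", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(41, {
    n <- 300
    mu <- pmax(rlnorm(n, log(100), 0.7), 10)
    fc <- ifelse(seq_len(n) <= 60, 2, 1)
    cnt <- cbind(matrix(rnbinom(n * 3, mu = mu, size = 15), n),
                 matrix(rnbinom(n * 3, mu = mu * fc, size = 15), n))
    colnames(cnt) <- paste0("s", 1:6)
    rc <- mkCounts(cnt, rep(c("a", "b"), each = 3), sf = rep(1, 6))
    mine <- differentialTest(rc, c("a", "b"))
    dds <- DESeq2::DESeqDataSetFromMatrix(
      cnt, data.frame(cond = factor(rep(c("a", "b"), each = 3))), ~cond)
    DESeq2::sizeFactors(dds) <- rep(1, 6)
    dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
    ref <- DESeq2::results(dds)
    ## same calls at FDR 0.1 for the clear effects, high rank agreement
    expect_gt(cor(-log10(mine$raw_p + 1e-300),
                  -log10(ref$pvalue + 1e-300), use = "complete.obs"), 0.9)
    expect_gt(cor(mine$log2FC, ref$log2FoldChange), 0.98)
  })
})

test_that("catalogue construction recovers planted labels", {
  ## noise-free: exact recovery
  regions <- GRanges("chr1", IRanges(seq_len(60) * 5000, width = 2000))
  truthLab <- rep(c("neuronal", "glial", "none"), each = 20)
  basePos <- ifelse(truthLab == "neuronal", 400,
                    ifelse(truthLab == "glial", 100, 250))
  baseNeg <- ifelse(truthLab == "glial", 400,
                    ifelse(truthLab == "neuronal", 100, 250))
  mkRc <- function(base, noise = FALSE, seed = 1) {
    cnt <- if (noise)
      withr::with_seed(seed, matrix(rnbinom(120, mu = rep(base, 2),
                                            size = 20), ncol = 2))
    else cbind(base, base)
    colnames(cnt) <- c("r1", "r2")
    RegionCounts(regions, cnt, sizeFactors = c(1, 1))
  }
  asKey <- function(gr) paste0(seqnames(gr), ":", start(gr), "-", end(gr))
  cat0 <- buildEnhancerCatalogue(mkRc(basePos), mkRc(baseNeg))
  got <- catalogueRegions(cat0)
  m <- match(asKey(got), asKey(regions))
  expect_equal(mcols(got)$label, truthLab[m])
  expect_equal(sum(truthLab != "none"), length(got))
  ## NB noise, 4-fold separation, n = 2 per fraction: >= 95% accuracy
  catN <- buildEnhancerCatalogue(mkRc(basePos, TRUE, 7),
                                 mkRc(baseNeg, TRUE, 8))
  gotN <- catalogueRegions(catN)
  mN <- match(asKey(gotN), asKey(regions))
  acc <- mean(mcols(gotN)$label == truthLab[mN])
  expect_gte(acc, 0.95)
  ## p_cutoff 0: empty catalogue
  expect_length(buildEnhancerCatalogue(mkRc(basePos), mkRc(baseNeg),
                                       pCutoff = 0), 0)
  ## differing universes error
  expect_error(buildEnhancerCatalogue(
    mkRc(basePos),
    RegionCounts(shift(regions, 1), cbind(r1 = baseNeg, r2 = baseNeg),
                 sizeFactors = c(1, 1))), "universes differ")
})
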