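mkCatalogue <- function() {
  EnhancerCatalogue(GRanges("chr1",
    IRanges(c(1000, 5000, 9000), width = 1000),
    label = c("neuronal", "glial", "neuronal")))
}

test_that("region attribution applies the ambiguity rule and partitions input", {
  cat <- mkCatalogue()
  regions <- GRanges("chr1", IRanges(
    c(1200, 5200, 3000, 1500), width = c(100, 100, 100, 4000)))
  mcols(regions)$direction <- c("down", "up", "down", "up")
  att <- attributeRegions(regions, cat)
  lab <- mcols(att$regions)$celltype_label
  expect_equal(lab, c("Neuronal", "Glial", "Non-specific", "Non-specific"))
  ## counts partition the input
  expect_equal(sum(att$counts), length(regions))
})

test_that("metaprofiles are flat on uniform tracks and strand-flipped", {
  sl <- c(chrM = 2e5)
  flat <- SignalTrack(list(chrM = rep(1, 1000)), 200L, sl,
                      normalization = "rpgc_1x")
  genes <- GRanges("chrM", IRanges(c(50000, 120000), width = 8000),
                   strand = c("+", "-"))
  mp <- metaprofile(flat, genes)
  expect_equal(mp$profile, rep(1, 140), tolerance = 1e-9)
  expect_equal(mp$featureMeans, c(1, 1), tolerance = 1e-9)
  ## raw tracks are rejected
  raw <- SignalTrack(list(chrM = rep(1, 1000)), 200L, sl)
  expect_error(metaprofile(raw, genes), "1x")
  ## triangular coverage equals a direct interpolation oracle
  tri <- SignalTrack(list(chrM = c(seq(0, 499), seq(500, 1))), 200L, sl,
                     normalization = "rpgc_1x")
  g1 <- GRanges("chrM", IRanges(60001, 70000), strand = "+")
  prof <- metaprofile(tri, g1, flankBp = 2000, flankBins = 20,
                      bodyBins = 100)$profile
  vals <- trackValues(tri)$chrM
  oracle <- vapply(seq_len(100), function(i) {
    from <- 60000 + (i - 1) * 100; to <- from + 100
    bins <- (from %/% 200 + 1):((to - 1) %/% 200 + 1)
    tot <- 0
    for (b in bins) {
      lo <- max(from, (b - 1) * 200); hi <- min(to, b * 200)
      tot <- tot + vals[b] * (hi - lo) / 200
    }
    tot / (100 / 200)
  }, 0)
  expect_equal(prof[21:120], oracle, tolerance = 1e-9)
  ## minus-strand gene is the reverse of the same gene on plus
  g2m <- GRanges("chrM", IRanges(60001, 70000), strand = "-")
  expect_equal(metaprofile(tri, g2m)$profile,
               rev(metaprofile(tri, g1)$profile))
  ## clipping warns
  gEdge <- GRanges("chrM", IRanges(100, 3000), strand = "+")
  expect_warning(metaprofile(flat, gEdge), "clipped")
})

test_that("k-means recovers planted archetypes deterministically", {
  withr::with_seed(50, {
    arch <- rbind(c(rep(5, 10), rep(0, 10)), c(rep(0, 10), rep(5, 10)))
    lab <- rep(1:2, each = 30)
    x <- arch[lab, ] + matrix(rnorm(60 * 20, sd = 0.3), 60)
    rownames(x) <- sprintf("g%02d", 1:60)
  })
  cl <- clusterGeneProfiles(x, k = 2, seed = 3)
  ## perfect agreement with the planted labels up to label swap
  tab <- table(cl$cluster, lab)
  expect_equal(max(sum(diag(tab)), tab[1, 2] + tab[2, 1]), 60)
  ## identical rows, k = 1: zero inertia
  same <- matrix(1, 10, 5, dimnames = list(letters[1:10], NULL))
  expect_equal(clusterGeneProfiles(same, k = 1, seed = 1)$totWithinss, 0)
  ## determinism
  cl2 <- clusterGeneProfiles(x, k = 2, seed = 3)
  expect_identical(cl$cluster, cl2$cluster)
  expect_error(clusterGeneProfiles(same, k = 11, seed = 1), "exceeds")
})

test_that("cluster enrichment behaves at the null, the extreme and k = 1", {
  withr::with_seed(60, {
    genes <- sprintf("g%03d", 1:500)
    cl <- list(cluster = setNames(sample(1:5, 500, replace = TRUE), genes),
               k = 5L)
    ## null: uniform top genes -> adjusted p mostly near 1
    hits <- replicate(20, {
      de <- data.frame(gene_id = genes, log2FC = -abs(rnorm(500)),
                       raw_p = runif(500), adj_p = runif(500))
      enr <- clusterEnrichment(de, cl, topN = 50, direction = "down")
      min(enr$adj_p)
    })
    expect_gte(mean(hits >= 0.5), 0.8)
  })
  ## all top genes in one small cluster: astronomically significant
  cl1 <- list(cluster = setNames(c(rep(1L, 50), rep(2L, 450)),
                                 sprintf("g%03d", 1:500)), k = 2L)
  de <- data.frame(gene_id = sprintf("g%03d", 1:500),
                   log2FC = -1, raw_p = c(rep(1e-6, 50), rep(0.5, 450)),
                   adj_p = 1)
  enr <- clusterEnrichment(de, cl1, topN = 50, direction = "down")
  expect_lt(enr$raw_p[1], 1e-40)
  ## k = 1: everything observed, p = 1
  clk1 <- list(cluster = setNames(rep(1L, 500), sprintf("g%03d", 1:500)),
               k = 1L)
  enr1 <- clusterEnrichment(de, clk1, topN = 50, direction = "down")
  expect_equal(enr1$observed, 50)
  expect_equal(enr1$raw_p, 1)
  expect_error(clusterEnrichment(de, cl1, topN = 1000, direction = "down"),
               "top_n")
})

test_that("cell-type specificity enrichment matches enumeration", {
  ct <- data.frame(gene_id = sprintf("g%02d", 1:60),
                   log2FC = rep(c(2, -2), 30),
                   raw_p = 1e-9, adj_p = 1e-6)
  ## balanced set under a balanced null: p = 1
  bal <- celltypeSpecificityEnrichment(sprintf("g%02d", 1:10), ct)
  expect_equal(bal$nullProportion, 0.5)
  expect_equal(bal$p, 1)
  ## 30 neuronal / 0 glial under null 0.5: p = 2 * 2^-30
  ctAll <- data.frame(gene_id = c(sprintf("n%02d", 1:30),
                                  sprintf("m%02d", 1:30)),
                      log2FC = rep(c(2, -2), each = 30),
                      raw_p = 1e-9, adj_p = 1e-6)
  one <- celltypeSpecificityEnrichment(sprintf("n%02d", 1:30), ctAll)
  expect_equal(one$p, 2 * 2^-30, tolerance = 1e-12)
  expect_error(celltypeSpecificityEnrichment(
    "x", transform(ct, adj_p = 1)), "no cell-type-specific")
})

test_that("chip-rna regression recovers exact and hand-computed fits", {
  genes <- sprintf("g%02d", 1:20)
  chip <- setNames(seq(-2, 2, length.out = 20), genes)
  de <- data.frame(gene_id = genes, log2FC = unname(chip),
                   raw_p = 0.5, adj_p = rep(c(0.01, 0.5), 10))
  fit <- chipRnaRegression(chip, de)
  all <- fit[fit$stratum == "all", ]
  expect_equal(all$r, 1); expect_equal(all$slope, 1)
  ## 5-point hand dataset against the closed-form Pearson formula
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  rHand <- sum((x - 3) * (y - mean(y))) /
    sqrt(sum((x - 3)^2) * sum((y - mean(y))^2))
  de5 <- data.frame(gene_id = letters[1:5], log2FC = y, raw_p = 0.5,
                    adj_p = 0.5)
  fit5 <- chipRnaRegression(setNames(x, letters[1:5]), de5)
  expect_equal(fit5[fit5$stratum == "all", "r"], rHand)
  expect_error(chipRnaRegression(setNames(rep(1, 5), letters[1:5]), de5),
               "constant predictor")
})

test_that("concordance analysis reports labels, fractions and Spearman", {
  regions <- GRanges("chr1", IRanges(c(1200, 5200, 3000, 7000),
                                     width = 100))
  gd <- data.frame(log2FC = c(-1, 2, 0.5, -0.4),
                   raw_p = c(0.01, 0.01, 0.01, 0.5))
  ad <- data.frame(log2FC = c(-2, 1, -0.5, -1),
                   raw_p = c(0.01, 0.01, 0.01, 0.5))
  out <- concordanceAnalysis(regions, gd, ad, mkCatalogue(),
                             signal = matrix(rnorm(16), 4))
  ## region 4 filtered (p = 0.5); 2 of 3 retained are concordant
  expect_equal(nrow(out$table), 3)
  expect_equal(out$concordance, 2 / 3)
  expect_equal(out$byLabel["Neuronal", "concordance"], 1)
  expect_equal(sort(out$order), 1:3)
  expect_error(concordanceAnalysis(regions, transform(gd, raw_p = 1),
                                   ad, mkCatalogue()),
               "no region passes")
})

test_that("chromosome enrichment flags concentration and handles degenerate input", {
  uni <- GRanges(rep(c("chr1", "chr2"), c(90, 10)),
                 IRanges(seq_len(100) * 1000, width = 100))
  mcols(uni)$gene_id <- sprintf("g%03d", 1:100)
  ## all DEGs on the small chromosome
  de <- data.frame(gene_id = sprintf("g%03d", 91:100),
                   adj_p = 1e-4, chromosome = "chr2")
  res <- chromosomeEnrichment(de, uni)
  expect_lt(res$raw_p[res$chromosome == "chr2"], 1e-9)
  expect_equal(res$pctDeg[res$chromosome == "chr2"], 100)
  ## single-chromosome universe: p = 1
  uni1 <- uni[1:90]
  de1 <- data.frame(gene_id = sprintf("g%03d", 1:5), adj_p = 1e-4,
                    chromosome = "chr1")
  expect_equal(chromosomeEnrichment(de1, uni1)$raw_p, 1)
  expect_error(chromosomeEnrichment(de, uni1), "absent")
  ## null: uniform DEGs are unenriched
  withr::with_seed(70, {
    deN <- data.frame(gene_id = sample(sprintf("g%03d", 1:100), 30),
                      adj_p = 1e-4)
    deN$chromosome <- as.character(seqnames(uni))[
      match(deN$gene_id, mcols(uni)$gene_id)]
    resN <- chromosomeEnrichment(deN, uni)
    expect_true(all(resN$adj_p > 0.05))
  })
})

test_that("group-wise z-score testing matches the textbook KW formula", {
  ## identical group distributions: p not significant
  expr <- rbind(g1 = rep(c(1, 5, 9), 4), g2 = rep(c(2, 4, 8), 4))
  same <- groupwiseZscoreTest(expr, c("g1", "g2"),
                              rep(c("A", "B"), times = 6))
  expect_gt(same$p, 0.5)
  ## hand 3-group example, no ties: H from the textbook rank formula
  ## (z-scoring a single gene row is monotone, so ranks are unchanged)
  vals <- c(27, 2, 4, 18, 7, 9, 1, 5, 11)
  grp <- rep(c("a", "b", "c"), each = 3)
  r <- rank(vals)
  H <- 12 / (9 * 10) * sum(tapply(r, grp, sum)^2 / 3) - 3 * 10
  e1 <- matrix(vals, 1, dimnames = list("g1", NULL))
  out3 <- groupwiseZscoreTest(e1, "g1", grp)
  expect_equal(out3$H, H)
  ## planted shift is detected
  withr::with_seed(80, {
    e <- matrix(rnorm(50 * 20), 50, dimnames = list(sprintf("g%02d", 1:50),
                                                    NULL))
    e[, 11:20] <- e[, 11:20] + 1
    out <- groupwiseZscoreTest(e, rownames(e), rep(c("A", "B"), each = 10))
    expect_lt(out$p, 0.01)
    expect_equal(dim(out$pairwise), c(1L, 1L))
  })
  expect_error(groupwiseZscoreTest(expr, "g1", c("A", "B", "B", rep("B", 9))),
               ">= 2 observations")
})

test_that("nuclear fractions follow the printed formula with the event floor", {
  expect_equal(unname(nuclearFractions(30, 70)),
               c(30, 70), ignore_attr = TRUE)
  expect_equal(unname(nuclearFractions(1e5, 0)[1]), 100)
  expect_warning(ok <- nuclearFractions(20000, 1), "30,000")
  expect_equal(sum(ok), 100)
  expect_silent(nuclearFractions(30000, 10000))
  expect_error(nuclearFractions(0, 0), "> 0")
})
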