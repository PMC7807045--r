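test_that("the fragment map matches a string-scan oracle on random sequence", {
  for (seed in 1:10) {
    s <- randomSeq(10000, seed)
    fm <- buildFragmentMap(c(chrR = s))
    oracle <- scanFragments(s)
    fr <- fragments(fm)
    expect_equal(start(fr), oracle$starts)
    expect_equal(end(fr), oracle$ends)
    expect_equal(mcols(fr)$nSecond, as.integer(oracle$nSecond))
    ## tiling invariant
    expect_equal(start(fr)[-1], end(fr)[-length(fr)] + 1L)
  }
})

test_that("fragment maps handle literals, blind chromosomes and palindromy", {
  fm <- buildFragmentMap(c(chrA = "AAAGATCAAAGTACAAAGATCAAA"))
  fr <- fragments(fm)
  expect_equal(start(fr), c(1L, 4L, 18L))
  expect_equal(mcols(fr)$nSecond, c(0L, 1L, 0L))
  expect_equal(mcols(fr)$firstSecondOffset[2], 11 - 4)
  ## no first site: one blind fragment spanning the chromosome
  b <- fragments(buildFragmentMap(c(chrB = "AAAACCCCTTTT")))
  expect_length(b, 1)
  expect_true(mcols(b)$blind)
  ## GATC/GTAC are palindromic: the reverse complement mirrors the map.
  ## Internal fragments are site-to-site spans and must match as a set;
  ## the two chromosome-end fragments differ by the site length because
  ## the site is assigned to its downstream fragment.
  s <- randomSeq(5000, 99)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  f1 <- fragments(buildFragmentMap(c(chr = s)))
  f2 <- fragments(buildFragmentMap(c(chr = rc)))
  inner <- function(f) sort(width(f)[-c(1, length(f))])
  expect_equal(inner(f1), inner(f2))
  expect_equal(sum(mcols(f1)$nSecond), sum(mcols(f2)$nSecond))
})

test_that("bait design criteria apply the strict printed distance bounds", {
  ## construct a chromosome with controllable geometry:
  ## GATC at 1, then GTAC at offset d1, next GATC sets fragment length d2
  mkChrom <- function(d1, d2) {
    x <- rep("A", d2 + 8)
    x[1:4] <- c("G", "A", "T", "C")
    x[(d1 + 1):(d1 + 4)] <- c("G", "T", "A", "C")
    x[(d2 + 1):(d2 + 4)] <- c("G", "A", "T", "C")
    paste(x, collapse = "")
  }
  check <- function(d1, d2) {
    fm <- buildFragmentMap(c(chr = mkChrom(d1, d2)))
    checkBaitDesign(fm, which(start(fragments(fm)) == 1L))
  }
  expect_true(check(351, 600)$pass)
  expect_false(check(350, 600)$pass)      # boundary: needs > 350
  expect_false(check(351, 500)$pass)      # boundary: needs > 500
  expect_false(check(351, 1500)$pass)     # boundary: needs < 1500
  expect_true(check(351, 1499)$pass)
  ## blind fragment fails with the reason
  fmB <- buildFragmentMap(c(chr = paste0(
    "GATC", strrep("A", 700), "GATC", strrep("A", 100))))
  res <- checkBaitDesign(fmB, 1)
  expect_false(res$pass)
  expect_match(res$reasons, "blind")
  expect_error(checkBaitDesign(fmB, 99), "not in map")
})

test_that("quantile normalization equalizes distributions and preserves ranks", {
  ## continuous (tie-free) profiles: the contract is exact
  p1 <- decayProfile(1, integerize = FALSE)
  p2 <- decayProfile(2, integerize = FALSE)
  qn <- quantileNormalize(list(p1, p2))
  sc <- setdiff(seq_along(p1@fragments), p1@excluded)
  ## all samples share the same sorted vector, exactly
  expect_identical(sort(qn[[1]]@score[sc]), sort(qn[[2]]@score[sc]))
  ## within-sample rank order of raw counts is preserved
  expect_equal(rank(qn[[1]]@score[sc]), rank(p1@counts[sc]))
  ## idempotent
  qn2 <- quantileNormalize(qn)
  expect_equal(qn2[[1]]@score, qn[[1]]@score, tolerance = 1e-12)
  ## identical profiles unchanged
  same <- quantileNormalize(list(p1, p1))
  expect_equal(same[[1]]@score[sc], p1@counts[sc])
  ## integer counts (with ties): ranks still preserved
  i1 <- decayProfile(3); i2 <- decayProfile(4)
  qi <- quantileNormalize(list(i1, i2))
  expect_equal(rank(qi[[1]]@score[sc], ties.method = "average"),
               rank(i1@counts[sc], ties.method = "average"))
  ## hand fixture
  fr <- GRanges("c", IRanges((0:2) * 10 + 1, (1:3) * 10))
  a <- FourCProfile(fr, c(1, 2, 3), 1, excluded = integer(0))
  b <- FourCProfile(fr, c(10, 20, 30), 1, excluded = integer(0))
  got <- quantileNormalize(list(a, b))
  expect_equal(got[[1]]@score, c(5.5, 11, 16.5))
  expect_equal(got[[2]]@score, c(5.5, 11, 16.5))
  expect_error(quantileNormalize(list(a)), ">= 2")
})

test_that("profile smoothing is a shrunken-window running mean", {
  fr <- GRanges("c", IRanges((0:40) * 10 + 1, (1:41) * 10))
  const <- FourCProfile(fr, rep(7, 41), 21, excluded = integer(0))
  expect_equal(smoothProfile(const)@score, rep(7, 41))
  ## impulse of height 21 spread by window 21 -> plateau of 1 (centre)
  imp <- rep(0, 41); imp[21] <- 21
  pi <- FourCProfile(fr, imp, 1, excluded = integer(0))
  sm <- smoothProfile(pi, 21)@score
  expect_equal(sm[11:31], rep(1, 21))
  ## shrunken symmetric edges: position 2 averages positions 1..3
  expect_equal(smoothProfile(pi, 5)@score[2], mean(imp[1:3]))
  ## window 1 is the identity; even windows are rejected
  expect_equal(smoothProfile(pi, 1)@score, imp)
  expect_error(smoothProfile(pi, 4), "odd")
  expect_error(smoothProfile(pi, 43), "exceeds")
})

test_that("interaction calling finds planted bumps and respects nulls", {
  run <- function(seed, bump) {
    ps <- list(m = decayProfile(seed, bumpAt = if (bump) 230:239),
               f = decayProfile(seed + 500, bumpAt = if (bump) 230:239))
    ps <- quantileNormalize(ps)
    ps <- lapply(ps, smoothProfile)
    callInteractions(ps, conditions = c("WT", "WT"))
  }
  hits <- 0; false <- 0
  for (s in 1:15) {
    r <- run(s, TRUE)$reproducible$WT
    hits <- hits + (length(r) > 0 && any(start(r) <= 239 & end(r) >= 230))
    false <- false + (length(run(s + 300, FALSE)$reproducible$WT) > 0)
  }
  expect_gte(hits, 14)
  expect_lte(false, 1)
  ## exactly monotone profiles yield no candidates
  n <- 200
  mono <- FourCProfile(GRanges("c", IRanges((seq_len(n) - 1) * 10 + 1,
                                            seq_len(n) * 10)),
                       rev(seq_len(n))^1.5, 1, excluded = integer(0))
  out <- callInteractions(list(a = mono, b = mono), c("x", "x"))
  expect_length(out$reproducible$x, 0)
  ## disjoint candidates across samples: no reproducible regions
  p1 <- decayProfile(7, bumpAt = 40:49)
  p2 <- decayProfile(8, bumpAt = 250:259)
  ps <- lapply(quantileNormalize(list(p1, p2)), smoothProfile)
  rep2 <- callInteractions(ps, c("y", "y"))$reproducible$y
  expect_length(rep2, 0)
})

test_that("differential interaction tests are exact on hand fixtures", {
  fr <- GRanges("c", IRanges((0:9) * 10 + 1, (1:10) * 10))
  mk <- function(v) {
    p <- FourCProfile(fr, rep(1, 10), 1, excluded = integer(0))
    p@score <- rep(v, 10)
    p
  }
  regions <- IRanges(3, 7)
  ## identical means: t = 0, p = 1
  same <- differentialInteraction(regions,
    list(mk(1), mk(2), mk(1), mk(2)), c("A", "A", "B", "B"))
  expect_equal(same$t, 0); expect_equal(same$raw_p, 1)
  ## non-degenerate paired fixture equals the closed-form paired t
  prof <- list(mk(1.0), mk(2.1), mk(2.0), mk(3.0))
  got <- differentialInteraction(regions, prof, c("A", "A", "B", "B"),
                                 paired = TRUE)
  ref <- t.test(c(2.0, 3.0), c(1.0, 2.1), paired = TRUE)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$raw_p, ref$p.value)
  ## zero-variance paired differences: Welch fallback with a warning
  expect_warning(
    fb <- differentialInteraction(regions,
      list(mk(1), mk(2), mk(2), mk(3)), c("A", "A", "B", "B"),
      paired = TRUE),
    "zero-variance")
  ref2 <- t.test(c(2, 3), c(1, 2))
  expect_equal(fb$raw_p, ref2$p.value)
  expect_error(differentialInteraction(regions, list(mk(1), mk(2)),
                                       c("A", "B")), ">= 2 samples")
  ## null regions: no BH-significant calls in most seeded runs
  sigCount <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      profs <- lapply(1:4, function(i) mk(0)) |>
        lapply(function(p) { p@score <- rnorm(10); p })
      regs <- IRanges(start = c(1, 4, 7), end = c(3, 6, 10))
      res <- differentialInteraction(regs, profs, c("A", "A", "B", "B"))
      sum(res$adj_p < 0.05)
    })
  }, 0)
  expect_gte(mean(sigCount == 0), 0.9)
})
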