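## Shared fixture builders for the test suite. Everything is generated in
## code at test time; no stored data.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

## random interval set on a small genome
randomIntervals <- function(n, seed, chroms = c("chr1", "chr2"),
                            maxPos = 1e4, maxWidth = 200) {
  withr::with_seed(seed, {
    chr <- sample(chroms, n, replace = TRUE)
    s <- sample.int(maxPos, n, replace = TRUE)
    w <- sample.int(maxWidth, n, replace = TRUE)
    GRanges(chr, IRanges(s, s + w))
  })
}

## quadratic brute-force overlap oracle
bruteForcePairs <- function(a, b, minOverlap = 1L) {
  out <- list()
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (as.character(seqnames(a))[i] != as.character(seqnames(b))[j]) next
    ov <- min(end(a)[i], end(b)[j]) - max(start(a)[i], start(b)[j]) + 1L
    if (ov >= minOverlap)
      out[[length(out) + 1L]] <- c(i, j, ov)
  }
  if (!length(out))
    return(data.frame(aIndex = integer(0), bIndex = integer(0),
                      overlapBp = integer(0)))
  m <- do.call(rbind, out)
  data.frame(aIndex = m[, 1], bIndex = m[, 2], overlapBp = m[, 3])
}

## exact two-sided binomial by enumeration (independent oracle)
enumBinomTwoSided <- function(obs, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[obs + 1]])
}

## brute-force island assembly oracle on a single window-count vector:
## returns list of (from, to, score) for maximal eligible runs bridging
## <= gapWin ineligible windows
bruteIslands <- function(counts, lambda, cstar, gapWin) {
  elig <- which(counts >= cstar)
  if (!length(elig)) return(list())
  groups <- list(elig[1])
  for (i in elig[-1]) {
    last <- groups[[length(groups)]]
    if (i - last[length(last)] <= gapWin + 1L)
      groups[[length(groups)]] <- c(last, i)
    else groups[[length(groups) + 1L]] <- i
  }
  lapply(groups, function(mem) {
    list(from = mem[1], to = mem[length(mem)],
         score = sum(-dpois(counts[mem], lambda, log = TRUE)))
  })
}

## single-chromosome track from a numeric vector of per-bin counts
vecTrack <- function(v, binSize = 200L, chrom = "chrT") {
  sl <- setNames(length(v) * binSize, chrom)
  SignalTrack(setNames(list(as.numeric(v)), chrom), binSize, sl)
}

## synthetic 4C profile over n fragments with power-law decay and an
## optional planted bump (multiplier over fragments bumpAt)
decayProfile <- function(seed, n = 300, bait = 150, bumpAt = NULL,
                         bumpFold = 3, noiseSd = 0.2, alpha = 0.8,
                         integerize = TRUE) {
  withr::with_seed(seed, {
    d <- abs(seq_len(n) - bait); d[bait] <- 1
    mu <- 200 / d^alpha
    if (!is.null(bumpAt)) mu[bumpAt] <- mu[bumpAt] * bumpFold
    cnt <- mu * rlnorm(n, 0, noiseSd)
    if (integerize) cnt <- round(cnt)
    fr <- GRanges("chrL", IRanges((seq_len(n) - 1) * 250 + 1,
                                  seq_len(n) * 250))
    FourCProfile(fr, cnt, bait)
  })
}

## independent string-scan restriction-fragment oracle
scanFragments <- function(seqStr, first = "GATC", second = "GTAC") {
  len <- nchar(seqStr)
  hits <- function(pat) {
    out <- integer(0); from <- 1L
    repeat {
      i <- regexpr(pat, substr(seqStr, from, len), fixed = TRUE)
      if (i < 0) break
      out <- c(out, from + i - 1L); from <- from + i
    }
    out
  }
  s1 <- hits(first)
  bounds <- sort(unique(c(1L, s1, len + 1L)))
  starts <- bounds[-length(bounds)]; ends <- bounds[-1] - 1L
  s2 <- hits(second)
  list(starts = starts, ends = ends,
       nSecond = vapply(starts, function(s) {
         sum(s2 >= s & s2 <= ends[which(starts == s)])
       }, 0L))
}

randomSeq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}

## tiny config for fast simulation tests (named overrides win)
tinyConfig <- function(seed = 1L, ...) {
  args <- list(
    seed = seed,
    genome = c(chr1 = 6e5, chr2 = 6e5),
    nGenes = 40L,
    enhancerPlan = data.frame(class = c("neuronal", "glial", "shared"),
                              n = c(12L, 12L, 6L), width = 2000L))
  over <- list(...)
  args[names(over)] <- over
  do.call(simulationConfig, args)
}
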