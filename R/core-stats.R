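#' Two-sided exact binomial enrichment test
#'
#' Exact two-sided binomial p-value under the minimum-likelihood convention:
#' the p-value is the total probability of all outcomes whose point
#' probability does not exceed that of the observed count. The mode of the
#' distribution therefore always yields p = 1.
#'
#' @param observed observed count, 0 <= observed <= n
#' @param n number of trials
#' @param p0 null proportion, strictly inside (0, 1)
#' @return two-sided p-value in (0, 1]
#' @examples
#' binomialEnrichment(5, 10, 0.5)  # mode -> 1
#' binomialEnrichment(0, 4, 0.5)   # 2/16
#' @export
binomialEnrichment <- function(observed, n, p0) {
  if (length(observed) != 1L || length(n) != 1L || length(p0) != 1L)
    stop("scalar arguments required")
  if (is.na(observed) || is.na(n) || observed < 0 || observed > n)
    stop("observed must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1) stop("p0 must be strictly inside (0, 1)")
  d <- dbinom(0:n, n, p0)
  p <- sum(d[d <= d[observed + 1]])
  min(1, p)
}

#' Multiple-testing correction
#'
#' Benjamini-Hochberg step-up (with monotonicity) or Bonferroni adjustment,
#' optionally against a family size larger than the supplied vector. Output
#' order matches input order.
#'
#' @param p vector of raw p-values in [0, 1]
#' @param method \code{"BH"} or \code{"bonferroni"}
#' @param m family size, defaults to \code{length(p)}
#' @return vector of adjusted p-values, capped at 1
#' @export
adjustPvalues <- function(p, method = c("BH", "bonferroni"), m = length(p)) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m must be >= length(p)")
  p.adjust(p, method = if (method == "BH") "BH" else "bonferroni", n = m)
}

#' Row-wise z-score standardization
#'
#' Centres and scales each row to mean 0 and sample (n-1 denominator)
#' standard deviation 1. Constant rows are mapped to zeros with a warning
#' rather than NaN.
#'
#' @param x numeric matrix (features x samples), at least 2 columns
#' @return matrix of the same dimension
#' @export
zscoreMatrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("at least 2 columns required")
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, sd)
  flat <- !is.na(sdv) & sdv == 0
  if (any(flat)) {
    warning(sum(flat), " constant row(s) mapped to zeros")
    sdv[flat] <- 1
  }
  z <- (x - mu) / sdv
  z[flat, ] <- 0
  z
}

#' Pairs of overlapping intervals
#'
#' Every pair (a_i, b_j) on the same chromosome with overlap length at least
#' \code{minOverlapBp}. Strand is ignored.
#'
#' @param a,b GRanges
#' @param minOverlapBp minimum overlap in bp (>= 1)
#' @return data.frame with columns \code{aIndex}, \code{bIndex},
#'   \code{overlapBp}
#' @export
intersectRegions <- function(a, b, minOverlapBp = 1L) {
  if (minOverlapBp < 1L) stop("minOverlapBp must be >= 1")
  hits <- findOverlaps(a, b, minoverlap = minOverlapBp, ignore.strand = TRUE)
  qi <- queryHits(hits)
  si <- subjectHits(hits)
  ov <- pmin(end(a)[qi], end(b)[si]) - pmax(start(a)[qi], start(b)[si]) + 1L
  data.frame(aIndex = qi, bIndex = si, overlapBp = as.integer(ov))
}

## Run fn with a temporarily fixed RNG state; restores the caller's stream.
withSeed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  fn()
}
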