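#' Read a BED file into GRanges
#'
#' Parses BED3/BED6 records. BED coordinates are 0-based half-open; the
#' returned GRanges uses the Bioconductor 1-based closed convention (the
#' conversion happens here, at the reader boundary). Track, browser and
#' comment lines are skipped. Malformed records (non-integer coordinates,
#' start >= end) raise an error naming the offending line.
#'
#' @param path BED file
#' @param chromNormalize optional chromosome-name normalizer: \code{"none"}
#'   (exact names, default), \code{"add"} (prepend "chr" when absent) or
#'   \code{"strip"} (remove a leading "chr")
#' @return GRanges in file order, with \code{name} and \code{score} metadata
#'   columns when present
#' @export
readBed <- function(path, chromNormalize = c("none", "add", "strip")) {
  chromNormalize <- match.arg(chromNormalize)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(GRanges())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L))
    stop("line ", idx[which(ncols < 3L)[1]], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(s) | is.na(e)
  if (any(bad)) stop("line ", idx[which(bad)[1]], ": non-integer coordinates")
  bad <- s >= e | s < 0
  if (any(bad))
    stop("line ", idx[which(bad)[1]],
         ": invalid interval (requires 0 <= start < end)")
  chrom <- switch(chromNormalize,
    none = chrom,
    add = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom)),
    strip = sub("^chr", "", chrom))
  gr <- GRanges(chrom, IRanges(s + 1L, e))
  if (all(ncols >= 4L)) mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
  if (all(ncols >= 5L))
    mcols(gr)$score <- suppressWarnings(
      as.numeric(vapply(fields, `[[`, "", 5L)))
  if (all(ncols >= 6L)) {
    st <- vapply(fields, `[[`, "", 6L)
    st[!st %in% c("+", "-")] <- "*"
    strand(gr) <- st
  }
  gr
}

fmtNum <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15,
                format(x, scientific = FALSE, trim = TRUE),
                formatC(signif(x, 6), format = "g", digits = 6)))
}

#' Write GRanges as BED
#'
#' Emits BED3 or BED6 (when a \code{name} column is present) with 0-based
#' half-open coordinates, deterministic column order and 6-significant-digit
#' float formatting for scores.
#'
#' @param gr GRanges; optional metadata columns \code{name} and \code{score}
#' @param path output file
#' @return the path, invisibly
#' @export
writeBed <- function(gr, path) {
  n <- length(gr)
  cols <- list(as.character(seqnames(gr)), start(gr) - 1L, end(gr))
  if (!is.null(mcols(gr)$name)) {
    score <- mcols(gr)$score
    if (is.null(score)) score <- rep(0, n)
    cols <- c(cols, list(mcols(gr)$name, fmtNum(score),
                         as.character(strand(gr))))
  }
  out <- do.call(paste, c(cols, sep = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Write a SignalTrack as bedGraph
#'
#' One record per bin, 0-based half-open spans, deterministic formatting.
#'
#' @param track a \linkS4class{SignalTrack}
#' @param path output file
#' @return the path, invisibly
#' @export
writeBedGraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bs <- binSize(track)
  for (chr in names(trackValues(track))) {
    v <- trackValues(track)[[chr]]
    n <- length(v)
    starts <- (seq_len(n) - 1L) * bs
    ends <- pmin(starts + bs, track@seqlengths[[chr]])
    writeLines(paste(chr, starts, ends, fmtNum(v), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph file into a SignalTrack
#'
#' Expects records aligned to a fixed bin grid (constant bin size; the last
#' bin of a chromosome may be short). Missing bins are zero-filled.
#'
#' @param path bedGraph file
#' @param binSize bin width in bp
#' @param seqlengths named chromosome lengths in bp
#' @param normalization normalization state to stamp on the track
#' @return a \linkS4class{SignalTrack}
#' @export
readSignalTrack <- function(path, binSize, seqlengths,
                            normalization = "raw") {
  tb <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "integer", "integer",
                                  "numeric"))
  vals <- lapply(names(seqlengths), function(chr) {
    v <- numeric(ceiling(seqlengths[[chr]] / binSize))
    rows <- tb[tb$chrom == chr, , drop = FALSE]
    if (nrow(rows)) {
      if (any(rows$start %% binSize != 0))
        stop("bedGraph records not aligned to the bin grid on ", chr)
      v[rows$start %/% binSize + 1L] <- rows$value
    }
    v
  })
  names(vals) <- names(seqlengths)
  SignalTrack(vals, binSize, seqlengths, normalization = normalization)
}

#' Write a data.frame as a deterministic TSV
#'
#' Tab-separated, header, no quoting, no row names; numeric columns formatted
#' at 6 significant digits.
#'
#' @param df data.frame
#' @param path output file
#' @return the path, invisibly
#' @export
writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- fmtNum(out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with header into a data.frame
#' @param path input file
#' @return data.frame
#' @export
readTsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
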