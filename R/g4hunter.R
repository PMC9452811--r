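#' Per-base G/C run-length scores
#'
#' The scoring rule behind sliding-window G-quadruplex prediction: every G
#' scores `+min(r, 4)` where `r` is the length of the maximal G-run
#' containing it; every C scores `-min(r, 4)` analogously; A, T and N score
#' 0. N breaks G/C runs. Case-insensitive.
#'
#' @param seq a DNA string (character scalar or `DNAString`), alphabet
#'   `{A,C,G,T,N}`.
#' @return integer vector, one score per base.
#' @export
g4_base_scores <- function(seq) {
  seq <- toupper(as.character(seq))
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(b) == 0L) return(integer(0))
  bad <- !(b %in% c("A", "C", "G", "T", "N"))
  if (any(bad))
    stop("non-DNA character(s) in sequence: ",
         paste(unique(b[bad]), collapse = ", "))
  r <- rle(b)
  sc <- integer(length(r$values))
  isg <- r$values == "G"; isc <- r$values == "C"
  sc[isg] <- pmin(r$lengths[isg], 4L)
  sc[isc] <- -pmin(r$lengths[isc], 4L)
  rep.int(sc, r$lengths)
}

#' Predict G-quadruplex sites on one chromosome
#'
#' Slides a window of `window` bp over the sequence; windows whose mean
#' base score (see [g4_base_scores()]) has absolute value `>= threshold`
#' qualify. Overlapping or bookended qualifying windows of the same sign
#' merge into one prediction spanning the merged windows; the score is the
#' mean base score recomputed over the merged interval. Positive scores
#' are called on `+`, negative on `-`.
#'
#' @param seq chromosome sequence (character or `DNAString`).
#' @param chrom chromosome name for the output ranges.
#' @param window odd window width in bp, `>= 5` (default 25).
#' @param threshold positive score threshold (default 1.5). The threshold
#'   is a required parameter of every genome-scale run; no attempt is made
#'   to hard-code a published site count.
#' @param trim if `TRUE`, trim each merged prediction to the outermost
#'   G (for `+`) or C (for `-`) it contains. Off by default: the merged
#'   window span itself is reported.
#' @return `GRanges` with `mcols` `mean_score` and `sequence` (the
#'   plus-strand genomic subsequence).
#' @export
g4_predict <- function(seq, chrom, window = 25L, threshold = 1.5,
                       trim = FALSE) {
  window <- as.integer(window)
  if (window < 5L || window %% 2L == 0L)
    stop("window must be an odd integer >= 5")
  if (threshold <= 0) stop("threshold must be positive")
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  empty <- GenomicRanges::GRanges(
    seqnames = character(0), ranges = IRanges::IRanges(),
    strand = character(0),
    mean_score = numeric(0), sequence = character(0))
  if (n < window) {
    warning("sequence shorter than window (", n, " < ", window,
            "); no predictions")
    return(empty)
  }
  sc <- g4_base_scores(seq)
  cs <- c(0, cumsum(sc))
  starts <- seq_len(n - window + 1L)             # 1-based window starts
  wmean <- (cs[starts + window] - cs[starts]) / window
  out <- list()
  for (sgn in c(1, -1)) {
    qual <- starts[sgn * wmean >= threshold]
    if (length(qual) == 0L) next
    # windows [i, i+w) and [j, j+w), j > i, overlap or bookend iff j <= i+w
    brk <- which(diff(qual) > window)
    grp <- rep.int(seq_len(length(brk) + 1L),
                   diff(c(0L, brk, length(qual))))
    first <- tapply(qual, grp, min)
    last <- tapply(qual, grp, max)
    s1 <- as.integer(first)                      # 1-based start
    e1 <- as.integer(last) + window - 1L         # 1-based inclusive end
    if (trim) {
      anchor <- if (sgn > 0) "G" else "C"
      for (k in seq_along(s1)) {
        bb <- strsplit(substr(seq, s1[k], e1[k]), "", fixed = TRUE)[[1]]
        hit <- which(bb == anchor)
        if (length(hit)) {
          e1[k] <- s1[k] + max(hit) - 1L
          s1[k] <- s1[k] + min(hit) - 1L
        }
      }
    }
    ms <- (cs[e1 + 1L] - cs[s1]) / (e1 - s1 + 1L)
    out[[length(out) + 1L]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(s1, e1),
      strand = if (sgn > 0) "+" else "-",
      mean_score = ms,
      sequence = substring(seq, s1, e1))
  }
  if (length(out) == 0L) return(empty)
  BiocGenerics::sort(do.call(c, out), ignore.strand = TRUE)
}

#' Predict G-quadruplex sites over a multi-chromosome genome
#'
#' Applies [g4_predict()] per chromosome and concatenates results.
#'
#' @param genome a named `DNAStringSet` (or named character vector).
#' @inheritParams g4_predict
#' @return `GRanges` with `mean_score` and `sequence` columns and
#'   `seqlengths` set from the genome.
#' @export
g4_predict_genome <- function(genome, window = 25L, threshold = 1.5,
                              trim = FALSE) {
  if (is.null(names(genome)) || any(names(genome) == ""))
    stop("genome sequences must be named by chromosome")
  res <- lapply(names(genome), function(chr)
    g4_predict(genome[[chr]], chr, window = window, threshold = threshold,
               trim = trim))
  gr <- suppressWarnings(do.call(c, res))
  sl <- vapply(genome, function(s) nchar(as.character(s)), numeric(1))
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  GenomeInfoDb::seqlengths(gr) <- sl
  gr
}
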