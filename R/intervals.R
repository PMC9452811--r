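#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom BiocGenerics start end width strand strand<- sort
#' @importFrom methods is as
NULL

#' Build a GRanges from BED-convention coordinates
#'
#' All public coordinates in this package follow the BED convention:
#' 0-based, half-open `[start, end)`. Internally intervals are held as
#' `GRanges` (1-based, closed); this constructor performs the shift.
#'
#' @param chrom character vector of chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end exclusive end positions; must satisfy `start < end`.
#' @param strand one of `"+"`, `"-"`, `"*"` (recycled). `"."` in BED maps
#'   to `"*"`.
#' @param score optional numeric score, stored in `mcols()$score`.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return A `GRanges`.
#' @export
interval_set <- function(chrom, start, end, strand = "*", score = NULL,
                         seqlengths = NULL) {
  if (length(chrom) == 0L) {
    gr <- GenomicRanges::GRanges(seqlengths = seqlengths)
    return(gr)
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be numeric")
  if (any(start < 0)) stop("malformed interval: negative start")
  if (any(start >= end)) stop("malformed interval: start >= end")
  strand <- ifelse(strand == ".", "*", strand)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1, end),
                               strand = strand,
                               seqlengths = seqlengths)
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- score
  gr
}

#' Merge an interval set into disjoint sorted intervals
#'
#' Overlapping and bookended intervals (`[0,10)` then `[10,20)`) merge;
#' strand is ignored, matching the unstranded nature of peak and track
#' inputs. The result covers exactly the same bases as the input.
#'
#' @param x A `GRanges`.
#' @return A sorted, disjoint, unstranded `GRanges`.
#' @export
merge_intervals <- function(x) {
  stopifnot(is(x, "GRanges"))
  GenomicRanges::reduce(x, ignore.strand = TRUE)
}

#' Total merged length of an interval set in bp
#'
#' @param x A `GRanges`.
#' @return Number of distinct bases covered.
#' @export
merged_length <- function(x) {
  sum(as.numeric(BiocGenerics::width(merge_intervals(x))))
}

#' Intersection size of two interval sets in bp
#'
#' Strand-blind; symmetric in its arguments.
#'
#' @param a,b `GRanges` objects.
#' @return `|bases(a) n bases(b)|` as a numeric count.
#' @export
intersect_bp <- function(a, b) {
  ia <- merge_intervals(a); ib <- merge_intervals(b)
  ov <- GenomicRanges::intersect(ia, ib, ignore.strand = TRUE)
  sum(as.numeric(BiocGenerics::width(ov)))
}

#' Jaccard index of two interval sets
#'
#' Intersection bp over union bp of the merged sets, the statistic used to
#' score transcription-factor / G4 co-localization. Returns 0 when the
#' union is empty.
#'
#' @param a,b `GRanges` objects.
#' @return A number in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  inter <- intersect_bp(a, b)
  uni <- merged_length(a) + merged_length(b) - inter
  if (uni == 0) return(0)
  inter / uni
}

#' Read a BED3/BED6 file
#'
#' Tab-separated, no header; `track`/`browser` lines are skipped. Returns
#' `GRanges` (0-based BED starts become 1-based `GRanges` starts).
#'
#' @param path path to the BED file.
#' @param seqlengths optional named chromosome lengths.
#' @return A `GRanges` with `name`/`score` columns when present.
#' @export
read_bed <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

#' Write a GRanges as BED
#'
#' Emits BED6 when strand or score is informative, BED3 otherwise.
#' Coordinates are converted back to the 0-based half-open convention.
#'
#' @param x A `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  rtracklayer::export(x, path, format = "bed")
  invisible(path)
}

#' Convert a GRanges to a BED-convention data frame
#'
#' @param x A `GRanges`.
#' @return data.frame with `chrom`, `start` (0-based), `end`, `strand`.
#' @export
as_bed_df <- function(x) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(x)),
                   start = BiocGenerics::start(x) - 1L,
                   end = BiocGenerics::end(x),
                   strand = as.character(BiocGenerics::strand(x)),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(x)
  if (ncol(mc) > 0) df <- cbind(df, as.data.frame(mc))
  df
}
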