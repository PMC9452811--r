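#' Read a simple gene table
#'
#' Tab-separated with a header row and columns `gene_id`, `chrom`,
#' `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end` (coordinates
#' 0-based half-open), plus optional `exon_starts` / `exon_ends`
#' (comma-separated, 0-based half-open). One canonical transcript per
#' gene; when exon columns are absent the transcript is treated as a
#' single exon.
#'
#' @param path path to the TSV file.
#' @return data.frame of gene models.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  validate_genes(df)
  df
}

#' Read gene models from BED12
#'
#' `thickStart`/`thickEnd` are taken as the CDS; blocks as exons.
#'
#' @param path path to the BED12 file.
#' @return data.frame in the [read_gene_table()] layout.
#' @export
read_genes_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- S4Vectors::mcols(gr)$blocks
  exon_starts <- exon_ends <- character(length(gr))
  for (i in seq_along(gr)) {
    if (!is.null(blocks) && length(blocks[[i]])) {
      abs_s <- BiocGenerics::start(gr)[i] - 1L + BiocGenerics::start(blocks[[i]]) - 1L
      abs_e <- abs_s + BiocGenerics::width(blocks[[i]])
      exon_starts[i] <- paste(abs_s, collapse = ",")
      exon_ends[i] <- paste(abs_e, collapse = ",")
    } else {
      exon_starts[i] <- as.character(BiocGenerics::start(gr)[i] - 1L)
      exon_ends[i] <- as.character(BiocGenerics::end(gr)[i])
    }
  }
  thick <- S4Vectors::mcols(gr)$thick
  df <- data.frame(
    gene_id = if (!is.null(S4Vectors::mcols(gr)$name))
      S4Vectors::mcols(gr)$name else paste0("gene", seq_along(gr)),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    tx_start = BiocGenerics::start(gr) - 1L,
    tx_end = BiocGenerics::end(gr),
    cds_start = BiocGenerics::start(thick) - 1L,
    cds_end = BiocGenerics::end(thick),
    exon_starts = exon_starts, exon_ends = exon_ends,
    stringsAsFactors = FALSE)
  validate_genes(df)
  df
}

validate_genes <- function(genes) {
  if (any(genes$tx_start >= genes$tx_end))
    stop("gene model with tx_start >= tx_end")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id in gene table")
  invisible(genes)
}

# exon blocks of one gene as 0-based half-open matrix (start, end)
gene_exons <- function(gene) {
  if (!is.null(gene$exon_starts) && !is.na(gene$exon_starts) &&
      nzchar(gene$exon_starts)) {
    s <- as.numeric(strsplit(as.character(gene$exon_starts), ",")[[1]])
    e <- as.numeric(strsplit(as.character(gene$exon_ends), ",")[[1]])
  } else {
    s <- gene$tx_start; e <- gene$tx_end
  }
  cbind(start = s, end = e)
}

#' Strand-aware gene windows
#'
#' `upstream`: `width` bp 5' of the TSS (for a `+` gene
#' `[tx_start - width, tx_start)`, mirrored for `-`), clipped at
#' chromosome bounds. `body`: the transcript span. `downstream`: `width`
#' bp past the 3' end.
#'
#' @param genes gene table (see [read_gene_table()]).
#' @param region one of `"upstream"`, `"body"`, `"downstream"`.
#' @param width window width for upstream (default 10000) or downstream
#'   (default 2000); ignored for `body`.
#' @param chrom_lengths named vector of chromosome lengths used for
#'   clipping.
#' @return `GRanges` named by `gene_id`, in gene order.
#' @export
gene_windows <- function(genes, region = c("upstream", "body", "downstream"),
                         width = NULL, chrom_lengths = NULL) {
  region <- match.arg(region)
  if (is.null(width))
    width <- switch(region, upstream = 10000, downstream = 2000, body = NA)
  plus <- genes$strand == "+"
  s <- numeric(nrow(genes)); e <- numeric(nrow(genes))
  if (region == "upstream") {
    s[plus] <- genes$tx_start[plus] - width; e[plus] <- genes$tx_start[plus]
    s[!plus] <- genes$tx_end[!plus]; e[!plus] <- genes$tx_end[!plus] + width
  } else if (region == "body") {
    s <- genes$tx_start; e <- genes$tx_end
  } else {
    s[plus] <- genes$tx_end[plus]; e[plus] <- genes$tx_end[plus] + width
    s[!plus] <- genes$tx_start[!plus] - width; e[!plus] <- genes$tx_start[!plus]
  }
  s <- pmax(s, 0)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[genes$chrom]
    if (any(is.na(lim))) stop("chrom_lengths missing for some gene chromosomes")
    e <- pmin(e, lim)
  }
  keep <- s < e
  gr <- interval_set(genes$chrom[keep], s[keep], e[keep],
                     strand = genes$strand[keep])
  names(gr) <- genes$gene_id[keep]
  gr
}
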