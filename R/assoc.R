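G4_LABELS <- c("G4-II", "G4-I", "G4-III", "noG4")

#' Label genes by the G4 evidence tier of a gene-anchored window
#'
#' Hierarchy (most to least evidence): a gene is `G4-II` if at least one
#' G4-II site overlaps the window; otherwise `G4-I` if at least one G4-I
#' peak does; otherwise `G4-III` if at least one predicted-only site
#' does; otherwise `noG4`. Windows: `upstream` = 10 kb 5' of the TSS,
#' `body` = transcript span, `downstream` = 2 kb past the 3' end; all
#' overlaps strand-blind with a 1 bp minimum.
#'
#' @param genes gene table.
#' @param groups an `EvidenceGroups` object.
#' @param region one of `"upstream"`, `"body"`, `"downstream"`.
#' @param chrom_lengths optional chromosome lengths for window clipping.
#' @param upstream,downstream window widths in bp.
#' @return data.frame with `gene_id`, `region`, `label`.
#' @export
label_genes <- function(genes, groups,
                        region = c("upstream", "body", "downstream"),
                        chrom_lengths = NULL, upstream = 10000,
                        downstream = 2000) {
  region <- match.arg(region)
  stopifnot(inherits(groups, "EvidenceGroups"))
  w <- switch(region, upstream = upstream, downstream = downstream, NULL)
  win <- gene_windows(genes, region, w, chrom_lengths)
  win <- win[genes$gene_id]                     # keep gene order
  has <- function(gr) GenomicRanges::countOverlaps(win, gr,
                                                   ignore.strand = TRUE) > 0
  h2 <- has(groups$g4_II); h1 <- has(groups$g4_I); h3 <- has(groups$g4_III)
  label <- ifelse(h2, "G4-II", ifelse(h1, "G4-I",
           ifelse(h3, "G4-III", "noG4")))
  data.frame(gene_id = genes$gene_id, region = region, label = label,
             stringsAsFactors = FALSE)
}

#' Flag genes with a confirmed G4 on the antisense strand of the body
#'
#' `TRUE` iff at least one G4-II site lies within the transcript span
#' `[tx_start, tx_end)` with strand opposite to the gene's strand. The
#' antisense strand is the transcription template, where a G4 can stall
#' the polymerase.
#'
#' @param genes gene table.
#' @param g4_II stranded `GRanges` of confirmed-and-predicted G4 sites.
#' @return logical vector, one per gene.
#' @export
antisense_flag <- function(genes, g4_II) {
  stopifnot(is(g4_II, "GRanges"))
  if (length(g4_II) && any(as.character(BiocGenerics::strand(g4_II)) == "*"))
    stop("antisense logic requires stranded G4-II entries")
  body <- gene_windows(genes, "body")
  ov <- GenomicRanges::findOverlaps(body, g4_II, ignore.strand = TRUE,
                                    type = "any")
  flag <- logical(nrow(genes))
  if (length(ov)) {
    gs <- as.character(BiocGenerics::strand(body))[S4Vectors::queryHits(ov)]
    ps <- as.character(BiocGenerics::strand(g4_II))[S4Vectors::subjectHits(ov)]
    anti <- gs != ps
    flag[unique(S4Vectors::queryHits(ov)[anti])] <- TRUE
  }
  flag
}

#' Compare expression between two gene sets
#'
#' Welch two-sample t-test on `log2(RPKM + 1)`; the median fold change is
#' reported on the raw RPKM scale (`median(A) / median(B)`), matching how
#' fold differences are usually quoted.
#'
#' @param ids_a,ids_b character vectors of gene ids (each side needs at
#'   least 2 genes present in `expr`).
#' @param expr data.frame with `gene_id` and `rpkm`.
#' @param name_a,name_b labels used in error messages and output.
#' @return list with `t`, `df`, `p`, `median_fold`, `n_a`, `n_b`.
#' @export
compare_expression <- function(ids_a, ids_b, expr,
                               name_a = "A", name_b = "B") {
  stopifnot(all(c("gene_id", "rpkm") %in% names(expr)))
  if (any(expr$rpkm < 0)) stop("rpkm must be non-negative")
  a <- expr$rpkm[expr$gene_id %in% ids_a]
  b <- expr$rpkm[expr$gene_id %in% ids_b]
  if (length(a) < 2) stop("group '", name_a, "' has fewer than 2 genes")
  if (length(b) < 2) stop("group '", name_b, "' has fewer than 2 genes")
  la <- log2(a + 1); lb <- log2(b + 1)
  if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
    # degenerate: both sides constant; equal means are indistinguishable
    tt <- list(statistic = if (mean(la) == mean(lb)) 0 else Inf,
               parameter = NA_real_,
               p.value = if (mean(la) == mean(lb)) 1 else 0)
  } else {
    tt <- stats::t.test(la, lb)
  }
  mf <- if (stats::median(b) > 0) stats::median(a) / stats::median(b)
        else NA_real_
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, median_fold = mf,
       n_a = length(a), n_b = length(b))
}

#' Upper-tail hypergeometric enrichment test
#'
#' Probability of observing at least `k` marked elements in a sample of
#' size `n` drawn without replacement from a population of `N` elements
#' of which `K` are marked: `p = P(X >= k)` by exact summation of the
#' hypergeometric mass.
#'
#' @param k observed marked elements in the sample.
#' @param n sample size.
#' @param K marked elements in the population.
#' @param N population size.
#' @return list of class `EnrichmentResult` with fields `k`, `n`, `K`,
#'   `N`, `p`.
#' @export
hypergeom_enrichment <- function(k, n, K, N) {
  if (k > n || n > N || K > N || k < 0 || K < 0)
    stop("inconsistent counts: need 0 <= k <= n <= N and 0 <= K <= N")
  if (k > K) stop("inconsistent counts: k exceeds K")
  hi <- min(n, K)
  p <- if (k == 0) 1.0 else sum(stats::dhyper(k:hi, K, N - K, n))
  p <- min(p, 1.0)
  structure(list(k = k, n = n, K = K, N = N, p = p),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("Hypergeometric enrichment: k=%d of n=%d (K=%d of N=%d), p = %.3g\n",
              x$k, x$n, x$K, x$N, x$p))
  invisible(x)
}
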