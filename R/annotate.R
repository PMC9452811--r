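FEATURE_CLASSES <- c("upstream10kb", "utr5", "utr3", "exon", "intron",
                     "downstream2kb", "intergenic")

#' Partition the genome into gene-anchored feature classes
#'
#' Builds the seven-class genomic feature map used for G4 distribution and
#' density: 10 kb upstream of the TSS (strand-aware, clipped at chromosome
#' bounds), 5'UTR, 3'UTR, (coding) exon, intron, 2 kb downstream of the
#' transcript end, and intergenic. Bases claimed by several classes are
#' resolved once by fixed precedence
#' `upstream10kb > utr5 > utr3 > exon > intron > downstream2kb >
#' intergenic`, so the classes tile every chromosome exactly.
#'
#' UTRs are the exonic bases outside the CDS on the appropriate side; a
#' gene with `cds_start == cds_end` (non-coding) contributes its exonic
#' bases to `exon` and none to the UTR classes.
#'
#' @param genes gene table (see [read_gene_table()]).
#' @param chrom_lengths named vector covering all gene chromosomes.
#' @param upstream,downstream window widths in bp.
#' @return Object of class `FeatureMap`: list with `classes` (named list
#'   of disjoint `GRanges`) and `lengths` (named bp totals `L_k`).
#' @export
build_feature_map <- function(genes, chrom_lengths, upstream = 10000,
                              downstream = 2000) {
  validate_genes(genes)
  if (!all(genes$chrom %in% names(chrom_lengths)))
    stop("chrom_lengths missing for some gene chromosomes")
  if (any(genes$tx_end > chrom_lengths[genes$chrom]))
    stop("gene beyond chromosome bounds")
  genome <- interval_set(names(chrom_lengths),
                         rep(0, length(chrom_lengths)),
                         unname(chrom_lengths),
                         seqlengths = chrom_lengths)

  up <- gene_windows(genes, "upstream", upstream, chrom_lengths)
  down <- gene_windows(genes, "downstream", downstream, chrom_lengths)
  # per-gene interval arithmetic in plain vectors; GRanges built per class
  acc <- list(utr5 = list(), utr3 = list(), exon = list(), intron = list())
  clip <- function(ex, lo, hi) {      # exon blocks restricted to [lo, hi)
    s <- pmax(ex[, 1], lo); e <- pmin(ex[, 2], hi)
    keep <- s < e
    if (!any(keep)) NULL else cbind(s[keep], e[keep])
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- gene_exons(g)
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    if (nrow(ex) > 1) {
      gs <- ex[-nrow(ex), 2]; ge <- ex[-1, 1]
      keep <- gs < ge
      if (any(keep))
        acc$intron[[length(acc$intron) + 1L]] <-
          cbind(g$chrom, gs[keep], ge[keep])
    }
    if (g$cds_start < g$cds_end) {
      lo5 <- if (g$strand == "+") c(g$tx_start, g$cds_start)
             else c(g$cds_end, g$tx_end)
      lo3 <- if (g$strand == "+") c(g$cds_end, g$tx_end)
             else c(g$tx_start, g$cds_start)
      u5 <- clip(ex, lo5[1], lo5[2]); u3 <- clip(ex, lo3[1], lo3[2])
      cd <- clip(ex, g$cds_start, g$cds_end)
      if (!is.null(u5))
        acc$utr5[[length(acc$utr5) + 1L]] <- cbind(g$chrom, u5)
      if (!is.null(u3))
        acc$utr3[[length(acc$utr3) + 1L]] <- cbind(g$chrom, u3)
      if (!is.null(cd))
        acc$exon[[length(acc$exon) + 1L]] <- cbind(g$chrom, cd)
    } else {
      acc$exon[[length(acc$exon) + 1L]] <- cbind(g$chrom, ex)
    }
  }
  cat_gr <- function(lst) {
    if (length(lst) == 0L) return(GenomicRanges::GRanges())
    m <- do.call(rbind, lst)
    merge_intervals(interval_set(m[, 1], as.numeric(m[, 2]),
                                 as.numeric(m[, 3])))
  }
  raw <- list(upstream10kb = merge_intervals(up),
              utr5 = cat_gr(acc$utr5), utr3 = cat_gr(acc$utr3),
              exon = cat_gr(acc$exon), intron = cat_gr(acc$intron),
              downstream2kb = merge_intervals(down))
  classes <- list(); claimed <- GenomicRanges::GRanges()
  for (k in names(raw)) {
    cls <- GenomicRanges::setdiff(raw[[k]], claimed, ignore.strand = TRUE)
    classes[[k]] <- cls
    claimed <- merge_intervals(c(claimed, cls))
  }
  classes$intergenic <- GenomicRanges::setdiff(genome, claimed,
                                               ignore.strand = TRUE)
  lens <- vapply(classes, merged_length, numeric(1))
  structure(list(classes = classes, lengths = lens,
                 chrom_lengths = chrom_lengths),
            class = "FeatureMap")
}

#' @export
print.FeatureMap <- function(x, ...) {
  cat("FeatureMap (", sum(x$lengths), "bp in",
      length(x$chrom_lengths), "chromosome(s) )\n")
  print(x$lengths)
  invisible(x)
}

#' Assign each interval to one feature class by its midpoint
#'
#' The class containing the interval midpoint (`floor((start + end) / 2)`
#' in 0-based coordinates) labels the interval, so intervals spanning
#' class boundaries get exactly one label and class fractions over any set
#' sum to 1.
#'
#' @param x `GRanges` of G4 sites (or any intervals).
#' @param fmap a `FeatureMap`.
#' @return character vector of class labels, one per interval.
#' @export
assign_region <- function(x, fmap) {
  stopifnot(inherits(fmap, "FeatureMap"))
  if (length(x) == 0L) return(character(0))
  mid0 <- floor((BiocGenerics::start(x) - 1 + BiocGenerics::end(x)) / 2)
  pts <- interval_set(as.character(GenomeInfoDb::seqnames(x)), mid0, mid0 + 1)
  lab <- rep(NA_character_, length(x))
  for (k in names(fmap$classes)) {
    hit <- GenomicRanges::countOverlaps(pts, fmap$classes[[k]],
                                        ignore.strand = TRUE) > 0
    lab[is.na(lab) & hit] <- k
  }
  if (anyNA(lab)) stop("interval midpoint outside the feature map genome")
  lab
}

#' G4 density (BPKB) per evidence group and feature class
#'
#' Density of group g in class k is `D_k = 1000 * sum(W_i) / L_k` where
#' `W_i` is the bp overlap of the i-th G4 with class k (a G4 spanning a
#' boundary contributes its overlap to each class) and `L_k` the merged
#' class length. Units: bp of G4 per kb of class ("BPKB"). A class of zero
#' length yields `NA` (undefined), not zero.
#'
#' @param groups an `EvidenceGroups` object.
#' @param fmap a `FeatureMap`.
#' @return data.frame with `group`, `class`, `overlap_bp` (`sum W_i`),
#'   `class_bp` (`L_k`) and `density_bpkb`.
#' @export
density_table <- function(groups, fmap) {
  stopifnot(inherits(groups, "EvidenceGroups"), inherits(fmap, "FeatureMap"))
  grs <- list(`G4-I` = groups$g4_I, `G4-II` = groups$g4_II,
              `G4-III` = groups$g4_III)
  res <- expand.grid(group = names(grs), class = names(fmap$classes),
                     stringsAsFactors = FALSE)
  res$overlap_bp <- mapply(function(g, k)
    intersect_bp(grs[[g]], fmap$classes[[k]]), res$group, res$class)
  res$class_bp <- fmap$lengths[res$class]
  res$density_bpkb <- ifelse(res$class_bp > 0,
                             1000 * res$overlap_bp / res$class_bp, NA_real_)
  rownames(res) <- NULL
  res
}

#' Histogram of G4 midpoint distances to the nearest TSS
#'
#' Signed distance in gene orientation: negative means upstream of the
#' TSS. For a `+` gene the TSS is `tx_start`; for a `-` gene it is the
#' base at `tx_end - 1` and the sign flips. Each G4 midpoint is assigned
#' to its nearest TSS over all genes; midpoints outside `window` are
#' dropped, so the histogram total is the number of G4s within the
#' window.
#'
#' @param groups an `EvidenceGroups` object.
#' @param genes gene table.
#' @param window length-2 vector `c(from, to)` of signed distances
#'   (default `c(-10000, 500)`).
#' @param bin_size bin width in bp; must divide the window span evenly.
#' @return data.frame with `bin_start`, `bin_end` (signed distances,
#'   half-open bins) and one count column per group.
#' @export
tss_profile <- function(groups, genes, window = c(-10000, 500),
                        bin_size = 500) {
  stopifnot(inherits(groups, "EvidenceGroups"))
  span <- window[2] - window[1]
  if (span <= 0 || span %% bin_size != 0)
    stop("bin_size must divide the window span evenly")
  breaks <- seq(window[1], window[2], by = bin_size)
  tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1)
  dist_one <- function(gr) {
    if (length(gr) == 0L) return(numeric(0))
    mid <- floor((BiocGenerics::start(gr) - 1 + BiocGenerics::end(gr)) / 2)
    chr <- as.character(GenomeInfoDb::seqnames(gr))
    vapply(seq_along(gr), function(i) {
      j <- which(genes$chrom == chr[i])
      if (length(j) == 0L) return(NA_real_)
      d <- ifelse(genes$strand[j] == "+", mid[i] - tss[j], tss[j] - mid[i])
      d[which.min(abs(d))]
    }, numeric(1))
  }
  grs <- list(`G4-I` = groups$g4_I, `G4-II` = groups$g4_II,
              `G4-III` = groups$g4_III)
  out <- data.frame(bin_start = breaks[-length(breaks)],
                    bin_end = breaks[-1])
  for (g in names(grs)) {
    d <- dist_one(grs[[g]])
    d <- d[!is.na(d) & d >= window[1] & d < window[2]]
    out[[g]] <- as.vector(table(cut(d, breaks = breaks, right = FALSE)))
  }
  out
}
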