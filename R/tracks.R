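#' Fraction of group members overlapping a track
#'
#' The per-site overlap ratio: fraction of G4s in the group with at least
#' 1 bp overlap with the track (CpG islands, enhancers, super-enhancers,
#' open chromatin, ...). Strand-blind.
#'
#' @param group `GRanges` of G4 sites (must be non-empty).
#' @param track `GRanges` of a genomic track.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_ratio <- function(group, track) {
  if (length(group) == 0L) stop("empty G4 group")
  mean(GenomicRanges::countOverlaps(group, track, ignore.strand = TRUE) > 0)
}

#' Jaccard matrix between TF peak sets and G4 evidence groups
#'
#' One [jaccard_index()] per (TF, group) pair, plus a flag for scores
#' above `threshold` (default 0.1, the cut used to shortlist co-localized
#' factors).
#'
#' @param groups an `EvidenceGroups` object.
#' @param tf_sets named list of `GRanges`, one per transcription factor.
#' @param threshold flag cells with Jaccard score strictly above this.
#' @return data.frame with `tf`, `g4_I`, `g4_II`, `g4_III` and
#'   `above_threshold` (any group above the cut).
#' @export
tf_jaccard_matrix <- function(groups, tf_sets, threshold = 0.1) {
  stopifnot(inherits(groups, "EvidenceGroups"), length(tf_sets) > 0,
            !is.null(names(tf_sets)))
  res <- data.frame(tf = names(tf_sets), stringsAsFactors = FALSE)
  res$g4_I <- vapply(tf_sets, jaccard_index, numeric(1), b = groups$g4_I)
  res$g4_II <- vapply(tf_sets, jaccard_index, numeric(1), b = groups$g4_II)
  res$g4_III <- vapply(tf_sets, jaccard_index, numeric(1), b = groups$g4_III)
  res$above_threshold <- res$g4_I > threshold | res$g4_II > threshold |
    res$g4_III > threshold
  rownames(res) <- NULL
  res
}

#' Read a bedMethyl-like methylation table
#'
#' Tab-separated with header: `chrom`, `start` (0-based CpG position),
#' `end`, `coverage`, `beta`; an optional `context` column restricts rows
#' to CpG (`"CpG"`/`"CG"`) — CHG/CHH rows are dropped. With
#' `percent = TRUE` the last column is a methylation percentage and is
#' divided by 100.
#'
#' @param path path to the TSV.
#' @param percent is the methylation column a percentage?
#' @return data.frame with `chrom`, `start`, `end`, `coverage`, `beta`.
#' @export
read_methyl <- function(path, percent = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "coverage", "beta")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("methylation table missing column(s): ",
                         paste(miss, collapse = ", "))
  if ("context" %in% names(df))
    df <- df[df$context %in% c("CpG", "CG"), , drop = FALSE]
  if (percent) df$beta <- df$beta / 100
  if (any(df$beta < 0 | df$beta > 1)) stop("beta values outside [0, 1]")
  if (any(df$coverage < 0)) stop("negative coverage")
  df[need]
}

#' Filter CpG records by bisulfite read coverage
#'
#' Retains records with `coverage >= min_cov` (boundary inclusive).
#'
#' @param records methylation data.frame (see [read_methyl()]).
#' @param min_cov minimum read count, default 10.
#' @return The filtered data.frame.
#' @export
filter_methyl <- function(records, min_cov = 10) {
  records[records$coverage >= min_cov, , drop = FALSE]
}

#' Methylation state of beta values
#'
#' Hypomethylated iff `beta <= 0.1`, hypermethylated iff `beta >= 0.9`
#' (both boundaries inclusive), otherwise intermediate.
#'
#' @param beta numeric vector in `[0, 1]`.
#' @return character vector of `"hypo"`, `"intermediate"`, `"hyper"`.
#' @export
methyl_state <- function(beta) {
  if (any(beta < 0 | beta > 1)) stop("beta outside [0, 1]")
  ifelse(beta <= 0.1, "hypo", ifelse(beta >= 0.9, "hyper", "intermediate"))
}

#' Methylation state summary per G4 evidence group
#'
#' Each CpG is assigned to every group whose merged intervals cover its
#' position (tiers can overlap since G4-I is peak-shaped); with
#' `unique_assignment = TRUE` a multiply-covered CpG counts only in the
#' highest-priority group (II > I > III). Per group: CpG count, state
#' fractions (hypo / intermediate / hyper, summing to 1) and CpG density
#' per kb of merged group length.
#'
#' @param records filtered methylation data.frame.
#' @param groups an `EvidenceGroups` object.
#' @param unique_assignment count multiply-covered CpGs once?
#' @return data.frame, one row per group: `group`, `n_cpg`,
#'   `frac_hypo`, `frac_intermediate`, `frac_hyper`, `cpg_density`.
#' @export
methyl_by_group <- function(records, groups, unique_assignment = FALSE) {
  stopifnot(inherits(groups, "EvidenceGroups"))
  pts <- interval_set(records$chrom, records$start, records$start + 1)
  st <- methyl_state(records$beta)
  grs <- list(`G4-II` = groups$g4_II, `G4-I` = groups$g4_I,
              `G4-III` = groups$g4_III)
  inside <- lapply(grs, function(g)
    GenomicRanges::countOverlaps(pts, merge_intervals(g)) > 0)
  if (unique_assignment) {
    inside$`G4-I` <- inside$`G4-I` & !inside$`G4-II`
    inside$`G4-III` <- inside$`G4-III` & !inside$`G4-II` & !inside$`G4-I`
  }
  one <- function(name) {
    sel <- st[inside[[name]]]
    n <- length(sel)
    ml <- merged_length(grs[[name]])
    data.frame(group = name, n_cpg = n,
               frac_hypo = if (n) mean(sel == "hypo") else NA_real_,
               frac_intermediate = if (n) mean(sel == "intermediate") else NA_real_,
               frac_hyper = if (n) mean(sel == "hyper") else NA_real_,
               cpg_density = if (ml > 0) 1000 * n / ml else NA_real_)
  }
  out <- do.call(rbind, lapply(c("G4-I", "G4-II", "G4-III"), one))
  rownames(out) <- NULL
  out
}

#' Methylation state profile near chromosome ends
#'
#' Distance of a CpG from the nearer chromosome end is
#' `min(pos, chrom_length - pos)`. CpGs within `max_dist` (inclusive) are
#' binned in half-open `bin`-bp bins, the final bin closed so a CpG at
#' exactly `max_dist` is kept. Hypo/hyper fractions are reported for
#' (a) all CpGs and (b) CpGs covered by any G4 interval.
#'
#' @param records filtered methylation data.frame.
#' @param groups an `EvidenceGroups` object.
#' @param chrom_lengths named chromosome lengths.
#' @param max_dist maximum distance from a chromosome end (default 60 kb).
#' @param bin bin width (default 10 kb).
#' @return data.frame per bin: `bin_start`, `bin_end`, `n_all`,
#'   `frac_hypo_all`, `frac_hyper_all`, `n_g4`, `frac_hypo_g4`,
#'   `frac_hyper_g4`.
#' @export
telomere_profile <- function(records, groups, chrom_lengths,
                             max_dist = 60000, bin = 10000) {
  stopifnot(inherits(groups, "EvidenceGroups"))
  if (!all(records$chrom %in% names(chrom_lengths)))
    stop("chrom_lengths missing for some record chromosomes")
  len <- chrom_lengths[records$chrom]
  d <- pmin(records$start, len - records$start)
  keep <- d <= max_dist
  rec <- records[keep, , drop = FALSE]; d <- d[keep]
  idx <- pmin(d %/% bin, max_dist %/% bin - 1) + 1   # final bin closed
  st <- methyl_state(rec$beta)
  allg4 <- merge_intervals(c(merge_intervals(groups$g4_I),
                             merge_intervals(groups$g4_II),
                             merge_intervals(groups$g4_III)))
  pts <- interval_set(rec$chrom, rec$start, rec$start + 1)
  ing4 <- GenomicRanges::countOverlaps(pts, allg4) > 0
  nb <- max_dist %/% bin
  out <- data.frame(bin_start = (seq_len(nb) - 1) * bin,
                    bin_end = seq_len(nb) * bin)
  stat <- function(sel) {
    n <- tabulate(idx[sel], nbins = nb)
    fh <- fH <- rep(NA_real_, nb)
    for (bme in seq_len(nb)) {
      s <- sel & idx == bme
      if (any(s)) {
        fh[bme] <- mean(st[s] == "hypo"); fH[bme] <- mean(st[s] == "hyper")
      }
    }
    list(n = n, hypo = fh, hyper = fH)
  }
  a <- stat(rep(TRUE, nrow(rec))); b <- stat(ing4)
  out$n_all <- a$n; out$frac_hypo_all <- a$hypo; out$frac_hyper_all <- a$hyper
  out$n_g4 <- b$n; out$frac_hypo_g4 <- b$hypo; out$frac_hyper_g4 <- b$hyper
  out
}
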