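#' Partition G4 evidence into tiers I / II / III
#'
#' G4-II: predictions with at least 1 bp overlap with at least one ChIP
#' peak (prediction coordinates and strand retained; the predicted
#' intervals are the units, a single peak may certify many predictions).
#' G4-III: the remaining predictions. G4-I: peaks overlapping no
#' prediction (peak coordinates, unstranded); a peak overlapping any
#' prediction contributes nothing to G4-I, even its non-overlapping
#' portion. Overlap is strand-blind because peaks are unstranded.
#'
#' @param predictions `GRanges` of predicted G4 sites (stranded).
#' @param peaks `GRanges` of ChIP-seq peaks.
#' @return An object of class `EvidenceGroups`: a list with `g4_I`,
#'   `g4_II`, `g4_III` (`GRanges`) and `n_supporting_peaks`.
#' @export
classify_g4 <- function(predictions, peaks) {
  stopifnot(is(predictions, "GRanges"), is(peaks, "GRanges"))
  ov <- GenomicRanges::findOverlaps(predictions, peaks, ignore.strand = TRUE)
  hit_pred <- unique(S4Vectors::queryHits(ov))
  hit_peak <- unique(S4Vectors::subjectHits(ov))
  g4_II <- predictions[hit_pred]
  g4_III <- predictions[setdiff(seq_along(predictions), hit_pred)]
  g4_I <- peaks[setdiff(seq_along(peaks), hit_peak)]
  if (length(g4_I)) BiocGenerics::strand(g4_I) <- "*"
  structure(list(g4_I = g4_I, g4_II = g4_II, g4_III = g4_III,
                 n_supporting_peaks = length(hit_peak)),
            class = "EvidenceGroups")
}

#' @export
print.EvidenceGroups <- function(x, ...) {
  cat("EvidenceGroups\n")
  cat("  G4-I   (ChIP only):        ", length(x$g4_I), "\n")
  cat("  G4-II  (ChIP + predicted): ", length(x$g4_II), "\n")
  cat("  G4-III (predicted only):   ", length(x$g4_III), "\n")
  cat("  supporting peaks:          ", x$n_supporting_peaks, "\n")
  invisible(x)
}

#' Summarize evidence groups
#'
#' @param groups an `EvidenceGroups` object.
#' @return data.frame with one row per group: count, total bp and width
#'   quartiles.
#' @export
group_summary <- function(groups) {
  stopifnot(inherits(groups, "EvidenceGroups"))
  one <- function(name, gr) {
    w <- BiocGenerics::width(gr)
    if (length(w) == 0L) w <- NA_real_
    q <- stats::quantile(w, c(.25, .5, .75), na.rm = TRUE)
    data.frame(group = name, n = length(gr),
               total_bp = if (length(gr)) sum(as.numeric(BiocGenerics::width(gr))) else 0,
               width_q25 = unname(q[1]), width_median = unname(q[2]),
               width_q75 = unname(q[3]))
  }
  rbind(one("G4-I", groups$g4_I), one("G4-II", groups$g4_II),
        one("G4-III", groups$g4_III))
}
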