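#' Extract G4 "feet": flanking sequences around predicted sites
#'
#' For a `+` site `[s, e)` (0-based half-open) the left foot is
#' `[s - flank, s)` and the right foot `[e, e + flank)`. For a `-` site
#' both windows are reverse-complemented and swapped so "left" is always
#' 5' in the G4 sense orientation. Windows are clipped at chromosome
#' bounds, so a foot can be shorter than `flank` near an edge; feet never
#' include G4 bases.
#'
#' @param predictions stranded `GRanges` of G4 sites.
#' @param genome named `DNAStringSet` (or named character vector).
#' @param flank foot width in bp, default 50.
#' @return data.frame with `g4_id`, `chrom`, `start`, `end`, `strand`,
#'   `left`, `right` (foot sequences, G4 sense orientation).
#' @export
extract_feet <- function(predictions, genome, flank = 50) {
  stopifnot(is(predictions, "GRanges"))
  chr <- as.character(GenomeInfoDb::seqnames(predictions))
  if (!all(chr %in% names(genome)))
    stop("prediction chromosome(s) absent from genome")
  seqs <- lapply(genome, as.character)
  lens <- vapply(seqs, nchar, numeric(1))
  s0 <- BiocGenerics::start(predictions) - 1L
  e0 <- BiocGenerics::end(predictions)
  if (any(s0 < 0) || any(e0 > lens[chr]))
    stop("G4 site outside genome bounds")
  std <- as.character(BiocGenerics::strand(predictions))
  left <- right <- character(length(predictions))
  for (i in seq_along(predictions)) {
    sq <- seqs[[chr[i]]]
    ls <- max(s0[i] - flank, 0)
    l <- if (ls < s0[i]) substr(sq, ls + 1, s0[i]) else ""
    re <- min(e0[i] + flank, lens[[chr[i]]])
    r <- if (e0[i] < re) substr(sq, e0[i] + 1, re) else ""
    if (std[i] == "-") {
      tmp <- revcomp(l); l <- revcomp(r); r <- tmp
    }
    left[i] <- l; right[i] <- r
  }
  data.frame(g4_id = if (!is.null(names(predictions)) &&
                         all(nzchar(names(predictions))))
               names(predictions)
             else paste0("g4_", seq_along(predictions)),
             chrom = chr, start = s0, end = e0, strand = std,
             left = left, right = right, stringsAsFactors = FALSE)
}

revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Per-site k-mer presence frequencies over feet
#'
#' The frequency of k-mer m is the fraction of G4 sites whose left OR
#' right foot contains m at least once (presence/absence per site, not
#' occurrence counts). All `4^k` k-mers are reported.
#'
#' @param feet data.frame from [extract_feet()].
#' @param k k-mer length, default 6.
#' @return data.frame with `kmer`, `count` (sites containing it), `freq`;
#'   attribute `n_sites`.
#' @export
kmer_presence <- function(feet, k = 6) {
  stopifnot(k >= 1)
  n <- nrow(feet)
  pad <- function(x) ifelse(nchar(x) >= k, x, strrep("N", k)) # too short: no k-mers
  l <- Biostrings::DNAStringSet(pad(feet$left))
  r <- Biostrings::DNAStringSet(pad(feet$right))
  cl <- Biostrings::oligonucleotideFrequency(l, width = k)
  cr <- Biostrings::oligonucleotideFrequency(r, width = k)
  pres <- (cl > 0) | (cr > 0)
  count <- if (n) colSums(pres) else
    stats::setNames(rep(0L, 4^k), colnames(Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet("A"), width = k)))
  out <- data.frame(kmer = names(count), count = as.integer(count),
                    freq = if (n) as.numeric(count) / n else 0,
                    stringsAsFactors = FALSE)
  attr(out, "n_sites") <- n
  out
}

#' Binomial fold-enrichment test of k-mers between two foot sets
#'
#' For each k-mer: fold enrichment `fe = f_t / max(f_b, floor)` where
#' `f_t`, `f_b` are per-site presence frequencies in target and
#' background and `floor = 1 / (2 * N_background)` guards against zero or
#' infinite ratios; `p = P(X >= n_t)` with
#' `X ~ Binomial(N_target, max(f_b, floor))`; `p_adj` is Bonferroni over
#' the full family of `4^k` k-mers (each direction tested as its own
#' family).
#'
#' @param target,background [kmer_presence()] tables over the same `k`.
#' @return data.frame with `kmer`, `freq_target`, `freq_background`,
#'   `n_target`, `N_target`, `fe`, `p`, `p_adj`, sorted by `p`.
#' @export
kmer_enrichment <- function(target, background) {
  if (!identical(target$kmer, background$kmer))
    stop("target and background tables must cover the same k-mers")
  N_t <- attr(target, "n_sites"); N_b <- attr(background, "n_sites")
  if (is.null(N_t) || N_t == 0) stop("empty target set")
  if (is.null(N_b) || N_b == 0) stop("empty background set")
  floor_f <- 1 / (2 * N_b)
  fb <- pmax(background$freq, floor_f)
  p <- stats::pbinom(target$count - 1, N_t, fb, lower.tail = FALSE)
  out <- data.frame(kmer = target$kmer,
                    freq_target = target$freq,
                    freq_background = background$freq,
                    n_target = target$count, N_target = N_t,
                    fe = target$freq / fb,
                    p = p,
                    p_adj = pmin(1, p * nrow(target)),
                    stringsAsFactors = FALSE)
  out[order(out$p, out$kmer), ]
}

#' Apply the published significance filters
#'
#' Retains k-mers with Bonferroni-adjusted `p_adj < p_adj_max`, fold
#' enrichment `fe > fe_min` and target frequency `freq_target >
#' freq_min` — all strict inequalities.
#'
#' @param results a [kmer_enrichment()] table.
#' @param p_adj_max,fe_min,freq_min thresholds (defaults 0.05, 4, 0.02).
#' @return The filtered table.
#' @export
filter_significant <- function(results, p_adj_max = 0.05, fe_min = 4,
                               freq_min = 0.02) {
  results[results$p_adj < p_adj_max & results$fe > fe_min &
            results$freq_target > freq_min, , drop = FALSE]
}

#' Greedy clustering of significant k-mers into motif PFMs
#'
#' Seeds a cluster with the highest-frequency unassigned k-mer; an
#' unassigned k-mer joins the cluster if its best ungapped alignment to
#' the cluster consensus over shifts -2..+2 covers at least 4 positions
#' with at most 1 mismatch. The position-frequency matrix accumulates
#' frequency-weighted base counts per aligned column and the consensus
#' (majority base per column, ties alphabetical) is recomputed after each
#' join; the process repeats until all k-mers are assigned.
#'
#' @param kmers character vector of k-mers (all the same length).
#' @param freqs numeric weights (target frequencies), same length.
#' @param max_shift maximum offset tried, default 2.
#' @param min_overlap,max_mismatch alignment acceptance rule.
#' @return list of clusters, each a list with `members` (data.frame
#'   `kmer`, `freq`, `offset`), `pfm` (4 x width matrix, rows ACGT) and
#'   `consensus`.
#' @export
cluster_motifs <- function(kmers, freqs, max_shift = 2, min_overlap = 4,
                           max_mismatch = 1) {
  stopifnot(length(kmers) == length(freqs), length(kmers) >= 1)
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop("k-mers must share one length")
  ord <- order(-freqs, kmers)
  kmers <- kmers[ord]; freqs <- freqs[ord]
  assigned <- rep(FALSE, length(kmers))
  clusters <- list()
  align <- function(kmer, consensus) {
    best <- NULL
    for (s in seq(-max_shift, max_shift)) {
      # kmer position i aligns to consensus position i + s
      ov <- intersect(seq_len(k) + s, seq_len(nchar(consensus)))
      if (length(ov) < min_overlap) next
      kb <- substring(kmer, ov - s, ov - s)
      cb <- substring(consensus, ov, ov)
      mm <- sum(kb != cb)
      if (mm <= max_mismatch &&
          (is.null(best) || mm < best$mm ||
           (mm == best$mm && length(ov) > best$nov)))
        best <- list(shift = s, mm = mm, nov = length(ov))
    }
    best
  }
  consensus_of <- function(pfm) {
    paste(rownames(pfm)[apply(pfm, 2, which.max)], collapse = "")
  }
  while (!all(assigned)) {
    seed <- which(!assigned)[1]
    assigned[seed] <- TRUE
    # columns indexed relative to the seed; offset = start column of member
    lo <- 1; hi <- k
    pfm <- matrix(0, 4, k, dimnames = list(c("A", "C", "G", "T"), NULL))
    add <- function(pfm, kmer, freq, off) {
      for (i in seq_len(k)) {
        b <- substr(kmer, i, i)
        pfm[b, off + i - 1] <- pfm[b, off + i - 1] + freq
      }
      pfm
    }
    members <- data.frame(kmer = kmers[seed], freq = freqs[seed],
                          offset = 0, stringsAsFactors = FALSE)
    pfm <- add(pfm, kmers[seed], freqs[seed], 1)
    repeat {
      cons <- consensus_of(pfm)
      joined <- FALSE
      for (j in which(!assigned)) {
        al <- align(kmers[j], cons)
        if (is.null(al)) next
        off <- al$shift   # member start relative to current pfm col 1 - 1
        if (off < 0) {    # grow pfm on the left
          pad <- matrix(0, 4, -off, dimnames = list(rownames(pfm), NULL))
          pfm <- cbind(pad, pfm)
          members$offset <- members$offset - off
          off <- 0
        }
        if (off + k > ncol(pfm)) {
          pad <- matrix(0, 4, off + k - ncol(pfm),
                        dimnames = list(rownames(pfm), NULL))
          pfm <- cbind(pfm, pad)
        }
        pfm <- add(pfm, kmers[j], freqs[j], off + 1)
        members <- rbind(members,
                         data.frame(kmer = kmers[j], freq = freqs[j],
                                    offset = off, stringsAsFactors = FALSE))
        assigned[j] <- TRUE
        joined <- TRUE
        break
      }
      if (!joined) break
    }
    clusters[[length(clusters) + 1L]] <-
      list(members = members, pfm = pfm, consensus = consensus_of(pfm))
  }
  clusters
}

#' Write motif clusters in MEME minimal format
#'
#' Column probabilities are the PFM columns normalized to 1; columns with
#' zero total weight (outside every member's span) get uniform 0.25.
#'
#' @param clusters result of [cluster_motifs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meme_pfm <- function(clusters, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: +", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    pr <- apply(cl$pfm, 2, function(col) {
      s <- sum(col); if (s > 0) col / s else rep(0.25, 4)
    })
    writeLines(sprintf("MOTIF cluster%d %s", i, cl$consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(pr), nrow(cl$members)), con)
    for (j in seq_len(ncol(pr)))
      writeLines(paste(sprintf("%.6f", pr[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write foot sequences as FASTA
#'
#' @param feet data.frame from [extract_feet()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feet_fasta <- function(feet, path) {
  keep <- nzchar(feet$left) | nzchar(feet$right)
  ids <- c(paste0(feet$g4_id, "_left"), paste0(feet$g4_id, "_right"))
  seqs <- c(feet$left, feet$right)
  ok <- nzchar(seqs)
  ss <- Biostrings::DNAStringSet(seqs[ok])
  names(ss) <- ids[ok]
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
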