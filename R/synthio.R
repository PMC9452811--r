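#' Configuration for the synthetic multi-omics generator
#'
#' Defaults describe the emulated world: two 500-kb chromosomes carrying
#' 56 single-exon genes in non-overlapping 16-kb slots (10 kb upstream +
#' 3 kb body + 2 kb downstream + margin), an AT-rich (60% A/T) background
#' screened of incidental G4 windows, planted G4 consensus sequences
#' (four G-runs of `g4_run` bases, A/T loops of 1-7 bp) on both strands,
#' ChIP peaks capturing a tunable fraction of plantings plus false peaks
#' overlapping no prediction, epigenomic tracks placed in upstream
#' windows at the given per-gene prevalences, CpG beta values from a
#' hypo/intermediate/hyper mixture re-weighted inside each G4 tier, and
#' expression sampled from the published logistic equation
#' ([g4_printed_model()]).
#'
#' @param chrom_lengths named chromosome lengths.
#' @param n_genes number of genes (must fit the slot layout).
#' @param gene_body,upstream,downstream window widths in bp.
#' @param p_upstream_g4 probability a gene gets a planted upstream G4.
#' @param p_antisense probability a gene gets a planted antisense body G4.
#' @param n_intergenic planted G4s outside gene neighborhoods.
#' @param g4_run G-run length of planted consensus (4 guarantees
#'   detection at the default window/threshold).
#' @param g4_loop_range loop length range, default `c(1, 7)`.
#' @param capture_rate fraction of planted G4s covered by a ChIP peak.
#' @param false_peak_rate per-gene probability of a peak with no
#'   underlying prediction (also scales intergenic false peaks).
#' @param track_prevalence named per-gene probabilities for `cgi`,
#'   `enhancer`, `se`, `open_chrom` upstream placement.
#' @param n_tf number of synthetic TF peak sets.
#' @param methyl_weights named list of `c(hypo, intermediate, hyper)`
#'   mixture weights for contexts `g4_II`, `g4_I`, `g4_III`,
#'   `background`.
#' @param coverage_mu,coverage_size negative-binomial CpG read coverage.
#' @param expression_model a `g4_model` driving class sampling.
#' @param mu_low,mu_high,sd_log class-conditional log-expression:
#'   `rpkm = exp(z)`, `z ~ N(mu_class, sd_log)`.
#' @param at_frac background A/T fraction.
#' @param seed integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chrA = 500000, chrB = 500000),
                       n_genes = 56,
                       gene_body = 3000, upstream = 10000, downstream = 2000,
                       p_upstream_g4 = 0.8, p_antisense = 0.25,
                       n_intergenic = 40,
                       g4_run = 4, g4_loop_range = c(1, 7),
                       capture_rate = 0.55, false_peak_rate = 0.15,
                       track_prevalence = c(cgi = 0.5, enhancer = 0.15,
                                            se = 0.08, open_chrom = 0.4),
                       n_tf = 5,
                       methyl_weights = list(
                         g4_II = c(0.744, 0.170, 0.086),
                         g4_I = c(0.556, 0.280, 0.164),
                         g4_III = c(0.587, 0.293, 0.120),
                         background = c(0.637, 0.240, 0.123)),
                       coverage_mu = 25, coverage_size = 3,
                       expression_model = g4_printed_model(),
                       mu_low = 0, mu_high = 2.5, sd_log = 1,
                       at_frac = 0.6, seed = 1) {
  stopifnot(capture_rate >= 0, capture_rate <= 1,
            false_peak_rate >= 0, false_peak_rate <= 1,
            p_upstream_g4 >= 0, p_upstream_g4 <= 1,
            all(track_prevalence >= 0 & track_prevalence <= 1),
            all(chrom_lengths > 0), g4_run >= 3)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# one planted G4 consensus: four G-runs separated by 1-7 bp loops; "-"
# strand plants the reverse complement (C-runs). Loops of >= 2 bp start
# with a CpG so planted sites are CpG-bearing, mirroring the CpG density
# observed at confirmed G4s; the loop C costs only -1 (run of one) while
# the loop G joins the following run, so detection is never endangered.
make_g4_motif <- function(run, loop_range, strand) {
  loops <- vapply(1:3, function(i) {
    n <- sample(seq(loop_range[1], loop_range[2]), 1)
    if (n >= 2)
      paste0("CG", paste(sample(c("A", "T"), n - 2, replace = TRUE),
                         collapse = ""))
    else
      paste(sample(c("A", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
  m <- paste0(strrep("G", run), loops[1], strrep("G", run), loops[2],
              strrep("G", run), loops[3], strrep("G", run))
  if (strand == "-") revcomp(m) else m
}

# rewrite G/C bases to A/T inside intervals a scan flags, until the
# background carries no incidental G4 windows
scrub_background <- function(bases, chrom, window, threshold, max_iter = 8) {
  for (it in seq_len(max_iter)) {
    pr <- suppressWarnings(
      g4_predict(paste(bases, collapse = ""), chrom,
                 window = window, threshold = threshold))
    if (length(pr) == 0L) return(bases)
    for (i in seq_along(pr)) {
      idx <- BiocGenerics::start(pr)[i]:BiocGenerics::end(pr)[i]
      gc <- idx[bases[idx] %in% c("G", "C")]
      bases[gc] <- sample(c("A", "T"), length(gc), replace = TRUE)
    }
  }
  stop("failed to scrub background of incidental G4 windows")
}

#' Generate a synthetic multi-omics bundle with ground truth
#'
#' Produces every input the pipeline consumes — genome, ChIP peaks, gene
#' table, epigenomic tracks, TF peak sets, CpG methylation and expression
#' — plus a `truth` record of what was planted, all reproducible from
#' `config$seed`. Planted G4s are exact consensus matches that score
#' above the default prediction threshold by construction, and the
#' background is screened so the planted sites are the only predictions;
#' intended per-gene features therefore equal the realized ones.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (`DNAStringSet`), `peaks`, `tracks`,
#'   `tf_sets` (`GRanges` / named lists thereof), `genes`, `methyl`,
#'   `expr` (data.frames), `truth` (list) and `config`.
#' @export
simulate_g4_data <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(as.integer(cfg$seed))
  slot <- cfg$upstream + cfg$gene_body + cfg$downstream + 1000
  per_chrom <- floor((cfg$chrom_lengths - 2000) / slot)
  if (sum(per_chrom) < cfg$n_genes)
    stop("chromosomes too short for requested gene count")

  ## background, screened of incidental G4 windows
  p_gc <- (1 - cfg$at_frac) / 2
  genome <- lapply(names(cfg$chrom_lengths), function(chr) {
    b <- sample(c("A", "T", "G", "C"), cfg$chrom_lengths[[chr]],
                replace = TRUE,
                prob = c(cfg$at_frac / 2, cfg$at_frac / 2, p_gc, p_gc))
    scrub_background(b, chr, 25, 1.5)
  })
  names(genome) <- names(cfg$chrom_lengths)

  ## gene layout on fixed slots
  counts <- pmin(per_chrom, ceiling(cfg$n_genes * per_chrom / sum(per_chrom)))
  while (sum(counts) > cfg$n_genes) counts[which.max(counts)] <-
    counts[which.max(counts)] - 1L
  genes <- do.call(rbind, lapply(seq_along(counts), function(ci) {
    chr <- names(cfg$chrom_lengths)[ci]
    if (counts[ci] == 0L) return(NULL)
    s <- 1000 + (seq_len(counts[ci]) - 1) * slot
    strand <- sample(c("+", "-"), counts[ci], replace = TRUE)
    tx_start <- ifelse(strand == "+", s + cfg$upstream,
                       s + cfg$downstream)
    tx_end <- tx_start + cfg$gene_body
    data.frame(chrom = chr, strand = strand, tx_start = tx_start,
               tx_end = tx_end, stringsAsFactors = FALSE)
  }))
  genes$gene_id <- sprintf("gene%03d", seq_len(nrow(genes)))
  genes$cds_start <- genes$tx_start + 300
  genes$cds_end <- genes$tx_end - 300
  genes <- genes[, c("gene_id", "chrom", "strand", "tx_start", "tx_end",
                     "cds_start", "cds_end")]
  ng <- nrow(genes)
  up_win <- as_bed_df(gene_windows(genes, "upstream", cfg$upstream,
                                   cfg$chrom_lengths))

  ## plant G4s
  plant <- function(chr, lo, hi, strand) {
    motif <- make_g4_motif(cfg$g4_run, cfg$g4_loop_range, strand)
    w <- nchar(motif)
    if (hi - lo < w) stop("planting window too small")
    s0 <- sample(seq(lo, hi - w), 1)
    substr_vec <- strsplit(motif, "", fixed = TRUE)[[1]]
    genome[[chr]][(s0 + 1):(s0 + w)] <<- substr_vec
    data.frame(chrom = chr, start = s0, end = s0 + w, strand = strand,
               stringsAsFactors = FALSE)
  }
  planted <- list(); planted_ctx <- character(0); planted_gene <- character(0)
  has_up_g4 <- stats::runif(ng) < cfg$p_upstream_g4
  up_captured <- logical(ng)
  for (i in seq_len(ng)) {
    if (!has_up_g4[i]) next
    w <- up_win[i, ]
    planted[[length(planted) + 1L]] <-
      plant(w$chrom, w$start + 200, w$end - 200,
            sample(c("+", "-"), 1))
    planted_ctx <- c(planted_ctx, "upstream")
    planted_gene <- c(planted_gene, genes$gene_id[i])
  }
  has_anti <- stats::runif(ng) < cfg$p_antisense
  for (i in seq_len(ng)) {
    if (!has_anti[i]) next
    anti <- if (genes$strand[i] == "+") "-" else "+"
    planted[[length(planted) + 1L]] <-
      plant(genes$chrom[i], genes$tx_start[i] + 200, genes$tx_end[i] - 200,
            anti)
    planted_ctx <- c(planted_ctx, "antisense")
    planted_gene <- c(planted_gene, genes$gene_id[i])
  }
  ## intergenic plantings in the tail beyond the gene slots
  tails <- lapply(seq_along(counts), function(ci) {
    lo <- 1000 + counts[ci] * slot + 500
    hi <- cfg$chrom_lengths[[ci]] - 500
    if (hi - lo < 1000) NULL else c(lo, hi)
  })
  names(tails) <- names(cfg$chrom_lengths)
  tails <- tails[!vapply(tails, is.null, logical(1))]
  if (cfg$n_intergenic > 0 && length(tails)) {
    spots <- do.call(rbind, lapply(names(tails), function(chr) {
      # spacing leaves room for motif (<= 37 bp) plus window extension on
      # both sides, so neighboring plantings can never merge
      grid <- seq(tails[[chr]][1], tails[[chr]][2] - 450, by = 450)
      data.frame(chrom = chr, lo = grid, stringsAsFactors = FALSE)
    }))
    pick <- spots[sample(nrow(spots), min(cfg$n_intergenic, nrow(spots))), ]
    for (j in seq_len(nrow(pick))) {
      planted[[length(planted) + 1L]] <-
        plant(pick$chrom[j], pick$lo[j], pick$lo[j] + 250,
              sample(c("+", "-"), 1))
      planted_ctx <- c(planted_ctx, "intergenic")
      planted_gene <- c(planted_gene, NA_character_)
    }
  }
  planted <- do.call(rbind, planted)
  np <- nrow(planted)
  captured <- stats::runif(np) < cfg$capture_rate
  planted$captured <- captured
  planted$context <- planted_ctx
  planted$gene_id <- planted_gene

  ## ChIP peaks: capture peaks over captured plantings + false peaks
  cap <- planted[planted$captured, , drop = FALSE]
  peaks <- NULL
  if (nrow(cap)) {
    slop_l <- sample(10:60, nrow(cap), replace = TRUE)
    slop_r <- sample(10:60, nrow(cap), replace = TRUE)
    peaks <- data.frame(chrom = cap$chrom,
                        start = pmax(cap$start - slop_l, 0),
                        end = pmin(cap$end + slop_r,
                                   cfg$chrom_lengths[cap$chrom]),
                        stringsAsFactors = FALSE)
  }
  false_up <- !has_up_g4 & stats::runif(ng) < cfg$false_peak_rate
  if (any(false_up)) {
    w <- up_win[false_up, , drop = FALSE]
    s0 <- w$start + 200 + floor(stats::runif(nrow(w)) *
                                  (w$end - w$start - 550))
    peaks <- rbind(peaks, data.frame(chrom = w$chrom, start = s0,
                                     end = s0 + 150,
                                     stringsAsFactors = FALSE))
  }
  n_false_ig <- round(cfg$false_peak_rate * ng / 2)
  if (n_false_ig > 0 && length(tails)) {
    chr <- sample(names(tails), n_false_ig, replace = TRUE)
    s0 <- vapply(chr, function(ch)
      sample(seq(tails[[ch]][1], tails[[ch]][2] - 150), 1), numeric(1))
    fp <- data.frame(chrom = chr, start = s0, end = s0 + 150,
                     stringsAsFactors = FALSE)
    ## drop any that touch a planting (they must carry no prediction)
    pg <- interval_set(planted$chrom, pmax(planted$start - 60, 0),
                       planted$end + 60)
    keep <- GenomicRanges::countOverlaps(
      interval_set(fp$chrom, fp$start, fp$end), pg) == 0
    peaks <- rbind(peaks, fp[keep, , drop = FALSE])
  }
  peaks_gr <- if (is.null(peaks) || nrow(peaks) == 0)
    GenomicRanges::GRanges(seqlengths = cfg$chrom_lengths)
  else interval_set(peaks$chrom, peaks$start, peaks$end,
                    seqlengths = cfg$chrom_lengths)

  ## epigenomic tracks in upstream windows + a few intergenic intervals
  track_delta <- matrix(0L, ng, length(cfg$track_prevalence),
                        dimnames = list(genes$gene_id,
                                        names(cfg$track_prevalence)))
  tracks <- list()
  for (tr in names(cfg$track_prevalence)) {
    hit <- stats::runif(ng) < cfg$track_prevalence[[tr]]
    track_delta[, tr] <- as.integer(hit)
    ivs <- NULL
    if (any(hit)) {
      w <- up_win[hit, , drop = FALSE]
      width <- sample(1000:3000, nrow(w), replace = TRUE)
      s0 <- w$start + floor(stats::runif(nrow(w)) * (w$end - w$start - width))
      ivs <- data.frame(chrom = w$chrom, start = pmax(s0, w$start),
                        end = pmin(s0 + width, w$end),
                        stringsAsFactors = FALSE)
    }
    if (length(tails)) {
      chr <- sample(names(tails), 5, replace = TRUE)
      s0 <- vapply(chr, function(ch)
        sample(seq(tails[[ch]][1], tails[[ch]][2] - 500), 1), numeric(1))
      ivs <- rbind(ivs, data.frame(chrom = chr, start = s0, end = s0 + 500,
                                   stringsAsFactors = FALSE))
    }
    tracks[[tr]] <- interval_set(ivs$chrom, ivs$start, ivs$end,
                                 seqlengths = cfg$chrom_lengths)
  }

  ## TF peak sets over captured plantings at graded rates
  tf_sets <- list()
  if (cfg$n_tf > 0) {
    rates <- seq(0.15, 0.75, length.out = cfg$n_tf)
    for (j in seq_len(cfg$n_tf)) {
      base <- cap[stats::runif(nrow(cap)) < rates[j], , drop = FALSE]
      ivs <- if (nrow(base)) data.frame(chrom = base$chrom,
                                        start = pmax(base$start - 20, 0),
                                        end = base$end + 20,
                                        stringsAsFactors = FALSE) else NULL
      if (length(tails)) {
        chr <- sample(names(tails), 8, replace = TRUE)
        s0 <- vapply(chr, function(ch)
          sample(seq(tails[[ch]][1], tails[[ch]][2] - 200), 1), numeric(1))
        ivs <- rbind(ivs, data.frame(chrom = chr, start = s0, end = s0 + 200,
                                     stringsAsFactors = FALSE))
      }
      tf_sets[[sprintf("TF%02d", j)]] <-
        interval_set(ivs$chrom, ivs$start, ivs$end,
                     seqlengths = cfg$chrom_lengths)
    }
  }

  ## per-gene truth features and expression from the configured model
  lab <- rep("noG4", ng)
  for (i in seq_len(ng)) {
    mine <- planted$context == "upstream" &
      !is.na(planted$gene_id) & planted$gene_id == genes$gene_id[i]
    if (any(mine & planted$captured)) lab[i] <- "G4-II"
    else if (false_up[i]) lab[i] <- "G4-I"
    else if (any(mine)) lab[i] <- "G4-III"
  }
  anti_truth <- vapply(seq_len(ng), function(i) {
    mine <- planted$context == "antisense" &
      !is.na(planted$gene_id) & planted$gene_id == genes$gene_id[i]
    any(mine & planted$captured)
  }, logical(1))
  features <- cbind(g4I_up = as.integer(lab == "G4-I"),
                    g4II_up = as.integer(lab == "G4-II"),
                    g4III_up = as.integer(lab == "G4-III"),
                    track_delta[, c("enhancer", "se", "cgi", "open_chrom")],
                    antisense = as.integer(anti_truth))
  rownames(features) <- genes$gene_id
  y <- predict_logodds(cfg$expression_model, features)
  class <- as.integer(stats::runif(ng) < stats::plogis(y))
  z <- stats::rnorm(ng, ifelse(class == 1, cfg$mu_high, cfg$mu_low),
                    cfg$sd_log)
  expr <- data.frame(gene_id = genes$gene_id, rpkm = exp(z),
                     stringsAsFactors = FALSE)

  ## CpG methylation over actual CG dinucleotides
  seq_chr <- vapply(genome, paste, character(1), collapse = "")
  methyl <- do.call(rbind, lapply(names(seq_chr), function(chr) {
    m <- gregexpr("CG", seq_chr[[chr]], fixed = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(chrom = chr, start = as.integer(m) - 1L,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(methyl) && nrow(methyl)) {
    methyl$end <- methyl$start + 2L
    pts <- interval_set(methyl$chrom, methyl$start, methyl$start + 1)
    ctx <- rep("background", nrow(methyl))
    # the planted motif itself carries no CpG (G-runs + A/T loops), so the
    # tier-specific methylation context extends 30 bp around each planting
    # — wider than any window extension a prediction can acquire
    pad <- 30
    ctx_sets <- list(
      g4_III = planted[!planted$captured, , drop = FALSE],
      g4_I = NULL, g4_II = planted[planted$captured, , drop = FALSE])
    inII <- GenomicRanges::countOverlaps(
      pts, interval_set(ctx_sets$g4_II$chrom,
                        pmax(ctx_sets$g4_II$start - pad, 0),
                        ctx_sets$g4_II$end + pad)) > 0
    inIII <- GenomicRanges::countOverlaps(
      pts, interval_set(ctx_sets$g4_III$chrom,
                        pmax(ctx_sets$g4_III$start - pad, 0),
                        ctx_sets$g4_III$end + pad)) > 0
    g4I_only <- classify_g4(
      interval_set(planted$chrom, planted$start, planted$end,
                   strand = planted$strand), peaks_gr)$g4_I
    inI <- GenomicRanges::countOverlaps(pts, g4I_only) > 0
    ctx[inIII] <- "g4_III"; ctx[inI] <- "g4_I"; ctx[inII] <- "g4_II"
    state <- vapply(ctx, function(cx) {
      sample(c("hypo", "intermediate", "hyper"), 1,
             prob = cfg$methyl_weights[[cx]])
    }, character(1))
    methyl$beta <- ifelse(state == "hypo", stats::runif(nrow(methyl), 0, 0.1),
                   ifelse(state == "hyper", stats::runif(nrow(methyl), 0.9, 1),
                          stats::runif(nrow(methyl), 0.15, 0.85)))
    methyl$coverage <- stats::rnbinom(nrow(methyl), mu = cfg$coverage_mu,
                                      size = cfg$coverage_size)
    methyl <- methyl[, c("chrom", "start", "end", "coverage", "beta")]
  }

  genome_dss <- Biostrings::DNAStringSet(seq_chr)
  truth <- list(g4 = planted,
                gene_label = stats::setNames(lab, genes$gene_id),
                antisense = stats::setNames(anti_truth, genes$gene_id),
                features = features, class = stats::setNames(class,
                                                             genes$gene_id))
  list(genome = genome_dss, peaks = peaks_gr, tracks = tracks,
       tf_sets = tf_sets, genes = genes, methyl = methyl, expr = expr,
       truth = truth, config = cfg)
}

#' Gene-level feature cohort from a logistic model
#'
#' Samples binary features at the given prevalences (upstream tiers as a
#' mutually exclusive multinomial), draws the high/low class from the
#' model's logistic probability, and generates RPKM as `exp(z)` with a
#' class-shifted normal `z`. Used for parameter-recovery and null
#' simulations at sizes where a sequence-level genome is unnecessary.
#'
#' @param n number of genes.
#' @param model a `g4_model` (default: the published equation).
#' @param upstream_probs probabilities for upstream labels
#'   `c(g4I, g4II, g4III, none)`, summing to 1.
#' @param track_probs named prevalences for `enhancer`, `se`, `cgi`,
#'   `open_chrom`, `antisense`.
#' @param mu_low,mu_high,sd_log class-conditional log-expression.
#' @param seed integer RNG seed.
#' @param null_labels if `TRUE`, the class is drawn independently of the
#'   features (negative control).
#' @return list with `features` (n x 8 matrix), `logodds`, `class`,
#'   `expr` (data.frame `gene_id`, `rpkm`).
#' @export
simulate_feature_cohort <- function(n, model = g4_printed_model(),
                                    upstream_probs = c(0.24, 0.51, 0.22, 0.03),
                                    track_probs = c(enhancer = 0.15,
                                                    se = 0.08, cgi = 0.5,
                                                    open_chrom = 0.4,
                                                    antisense = 0.2),
                                    mu_low = 0, mu_high = 2.5, sd_log = 1,
                                    seed = 1, null_labels = FALSE) {
  stopifnot(abs(sum(upstream_probs) - 1) < 1e-8)
  set.seed(as.integer(seed))
  up <- sample(c("g4I_up", "g4II_up", "g4III_up", "none"), n,
               replace = TRUE, prob = upstream_probs)
  f <- cbind(g4I_up = as.integer(up == "g4I_up"),
             g4II_up = as.integer(up == "g4II_up"),
             g4III_up = as.integer(up == "g4III_up"),
             enhancer = as.integer(stats::runif(n) < track_probs[["enhancer"]]),
             se = as.integer(stats::runif(n) < track_probs[["se"]]),
             cgi = as.integer(stats::runif(n) < track_probs[["cgi"]]),
             open_chrom = as.integer(stats::runif(n) <
                                       track_probs[["open_chrom"]]),
             antisense = as.integer(stats::runif(n) <
                                      track_probs[["antisense"]]))
  rownames(f) <- sprintf("gene%05d", seq_len(n))
  lo <- predict_logodds(model, f)
  class <- if (null_labels) as.integer(stats::runif(n) < 0.5)
           else as.integer(stats::runif(n) < stats::plogis(lo))
  z <- stats::rnorm(n, ifelse(class == 1, mu_high, mu_low), sd_log)
  list(features = f, logodds = lo,
       class = stats::setNames(class, rownames(f)),
       expr = data.frame(gene_id = rownames(f), rpkm = exp(z),
                         stringsAsFactors = FALSE))
}

#' Recovery metrics of pipeline outputs against planted truth
#'
#' @param truth the `truth` element of [simulate_g4_data()] output.
#' @param predictions `GRanges` from [g4_predict_genome()].
#' @param groups optional `EvidenceGroups` from [classify_g4()].
#' @param features optional realized feature matrix from
#'   [build_features()].
#' @return list with `sensitivity` (planted G4s recovered by a
#'   same-strand prediction), `precision` (predictions overlapping a
#'   planting), `group_confusion` (intended vs realized tier for planted
#'   sites) and `feature_agreement` (fraction of matching feature cells),
#'   the latter two `NULL` when their inputs are absent.
#' @export
truth_report <- function(truth, predictions, groups = NULL,
                         features = NULL) {
  if (is.null(truth$g4) || nrow(truth$g4) == 0)
    return(list(sensitivity = NA_real_, precision = NA_real_,
                group_confusion = NULL, feature_agreement = NULL))
  tg <- interval_set(truth$g4$chrom, truth$g4$start, truth$g4$end,
                     strand = truth$g4$strand)
  hit <- GenomicRanges::countOverlaps(tg, predictions,
                                      ignore.strand = FALSE) > 0
  prec <- if (length(predictions))
    mean(GenomicRanges::countOverlaps(predictions, tg,
                                      ignore.strand = FALSE) > 0)
  else NA_real_
  conf <- NULL
  if (!is.null(groups)) {
    intended <- ifelse(truth$g4$captured, "G4-II", "G4-III")
    inII <- GenomicRanges::countOverlaps(tg, groups$g4_II,
                                         ignore.strand = FALSE) > 0
    inIII <- GenomicRanges::countOverlaps(tg, groups$g4_III,
                                          ignore.strand = FALSE) > 0
    realized <- ifelse(inII, "G4-II", ifelse(inIII, "G4-III", "missed"))
    conf <- table(intended = intended, realized = realized)
  }
  fa <- NULL
  if (!is.null(features)) {
    tf <- truth$features[rownames(features), colnames(features)]
    fa <- mean(features == tf)
  }
  list(sensitivity = mean(hit), precision = prec,
       group_confusion = conf, feature_agreement = fa)
}

#' Write a synthetic bundle to disk in standard formats
#'
#' FASTA genome, BED peaks/tracks/TF sets, TSV gene table, methylation
#' and expression tables, JSON truth and config.
#'
#' @param sim output of [simulate_g4_data()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             peaks = file.path(dir, "peaks.bed"),
             genes = file.path(dir, "genes.tsv"),
             methyl = file.path(dir, "methylation.tsv"),
             expr = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.json"))
  Biostrings::writeXStringSet(sim$genome, paths[["genome"]])
  write_bed(sim$peaks, paths[["peaks"]])
  utils::write.table(sim$genes, paths[["genes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (tr in names(sim$tracks)) {
    p <- file.path(dir, paste0("track_", tr, ".bed"))
    write_bed(sim$tracks[[tr]], p)
    paths[[paste0("track_", tr)]] <- p
  }
  for (tf in names(sim$tf_sets)) {
    p <- file.path(dir, paste0("tf_", tf, ".bed"))
    write_bed(sim$tf_sets[[tf]], p)
    paths[[paste0("tf_", tf)]] <- p
  }
  if (!is.null(sim$methyl))
    utils::write.table(sim$methyl, paths[["methyl"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(sim$expr, paths[["expr"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$features <- as.data.frame(truth$features)
  jsonlite::write_json(truth, paths[["truth"]], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  cfgj <- sim$config
  cfgj$expression_model <- list(intercept = cfgj$expression_model$intercept,
                                coefficients = as.list(
                                  cfgj$expression_model$coefficients))
  cfgj$methyl_weights <- lapply(cfgj$methyl_weights, as.list)
  jsonlite::write_json(unclass(cfgj), paths[["config"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
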