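#' Assemble a pipeline run configuration
#'
#' Paths may be `NULL`; stages whose inputs are missing are skipped with
#' a logged notice. Defaults follow the published analysis where a value
#' is printed (25-bp window, threshold 1.5, 10-kb upstream, 2-kb
#' downstream, 50-bp feet, quartile labels, coverage >= 10).
#'
#' @param fasta,peaks,genes paths to genome FASTA, peak BED, gene table
#'   TSV (required for a full run).
#' @param tracks named list of BED paths (`cgi`, `enhancer`, `se`,
#'   `open_chrom`).
#' @param tf_beds named list of TF BED paths.
#' @param methyl path to a methylation TSV.
#' @param expression path to an expression TSV (`gene_id`, `rpkm`).
#' @param out_dir output directory.
#' @param window,threshold G4 prediction parameters.
#' @param upstream,downstream gene window widths.
#' @param flank foot width.
#' @param quantile expression label quantile.
#' @param min_cov methylation coverage filter.
#' @param alpha elastic-net mixing parameter.
#' @param seed top-level seed; per-stage seeds are derived from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(fasta = NULL, peaks = NULL, genes = NULL,
                       tracks = list(), tf_beds = list(), methyl = NULL,
                       expression = NULL, out_dir = "g4tier_out",
                       window = 25, threshold = 1.5, upstream = 10000,
                       downstream = 2000, flank = 50, quantile = 0.25,
                       min_cov = 10, alpha = 0.5, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file mirroring the [run_config()] fields.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(run_config, raw[intersect(names(raw),
                                           names(formals(run_config)))])
  cfg
}

stage_log <- function(...) message("[g4tier] ", ...)

#' Run the full analysis pipeline
#'
#' predict -> classify -> annotate -> gene association -> tracks ->
#' expression model -> feet, writing one TSV per result plus a
#' machine-readable JSON manifest (files, parameters, seed, md5
#' checksums). Stages with missing inputs are skipped and marked in the
#' manifest; reruns on identical inputs are byte-identical. All
#' randomness derives from `config$seed`.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_g4_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list(); skipped <- character(0)
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[name]] <<- p
  }
  need <- function(what, path) {
    if (is.null(path)) return(FALSE)
    if (!file.exists(path)) stop("input not found for ", what, ": ", path)
    TRUE
  }
  if (!need("predict", cfg$fasta)) stop("a genome FASTA is required")
  stage_log("predict: window=", cfg$window, " threshold=", cfg$threshold)
  genome <- Biostrings::readDNAStringSet(cfg$fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  pred <- g4_predict_genome(genome, window = cfg$window,
                            threshold = cfg$threshold)
  emit(as_bed_df(pred), "predictions")

  groups <- NULL
  if (need("classify", cfg$peaks)) {
    pk <- read_bed(cfg$peaks)
    groups <- classify_g4(pred, pk)
    stage_log("classify: ", length(groups$g4_II), " G4-II / ",
              length(groups$g4_I), " G4-I / ", length(groups$g4_III),
              " G4-III")
    emit(group_summary(groups), "group_summary")
    for (g in c("g4_I", "g4_II", "g4_III")) {
      p <- file.path(cfg$out_dir, paste0(g, ".bed"))
      write_bed(groups[[g]], p); outputs[[g]] <- p
    }
  } else skipped <- c(skipped, "classify")

  genes <- NULL
  if (need("annotate", cfg$genes)) {
    genes <- read_gene_table(cfg$genes)
    fmap <- build_feature_map(genes, chrom_lengths,
                              upstream = cfg$upstream,
                              downstream = cfg$downstream)
    if (!is.null(groups)) {
      dist <- lapply(list(`G4-I` = groups$g4_I, `G4-II` = groups$g4_II,
                          `G4-III` = groups$g4_III), function(gr) {
        lab <- assign_region(gr, fmap)
        as.vector(table(factor(lab, levels = names(fmap$classes))))
      })
      df <- data.frame(class = names(fmap$classes), dist,
                       check.names = FALSE)
      emit(df, "region_distribution")
      emit(density_table(groups, fmap), "density")
      emit(tss_profile(groups, genes), "tss_profile")
    }
  } else skipped <- c(skipped, "annotate")

  expr <- NULL
  if (need("expression", cfg$expression))
    expr <- utils::read.delim(cfg$expression, stringsAsFactors = FALSE)
  if (!is.null(genes) && !is.null(groups)) {
    labs <- do.call(rbind, lapply(c("upstream", "body", "downstream"),
                                  function(r)
      label_genes(genes, groups, r, chrom_lengths,
                  upstream = cfg$upstream, downstream = cfg$downstream)))
    emit(labs, "gene_labels")
    if (!is.null(expr)) {
      up <- labs[labs$region == "upstream", ]
      summ <- do.call(rbind, lapply(split(up$gene_id, up$label),
                                    function(ids) {
        r <- expr$rpkm[expr$gene_id %in% ids]
        data.frame(n = length(r), median_rpkm = stats::median(r),
                   mean_rpkm = mean(r))
      }))
      summ <- cbind(label = rownames(summ), summ)
      emit(summ, "expression_by_label")
    }
  } else skipped <- c(skipped, "assoc")

  track_grs <- NULL
  if (length(cfg$tracks) && !is.null(groups)) {
    track_grs <- lapply(cfg$tracks, read_bed)
    ov <- do.call(rbind, lapply(names(track_grs), function(tr)
      data.frame(track = tr,
                 g4_I = overlap_ratio(groups$g4_I, track_grs[[tr]]),
                 g4_II = overlap_ratio(groups$g4_II, track_grs[[tr]]),
                 g4_III = overlap_ratio(groups$g4_III, track_grs[[tr]]))))
    emit(ov, "track_overlap")
  } else skipped <- c(skipped, "tracks")

  if (length(cfg$tf_beds) && !is.null(groups)) {
    tf <- lapply(cfg$tf_beds, read_bed)
    emit(tf_jaccard_matrix(groups, tf), "tf_jaccard")
  } else skipped <- c(skipped, "tf_jaccard")

  if (!is.null(cfg$methyl) && !is.null(groups) && need("methyl", cfg$methyl)) {
    rec <- filter_methyl(read_methyl(cfg$methyl), cfg$min_cov)
    emit(methyl_by_group(rec, groups), "methylation_summary")
    emit(telomere_profile(rec, groups, chrom_lengths), "telomere_profile")
  } else skipped <- c(skipped, "methyl")

  if (!is.null(genes) && !is.null(groups) && !is.null(expr) &&
      !is.null(track_grs) &&
      all(c("cgi", "enhancer", "se", "open_chrom") %in% names(track_grs))) {
    labels <- make_labels(expr, cfg$quantile)
    if (min(table(labels)) < 5) {
      stage_log("model: cohort too small for cross-validation; skipped")
      skipped <- c(skipped, "model")
    } else {
      stage_log("model: alpha=", cfg$alpha, " seed=", cfg$seed)
      feats <- build_features(genes, groups, track_grs, chrom_lengths,
                              upstream = cfg$upstream)
      sp <- split_labels(labels, 0.7, seed = cfg$seed + 1L)
      fit <- fit_expression_model(feats[names(sp$train), , drop = FALSE],
                                  sp$train, alpha = cfg$alpha,
                                  nfolds = max(3, min(10,
                                    min(table(sp$train)))),
                                  seed = cfg$seed + 2L)
      ev <- evaluate_model(fit, feats[names(sp$test), , drop = FALSE],
                           sp$test)
      p <- file.path(cfg$out_dir, "model_coefficients.tsv")
      write_model_tsv(fit, p); outputs[["model_coefficients"]] <- p
      emit(as.data.frame(ev$confusion), "model_confusion")
      emit(data.frame(metric = c("accuracy", "auc"),
                      value = c(ev$accuracy, ev$auc)), "model_metrics")
    }
  } else skipped <- c(skipped, "model")

  if (!is.null(groups)) {
    feetII <- extract_feet(groups$g4_II, genome, flank = cfg$flank)
    feetIII <- extract_feet(groups$g4_III, genome, flank = cfg$flank)
    if (nrow(feetII) && nrow(feetIII)) {
      tII <- kmer_presence(feetII); tIII <- kmer_presence(feetIII)
      enr <- kmer_enrichment(tII, tIII)
      emit(enr, "feet_enrichment_g4II")
      sig <- filter_significant(enr)
      emit(sig, "feet_significant_g4II")
      if (nrow(sig)) {
        cl <- cluster_motifs(sig$kmer, sig$freq_target)
        p <- file.path(cfg$out_dir, "feet_motifs_g4II.meme")
        write_meme_pfm(cl, p); outputs[["feet_motifs_g4II"]] <- p
      }
    }
  } else skipped <- c(skipped, "feet")

  manifest <- list(
    package = "g4tier",
    version = as.character(utils::packageVersion("g4tier")),
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    seed = cfg$seed,
    skipped = as.list(skipped),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  stage_log("done: ", length(outputs), " outputs, ",
            length(skipped), " stage(s) skipped")
  invisible(manifest)
}
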