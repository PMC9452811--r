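#' Canonical feature order of the expression model
#'
#' Eight binary indicators, in the fixed order used by every model
#' function: the three mutually exclusive upstream G4 tiers (one-hot of
#' the gene's upstream label), four epigenomic-track indicators on the
#' 10-kb upstream window, and the antisense-G4 flag.
#'
#' @return character vector of feature names.
#' @export
g4_feature_names <- function() {
  c("g4I_up", "g4II_up", "g4III_up", "enhancer", "se", "cgi",
    "open_chrom", "antisense")
}

#' The published eight-feature expression model
#'
#' The reported elastic-net logistic equation relating G4 evidence tiers
#' and epigenomic context to the log-odds that a gene is highly
#' expressed:
#' `y = -4.94 + 0.80 dG4-I:up + 1.60 dG4-II:up - 1.21 dG4-III:up +
#' 0.56 dEnhancer + 1.33 dSE + 1.73 dCGI + 3.00 dOpenChrom -
#' 0.15 dG4:Antisense`.
#'
#' @return A `g4_model` object (see [fit_expression_model()]) carrying
#'   the published intercept and coefficients.
#' @export
g4_printed_model <- function() {
  coefs <- c(g4I_up = 0.80, g4II_up = 1.60, g4III_up = -1.21,
             enhancer = 0.56, se = 1.33, cgi = 1.73,
             open_chrom = 3.00, antisense = -0.15)
  structure(list(intercept = -4.94, coefficients = coefs,
                 meta = list(source = "published equation")),
            class = "g4_model")
}

#' @export
print.g4_model <- function(x, ...) {
  cat("g4_model: logit P(high expression)\n")
  cat(sprintf("  intercept  %+.4f\n", x$intercept))
  for (nm in names(x$coefficients))
    cat(sprintf("  %-10s %+.4f\n", nm, x$coefficients[[nm]]))
  invisible(x)
}

#' Build the eight binary per-gene features
#'
#' Upstream indicators are the one-hot encoding of the gene's upstream
#' label from [label_genes()] (`noG4` maps to all three zero), so at most
#' one of the three is 1. Track indicators are 1 iff the gene's 10-kb
#' upstream window overlaps the track by at least 1 bp. The antisense
#' indicator comes from [antisense_flag()].
#'
#' @param genes gene table.
#' @param groups an `EvidenceGroups` object.
#' @param tracks named list of `GRanges` with elements `cgi`, `enhancer`,
#'   `se`, `open_chrom`.
#' @param chrom_lengths optional chromosome lengths for window clipping.
#' @param upstream upstream window width in bp.
#' @return integer 0/1 matrix, genes x 8, rownames `gene_id`, columns in
#'   [g4_feature_names()] order.
#' @export
build_features <- function(genes, groups, tracks, chrom_lengths = NULL,
                           upstream = 10000) {
  need <- c("cgi", "enhancer", "se", "open_chrom")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) stop("tracks missing: ", paste(miss, collapse = ", "))
  lab <- label_genes(genes, groups, "upstream", chrom_lengths,
                     upstream = upstream)$label
  win <- gene_windows(genes, "upstream", upstream, chrom_lengths)
  win <- win[genes$gene_id]
  hit <- function(tr) as.integer(
    GenomicRanges::countOverlaps(win, tr, ignore.strand = TRUE) > 0)
  m <- cbind(g4I_up = as.integer(lab == "G4-I"),
             g4II_up = as.integer(lab == "G4-II"),
             g4III_up = as.integer(lab == "G4-III"),
             enhancer = hit(tracks$enhancer),
             se = hit(tracks$se),
             cgi = hit(tracks$cgi),
             open_chrom = hit(tracks$open_chrom),
             antisense = as.integer(antisense_flag(genes, groups$g4_II)))
  rownames(m) <- genes$gene_id
  m
}

#' Binary expression labels from RPKM quantiles
#'
#' Top `quantile` fraction of genes by expression labeled 1 ("high"),
#' bottom fraction labeled 0 ("low"), middle excluded; `k = floor(n * q)`
#' genes on each side so the classes balance. Ranking is by
#' `(rpkm, gene_id)` ascending, so ties at either cut are broken by
#' lexicographic gene id, deterministically; labels are invariant to any
#' monotone transform of RPKM.
#'
#' @param expr data.frame with `gene_id` and `rpkm`.
#' @param quantile fraction per tail, default 0.25.
#' @return named integer vector (0/1) over the labeled genes.
#' @export
make_labels <- function(expr, quantile = 0.25) {
  n <- nrow(expr)
  if (n < 8) stop("need at least 8 genes")
  if (length(unique(expr$rpkm)) == 1L)
    stop("all expression values equal: no quantile separation")
  k <- floor(n * quantile)
  ord <- order(expr$rpkm, expr$gene_id)
  low <- expr$gene_id[ord[seq_len(k)]]
  high <- expr$gene_id[ord[seq(n - k + 1, n)]]
  stats::setNames(c(rep(0L, k), rep(1L, k)), c(low, high))
}

#' Stratified train/test split
#'
#' Random 7:3 (by default) split of labeled genes, stratified so the 1:1
#' class balance holds in both partitions; deterministic under a fixed
#' seed.
#'
#' @param labels named 0/1 vector from [make_labels()].
#' @param train_frac fraction of each class assigned to training.
#' @param seed integer RNG seed.
#' @return list with `train` and `test`, each a named 0/1 vector.
#' @export
split_labels <- function(labels, train_frac = 0.7, seed = 1) {
  ids1 <- names(labels)[labels == 1]; ids0 <- names(labels)[labels == 0]
  if (length(ids1) < 2 || length(ids0) < 2)
    stop("a class is too small to stratify")
  set.seed(as.integer(seed))
  tr1 <- sample(ids1, round(length(ids1) * train_frac))
  tr0 <- sample(ids0, round(length(ids0) * train_frac))
  tr <- c(tr1, tr0)
  te <- setdiff(c(ids1, ids0), tr)
  list(train = labels[tr], test = labels[te])
}

#' Fit the elastic-net logistic expression model
#'
#' Penalized logistic regression of high/low expression on the eight
#' binary indicators, mixing L1 and L2 penalties (`alpha`, default 0.5);
#' the penalty strength `lambda` is chosen by `nfolds`-fold
#' cross-validation (`lambda.min`). Fold assignment is drawn from `seed`,
#' so the fit is reproducible. A constant feature triggers a warning but
#' is retained (the penalty handles it).
#'
#' @param x 0/1 feature matrix with columns [g4_feature_names()].
#' @param y 0/1 labels aligned with `x` rows (or named; matched by name
#'   when both are named).
#' @param alpha elastic-net mixing parameter in `[0, 1]`.
#' @param nfolds cross-validation folds, default 10.
#' @param seed integer RNG seed.
#' @return A `g4_model` with `intercept`, `coefficients` and `meta`
#'   (alpha, lambda, nfolds, seed, n).
#' @export
fit_expression_model <- function(x, y, alpha = 0.5, nfolds = 10, seed = 1) {
  if (!is.null(names(y)) && !is.null(rownames(x)))
    x <- x[names(y), , drop = FALSE]
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  if (min(table(y)) < nfolds)
    stop("need at least nfolds samples per class")
  cv <- apply(x, 2, function(col) stats::var(col))
  if (any(cv == 0))
    warning("constant feature(s): ",
            paste(colnames(x)[cv == 0], collapse = ", "))
  set.seed(as.integer(seed))
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  fit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                           foldid = foldid, standardize = FALSE)
  co <- as.numeric(stats::coef(fit, s = "lambda.min"))
  names(co) <- c("(Intercept)", colnames(x))
  structure(list(intercept = co[[1]],
                 coefficients = co[-1],
                 meta = list(alpha = alpha, lambda = fit$lambda.min,
                             nfolds = nfolds, seed = seed, n = nrow(x)),
                 cv_fit = fit),
            class = "g4_model")
}

#' Linear predictor (log-odds) of the expression model
#'
#' `y = intercept + sum_i coefficient_i * delta_i`. Affine in the
#' indicator vector; the all-zero vector returns the intercept.
#'
#' @param model a `g4_model`.
#' @param fv a numeric vector of 8 indicators, or a matrix with one row
#'   per gene (columns matched to [g4_feature_names()] by name when
#'   present).
#' @return numeric log-odds, one per row of `fv`.
#' @export
predict_logodds <- function(model, fv) {
  stopifnot(inherits(model, "g4_model"))
  if (is.null(dim(fv))) fv <- matrix(fv, nrow = 1,
                                     dimnames = list(NULL, names(fv)))
  if (!is.null(colnames(fv)))
    fv <- fv[, names(model$coefficients), drop = FALSE]
  if (ncol(fv) != length(model$coefficients))
    stop("feature vector length mismatch")
  as.numeric(model$intercept + fv %*% model$coefficients)
}

#' Evaluate a fitted model on a test set
#'
#' Class predicted at probability 0.5; AUC by the rank (Mann-Whitney)
#' statistic over the test scores, so an all-tied score vector gives 0.5.
#'
#' @param model a `g4_model`.
#' @param x test feature matrix.
#' @param y test 0/1 labels (both classes must be present).
#' @return list with `accuracy`, `confusion` (2x2 table, truth in rows),
#'   `auc`, `n`.
#' @export
evaluate_model <- function(model, x, y) {
  if (!is.null(names(y)) && !is.null(rownames(x)))
    x <- x[names(y), , drop = FALSE]
  if (length(y) == 0L) stop("empty test set")
  if (length(unique(y)) < 2L) stop("AUC undefined on a single-class test set")
  lo <- predict_logodds(model, x)
  pred <- as.integer(stats::plogis(lo) >= 0.5)
  conf <- table(factor(y, levels = c(0, 1)), factor(pred, levels = c(0, 1)),
                dnn = c("truth", "predicted"))
  r <- rank(lo)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(accuracy = mean(pred == y), confusion = conf, auc = auc,
       n = length(y))
}

#' Write model coefficients as TSV
#'
#' @param model a `g4_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_tsv <- function(model, path) {
  df <- data.frame(term = c("(Intercept)", names(model$coefficients)),
                   estimate = c(model$intercept,
                                unname(model$coefficients)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
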