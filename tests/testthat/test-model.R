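test_that("the published equation evaluates as printed", {
  m <- g4_printed_model()
  expect_equal(predict_logodds(m, rep(0, 8)), -4.94)
  expect_equal(predict_logodds(m, rep(1, 8)), 2.72)
  v <- stats::setNames(rep(0, 8), g4_feature_names())
  v["open_chrom"] <- 1
  expect_equal(predict_logodds(m, v), -1.94)
  # affine in disjoint-support indicators: y(a) + y(b) - y(0) = y(a+b)
  a <- stats::setNames(c(1, 0, 0, 0, 0, 1, 0, 0), g4_feature_names())
  b <- stats::setNames(c(0, 0, 0, 1, 0, 0, 1, 0), g4_feature_names())
  expect_equal(predict_logodds(m, a) + predict_logodds(m, b) -
                 predict_logodds(m, rep(0, 8)),
               predict_logodds(m, a + b))
})

test_that("feature building is one-hot and matches simulator truth", {
  fx <- sim_fixture()
  f <- build_features(fx$sim$genes, fx$groups, fx$sim$tracks,
                      fx$chrom_lengths)
  expect_equal(colnames(f), g4_feature_names())
  expect_true(all(f %in% c(0L, 1L)))
  expect_true(all(rowSums(f[, c("g4I_up", "g4II_up", "g4III_up")]) <= 1))
  expect_equal(f, fx$sim$truth$features[rownames(f), colnames(f)])
})

test_that("labels take the quartile tails with deterministic ties", {
  expr <- data.frame(gene_id = paste0("g", 1:8), rpkm = c(1:8) * 1.0)
  lab <- make_labels(expr)
  expect_equal(sum(lab == 1), 2)
  expect_equal(sum(lab == 0), 2)
  expect_setequal(names(lab)[lab == 1], c("g7", "g8"))
  expect_setequal(names(lab)[lab == 0], c("g1", "g2"))
  # monotone-transform invariance
  expr2 <- expr; expr2$rpkm <- log1p(expr$rpkm)
  expect_identical(make_labels(expr2), lab)
  # ties at the cut break lexicographically
  e3 <- data.frame(gene_id = c("a", "b", "c", "d", "e", "f", "g", "h"),
                   rpkm = c(0, 0, 0, 5, 5, 9, 9, 9))
  l3 <- make_labels(e3)
  expect_setequal(names(l3)[l3 == 0], c("a", "b"))
  expect_setequal(names(l3)[l3 == 1], c("h", "g"))
  expect_error(make_labels(data.frame(gene_id = letters[1:8],
                                      rpkm = rep(2, 8))), "equal")
  expect_error(make_labels(expr[1:5, ]), "at least 8")
})

test_that("stratified split is balanced and seed-deterministic", {
  labels <- stats::setNames(rep(c(0L, 1L), each = 100),
                            sprintf("g%03d", 1:200))
  sp <- split_labels(labels, 0.7, seed = 5)
  expect_equal(sum(sp$train == 1), 70)
  expect_equal(sum(sp$train == 0), 70)
  expect_equal(sum(sp$test == 1), 30)
  sp2 <- split_labels(labels, 0.7, seed = 5)
  expect_identical(sp, sp2)
  sp3 <- split_labels(labels, 0.7, seed = 6)
  expect_false(identical(names(sp$train), names(sp3$train)))
  expect_error(split_labels(stats::setNames(c(0L, 1L), c("a", "b"))),
               "stratify")
})

test_that("evaluation handles perfect separation and all-tied scores", {
  m <- g4_printed_model()
  x <- rbind(matrix(0, 5, 8), matrix(1, 5, 8))
  colnames(x) <- g4_feature_names()
  y <- rep(c(0L, 1L), each = 5)
  ev <- evaluate_model(m, x, y)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(ev$auc, 1.0)
  expect_equal(as.vector(ev$confusion), c(5, 0, 0, 5))
  # all-equal scores give AUC 0.5 under the rank tie convention
  x0 <- matrix(0, 10, 8); colnames(x0) <- g4_feature_names()
  ev0 <- evaluate_model(m, x0, rep(c(0L, 1L), 5))
  expect_equal(ev0$auc, 0.5)
  expect_error(evaluate_model(m, x0, rep(1L, 10)), "single-class")
})

test_that("fit warns on constant features and is seed-reproducible", {
  co <- simulate_feature_cohort(600, seed = 51)
  x <- co$features; x[, "se"] <- 0L
  expect_warning(f1 <- fit_expression_model(x, co$class, seed = 52),
                 "constant")
  suppressWarnings({
    f2 <- fit_expression_model(x, co$class, seed = 52)
  })
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$intercept, f2$intercept)
})

test_that("features independent of labels give chance AUC", {
  nul <- simulate_feature_cohort(2000, seed = 21, null_labels = TRUE)
  sp <- split_labels(nul$class, 0.7, seed = 22)
  fit <- fit_expression_model(nul$features[names(sp$train), ], sp$train,
                              seed = 23)
  ev <- evaluate_model(fit, nul$features[names(sp$test), ], sp$test)
  expect_gte(ev$auc, 0.45)
  expect_lte(ev$auc, 0.55)
})
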