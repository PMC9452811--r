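hand_gene <- data.frame(gene_id = "g1", chrom = "c", strand = "+",
                        tx_start = 20000, tx_end = 30000,
                        cds_start = 21000, cds_end = 29000,
                        stringsAsFactors = FALSE)

test_that("feature map lays out the hand example on both strands", {
  fm <- build_feature_map(hand_gene, c(c = 100000))
  b <- function(k) as_bed_df(fm$classes[[k]])
  expect_equal(b("upstream10kb")[, c("start", "end")],
               data.frame(start = 10000, end = 20000))
  expect_equal(b("utr5")$start, 20000); expect_equal(b("utr5")$end, 21000)
  expect_equal(b("utr3")$start, 29000); expect_equal(b("utr3")$end, 30000)
  expect_equal(b("exon")$start, 21000); expect_equal(b("exon")$end, 29000)
  expect_equal(b("downstream2kb")$start, 30000)
  expect_equal(b("downstream2kb")$end, 32000)
  expect_equal(sum(fm$lengths), 100000)   # classes tile the genome
  gm <- hand_gene; gm$strand <- "-"
  fm2 <- build_feature_map(gm, c(c = 100000))
  expect_equal(as_bed_df(fm2$classes$upstream10kb)$start, 30000)
  expect_equal(as_bed_df(fm2$classes$upstream10kb)$end, 40000)
})

test_that("gene beyond chromosome bounds is an input error", {
  expect_error(build_feature_map(hand_gene, c(c = 25000)), "bounds")
})

test_that("precedence resolves overlaps once, matching a per-base oracle", {
  # gene B's upstream overlaps gene A's exon
  genes <- rbind(hand_gene,
                 data.frame(gene_id = "g2", chrom = "c", strand = "+",
                            tx_start = 36000, tx_end = 40000,
                            cds_start = 36500, cds_end = 39500))
  fm <- build_feature_map(genes, c(c = 100000))
  expect_equal(sum(fm$lengths), 100000)
  # pairwise disjoint
  all_cls <- do.call(c, unname(lapply(fm$classes, identity)))
  expect_equal(merged_length(all_cls), 100000)
  # per-base oracle with explicit precedence
  oracle <- rep("intergenic", 100000)
  paint <- function(lab, s, e) {
    idx <- (s + 1):e
    free <- oracle[idx] == "intergenic"
    oracle[idx[free]] <<- lab
  }
  for (g in seq_len(nrow(genes))) {
    r <- genes[g, ]
    paint("upstream10kb", r$tx_start - 10000, r$tx_start)
  }
  for (g in seq_len(nrow(genes))) {
    r <- genes[g, ]
    paint("utr5", r$tx_start, r$cds_start)
  }
  for (g in seq_len(nrow(genes))) {
    r <- genes[g, ]
    paint("utr3", r$cds_end, r$tx_end)
  }
  for (g in seq_len(nrow(genes))) {
    r <- genes[g, ]
    paint("exon", r$cds_start, r$cds_end)
  }
  for (g in seq_len(nrow(genes))) {
    r <- genes[g, ]
    paint("downstream2kb", r$tx_end, r$tx_end + 2000)
  }
  for (k in names(fm$classes))
    expect_equal(merged_length(fm$classes[[k]]), sum(oracle == k), info = k)
})

test_that("midpoint assignment is unique and fractions sum to 1", {
  fm <- build_feature_map(hand_gene, c(c = 100000))
  expect_equal(assign_region(interval_set("c", 19990, 20010), fm), "utr5")
  expect_equal(assign_region(interval_set("c", 60000, 60040), fm),
               "intergenic")
  set.seed(21)
  d <- random_intervals(100, 99000)
  lab <- assign_region(interval_set("c", d$start, d$end), fm)
  expect_length(lab, 100)
  expect_equal(sum(table(lab) / 100), 1)
})

test_that("density follows the BPKB formula and a per-base oracle", {
  genes <- data.frame(gene_id = "g", chrom = "c", strand = "+",
                      tx_start = 4000, tx_end = 8000,
                      cds_start = 4000, cds_end = 8000)
  fm <- build_feature_map(genes, c(c = 10000), upstream = 4000,
                          downstream = 1000)
  g4s <- interval_set("c", c(500, 1500, 3950), c(600, 1600, 4050),
                      strand = "+")
  gr <- classify_g4(g4s, interval_set("c", 0, 10000))
  dt <- density_table(gr, fm)
  up <- dt[dt$group == "G4-II" & dt$class == "upstream10kb", ]
  # overlaps: 100 + 100 + 50 of the boundary-spanning G4
  expect_equal(up$overlap_bp, 250)
  expect_equal(up$density_bpkb, 1000 * 250 / 4000)
  ex <- dt[dt$group == "G4-II" & dt$class == "exon", ]
  expect_equal(ex$overlap_bp, 50)   # spanning G4 contributes to both sides
  # class with no G4
  expect_equal(dt$density_bpkb[dt$group == "G4-II" &
                                 dt$class == "downstream2kb"], 0)
  # per-base oracle on the toy genome
  mask_g4 <- bp_mask(data.frame(start = c(500, 1500, 3950),
                                end = c(600, 1600, 4050)), 10000)
  for (k in names(fm$classes)) {
    mk <- if (merged_length(fm$classes[[k]]) == 0) logical(10000)
          else bp_mask(as_bed_df(fm$classes[[k]]), 10000)
    row <- dt[dt$group == "G4-II" & dt$class == k, ]
    expect_equal(row$overlap_bp, sum(mask_g4 & mk), info = k)
  }
  # zero-length class is undefined, not zero
  expect_true(is.na(dt$density_bpkb[dt$class == "intron"][1]))
})

test_that("TSS profile uses gene-oriented signed distance", {
  genes <- rbind(hand_gene,
                 data.frame(gene_id = "g2", chrom = "c", strand = "-",
                            tx_start = 50000, tx_end = 60000,
                            cds_start = 50000, cds_end = 60000))
  # one G4 midpoint exactly at the + TSS, one 500 bp 5' of the - TSS
  g4s <- interval_set("c", c(19995, 60489), c(20005, 60509), strand = "+")
  gr <- classify_g4(g4s, interval_set("c", 0, 100000))
  pr <- tss_profile(gr, genes)
  at0 <- pr[pr$bin_start == 0, ]
  expect_equal(at0$`G4-II`, 1)
  atm500 <- pr[pr$bin_start == -500, ]
  expect_equal(atm500$`G4-II`, 1)
  expect_equal(sum(pr$`G4-II`), 2)  # conservation within the window
  expect_error(tss_profile(gr, genes, bin_size = 333), "evenly")
})
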