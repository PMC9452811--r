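mk_groups2 <- function(g4_I = NULL, g4_II = NULL, g4_III = NULL) {
  gr0 <- function(x) if (is.null(x)) GenomicRanges::GRanges() else x
  structure(list(g4_I = gr0(g4_I), g4_II = gr0(g4_II),
                 g4_III = gr0(g4_III), n_supporting_peaks = 0L),
            class = "EvidenceGroups")
}

test_that("overlap ratio counts members touching the track", {
  s <- (0:9) * 100
  group <- interval_set("c", s, s + 50, strand = "+")
  track <- interval_set("c", c(20, 120, 230), c(30, 130, 260))
  expect_equal(overlap_ratio(group, track), 0.3)
  expect_equal(overlap_ratio(group, interval_set("c", 0, 10000)), 1.0)
  expect_error(overlap_ratio(GenomicRanges::GRanges(), track), "empty")
  # monotone in the track
  bigger <- c(track, interval_set("c", 330, 360))
  expect_gte(overlap_ratio(group, bigger), overlap_ratio(group, track))
  # brute-force membership count
  set.seed(41)
  dg <- random_intervals(25, 2000); dt_ <- random_intervals(10, 2000)
  g <- interval_set("c", dg$start, dg$end)
  tr <- interval_set("c", dt_$start, dt_$end)
  brute <- mean(vapply(seq_len(nrow(dg)), function(i)
    any(pmax(dg$start[i], dt_$start) < pmin(dg$end[i], dt_$end)),
    logical(1)))
  expect_equal(overlap_ratio(g, tr), brute)
})

test_that("TF Jaccard matrix matches pairwise jaccard and flags > 0.1", {
  gII <- interval_set("c", c(100, 300), c(150, 360), strand = "+")
  gI <- interval_set("c", 1000, 1100)
  gIII <- interval_set("c", 2000, 2030, strand = "-")
  groups <- mk_groups2(g4_I = gI, g4_II = gII, g4_III = gIII)
  tfs <- list(same = gII, nowhere = interval_set("c", 5000, 5100))
  m <- tf_jaccard_matrix(groups, tfs)
  expect_equal(m$g4_II[m$tf == "same"], 1.0)
  expect_equal(unlist(m[m$tf == "nowhere", c("g4_I", "g4_II", "g4_III")]),
               c(g4_I = 0, g4_II = 0, g4_III = 0))
  expect_true(m$above_threshold[m$tf == "same"])
  expect_false(m$above_threshold[m$tf == "nowhere"])
  # agrees with jaccard_index cell by cell on random sets
  set.seed(42)
  tfs2 <- lapply(1:5, function(i) {
    d <- random_intervals(8, 3000); interval_set("c", d$start, d$end)
  })
  names(tfs2) <- paste0("tf", 1:5)
  m2 <- tf_jaccard_matrix(groups, tfs2)
  for (i in 1:5)
    expect_equal(m2$g4_II[i], jaccard_index(tfs2[[i]], gII))
})

test_that("coverage filter boundary is inclusive at 10", {
  rec <- data.frame(chrom = "c", start = 1:100 * 10, end = 1:100 * 10 + 2,
                    coverage = rep(c(10, 9, 30, 5, 12), 20),
                    beta = runif(100))
  kept <- filter_methyl(rec)
  expect_equal(nrow(kept), 60)
  expect_true(all(kept$coverage >= 10))
  expect_equal(nrow(filter_methyl(data.frame(coverage = 9, beta = 0.5))), 0)
})

test_that("methylation states partition [0,1] with inclusive cuts", {
  expect_equal(methyl_state(c(0.1, 0.9, 0.5, 0, 1)),
               c("hypo", "hyper", "intermediate", "hypo", "hyper"))
  expect_error(methyl_state(1.2), "outside")
  set.seed(43)
  b <- runif(200)
  st <- methyl_state(b)
  expect_true(all(st %in% c("hypo", "intermediate", "hyper")))
  expect_equal(sum(prop.table(table(st))), 1)
})

test_that("per-group methylation summary counts and densities", {
  gII <- interval_set("c", 0, 1000, strand = "+")
  gI <- interval_set("c", 500, 1500)
  groups <- mk_groups2(g4_I = gI, g4_II = gII)
  rec <- data.frame(chrom = "c",
                    start = c(100, 300, 600, 700, 900, 5000),
                    end = c(102, 302, 602, 702, 902, 5002),
                    coverage = 30,
                    beta = c(0.05, 0.05, 0.95, 0.5, 0.05, 0.05))
  s <- methyl_by_group(rec, groups)
  expect_equal(s$n_cpg[s$group == "G4-II"], 5)
  expect_equal(s$cpg_density[s$group == "G4-II"], 5.0)
  expect_equal(s$frac_hypo[s$group == "G4-II"] +
                 s$frac_intermediate[s$group == "G4-II"] +
                 s$frac_hyper[s$group == "G4-II"], 1)
  # CpG at 5000 is outside every group; multiply-covered CpGs count twice
  expect_equal(s$n_cpg[s$group == "G4-I"], 3)
  u <- methyl_by_group(rec, groups, unique_assignment = TRUE)
  expect_equal(u$n_cpg[u$group == "G4-I"], 0)
})

test_that("planted hypomethylation shows up strongest in G4-II", {
  fx <- sim_fixture()
  rec <- filter_methyl(fx$sim$methyl)
  s <- methyl_by_group(rec, fx$groups)
  expect_gt(s$frac_hypo[s$group == "G4-II"],
            s$frac_hypo[s$group == "G4-I"])
  expect_gt(s$frac_hypo[s$group == "G4-II"],
            s$frac_hypo[s$group == "G4-III"])
  fr <- s[, c("frac_hypo", "frac_intermediate", "frac_hyper")]
  expect_equal(rowSums(fr), rep(1, 3), ignore_attr = TRUE)
})

test_that("telomere profile distances, cutoff and stream nesting", {
  gII <- interval_set("chr1", 4000, 6000, strand = "+")
  groups <- mk_groups2(g4_II = gII)
  rec <- data.frame(chrom = "chr1",
                    start = c(5000, 995000, 70000, 60000, 940001),
                    end = c(5002, 995002, 70002, 60002, 940003),
                    coverage = 30, beta = c(0.05, 0.95, 0.5, 0.5, 0.5))
  tp <- telomere_profile(rec, groups, c(chr1 = 1e6))
  # 5,000 from either end lands in the first bin; 70,000 is excluded
  expect_equal(tp$n_all[tp$bin_start == 0], 2)
  expect_equal(sum(tp$n_all), 4)         # 60 kb boundary inclusive
  expect_equal(tp$n_all[tp$bin_start == 50000], 2)
  expect_true(all(tp$n_g4 <= tp$n_all))
  expect_equal(tp$n_g4[tp$bin_start == 0], 1)
})
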