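test_that("feet extraction follows the strand convention and clips", {
  set.seed(61)
  gseq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  genome <- c(c = gseq)
  fp <- extract_feet(interval_set("c", 100, 120, strand = "+"), genome)
  expect_equal(fp$left, substr(gseq, 51, 100))
  expect_equal(fp$right, substr(gseq, 121, 170))
  fm <- extract_feet(interval_set("c", 100, 120, strand = "-"), genome)
  expect_equal(fm$left, rc_chr(fp$right))
  expect_equal(fm$right, rc_chr(fp$left))
  # edge clip
  f20 <- extract_feet(interval_set("c", 20, 40, strand = "+"), genome)
  expect_equal(nchar(f20$left), 20)
  expect_equal(nchar(f20$right), 50)
  expect_error(extract_feet(interval_set("c", 150, 260, strand = "+"),
                            genome), "outside")
  expect_error(extract_feet(interval_set("chrX", 0, 10, strand = "+"),
                            genome), "absent")
})

test_that("k-mer presence is per-site and matches a substring scan", {
  feet <- data.frame(
    g4_id = c("a", "b", "c", "d"),
    left = c("GCGCGCAAAA", "AAAAAAAAAA", "GCGCGCTTTT", "AAAAAAAAAA"),
    right = c("TTTTTTTTTT", "TTTTTTTTTT", "GCGCGCGCGC", "TTTTTTTTTT"),
    stringsAsFactors = FALSE)
  kp <- kmer_presence(feet)
  expect_equal(nrow(kp), 4096)
  expect_equal(kp$freq[kp$kmer == "GCGCGC"], 0.5)   # sites a and c
  expect_equal(kp$freq[kp$kmer == "CCCCCC"], 0)
  expect_equal(attr(kp, "n_sites"), 4)
  # brute-force substring scan on random feet
  set.seed(62)
  rf <- make_feet(30, 0)
  kp2 <- kmer_presence(rf)
  brute <- vapply(kp2$kmer, function(m)
    mean(grepl(m, rf$left, fixed = TRUE) | grepl(m, rf$right, fixed = TRUE)),
    numeric(1))
  expect_equal(kp2$freq, unname(brute[kp2$kmer]))
  # frequencies invariant to foot order
  swapped <- rf; swapped$left <- rf$right; swapped$right <- rf$left
  expect_equal(kmer_presence(swapped)$freq, kp2$freq)
  # feet shorter than k contribute no k-mers
  short <- data.frame(g4_id = "s", left = "ACG", right = "")
  expect_equal(sum(kmer_presence(short)$count), 0)
})

test_that("binomial enrichment matches closed form and enumeration", {
  mk <- function(count, n) {
    t <- data.frame(kmer = "AAAAAA", count = count, freq = count / n)
    attr(t, "n_sites") <- n
    t
  }
  e <- kmer_enrichment(mk(10, 10), mk(5, 10))
  expect_equal(e$p, 2^-10, tolerance = 1e-12)
  e0 <- kmer_enrichment(mk(0, 10), mk(5, 10))
  expect_equal(e0$p, 1.0)
  # exhaustive enumeration of all outcome sequences, N <= 12
  set.seed(63)
  for (i in 1:5) {
    N <- sample(4:12, 1); k <- sample(0:N, 1)
    nb <- sample(3:10, 1); cb <- sample(1:nb, 1)
    e2 <- kmer_enrichment(mk(k, N), mk(cb, nb))
    pb <- max(cb / nb, 1 / (2 * nb))
    expect_equal(e2$p, binom_tail_enum(k, N, pb), tolerance = 1e-10)
  }
  # monotone decreasing p in the observed count
  ps <- vapply(0:10, function(k) kmer_enrichment(mk(k, 10), mk(3, 10))$p,
               numeric(1))
  expect_true(all(diff(ps) <= 0))
  # swapping target and background inverts fe when no floor binds
  a <- mk(6, 10); b <- mk(3, 10)
  expect_equal(kmer_enrichment(a, b)$fe * kmer_enrichment(b, a)$fe, 1)
  expect_error(kmer_enrichment(mk(0, 0), mk(3, 10)), "empty")
})

test_that("significance filters are strict as printed", {
  res <- data.frame(kmer = c("a", "b", "c", "d"),
                    freq_target = c(0.3, 0.3, 0.3, 0.019),
                    freq_background = 0.01,
                    n_target = 1, N_target = 10,
                    fe = c(30, 30, 4.0, 30),
                    p = 1e-9,
                    p_adj = c(1e-6, 0.05, 1e-6, 1e-6))
  kept <- filter_significant(res)
  expect_equal(kept$kmer, "a")   # b: p_adj == 0.05; c: fe == 4; d: freq
})

test_that("greedy clustering aligns, splits and conserves weight", {
  cl <- cluster_motifs(c("GCGCGC", "CGCGCG"), c(0.3, 0.2))
  expect_length(cl, 1)
  expect_equal(ncol(cl[[1]]$pfm), 7)
  expect_equal(sum(cl[[1]]$pfm), (0.3 + 0.2) * 6)
  cl2 <- cluster_motifs(c("GCGCGC", "TATATC"), c(0.3, 0.2))
  expect_length(cl2, 2)
  cl3 <- cluster_motifs("GGGGGG", 0.5)
  expect_length(cl3, 1)
  expect_true(all(colSums(cl3[[1]]$pfm) == 0.5))
  expect_true(all(cl3[[1]]$pfm["G", ] == 0.5))
  # every k-mer lands in exactly one cluster; total weight conserved
  set.seed(64)
  km <- unique(vapply(1:12, function(i)
    paste(sample(c("G", "C", "A"), 6, replace = TRUE), collapse = ""),
    character(1)))
  fr <- runif(length(km), 0.02, 0.3)
  cls <- cluster_motifs(km, fr)
  members <- unlist(lapply(cls, function(cl) cl$members$kmer))
  expect_setequal(members, km)
  expect_equal(anyDuplicated(members), 0)
  expect_equal(sum(vapply(cls, function(cl) sum(cl$pfm), numeric(1))),
               sum(fr) * 6)
})

test_that("MEME export writes normalized probability columns", {
  cl <- cluster_motifs(c("GCGCGC", "CGCGCG"), c(0.3, 0.2))
  p <- withr::local_tempfile(fileext = ".meme")
  write_meme_pfm(cl, p)
  lines <- readLines(p)
  expect_true(any(grepl("^MEME version", lines)))
  expect_true(any(grepl("^MOTIF cluster1", lines)))
  probs <- read.table(text = lines[grep("^[0-9.]+ ", lines)])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
})
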