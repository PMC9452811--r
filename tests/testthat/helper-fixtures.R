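# Shared fixtures, built once per test run.

.fix <- new.env(parent = emptyenv())

# default-world simulation plus its predictions and evidence groups
sim_fixture <- function() {
  if (is.null(.fix$sim)) {
    .fix$sim <- simulate_g4_data(sim_config(seed = 42))
    .fix$pred <- g4_predict_genome(.fix$sim$genome)
    .fix$groups <- classify_g4(.fix$pred, .fix$sim$peaks)
    .fix$chrom_lengths <- stats::setNames(
      Biostrings::width(.fix$sim$genome), names(.fix$sim$genome))
  }
  list(sim = .fix$sim, pred = .fix$pred, groups = .fix$groups,
       chrom_lengths = .fix$chrom_lengths)
}

# a smaller, faster world for tests that need several independent runs
small_config <- function(seed, ...) {
  sim_config(chrom_lengths = c(chrA = 250000), n_genes = 14,
             n_intergenic = 15, seed = seed, ...)
}

# per-base boolean-array oracle for interval algebra on one toy chromosome
# (intervals given 0-based half-open on a chromosome of length len)
bp_mask <- function(df, len) {
  m <- logical(len)
  for (i in seq_len(nrow(df))) m[(df$start[i] + 1):df$end[i]] <- TRUE
  m
}

# random interval data.frame on a toy chromosome
random_intervals <- function(n, len, max_w = 120) {
  s <- sample.int(len - max_w, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  data.frame(start = s, end = pmin(s + w, len))
}

rc_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# exhaustive upper-tail binomial: enumerate all 2^N outcome sequences
binom_tail_enum <- function(k, N, p) {
  if (k <= 0) return(1)
  total <- 0
  for (code in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(code))[1:N]
    s <- sum(bits)
    if (s >= k) total <- total + p^s * (1 - p)^(N - s)
  }
  total
}

# exhaustive upper-tail hypergeometric by enumerating all C(N, n) draws
hyper_tail_enum <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}

# feet table with a 6-mer planted in a given fraction of sites; the
# remaining sequence is A/T so no G/C k-mer arises by chance
make_feet <- function(n, planted_frac, kmer = "GCGCGC", width = 50) {
  left <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "T"), width, replace = TRUE), collapse = ""),
    character(1))
  right <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "T"), width, replace = TRUE), collapse = ""),
    character(1))
  n_pl <- round(n * planted_frac)
  if (n_pl > 0) {
    for (i in seq_len(n_pl)) {
      pos <- sample(width - nchar(kmer), 1)
      substr(left[i], pos, pos + nchar(kmer) - 1) <- kmer
    }
  }
  data.frame(g4_id = paste0("s", seq_len(n)), left = left, right = right,
             stringsAsFactors = FALSE)
}
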