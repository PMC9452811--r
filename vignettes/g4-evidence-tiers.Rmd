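---
title: "Evidence-tiered G-quadruplex analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-tiered G-quadruplex analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4tier)
```

## The problem

G-quadruplexes (G4s) are four-stranded DNA structures formed by stacked
guanine tetrads, with the sequence consensus
`G≥3 N1–7 G≥3 N1–7 G≥3 N1–7 G≥3`. Genome-wide G4 catalogs come from two
very different kinds of evidence: sequence-based prediction, which marks
everything that *could* fold, and ChIP-seq with structure-specific
antibodies, which marks what was *bound* in one cell state — subject to
antibody specificity. The two only partially agree. `g4tier` organizes
that disagreement into three tiers and carries the tiers through a
complete regulatory-genomics analysis: genomic distribution and density,
gene-expression association, epigenomic context, CpG methylation,
TF co-localization, a compact predictive model of expression, and
sequence enrichment in the G4 flanks ("feet").

Tier definitions, applied by `classify_g4()` with a 1-bp minimum
overlap:

* **G4-II** — predictions overlapping at least one peak. The
  *prediction* intervals are the units (predictions typically outnumber
  the peaks that certify them, and keep strand information that peaks
  lack).
* **G4-III** — the remaining predictions.
* **G4-I** — peaks overlapping no prediction. A peak that certifies any
  prediction contributes nothing to G4-I, even its non-overlapping
  portion.

This makes `|G4-II| + |G4-III| = |predictions|` an exact invariant, and
makes G4-II monotone non-decreasing (G4-III non-increasing) in the peak
set — both are tested properties.

## Prediction by run-length scoring

`g4_base_scores()` assigns each base an integer: a G in a maximal run of
`r` G's scores `+min(r, 4)`, a C scores `−min(r, 4)` analogously, A/T/N
score 0, and N breaks runs. Note the consequence that an isolated G
scores +1 (not 0): the rule is about runs, and a run can have length 1.
`g4_predict()` slides a `window`-bp window (default 25, odd) and keeps
windows whose mean score has absolute value at least `threshold`
(default 1.5). Overlapping or bookended qualifying windows of the same
sign merge; the reported interval spans the merged windows and the score
is the mean base score *recomputed over that span*. Positive means
plus-strand, negative minus.

Numerical notes:

* Re-scoring over the merged span can dip below the threshold when many
  marginal windows chain; we report the recomputed value rather than
  enforcing a post-merge bound, because the merged span — not any single
  window — is the object of interest. An optional `trim = TRUE` cuts the
  span to its outermost G (or C) anchors; it is off by default because
  the untrimmed span is the simplest defensible definition.
* The threshold that produced any published genome-wide site count is
  not recoverable from a count alone, so the threshold is an explicit,
  logged parameter of every run; nothing in the package tries to match a
  specific site total.
* Antisymmetry under reverse complement (mirrored intervals, flipped
  strand, negated score) is exact and is tested on random sequences.

## Genomic annotation and density

`build_feature_map()` tiles each chromosome into seven classes:
`upstream10kb` (strand-aware, 5′ of the TSS), `utr5`, `utr3`, `exon`
(CDS-overlapping exonic bases), `intron`, `downstream2kb`, `intergenic`.
Bases claimed by several genes are resolved once by the fixed precedence
`upstream10kb > utr5 > utr3 > exon > intron > downstream2kb >
intergenic`. The precedence had to be chosen (annotation tools differ
here); promoter-proximal classes win because the analysis is
promoter-centric, and the choice is documented so the per-base oracle
tests can assert it exactly. With precedence applied, the class lengths
sum to the genome length on every input — a tested invariant.

Two different assignment rules are used deliberately:

* `assign_region()` labels each G4 by the class containing its
  *midpoint*, so every site gets exactly one label and per-class
  fractions sum to 1.
* `density_table()` instead uses full overlap widths:
  `D_k = 1000 · ΣW_i / L_k` (bp of G4 per kb of class, "BPKB"), where a
  boundary-spanning G4 contributes its overlap to each class it touches.
  A zero-length class yields `NA` (undefined), never 0.

`tss_profile()` bins signed midpoint-to-nearest-TSS distances in gene
orientation (negative = upstream) over `[-10000, 500)` by default.

## Gene association and enrichment

`label_genes()` applies the evidence hierarchy G4-II > G4-I > G4-III >
noG4 to a gene-anchored window: upstream (10 kb 5′ of the TSS, clipped
at position 0 and chromosome ends), body (transcript span), or
downstream (2 kb past the 3′ end). `antisense_flag()` is true when a
stranded G4-II site lies inside the half-open transcript span on the
strand opposite the gene — the transcription template, where a folded
G4 can stall the polymerase.

`compare_expression()` is a Welch two-sample *t*-test on
`log2(RPKM + 1)`. The source analysis says only "two-paired T-test";
since the compared gene sets are unpaired and of unequal size, the
Welch unpaired reading is the only coherent one, and the log scale is
standard for RPKM. Because quoted fold changes are raw-scale medians,
the raw `median(A)/median(B)` is reported alongside. When both sides are
constant, equal means return t = 0, p = 1 by convention.

`hypergeom_enrichment()` computes the exact upper tail
`P(X ≥ k)` for X hypergeometric(N, K, n) by summation; it reproduces the
worked example (k = 208 of n = 327 versus K = 8,923 of N = 17,420 gives
p ≈ 3.4 × 10⁻⁶) and matches exhaustive draw enumeration for N ≤ 12 to
12 decimals. Whether a given enrichment question should use the
G4-bearing gene universe or all coding genes as N is a scientific
choice left to the caller; the operation is generic.

## Methylation

β is the proportion of methylated reads at a CpG. Records need
`coverage ≥ 10` (inclusive) to be used; states are hypo (β ≤ 0.1),
hyper (β ≥ 0.9) — both boundaries inclusive, as stated — and
intermediate otherwise, a partition of [0, 1]. Only CpG context is
analyzed; readers drop CHG/CHH rows. A CpG covered by intervals of two
tiers counts in both by default, because tier interval sets can overlap
(G4-I is peak-shaped); `unique_assignment = TRUE` gives the
percentages-sum-to-100 variant with priority II > I > III.
`telomere_profile()` measures `min(pos, chrom_length − pos)`, keeps
CpGs within 60 kb of an end, and bins half-open 10-kb bins with the
final bin closed so a CpG at exactly 60 kb is retained.

## The expression model

Eight binary per-gene indicators, in fixed order: one-hot upstream tier
(`g4I_up`, `g4II_up`, `g4III_up`; `noG4` is the all-zero reference),
track presence on the 10-kb upstream window (`enhancer`, `se`, `cgi`,
`open_chrom`, ≥ 1 bp overlap), and `antisense`. Two design points were
genuinely open and are resolved as follows: the three upstream
indicators are the mutually exclusive hierarchy one-hot (matching how
the gene groups are defined) rather than independent presence flags;
and track indicators are computed on the upstream window, not on the G4
sites, because the model is per-gene.

Labels: top RPKM quartile = 1, bottom quartile = 0, middle excluded;
`floor(n·q)` genes per side so classes balance; ties at a cut break by
lexicographic gene id, so labels are deterministic and invariant to
monotone transforms of expression. The split is stratified 7:3 and
seed-deterministic.

Fitting uses glmnet's penalized logistic regression. The mixing
parameter defaults to `alpha = 0.5` (not reported by the source; only
the penalty strength is selected, by 10-fold cross-validation at
`lambda.min` with seed-derived fold ids). `standardize = FALSE` because
all predictors are 0/1 indicators on a common scale — standardizing
would silently up-weight rare features. Evaluation thresholds the
probability at 0.5 and computes AUC by the rank (Mann–Whitney)
statistic, so an all-tied score vector scores 0.5.

The published equation is packaged as `g4_printed_model()`; its linear
predictor at the all-zero vector is the intercept −4.94. Parameter
recovery is tested by drawing 8,000 genes from this model
(`simulate_feature_cohort()`) and refitting: all eight coefficient
signs match, Spearman ρ > 0.8 against the printed magnitudes, held-out
AUC ≥ 0.8. The smallest coefficient (antisense, −0.15) is the fragile
one under L1 shrinkage; `lambda.min` rather than `lambda.1se` is used
partly so that weak-but-real effects survive.

## G4 feet and 6-mer enrichment

Feet are the ±50-bp flanks of predicted sites, reported in G4 sense
orientation (for minus-strand sites both flanks are
reverse-complemented and swapped), clipped at chromosome ends, never
including G4 bases. `kmer_presence()` scores presence/absence per site
(a 6-mer in either foot counts that site once) — matching how
"occupied X% of feet" is naturally read — not occurrence counts.

`kmer_enrichment()` compares target and background tables:
`fe = f_t / max(f_b, floor)` with `floor = 1/(2·N_background)` to avoid
zero or infinite ratios, and `p = P(X ≥ n_t)`,
`X ~ Binomial(N_target, max(f_b, floor))`. Bonferroni uses the full
family of 4⁶ = 4,096 6-mers, each enrichment direction tested as its own
family (the two directions produce separate significant sets).
`filter_significant()` applies the stated strict cuts: adjusted
p < 0.05, F.E. > 4, target frequency > 0.02 — a k-mer sitting exactly on
any boundary is dropped.

The clustering of significant 6-mers into motif PFMs follows a greedy
scheme (the original procedure lives in a prior publication and is not
fully specified): seed with the highest-frequency unassigned 6-mer;
join a 6-mer when its best ungapped alignment to the cluster consensus
over shifts −2…+2 has ≥ 4 overlapping positions and ≤ 1 mismatch; add
frequency-weighted counts to the PFM; recompute the majority consensus
(ties alphabetical) after each join. Every significant 6-mer lands in
exactly one cluster and total PFM weight is conserved. PFMs are
exported in MEME minimal format.

## The synthetic world

`simulate_g4_data()` emulates every real input so the pipeline cannot
tell synthetic from real at the format level. Its defaults *are* the
stated world:

* Two 500-kb chromosomes; 56 single-exon genes in non-overlapping 16-kb
  slots (10 kb upstream + 3 kb body + 2 kb downstream + margin), so
  gene windows never interact and per-gene ground truth is exact.
* Background 60% A/T. At that GC content, incidental windows do pass the
  default predictor (about 17 per 600 kb measured empirically), which
  would blur planted-truth bookkeeping; the generator therefore
  *scrubs* the background — G/C bases inside any incidental qualifying
  window are rewritten to A/T before planting — so planted sites are
  the only predictions. Real genomes are of course not scrubbed; a green
  recovery test certifies the machinery, not genome-scale specificity.
* Planted G4s are exact consensus matches: four G-runs of 4, loops of
  1–7 bp. Run length 4 guarantees detection at the default window and
  threshold for every loop configuration (worst case mean ≈ 1.6 with
  maximal flanking C-runs). Loops of ≥ 2 bp begin with a CpG so
  confirmed sites are CpG-bearing — mirroring the observation that
  high-confidence G4 regions are the most CpG-dense — at a scoring cost
  of only −1 per loop C (the loop G joins the following run).
* Peaks capture each planting with probability `capture_rate` (default
  0.55, giving roughly the published mix of confirmed and
  predicted-only sites); false peaks (rate 0.15) are placed away from
  any prediction. Tier-specific methylation mixtures re-weight β within
  ±30 bp of plantings (hypo weight 0.744 for captured, 0.556/0.587 for
  the other tiers, 0.637 background — the published tier fractions);
  the ±30-bp pad exists because the motif interior alone carries too
  few CpGs to express the planted effect.
* Expression: the realized feature vector feeds the configured model
  (default: the printed equation); the high/low class is a Bernoulli
  draw of the logistic probability; `RPKM = exp(z)` with
  `z ~ N(0 or 2.5, 1)` by class — a separation chosen so a
  well-specified refit reaches AUC ≥ 0.8, echoing (not reproducing) the
  published performance.

What the generator does **not** emulate: read-level noise, peak-calling
artifacts, isoform structure, chromosome-scale composition
heterogeneity, LiftOver error, or antibody-specificity biology. A green
test on this world establishes that the operations compute what they
claim on well-formed inputs with known truth — not that the biological
conclusions transfer.

## Known limitations

* Genome-scale published counts (site totals, real-data AUC/accuracy)
  require the original ENCODE/GEO/CCLE inputs and are out of scope; the
  in-package checks are the desk-scale worked examples plus
  property/oracle suites.
* One canonical transcript per gene; no isoform resolution.
* The motif-clustering scheme is a documented stand-in for a procedure
  specified only by citation.
* `tss_profile()` computes nearest-TSS distances gene-by-gene; it is
  quadratic in the worst case and intended for cohort-scale, not
  whole-genome, use.
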