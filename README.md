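# g4tier

Evidence-tiered analysis of G-quadruplex (G4) sites in genomic context.

G-quadruplexes are four-stranded structures formed by stacked guanine
tetrads in G-rich DNA (consensus `G≥3 N1–7 G≥3 N1–7 G≥3 N1–7 G≥3`). Two
kinds of genome-wide evidence exist for them: sequence-based prediction
and ChIP-seq with structure-specific antibodies — and they disagree.
`g4tier` is built for regulatory genomicists who want to reconcile the
two: it partitions candidate sites into three evidence tiers and asks how
each tier relates to gene expression, epigenomic context, DNA methylation
and transcription-factor binding.

* **G4-I** — detected by ChIP-seq only (peak-shaped, unstranded),
* **G4-II** — predicted *and* ChIP-confirmed (the high-confidence tier;
  prediction coordinates and strand retained),
* **G4-III** — predicted only.

## What the package computes

* **Prediction** — a run-length scoring scheme: each G scores
  `+min(run, 4)`, each C `−min(run, 4)`; windows of `w = 25` bp whose
  mean absolute score reaches `T = 1.5` are called, merged per strand,
  and re-scored over the merged span (`g4_predict`, `g4_predict_genome`).
* **Classification & annotation** — tier partition against peaks
  (`classify_g4`); a seven-class genomic feature map (10 kb upstream,
  5′UTR, 3′UTR, exon, intron, 2 kb downstream, intergenic) with fixed
  precedence; G4 density in bp-per-kb, `D_k = 1000 · ΣW_i / L_k`
  (`density_table`); TSS-distance profiles.
* **Gene association** — per-gene tier labels by the hierarchy
  G4-II > G4-I > G4-III > noG4 on upstream/body/downstream windows
  (`label_genes`); antisense-G4 flags; Welch *t* comparisons of
  log2(RPKM+1); exact upper-tail hypergeometric enrichment.
* **Tracks & methylation** — per-site overlap ratios, TF/G4 Jaccard
  matrices, CpG β-value states (hypo β ≤ 0.1, hyper β ≥ 0.9), per-tier
  methylation summaries, telomere-proximal profiles.
* **Expression model** — eight binary per-gene indicators
  (three upstream tiers one-hot, enhancer/SE/CGI/open-chromatin on the
  upstream window, antisense G4) in an elastic-net logistic regression
  of high vs low expression (top/bottom RPKM quartiles). The published
  fitted equation ships as `g4_printed_model()`:

  ```
  y = −4.94 + 0.80·δG4-I:up + 1.60·δG4-II:up − 1.21·δG4-III:up
      + 0.56·δEnhancer + 1.33·δSE + 1.73·δCGI + 3.00·δOpenChrom
      − 0.15·δG4:Antisense
  ```

  where `y` is the log-odds that a gene is highly expressed.
* **G4 feet** — ±50 bp flanks of predicted sites in G4 sense
  orientation; per-site 6-mer presence frequencies; binomial fold
  enrichment with Bonferroni correction over all 4096 6-mers; the
  printed filters (adjusted p < 0.05, F.E. > 4, frequency > 0.02);
  greedy clustering of significant 6-mers into position-frequency
  matrices exported in MEME minimal format.
* **Synthetic data** — `simulate_g4_data()` generates every input
  (FASTA, peak/track/TF BEDs, gene table, methylation and expression
  TSVs) with planted ground truth, so the whole pipeline is testable
  without any external download.

## Worked example

```r
library(g4tier)

## 1. simulate a small multi-omics world and recover the planted G4s
sim    <- simulate_g4_data(sim_config(seed = 42))
pred   <- g4_predict_genome(sim$genome, window = 25, threshold = 1.5)
groups <- classify_g4(pred, sim$peaks)
print(groups)
#> EvidenceGroups
#>   G4-I   (ChIP only):         3
#>   G4-II  (ChIP + predicted):  49
#>   G4-III (predicted only):    47
#>   supporting peaks:           49
truth_report(sim$truth, pred, groups)[c("sensitivity", "precision")]
#> $sensitivity [1] 1    $precision [1] 1

## 2. the published worked enrichment example
hypergeom_enrichment(k = 208, n = 327, K = 8923, N = 17420)
#> Hypergeometric enrichment: k=208 of n=327 (K=8923 of N=17420), p = 3.44e-06

## 3. the published expression model at the all-zero feature vector
predict_logodds(g4_printed_model(), rep(0, 8))
#> [1] -4.94

## 4. refit the model on a cohort drawn from it
cohort <- simulate_feature_cohort(8000, g4_printed_model(), seed = 11)
sp  <- split_labels(cohort$class, 0.7, seed = 12)
fit <- fit_expression_model(cohort$features[names(sp$train), ],
                            sp$train, seed = 13)
round(fit$coefficients, 2)
#>     g4I_up    g4II_up   g4III_up   enhancer         se        cgi
#>       0.77       1.65      -1.06       0.59       1.11       1.88
#> open_chrom  antisense
#>       2.95      -0.01
evaluate_model(fit, cohort$features[names(sp$test), ],
               sp$test)[c("accuracy", "auc")]
#> $accuracy [1] 0.85    $auc [1] 0.8801433
```

The simulation recovers every planted site (sensitivity and precision
1.0 — planted consensus motifs always exceed the default threshold and
the background is screened of incidental hits), the printed worked
example reproduces its p-value, and a cohort drawn from the printed
equation refits with matching coefficient signs and a held-out AUC of
0.88.

## Command line

`inst/scripts/g4pipe.R` wraps the main stages:

```sh
Rscript inst/scripts/g4pipe.R simulate --out simdir --seed 7
Rscript inst/scripts/g4pipe.R predict  --fasta genome.fa --window 25 \
        --threshold 1.5 --out predictions.bed
Rscript inst/scripts/g4pipe.R classify --predictions predictions.bed \
        --peaks peaks.bed --out-prefix g4
Rscript inst/scripts/g4pipe.R run-all  --config run.json
```

`run_g4_pipeline()` (or `run-all`) executes predict → classify →
annotate → association → tracks → model → feet, writes one TSV per
result and a JSON manifest with parameters, seed and md5 checksums;
stages with missing inputs are skipped and recorded.

## Documentation

The methods vignette (`vignettes/g4-evidence-tiers.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and
the numerical/design choices made where the underlying procedure left
them open.
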