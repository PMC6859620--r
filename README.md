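# m6Aquadrant

Joint analysis of N6-methyladenosine (m6A) mRNA methylation and gene
expression from MeRIP-seq style count data, for epitranscriptomics studies
that compare paired conditions — tumour vs adjacent tissue, hypoxia vs
normoxia, knockdown vs control. The package targets the common design in
which each sample yields an antibody-enriched (IP) and an un-enriched
(input) sequencing fraction, quantified as read counts over windows tiled
along transcripts, plus a matched gene-level RNA-seq expression table.

## What it computes

* **Window enrichment and peak calling.** Each window's share of its
  transcript's IP reads is tested against its share of the input reads with
  a one-sided exact (hypergeometric) test on the 2×2 table
  `[ip, totalIP − ip; input, totalInput − input]`; windows with p < 0.05
  are merged into peaks (runs of ≥ 2 significant windows, bridging ≤ 1
  non-significant window).
* **Differential methylation.** Per peak, counts are pooled per condition
  and the two-sided exact test is applied to
  `[IP_B, input_B; IP_A, input_A]`; the methylation change is
  `log2(((IP_B+1)/(input_B+1)) / ((IP_A+1)/(input_A+1)))`, with
  Benjamini–Hochberg FDR control across peaks (hyper/hypo calls at
  p < 0.05 and q < 0.05).
* **Quadrant classification.** Genes carrying both a directional
  methylation change and a directional expression change (CPM fold change)
  are labelled hyper-up, hyper-down, hypo-up or hypo-down; per-patient
  percentages are averaged unweighted into a cohort summary. A
  high-frequency rule extracts hyper-up genes shared by ≥ 3 patients, and
  a two-list screen intersects genes > 2-fold up on two regulatory axes.
* **Gene-set enrichment.** A from-scratch weighted running-sum enrichment
  score (hits climb by `|score|/Σ|score|`, misses fall by `1/(N−N_hits)`;
  ES = signed maximum deviation), with gene-label permutation NES and
  p-value, and a built-in 14-gene hypoxia metagene signature.
* **RNA decay kinetics.** First-order fits of `N_t/N_0 = exp(−kt)` (zero
  intercept on the log scale), half-life `t½ = ln2/k`.
* **LC-MS/MS calibration.** Standard curves per nucleoside channel
  (m6A 282→150, A 268→136), inverted to calibrated concentrations and the
  m6A/A ratio; percent-input qPCR enrichment via `100 · 2^ΔCt`.
* **Synthetic cohorts.** A seeded generator plants ground-truth peaks,
  methylation shifts and expression changes in negative-binomial counts,
  so every stage above is testable end-to-end without any external data.

## Worked example

```r
library(m6Aquadrant)

cfg     <- simConfig(nTranscripts = 300, nPatients = 4, seed = 42)
gt      <- generateTruth(cfg)
windows <- simulateMeripWindows(gt$truth, gt$transcripts, cfg)
expr    <- simulateExpression(gt$truth, cfg)

peaks <- callPeaks(windows)                       # 177 peaks
segmentFractions(peaks, gt$transcripts)
#> $frac_utr5 0.124  $frac_cds 0.412  $frac_utr3 0.463  (n_peaks 177)

dp <- differentialMethylation(peaks, windows)
table(S4Vectors::mcols(dp)$direction)
#> hyper  hypo  none
#>    56    21   100

calls <- quadrantsByPatient(peaks, windows, expr, gt$transcripts)
round(quadrantPercentages(calls)$cohort_mean, 2)
#>   hyper-up hyper-down    hypo-up  hypo-down
#>      64.39       9.57      14.84      11.20

fitDecay(simulateDecaySeries(0.3, c(0, 1, 2, 4, 6, 8), cv = 0.05, seed = 42))
#> DecayFit: k = 0.3098 /h, t1/2 = 2.238 h, R^2(log) = 0.9981 (n = 6)
```

Reading the output: the simulated cohort plants 70% of its differential
transcripts as hyper-up, and the recovered cohort mean (64% here, at a
modest 300-transcript cohort) tracks that mixture; peaks concentrate in
the 3'UTR and CDS as configured; the decay fit recovers the planted rate
k = 0.3/h within its noise level. `runPipeline(pipelineConfig(seed = 1),
"out/")` chains all stages (simulate → peaks → differential → quadrants →
screen → GSEA → decay → MS quantification) and writes TSV/BED/JSON
outputs plus a run manifest.

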