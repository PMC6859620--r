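---
title: "Methods: differential m6A, quadrant classification and kinetics"
author: "m6Aquadrant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential m6A, quadrant classification and kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Aquadrant)
```

# Scope and data model

m6Aquadrant analyses MeRIP-seq style experiments in transcript
coordinates. Each transcript is described by its 5'UTR, CDS and 3'UTR
lengths and tiled end-to-end with half-open windows (default 50 nt; the
last window absorbs the remainder, and a transcript shorter than one
window gets a single covering window). The unit observation is a window's
IP and input read count in one sample. On disk all coordinates are
0-based half-open (including BED, which is natively so); in memory the
package uses ordinary 1-based `GRanges`/`SummarizedExperiment` containers,
and the readers/writers convert between the two conventions.

The package starts from count tables. Alignment, read-level processing
and genome-coordinate peak calling are out of scope, as are motif or
sequence models: peaks here are positional intervals only.

# Window enrichment and peak calling

For a window with counts `(ip, input)` on a transcript with totals
`(totalIP, totalInput)`, enrichment is tested one-sided on the 2×2 table
`[ip, totalIP − ip; input, totalInput − input]`, conditioning on all
margins; the p-value is the upper hypergeometric tail. The exact test was
chosen because it is well defined at any count scale and admits a
brute-force enumeration oracle — the test suite checks equality with an
exhaustive factorial-based enumeration on *all* tables with margins ≤ 12
at tolerance 1e-12. Odds ratios carry a pseudocount of 1 on all four
cells so they are always finite; the pseudocount is a parameter
everywhere it is used.

Peaks are called on counts pooled across *all* samples (conditions and
replicates summed). Windows with p < `alpha` (default 0.05) are merged
per transcript into maximal runs bridging at most `maxGap` (default 1)
non-significant windows; runs with fewer than `minRun` (default 2)
significant windows are discarded. The peak p-value is the minimum
window p; the peak enrichment is the pooled odds ratio of the run. Merged
peaks never overlap within a transcript (a tested invariant). Pooled
calling followed by a differential test is the simplest defensible design
when each condition has few libraries; calling per condition and
intersecting is a reasonable alternative the package does not implement.

# Differential methylation

Per peak, IP and input counts of the overlapping windows are summed per
condition and the two-sided exact test is applied to
`[IP_B, input_B; IP_A, input_A]` (two-sided = total probability of all
tables at most as probable as the observed one, the standard Fisher
convention). The methylation change is

```
log2_meth_fc = log2( ((IP_B + 1)/(input_B + 1)) / ((IP_A + 1)/(input_A + 1)) )
```

Benjamini–Hochberg q-values are computed across all peaks (`bhAdjust()`,
backed by `stats::p.adjust`; "FDR adjustment" names no particular
procedure, and BH is the field default). A peak is directional
(hyper/hypo) when p < 0.05 *and* q < 0.05, the two-threshold rule under
which differential peaks are typically displayed. A peak with zero counts
in both conditions reports p = 1 and direction `none` rather than an
error.

# Quadrant classification

Expression changes are counts-per-million fold changes with a 0.5-CPM
pseudocount, `log2((CPM_B + 0.5)/(CPM_A + 0.5))`, not a shrinkage DE
model: quadrant assignment needs a direction, and a deterministic,
dependency-free statistic keeps the classification transparent. The
direction threshold defaults to 0 (pure sign), so every altered
methylated transcript is classified; the candidate screen instead uses a
threshold of 1 (2-fold), the conventional screening cutoff.

A gene with several differential peaks takes the peak with the smallest
q-value (ties: larger |log2 fold change|, then leftmost start) — a
deterministic rule favouring the strongest evidence; how a transcript
carrying both hyper and hypo peaks should be labelled is genuinely open,
and this is the package's resolution. Per-patient percentages are
computed within each patient's calls and averaged *unweighted* across
patients (each patient is one biological replicate of the cohort
pattern; pooling would overweight patients with many calls). The
high-frequency rule keeps hyper-up genes shared by at least 3 patients.

# Gene-set enrichment

The enrichment score is the classic weighted running sum with weight
p = 1: walking down the list ranked by score (descending, ties broken by
input order), hits add `|score| / Σ_hits |score|`, misses subtract
`1/(N − N_hits)`, and ES is the signed maximum deviation. The null model
permutes gene labels (size-matched random sets), not phenotypes: the
package consumes a single ranked list, so phenotype permutation is
unsupported by construction. The p-value carries the +1 correction and is
never exactly 0; NES divides ES by the mean magnitude of same-sign null
scores, keeping the sign of ES (NES = 0 when ES = 0; if no same-sign
null exists the p-value is floored at `1/(1 + n_permutations)` and NES
is NA with a warning). Rankings built from expression tables use the CPM
log2 fold change above. The 14-gene hypoxia metagene signature ships
with the package (`hypoxiaSignature()`).

# Decay kinetics, calibration, percent input

Decay series are normalised so the abundance at t = 0 is exactly 1 and
fitted as `ln N_t = −k·t` with the intercept fixed at zero — the exact
log-linear form of first-order decay `N_t/N_0 = exp(−kt)`. Nonlinear
least squares would weight early timepoints differently but estimates
the same rate for the low-noise series this assay produces; the
log-linear fit is the single implementation. Half-life is `ln2/k`, taken
from the same fitted `k` (a tested identity). A non-decaying series is
returned flagged with infinite half-life, not an error, since growing
"decay" curves do occur in practice. R² is reported on the log scale.

Calibration curves are ordinary least squares with a *free* intercept —
instrument baselines are not zero — per channel, with channels fixed to
the two nucleoside-to-base transitions (m6A 282→150, A 268→136).
Inversion refuses non-positive calibrated concentrations, naming the
offending channel, rather than returning a negative ratio. Percent input
is `100 · 2^((Ct_input − log2(dilution)) − Ct_IP)` with a configurable
input dilution factor (default 1); no housekeeping normalisation is
applied.

# The synthetic cohort generator

`simConfig()` defaults define the emulated study: 8 patients each
contributing a paired normal-like (A) and tumour-like (B) sample; mean
segment lengths 200/1200/800 nt (typical mammalian mRNA architecture);
half of transcripts methylated, half of those differential; a quadrant
mixture of 70/10/10/10 dominated by hyper-up; 4-fold IP enrichment inside
peaks, an extra 2.5-fold shift for differential peaks, 2-fold expression
changes; 500 reads per transcript per sample; peak midpoints placed
10/35/55 across 5'UTR/CDS/3'UTR (the 3'UTR/CDS bias of m6A); one planted
peak of 2 windows per methylated transcript, wide enough to exercise run
merging. Counts are negative binomial; patient-level size factors
(log-normal, CV ≈ 15%) are shared by a patient's two samples, mirroring
the paired design.

The default dispersion is 0.01, the near-Poisson *technical* regime, and
this is a deliberate modelling decision: the paired comparison is one
tumour library against one paratumour library from the same patient, so
within the 2×2 tables the only variance is within-library measurement
noise — patient-to-patient biological variation enters through size
factors and the planted effects, not through the count model. Exact
conditional tests assume (near-)multinomial sampling; at
biological-replicate-scale dispersion (≈ 0.1) they become
anti-conservative, and FDR control degrades accordingly. This is a known
limitation of exact tests on overdispersed counts and the main caveat
when transferring the tested guarantees to real data: with strong
biological replication per condition, a dispersion-aware model (e.g. a
negative-binomial GLM) is the better differential engine.

What the generator does *not* emulate: sequence content (no DRACH
motifs), multiple peaks per transcript, isoforms, GC or length biases,
batch effects, or count correlation between IP and input beyond the
shared expression rate. Passing tests therefore demonstrate the
statistical machinery under the stated model, not robustness to every
artefact of real libraries.

Seeding: every stochastic function takes or derives an integer seed; the
pipeline expands one global seed into per-stage seeds by fixed offsets,
so stages rerun in isolation reproduce exactly, and fixed seeds make all
outputs bit-identical (a tested invariant).

# Problem sizes in the test and acceptance suites

The suites run at desk scale, chosen to keep every check sharp but
quick: FDR control is measured on 20 cohorts of 2,000 transcripts
(10% planted gains, 2.5-fold shift, 4 patients); the test's size on
10,000 null windows; quadrant recovery on 10 cohorts of 1,000
transcripts with 8 patients (each cohort-mean hyper-up within ±5 points
of the planted 70); GSEA calibration on 200 null rankings of 100 genes
at 1,000 permutations; decay recovery on 100 series at 5% noise. Exact
oracles (hypergeometric enumeration, literal running-sum re-walk, BH
step-up) are implemented independently in the test helpers and compared
at 1e-12.

# Pipeline

`runPipeline()` chains simulate → peaks → differential → quadrants →
screen → GSEA → decay → MS quantification from one config. Inputs are
validated before anything runs; a stage failure is recorded in
`manifest.json` and downstream stages are skipped; outputs are written
atomically (temp file + rename) and only overwritten with
`force = TRUE`. Floats are serialised at 6 significant digits and JSON
keys sorted, so reruns are byte-identical. The pipeline's GSEA stage
scores the planted upregulated genes against the fold-change ranking —
with synthetic gene identifiers the hypoxia signature cannot overlap,
and a self-consistent planted set is the meaningful built-in check;
`nesAndPvalue()` accepts any GMT-loaded set for real data.
```{r pipeline, eval = FALSE}
cfg <- pipelineConfig(seed = 1,
                      sim = simConfig(nTranscripts = 200, nPatients = 4, seed = 1))
manifest <- runPipeline(cfg, "m6a-run")
```

# Known limitations

* Exact tests assume near-Poisson within-library counts (above); no
  shrinkage or dispersion estimation is performed.
* Peak boundaries are window-quantised; sub-window resolution is not
  attempted.
* The expression fold change is unmoderated; genes with very low counts
  rely on the 0.5-CPM pseudocount for stability.
* One peak per transcript is assumed by the *generator* (not by the
  caller); multi-peak behaviour is exercised only through merging and
  the multi-peak tie-break rule.
* GSEA reports a single set per call; multi-set FDR across collections
  is out of scope.
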