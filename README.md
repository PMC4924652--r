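# mtssr

Downstream analysis of **mTSS-seq** experiments: targeted MNase-seq that
captures the ~2 kb surrounding transcription start sites (TSSs) and
paired-end sequences the nuclease-protected fragments. Nucleosome-sized
protections (130–175 bp) report where nucleosomes sit; sub-nucleosomal
protections (<125 bp) act as a proxy for transcription-factor binding.
The package is written for chromatin biologists comparing matched
tumor/normal (or any two-condition) cohorts who want to ask: *where do
nucleosomes move, are the moves shared between patients, are they
directed by the underlying DNA sequence, and do they expose
transcription-factor binding sites?*

## What it computes

Given fragment intervals (BED, or name-paired BAM/SAM reduced to
template intervals), a TSS annotation (BED6), capture regions (BED3), a
DNA-encoded nucleosome-occupancy model track (bedGraph), TF peaks
(narrowPeak) and gene sets (GMT):

* **Occupancy & dyads** — per-bp fragments-per-million coverage
  (`fpm(b) = 10^6 · cov(b) / N`), and the windowed dyad track: fragment
  midpoints summed in 100-bp windows at a 10-bp step. Strand-oriented
  genes × positions matrices around TSSs (`tss_matrix()`).
* **Differential structure** — normal − tumor difference maps; per-gene
  Pearson correlation `r_g = cor(x_g^N, x_g^T)` with the lowest 20%
  called *changed*; cross-patient intersection with hypergeometric
  overlap tests; maximal difference regions where `|Δfpm| > 5`; merged
  region sets; gene-set enrichment (hypergeometric + BH).
* **Architecture** — k-means (k = 4) of unit-mean-scaled profiles over
  TSS ± 500 bp, cluster composition of gene subsets, and a stability
  scan showing which clusters merge/split at k ± 1.
* **DNA-encoded agreement** — per-gene correlations of each condition
  with the model track; the fraction of genes where the tumor agrees
  better, and `100 · (mean r_T − mean r_N) / |mean r_N|`.
* **Sequence periodicity** — pooled AA/TT/AT/TA positional frequency of
  150-bp protected fragments and its dominant period via detrended
  autocorrelation (the ~10 bp helical repeat).
* **TF footprints** — peak shuffling confined to capture space with
  observed/shuffled summit-count enrichment ratios; sub-nucleosomal
  midpoint aggregation at peak summits; percent binding change
  `100 · (S_T − S_N) / S_N` over the summit ± 100 bp core.
* **Synthetic studies** — a fully seeded generator
  (`sim_config()`/`simulate_study()`) planting four promoter
  architectures with NDRs, condition-specific dyad redistribution toward
  the model track, TF footprints with known binding multipliers, and
  periodic A/T dinucleotides under dyads, plus a truth file so every
  stage can be scored (`validate_against_truth()`).

## Worked example

Simulate a 60-gene cohort and recover its planted structure:

```r
library(mtssr)
cfg    <- sim_config(n_genes = 60, frag_count_per_gene = 1000, seed = 1)
ann    <- generate_annotation(cfg)
model  <- generate_model_track(ann, cfg)
peaks  <- generate_tf_peaks(ann, cfg)
normal <- simulate_fragments("normal", ann, cfg, peaks)
tumor  <- simulate_fragments("tumor",  ann, cfg, peaks)

mn <- tss_matrix(normal, ann$tss)   # 60 genes x 201 positions, 10-bp grid
mt <- tss_matrix(tumor,  ann$tss)

cc <- correlation_change_call(mn, mt)           # lowest-20% callers
ma <- model_agreement(mn, mt, model$matrix,
                      gene_subset = ann$design$gene_id[ann$design$changed])
cl <- cluster_profiles(mn, k = 4)               # promoter architectures
```

This prints/returns (seed 1):

```
fragments: 62729 normal / 62816 tumor
signal_matrix: 60 genes x 201 positions [-1000..1000 bp, step 10], units=dyads_per_million
changed calls: 12 | planted recovered: 12 of 12
tumor closer to DNA-encoded model at 100% of changed genes; mean r -0.14 -> 0.93
cluster_result: k=4, sizes=15/15/15/15, inertia=325 (seed 1357)
TF_A binding change: -19.1% (planted -13%)
```

All 12 planted redistributed genes land in the lowest-correlation 20%;
their tumor profiles correlate with the DNA-encoded model (mean r 0.93)
where the normal profiles do not (−0.14); the four planted architectures
are recovered as four equal clusters. The TF binding change is noisy at
this small scale (30 peaks); at the default 200-gene/2,000-fragment
scale it recovers the planted multipliers within ±3 percentage points
(see `tests/testthat/test-acceptance.R`).

A full file-based run is one call: `simulate_study()` writes
FASTA/BED/bedGraph/narrowPeak/GMT inputs plus `truth.json`, and
`run_all(run_config(...))` executes every stage into a `report.json`.
A thin CLI lives at `inst/cli/mtss.R`
(`Rscript mtss.R simulate|run|validate`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the dominant
spacing of the pooled A/T-dinucleotide positional frequency in synthetic
150-bp nucleosome-protected fragments (10,000 fragments per replicate,
20 replicate seeds, modal dominant period in bp) and writes it as JSON.

## Documentation

The methods vignette (`vignettes/mtss-analysis.Rmd`) describes the
signal model, parameter defaults and units, what the synthetic generator
does and does not emulate, numerical choices, and known limitations.
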