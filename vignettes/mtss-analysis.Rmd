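---
title: "Nucleosome distribution analysis at TSSs: methods and design notes"
author: "mtssr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleosome distribution analysis at TSSs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `mtssr`, the
defaults and their units, what the synthetic-study generator does and
does not emulate, and the numerical choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement model

Targeted MNase-seq of TSS windows yields paired-end fragments, each the
span of one nuclease-protected particle. Two size classes carry distinct
information:

* **nucleosomal**, 130–175 bp: protection by a histone octamer; the
  fragment midpoint estimates the nucleosome dyad;
* **sub-nucleosomal**, < 125 bp (floored at 50 bp in the simulator):
  protection by smaller DNA-binding proteins, a proxy for transcription
  factor occupancy.

The 125–129 bp gap is deliberate: it keeps the two classes
non-overlapping, so a fragment is never counted as both.

All coordinates are 0-based half-open (BED convention). The midpoint of
a length-$L$ fragment is $start + \lfloor L/2 \rfloor$, which makes every
downstream quantity integer-deterministic.

Two signal representations are used:

* per-bp **fpm** coverage: $\mathrm{fpm}(b) = 10^6\,c(b)/N$ where $c(b)$
  counts fragments covering base $b$ and $N$ is the sample's fragment
  total. The normalization denominator defaults to the on-target count
  (fragments whose midpoint lies in capture space) in the pipeline, so
  samples with different off-target rates remain comparable.
* the **dyad grid**: midpoints summed in 100-bp windows advanced by
  10 bp, reported at window centers. This is the default grid for
  correlation, clustering and model comparison; per-bp mode is available
  everywhere (`grid = "bp"`).

Per-gene matrices (`tss_matrix()`) are strand-oriented: minus-strand
rows are reversed so positive positions always run downstream in the
direction of transcription. Windows clipped at chromosome edges are
zero-filled and flagged, and such genes should be excluded from
correlation analyses (the pipeline's synthetic worlds never clip).

## Differential analysis

For each patient, the change statistic per gene is the Pearson
correlation between the normal and tumor signal over the TSS window.
Genes in the lowest quantile (default $q = 0.20$) are called *changed*;
exactly $\lfloor q\,n \rfloor$ genes are called, ties broken by
ascending $r$ then gene id, so a rerun reproduces the same set. Genes
with zero variance in either sample are excluded and logged. A
degenerate but defined case: identical matrices yield $r = 1$ everywhere
and the bottom-$q$ set is chosen purely by tie-break — documented rather
than forbidden, because calibration tests rely on the exact count.

Difference maps are *normal − tumor*: positive values mean occupancy
lost in the tumor. Difference regions are maximal runs of grid positions
with $|\Delta| > 5$ (two-sided by default; the figure convention colors
both gains and losses). The threshold is on the per-million-normalized
scale and is a free parameter: its absolute meaning depends on
sequencing depth and cohort size, so any cross-study use must re-anchor
it. Regions are called per patient and then merged (union of
overlapping or book-ended intervals, contributors recorded); calling on
grade-averaged tracks instead is possible by averaging matrices first.

Gene-set enrichment is an upper-tail hypergeometric test of the overlap
between the changed set and each collection set, BH-adjusted across
sets. Raw p-values are kept alongside q-values.

## Architecture clustering

Profiles over TSS ± 500 bp on the dyad grid are scaled per gene to unit
mean — not z-scored — because NDR depth relative to a gene's own
occupancy is exactly what distinguishes promoter architectures;
z-scoring would erase amplitude structure. Clustering is
`stats::kmeans` (Hartigan–Wong) with `nstart = 10` random starts under a
fixed seed (default 1357). A k-means++ initializer was considered and
rejected: with tens of starts on desk-scale data the solutions coincide,
and the base-R path keeps the dependency surface flat. Clusters are
renumbered by descending size so reports are stable. `k = n` is handled
specially (each gene its own cluster, inertia 0) because
`stats::kmeans` rejects that case.

`stability_scan()` reports the inertia curve and label-flow contingency
tables between adjacent k. Inertia non-increase in k is a property of
global optima; with shared seeds and ≥ 10 starts it holds in practice
and is asserted in the tests at `nstart = 25`.

## DNA-encoded model agreement

The DNA-encoded nucleosome-occupancy model is consumed as a bedGraph
track (its construction is out of scope). Per gene, both conditions are
correlated with the model over the TSS window on the dyad grid, the
model being resampled by bin means (partially covered edge bins use the
covered bases). The summary reports the fraction of genes where the
tumor is closer to the model and the percent change of the mean
correlation, $100\,(\bar r_T - \bar r_N)/|\bar r_N|$. The sign of that
summary flips under label swap but the magnitude rescales with the new
denominator — it is a reporting convention, not a symmetric distance.
Zero-variance model windows exclude a gene, with a log entry.

## Sequence periodicity

`dinuc_profile()` computes, over fragments of exactly 150 bp (a ± 5 bp
relaxed mode exists for sparse data; relaxed fragments are
center-trimmed), the per-position frequency of the pooled AA/TT/AT/TA
dinucleotides. Minus-strand fragments are reverse-complemented first;
for the pooled A/T classes this is a no-op, but custom class sets need
it. `estimate_period()` removes the linear trend, computes the
autocorrelation, and reports the first local maximum in the 5–25 bp lag
window that clears a Bonferroni-corrected white-noise band
(familywise level 0.02). A flat or aperiodic profile returns
`detected = FALSE`, never an exception; profiles that are flat up to
float noise (e.g. an exact linear ramp) are short-circuited by a
relative variance guard.

## TF footprints

Peak shuffling is confined to capture space — the data only exist
on-target, and genome-wide shuffling would deflate observed/shuffled
ratios artifactually. Each peak is placed uniformly over all valid
starts within its chromosome's capture regions, preserving its length;
100 iterations give stable means at desk scale. Region membership uses
the peak summit (single-point assignment avoids double counting across
merged regions). The enrichment ratio is observed count / mean shuffled
count with an empirical 95% interval from shuffled-count quantiles; a
zero shuffled mean is reported as infinite-with-flag.

Footprints aggregate fragment midpoints at offsets within ± 500 bp of
summits. **Normalization choice**: signals are scaled per million of
the *sample total* fragment count by default, not per million of the
size class. In a targeted experiment — and exactly in the simulator —
the sub-nucleosomal class total is dominated by the footprint fragments
themselves, so class-internal normalization would cancel the very
binding change being measured. The denominator is explicit (`total`)
and any convention can be passed. Binding change is
$100\,(S_T - S_N)/S_N$ over the summit ± 100 bp core; the core width is
a free parameter recorded in every report.

## The synthetic stated world

Defaults (`sim_config()`): 200 genes on 2 chromosomes, 2 kb capture
windows spaced so they never overlap; 2,000 nucleosomal fragments per
gene, length $\mathcal N(152, 10)$ truncated to [120, 200] bp; midpoint
jitter $\mathcal N(0, 20)$ bp around the occupancy-weighted dyads;
sub-nucleosomal lengths $\mathcal N(90, 15)$ truncated to [50, 124] bp;
20% of genes changed with full redistribution effect; tumor occupancy
downweighted ×0.6 on dyads downstream of the TSS in changed genes;
period-10, amplitude-1 A/T planting under dyads; TF footprints of ~50
fragments per peak with planted tumor/normal multipliers 0.87 and 1.31
(a 13% decrease and a 31% increase — the two signs observed for early
and advanced disease). Where the source material states no value
(jitter sd, background rate, model bump sd 30 bp, alternative-layout
shift 90 bp), a single realistic choice was made once and is not
revisited.

Four architecture templates are planted. Their design encodes the
qualitative clustering behavior being tested: templates 1 and 4 are both
"strong +1 array" shapes offset by ~30 bp — the most similar pair
(pairwise centroid correlation ≈ 0.76, below the 0.8 distinguishability
bound) — so a k = 3 clustering merges them; template 3 carries two
weight variants emphasizing the −1 or the −2 nucleosome, so a k = 5
clustering splits it. Template 2 is a wide-NDR distal arrangement. TF
peaks sit at each gene's NDR center, which also plants the expected
local nucleosomal depletion at summits.

What the generator does **not** emulate, hence what a green test does
not establish:

* sequencing error, adapter or quality artifacts, PCR duplicates,
  capture-efficiency bias (every fragment is on-target);
* coupling between fragment midpoints and the planted sequence: the
  periodic A/T signal is planted at the dyad *mode*, while occupancy
  fragments jitter (sd 20 bp) independently of sequence. Dyad-aligned
  periodicity therefore averages out in occupancy simulations, and the
  pipeline's dinucleotide stage honestly reports "not detected" there.
  The periodicity analysis is validated on the dedicated dyad-phased
  generator (`simulate_periodic_fragments()`), whose fragments are
  centered on their dyads — the idealized population the 150-bp
  fragment analysis assumes;
* signal continuation beyond the 2 kb island: profiles decay at window
  edges, so cohort-average claims are made on the promoter-proximal
  region;
* exchangeability of genes under the null *across* architectures:
  per-gene null correlation noise depends on profile shape (diffuse
  profiles are noisier), so with the 4-template mix the two-patient
  null overlap of changed sets sits systematically above the
  $n q^2$ chance expectation. This is a real property of
  correlation-quantile change calling on heterogeneous cohorts, worth
  knowing when interpreting cross-patient overlaps. The $n q^2$
  calibration is therefore asserted on an architecture-homogeneous
  cohort (`single_template = 1`).

Determinism: every stochastic step draws from a named stream derived
from the master seed (`sub_seed()`), so identical configurations give
byte-identical output files, and adding a patient does not perturb the
genome or another patient's fragments.

## Numerical and degenerate-input policy

* Empty fragment sets, empty gene subsets, empty region sets,
  zero-variance matrices and zero normal core signal raise errors that
  name the condition; "no periodicity" and "infinite ratio" are results,
  not errors.
* Fragments longer than 500 bp are dropped with a warning (gel size
  selection makes them implausible); the BAM reader keeps proper pairs
  with MAPQ ≥ 10 (configurable — the uniqueness filter is a convention,
  not a spec of the aligner).
* Quantile ties, cluster renumbering and shuffle placement are all
  deterministic under the documented tie-breaks and seeds.

## Known limitations

* The difference threshold (5) and binding-change core (± 100 bp) are
  reporting conventions whose absolute meaning depends on depth and
  grid; both appear in every report for that reason.
* `run_all()` caches stages by content hash of inputs and parameters;
  editing generator internals without bumping inputs requires clearing
  the cache directory.
* The pipeline's GO-style enrichment is generic gene-set enrichment
  over user-supplied GMT collections; it does not query any ontology
  service.
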