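---
title: "Methods: allele-specific reporter screens with dirscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific reporter screens with dirscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirscreen)
```

## The assay and its estimand

dirscreen analyses barcoded reporter screens (MPRA-style) in which each
candidate regulatory SNP is represented by two reporter constructs — one per
allele — carrying a 55-bp genomic window centered on the SNP upstream of a
minimal promoter, plus a promoter-only *blank* construct. The pooled plasmid
library is transfected into cells; barcodes are sequenced both from the
plasmid pool (DNA, the dosage control) and from reporter transcripts (RNA).

The per-construct readout is

\[
\text{activity}_{c,r} \;=\;
\frac{\mathrm{CPM}^{\mathrm{RNA}}_{c,r} / \mathrm{CPM}^{\mathrm{DNA}}_{c,r}}
     {\mathrm{CPM}^{\mathrm{RNA}}_{\mathrm{blank},r} /
      \mathrm{CPM}^{\mathrm{DNA}}_{\mathrm{blank},r}}
\]

for construct $c$ in replicate $r$: reads are scaled to counts-per-million
within each sub-library, the RNA/DNA ratio removes plasmid-dosage effects,
and dividing by the same replicate's blank ratio anchors activity 1 at the
bare promoter. Calibrating within each replicate removes replicate-level
efficiency differences; `compute_activity(calibrate = FALSE)` switches to
raw RNA/DNA ratios because the choice is not forced by the readout itself
(it changes p-values only when replicate blanks differ).

A SNP is called **regulatory** by a two-stage rule:

1. *Stage 1* — the two alleles drive expression differently: two-tailed
   Student's t-test with pooled variance on the replicate activities,
   $p < 0.05$.
2. *Stage 2* — the effect is material relative to the bare promoter: at
   least one allele's replicate-mean activity is $< 0.8$ or $> 1.2$.

Both thresholds are arguments of `classify()`. Two decisions here were
genuinely open and are worth recording. The classic equal-variance t form
is the default (Welch via `welch = TRUE`); with 3-vs-3 replicates the pooled
form is the conventional choice and is what "Student's t-test" denotes.
Stage 2 is evaluated on the replicate *mean* per allele rather than on any
single replicate: the mean is the quantity the fold change is built from,
and a single-replicate excursion rule would make the call noisier without
changing what it measures. Raw p-values drive the call (that is the
published procedure this pipeline mirrors); Benjamini–Hochberg q-values are
reported alongside for users who prefer FDR control. The regulatory set is
monotone in all three thresholds.

SNPs whose construct lacks DNA coverage in more than one replicate are
dropped from testing entirely rather than tested one-sided, since a fold
change with one allele estimated from fewer replicates is biased toward
noise; dropped SNPs are listed in the result's `dropped` attribute.

## Library design

`build_library()` emits two constructs per SNP plus exactly one blank.
Inserts are plus-strand 55-mers with the SNP at 1-based offset 28 (27-nt
flanks); no reverse-complement variants are emitted, one orientation
convention being simpler for matching and scoring. Cloning adapters are a
configurable oligo prefix/suffix and never enter the analysis. Only
biallelic single-nucleotide substitutions are accepted.

Simulated barcodes are 15-mers rejection-sampled to pairwise Hamming
distance $\ge 3$, so a single sequencing error can never convert one
barcode into another — exact matching then has zero cross-talk, and
1-mismatch matching remains unambiguous. Real libraries carry their own
barcode architecture; the pipeline takes a user-supplied barcode map TSV
for such data.

`build_sample_sheet()` addresses up to $24 \times 12 = 288$ sub-libraries
(first-round primer sets $\times$ second-round indexes). The assignment is
index-major (primer set cycles fastest) purely as a deterministic
convention; the true plate layout of a given experiment is the user's to
supply.

## What the simulator emulates

`sim_config()` fixes the generator's study conditions. Defaults:

| parameter | default | meaning |
|---|---|---|
| `n_snps` | 288 | panel size (577 constructs with blank) |
| `n_replicates` | 3 | biological replicates |
| `read_depth` | 1e6 | reads per sub-library |
| `fraction_regulatory` | 0.1 | SNPs with a planted allelic effect |
| `fold_range` | (2, 2) | planted fold between alleles |
| `regulatory_anchor` | 0.75 | weaker allele activity (fold 2 gives 0.75 vs 1.5) |
| `baseline_sdlog` | 0.15 | log-SD of non-regulatory baseline activity |
| `replicate_noise_cv` | 0.1 | CV of lognormal replicate noise per construct |
| `dna_dirichlet_concentration` | 10 | plasmid-pool evenness |
| `blank_proportion` | 0.01 | blank spike-in fraction of the pool |
| `per_base_error_rate` | 0.001 | substitution sequencing errors |
| `read_length` / `amplicon_split` | 150 / (271, 270) | paired-end geometry |

DNA proportions are drawn once from a symmetric Dirichlet (concentration 10
gives the few-fold abundance spread typical of cloned pools); each
replicate's DNA column is a multinomial draw at the configured depth. RNA
expected proportions are DNA proportion × true activity × lognormal
replicate noise, renormalized and sampled multinomially — the simplest
model under which the blank-calibrated CPM-ratio estimator is consistent
for the planted activity. No extra dispersion beyond the lognormal noise is
added. The regulatory pattern (0.75 vs 1.5 at fold 2) places both alleles
outside the stage-2 corridor symmetrically around 1.

Two generator choices are load-bearing for calibration. The blank is spiked
at a fixed 1% of the pool, and its activity carries no replicate noise (its
activity is 1 *by definition* — it is the reference point, not a measured
construct). Both mirror the role of a calibrator in the real assay: a
reference must be measured precisely for ratios against it to be
interpretable. If the blank were as noisy as any construct, dividing by it
would inject shared noise into every activity in a replicate; an unpaired
t-test double-counts that shared component in its variance estimate and
becomes conservative, and the null stage-1 positive rate would fall visibly
below its nominal 0.05.

Reads are emitted for the first-half amplicon with the fixed layout
`[primer 20 nt | index 8 nt | barcode 15 nt | constant filler]`, 271 bp in
total, read as 150-bp mates from both ends (29-bp overlap), with i.i.d.
substitution errors; qualities are constant Q37 (the error model lives in
the substitution rate, not the quality string). The barcode-free
second-half amplicon (270 bp) can be emitted with
`include_second_half = TRUE` and is ignored by default counting, since the
barcode lives in the first half in this layout. Read names encode the true
(sample, construct) so recovery can be scored. The real vector's amplicon
architecture differs in its particulars; this layout is an explicit
simulation stand-in, fixed and documented so that the read-processing chain
has an exact contract to invert.

The simulator does **not** model PCR amplification bias, duplicate reads,
indels, quality-score decay, or cell-to-cell heterogeneity. Passing tests
therefore demonstrate correctness of the quantification chain and
calibration of the statistics under multinomial counting plus lognormal
replicate noise — not robustness to every artifact of real sequencing;
real-data use still benefits from upstream QC.

Everything is reproducible: every random step derives from the config seed
through a local RNG scope, so identical configs give bit-identical FASTQ,
counts, peaks and Ct tables.

## Read processing

Pair merging is a maximum-agreement overlap scan (implemented in C++): mate
2 is reverse-complemented and the overlap length maximizing the number of
matching bases is chosen, subject to a mismatch rate $\le 0.1$ and a
minimum overlap of 20 bp; ties go to the longer overlap, disagreements take
the higher-quality base (mate 1 on ties), and pairs with no admissible
overlap are rejected and tallied, not errored. Demultiplexing tolerates 1
primer mismatch and 0 index mismatches by default (the index is short, so a
stray match is likelier); barcode matching is exact by default with an
optional 1-mismatch mode in which a read within distance 1 of two barcodes
is deliberately unassigned. "N" bases count as mismatches wherever they
fall. Accounting is conservative by construction: per sample, assigned
counts plus unassigned tallies equal the reads routed to that sample, and
merge/demultiplex failures are tallied globally.

At zero error rate the chain is an exact inverse of the simulator; at 1%
per-base error roughly 95% of reads remain assignable and essentially all
of those land on the correct construct — the Hamming-separated codes trade
a little recall for near-zero cross-talk, the right trade for counting.

## Clustering

Activity or expression heatmap workflows use row Z-scores (sample SD,
$n-1$; a convention that must be fixed somewhere, and the sample form
matches what `sd()` computes) followed by agglomerative clustering with
**uncentered Pearson correlation** similarity
$\sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}$ and distance $1 - s$, average
linkage — the classic Cluster 3.0 configuration for this workflow (the
linkage is switchable). Agglomeration order is deterministic, with
`stats::hclust`'s lowest-index tie-break. Average linkage on a metric
bounded in $[0, 2]$ produced no inversions on any test matrix, and the
suite asserts monotone merge heights. A variance-quantile row filter is
exposed for expression matrices where only high-variance genes should
enter; the quantile is a parameter rather than a guess at any particular
published cutoff. Outputs include the reordered matrix and Newick trees so
external viewers can render dendrograms.

## Chromatin support

Peak sets are BED files (0-based half-open; converted to 1-based GRanges
internally). A SNP at 1-based `pos` is supported when `pos - 1` lies in a
peak. The nomination rule is a boolean expression over assay names,
defaulting to `(ATAC | DNase) & (H3K27ac | H3K4me3)` — open chromatin and
an active mark — because "active chromatin support" is a conjunction of
accessibility and activity evidence; published peak choices vary, so the
rule is configuration, not code. Signal-level (bigWig) thresholding is out
of scope: peak calls are the reproducible contract. Chromosome `chr`
prefixes are harmonized to the panel's convention.

## Motif scoring

JASPAR-format PFMs are parsed with a 0.5 pseudocount per cell and a uniform
background (both recorded in the object; the pseudocount keeps zero counts
finite without flattening informative columns). Scores are log2-odds sums.
For an allele pair only placements whose window covers the SNP base are
scored, on both strands, and each allele keeps its best placement;
`delta = best(risk) − best(normal)`. Windows that do not cover the SNP are
identical between alleles, contribute delta 0 by construction, and would
only add noise to a |delta| ranking — hence the restriction. Best-hit
aggregation (max, not sum) is used because a single created or destroyed
site is the biological signal of interest at a SNP.

## qPCR quantifications

All qPCR formulas are delta-delta-Ct forms with the amplification
efficiency $E$ explicit (default exactly 2.0 — validated primers; override
per primer pair):

* ChIP/FAIRE enrichment: $E^{-[(Ct^{IP}_t - Ct^{in}_t) - (Ct^{IP}_c -
  Ct^{in}_c)]}$, target over input normalized to a control region.
* AS-qPCR allele ratio: $E^{-[\Delta Ct_{sample} - \Delta Ct_{gDNA}]}$,
  calibrated against heterozygous genomic DNA so unequal allele-specific
  primer efficiencies cancel; passing zero calibrator Cts gives the
  uncalibrated form for assays where no heterozygous template exists.
* getPCR wild-type fraction: $100 \cdot E^{-[\Delta\Delta Ct]}$ from a
  cut-site "watch" amplicon and a nearby control amplicon in edited vs mock
  DNA, clamped to $[0, 100]$ with a flag (noise can push the estimate out
  of range; the clamp is reported, never silent).

All are invariant to adding a constant to every Ct (machine offset), and
the A:B and B:A allele ratios are exact reciprocals.

Allele-specific read counting at a heterozygous SNP anchors each read on
the exact $2k+1$-mer context around the SNP ($k = 5$) on either strand —
alignment-free, so it works on raw FASTQ — and tallies the base in the SNP
slot; reads matching the context with a third base are tallied separately
and excluded from the two-sided exact binomial test against 0.5. A
SAM/BAM pileup path (`count_alleles_sam()`) covers aligned data.

## Numerical and degenerate-input conventions

* CPM requires a positive column total; all-zero samples are hard errors
  naming the sample.
* Zero pooled variance in the t-test: $p = 1$ for equal means, $p = 0$
  (flagged degenerate) for unequal means.
* Zero-variance rows are dropped before Z-scoring with a warning;
  zero-norm vectors are errors in uncentered correlation.
* BED parse errors carry the offending line number; `start >= end` is
  rejected.
* The reference base matching neither allele at a SNP is a warning (both
  alleles substituted in), not an error — panels routinely contain SNPs
  reported on the opposite strand of the reference.

## Problem sizes used in the checks

The package's own verification uses a 288-SNP library for the arithmetic
checks; a 50-SNP × 6-sub-library run of ~200,000 read pairs for the
round-trip; 50 simulated screens of 300 SNPs at depth $10^6$ with 3
replicates for null calibration (the stage-1 positive rate must sit inside
the 99% binomial band around 0.05 over 15,000 null SNP tests) and for
sensitivity/direction recovery of 10% planted fold-2 SNPs; and small
constructed fixtures elsewhere. These sizes make every Monte-Carlo check
tight enough to be meaningful while keeping the suite quick to run.

## Known limitations

* The count model has no overdispersion beyond lognormal replicate noise;
  real MPRA counts are often more dispersed, which would widen stage-1
  p-values rather than bias fold changes.
* The simulated amplicon layout is a stand-in, not a claim about any
  particular reporter vector.
* Motif deltas are score differences, not calibrated binding p-values; use
  them to rank, not to test.
* Survival analysis, eQTL lookup and signal-track graphics are outside the
  package's scope.
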