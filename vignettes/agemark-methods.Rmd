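---
title: "Detecting age-dynamic H3K4me3 domains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting age-dynamic H3K4me3 domains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`agemark` implements a complete analysis chain for asking how trimethylation
of histone H3 lysine 4 (H3K4me3) redistributes across a genome during aging,
modelled on a three-timepoint *C. elegans* somatic-cell design: L3 larvae,
day-2 (D2) and day-12 (D12) adults, with three ChIP replicates per timepoint
for the H3K4me3 antibody and an H3 control antibody, and two RNA-seq
replicates at D2 and D12. The chain is

1. binned coverage tracks and replicate QC (`tracks` functions),
2. enrichment-domain calling against a local Poisson background (`call_peaks`),
3. negative-binomial GLM testing of D12-vs-D2 peak counts with ratio and
   fold-change filters (`nb_glm_test`, `classify_dynamic`),
4. peak-to-gene assignment with a TES-exclusion rule (`assign_peaks`),
5. metagene k-means clustering and Fisher enrichment tests
   (`metagene_matrix`, `kmeans_cluster`, `cluster_enrichment`),
6. pre-ranked GSEA of a D2/L3 level ranking against the dynamic domains
   (`enrichment_score`, `permutation_significance`),
7. RNA differential expression and chromatin/RNA coupling statistics
   (`rna_differential`, `correlate_changes`, `overlap_partition`,
   `length_trend`), and
8. recovery scoring against simulated ground truth (`recover_truth`).

Because the real libraries of such a study live in sequencing archives, the
package ships a first-class synthetic-data generator
(`sim_config`, `simulate_experiment`) whose defaults encode the study design
itself; every downstream stage is exercised and tested against the
generator's known ground truth.

```{r, eval = FALSE}
library(agemark)
res <- run_pipeline(sim_config())
res$recovery
```

# The synthetic generator

## What it emulates

Each gene receives a ground-truth *marking regime*:

* **pattern** — TSS-peaked (a Gaussian kernel of sd 250 bp truncated at
  1 kb around the TSS) or gene-body (a flat plateau from TSS to TES).
  Default mix 60% TSS / 40% gene-body.
* **level** — low/mid/high, i.e. 2/4/8-fold over background. The multipliers
  were chosen once so that the weakest class is still detectable at default
  depth while the classes remain clearly separated on a log scale.
* **onset** — larval or adult deposition. Adult-onset genes carry 10% of
  their adult enrichment at L3 (the package asserts the resulting expected
  L3/D2 enrichment ratio is at most 0.2 directly from the mean function).
* **trend** — up/down/stable with age, applied as a `2^effect` multiplier on
  the enrichment component at D12; |log2 fold change| defaults to 1 and the
  marginal dynamic fraction to 30%. Dynamic propensity is deliberately
  non-uniform: gene-body/adult-onset genes are four times as likely to be
  dynamic as TSS/larval-onset genes (with intermediate groups at two-fold),
  reproducing the association between gene-body, adult-deposited marking and
  age dynamics that the pipeline is meant to detect.
* **RNA coupling** — with probability `coupling` (default 0.8) the gene's
  RNA trend mirrors its chromatin trend with the same log2 effect; otherwise
  the RNA is stable.

Counts are negative binomial per 25-bp bin around the expected profile,
which is smoothed with a 200-bp moving-average kernel standing in for
fragment extension (no read-level artifacts are simulated; alignment is out
of scope). H3 control libraries see the flat background only, making them
blind to the truth by construction. Each library's expected total equals
`chip_depth` (default 2×10⁶ reads over the 5-Mb toy genome, i.e. roughly
10 reads per background bin before enrichment mass is added — deep, but
typical of a pooled-worm ChIP compacted onto a 5-Mb genome).

A single experiment seed fans out to per-library substreams by hashing
(antibody, timepoint, replicate), so any library can be regenerated in
isolation and generation order is irrelevant.

## Noise parameters

The ChIP bin dispersion defaults to 0.1. The RNA gene-level dispersion is a
separate parameter defaulting to 0.02 (biological CV 14%): replicate worm
populations grown in parallel are genetically identical, and RNA-seq
count dispersion in such settings is conventionally far below the bin-level
noise of ChIP coverage. Note that a *peak-level* ChIP count is a sum over
many nearly independent bins, so its effective dispersion is the bin
dispersion divided by the number of bins — peak-level tests are therefore
much better powered than the bin dispersion alone would suggest.

## What the generator does not model

PCR duplicates, mappability and GC bias, germline/soma tissue mixtures,
isoform structure, and overdispersion that is correlated along the genome
(each bin draws independently). Passing the recovery tests therefore shows
that the statistical chain is wired correctly and calibrated under its own
assumptions — not that it is robust to every artifact of real libraries.

# Track normalization and QC

Normalized tracks are per-bin `RPKM(mark) − RPKM(control)` with
`RPKM = 10⁹·count/(library_size·bin_width)`; a bin where the two libraries
agree is exactly zero, and the subtraction is antisymmetric and invariant to
uniform depth rescaling. The replicate-QC representation counts both
libraries in 2-kb windows (80 bins of 25 bp) and takes
`log2(CPM_mark + 0.5) − log2(CPM_control + 0.5)`; the 0.5-CPM pseudocount
keeps empty windows finite. Windows are non-overlapping tiles: for
correlation and PCA, overlapping windows add no power and only correlate
neighbouring rows. Libraries pass QC when they correlate with at least one
other library above 0.8 (Pearson over windows); a constant window profile
has no defined correlation and is reported as a failure rather than NaN.

# Peak calling

The caller is a deliberately transparent re-implementation of the
narrow/broad local-Poisson strategy:

* counts are smoothed with a moving sum of `extsize` = 200 bp (model
  building is skipped; the fixed extension replaces fragment-shift
  estimation, and MFOLD-style model parameters are ignored because they
  only affect the disabled model step);
* the background rate per bin is the depth-scaled maximum of the genome-wide
  control rate and 1-kb/10-kb local control windows (`slocal`/`llocal`),
  so local fluctuations and contig-scale biases both raise the bar;
* each bin gets a Poisson upper-tail p-value; **narrow** mode keeps bins at
  Benjamini–Hochberg q < 0.01, **broad** mode keeps p < 0.05 cores extended
  through p < 0.1 flanks;
* retained bins merge across gaps of at most one bin (25 bp), domains
  shorter than `extsize` are dropped, and the summit is the leftmost
  maximum-signal bin.

Scores are `−log10` of the summit q (narrow) or p (broad), with p floored at
1e-300 to keep scores finite. Narrow and broad calls from both adult
timepoints are merged by 1-bp overlap (half-open intervals: touching
domains do not merge), and merged domains must then pass a
replicate-consistency gate: a per-replicate Poisson enrichment test of mark
over depth-scaled control within the domain, BH-corrected, significant in at
least 2 of 3 replicates at either adult timepoint. The published design
names only "the GLM method" for this step; the Poisson 2-of-3 rule is this
package's explicit stand-in and the test is pluggable.

# Differential marking

Raw (unscaled) peak counts feed an edgeR negative-binomial GLM with **full
library sizes** as offsets — depth normalization happens through the
offsets, not through count scaling. Dispersion is estimated as a common
value by adjusted profile likelihood over all peaks and shrunk tagwise
toward it with prior df 10; significance is by likelihood-ratio test.
Passing `dispersion = 0` reduces the machinery to the exact Poisson
likelihood-ratio test, which the test suite exploits as an oracle.

A peak is classified dynamic only if all three filters pass:

1. FDR < 0.05 (BH);
2. fold change of at least 30% in either direction (`min_fc = 1.3`);
3. depth-normalized H3K4me3/H3 ratio above 1.0 in **every** replicate of at
   least one adult timepoint ("at either time point" is read as: the ratio
   condition holds for all replicates of D2, or for all replicates of D12).

The FDR cutoff is 0.05 throughout; raising `min_fc` can only move peaks
from dynamic to stable (monotonicity is tested), and classes are invariant
to a global rescaling of every library.

The L3-vs-D2 contrast reuses the same machinery with relabelled classes
(`D2>L3` / `D2<L3` / `ns`) and, by default, no ratio filter — L3 libraries
of adult-onset regions legitimately sit near background, which is exactly
the signal the contrast is meant to detect.

# Gene assignment

Peaks overlapping a gene span by at least 1 bp are assigned to every
overlapped gene. Wholly intergenic peaks go to the nearest gene reading
*away* from the peak (the peak lies upstream of that gene's TSS),
with ties at equal distance on opposite strands keeping both genes; any
candidate for which the peak lies entirely 3′ of the gene's TES is
discarded, and peaks with no surviving candidate stay unassigned. Distances
are end-to-start gaps (0 when touching). Biotype filtering is left to the
caller as a downstream choice rather than baked into the assignment.

# Metagene clustering

Profiles are 50 upstream-flank bins (2 kb at 40 bp), 100 gene-body bins
(linear rebinning that conserves the interval mean), and 50 downstream
bins, strand-oriented. The flank/body bin counts are this package's choice:
40-bp flank resolution matches the 2-kb flank, and 100 body bins keep the
matrix small while leaving the TSS kernel clearly visible. D2 and D12
matrices are concatenated column-wise before clustering, so cluster shape
reflects both adult timepoints. k-means uses k-means++ seeding with 10
restarts (best within-cluster sum of squares kept) and is deterministic
given the seed; k defaults to 25, kept as a parameter because no principled
selection criterion is specified for it. Labels are canonicalized `a`–`y`
by descending centroid mean, making "cluster a" reproducibly the
strongest-marked cluster. Per-cluster enrichment of any binary gene flag
uses a two-sided Fisher exact test (internal vectorized implementation,
cross-checked against `stats::fisher.test`) with BH correction across
clusters; `group_contrast` pools several clusters against the rest.

# Pre-ranked GSEA

Peaks are ranked by `log2` ratio of mean normalized H3K4me3 level at D2
over L3 (descending; ties broken by id so the ranking is deterministic),
set membership is defined by at least 1 bp of overlap with the dynamic
domains, and the enrichment score is the signed maximum deviation of the
weighted Kolmogorov–Smirnov running sum (hit increments
`|score|^w / Σ|score|^w`, miss decrements `1/(N − N_members)`; weight
defaults to 1, the classic weighted scheme). Exact positive/negative ties
of the running-sum extreme resolve to the positive extreme. Significance
comes from label permutation — random member sets of the observed size —
with the add-one rule (p is never 0), NES as ES over the mean same-sign
null |ES|, and, for a single query set, FDR as the fraction of null |NES|
at least as large as observed.

# RNA integration

RNA differential expression follows the standard edgeR path: TMM library
scaling, common/trended/tagwise dispersion, GLM likelihood-ratio test,
BH correction; "expression change" means FDR < 0.05 everywhere downstream.
Chromatin/RNA coupling is Spearman's rho between per-gene log2 fold
changes; genes carrying several peaks are summarized by a depth-weighted
mean of their peaks' fold changes (one value per gene; a per-peak variant
is available by correlating on peak ids instead). The expected rho under
the generator's own truth law and noise model is computed by
`coupling_rho`, a 10⁵-draw Monte-Carlo oracle that never touches the
pipeline — the acceptance suite requires the measured rho to land within
0.1 of it. The peak-length trend uses geometric length bins over
0.2–10 kb (no canonical bin edges exist for this display, so the edges are
a parameter), restricted to single-gene peaks, with a permutation p-value
for the Spearman trend statistic; all-flagged or single-bin inputs are
reported as degenerate rather than forced to a number.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; GFF3 converts on
  read/write (via `rtracklayer`).
* Empty tracks produce empty peak sets, not errors; empty query sets for
  overlap fractions are errors (0/0 is undefined).
* Odds ratios are sample odds ratios (`ad/bc`), reported as `Inf` on
  degenerate tables rather than a conditional MLE.
* Summit ties break to the leftmost coordinate; ranking ties break
  lexicographically by id; the k-means label permutation is fixed by
  centroid ordering.
* All simulation entry points derive their RNG streams from the
  experiment seed; `run_pipeline` run twice with the same config writes
  byte-identical report tables.

# Problem sizes used by the test suite

The default configuration — one 5-Mb chromosome, 500 genes, 30% dynamic,
|log2FC| = 1, coupling 0.8, seed 7 — is the scale at which end-to-end
recovery is asserted (precision/recall ≥ 0.8 for dynamic domains, ≥ 0.8
recall of adult-onset D2>L3 classification, coupling rho within 0.1 of the
Monte-Carlo oracle). Caller calibration runs on a 5-Mb null track at a mean
of 30 reads per bin with twenty 1-kb fold-8 spike-ins (Jaccard ≥ 0.7
each); the differential test's type-I error is checked on 2,000 null NB
peaks at dispersion 0.1 (3 vs 3). Unit tests use smaller genomes (0.2–1 Mb)
wherever the full scale adds nothing.

# Known limitations

The caller is not a numerical clone of any external peak caller; it
reproduces the strategy, not the implementation. The replicate-consistency
test is a stand-in for an unspecified published step. Real-data ingestion
is limited to bedGraph/GFF3/BED and per-bin count tables — BAM ingestion is
intentionally absent. The generator's independence of bins means
long-range covariance structure in real coverage is untested, and the
microarray-based ranked lists that the GSEA functions can consume are
treated as generic inputs, not re-derived.
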