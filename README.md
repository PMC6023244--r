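# agemark

Detecting age-dynamic H3K4me3 domains from ChIP-seq coverage, and relating
them to deposition timing and RNA expression change.

In aging *C. elegans* somatic cells, a sizeable fraction of H3K4me3
(histone H3 lysine-4 trimethylation) enrichment domains change between
young (day-2) and old (day-12) adults; the changing domains tend to span
gene bodies, to be deposited during adulthood rather than development (low
signal at the L3 larval stage), and to move together with the RNA output of
their genes. `agemark` is a reusable, tested implementation of the full
analysis chain behind that kind of observation, for epigenomics analysts
who have binned coverage (bedGraph) for a mark and a control antibody
across timepoints, plus gene annotation and RNA-seq counts — or who want to
validate the chain end-to-end on simulated data first.

## The statistics at the core

* **Domain calling.** Mark counts smoothed over the fragment scale
  (`extsize` = 200 bp) are tested per 25-bp bin against a local Poisson
  background `λ_local = max(λ_genome, λ_1kb, λ_10kb)` estimated from the
  control and scaled for depth. Narrow domains keep bins at BH *q* < 0.01;
  broad domains extend *p* < 0.05 cores through *p* < 0.1 flanks. Calls
  merge by ≥ 1 bp overlap and must be enriched (Poisson, BH *q* < 0.05) in
  ≥ 2 of 3 replicates.
* **Differential marking.** Per-domain counts with full library sizes as
  offsets enter a negative-binomial GLM (edgeR; common dispersion shrunk
  tagwise, likelihood-ratio test). A domain is *dynamic* only if FDR < 0.05,
  |fold change| ≥ 30%, and its H3K4me3/H3 ratio exceeds 1.0 in every
  replicate of at least one timepoint.
* **Geometry and timing.** Metagene matrices (2-kb flanks at 40 bp, 100
  length-scaled body bins) are k-means clustered (k = 25, k-means++ with
  restarts, deterministic); Fisher exact tests measure per-cluster
  enrichment of dynamic marking. An L3-vs-D2 contrast classifies domains by
  deposition onset.
* **Coupling to expression.** Pre-ranked GSEA (weighted KS enrichment score
  with set-label permutation) asks whether dynamic domains concentrate
  among adult-deposited ones; edgeR TMM + GLM calls RNA changes; Spearman's
  rho couples per-gene chromatin and RNA log2 fold changes.
* **Ground truth.** A negative-binomial generator simulates the entire
  design (3 ChIP replicates × {L3, D2, D12} × {H3K4me3, H3}; 2 RNA
  replicates × {D2, D12}) over a toy genome with per-gene marking pattern,
  level, onset, age trend and coupled RNA trend, so precision/recall of the
  whole chain is measurable.

## Worked example

```r
library(agemark)

cfg <- sim_config(n_genes = 100, chrom_length = 1e6,
                  chip_depth = 4e5, rna_depth = 2e5)
res <- run_pipeline(cfg, n_perm = 500)

nrow(res$peaks)
#> [1] 98
table(res$dynamic$class)
#> decreased increased    stable
#>        10        15        73
res$recovery[c("precision", "recall", "onset_recall")]
#> $precision  [1] 1
#> $recall     [1] 0.9230769
#> $onset_recall [1] 0.8333333
res$coupling$rho
#> [1] 0.4425413
res$gsea$es
#> [1] 0.523117
```

Reading: of 98 called enrichment domains, 25 are classified age-dynamic
(FDR, 30% fold and H3-ratio filters); every dynamic call overlaps a truly
dynamic gene in the right direction (precision 1.0) and 92% of truly
dynamic genes are recovered; 83% of adult-onset genes are correctly read as
D2 > L3; per-gene chromatin and RNA fold changes correlate at rho = 0.44
(the generator's own coupling-induced rho for this configuration — see
`coupling_rho()` — is ≈ 0.45); and the dynamic domains are enriched near
the top of the D2/L3-ratio ranking with an enrichment score of 0.52.

A thin command-line front end is installed with the package:

```sh
Rscript <library>/agemark/exec/agemark simulate --outdir sim/ --seed 3
Rscript <library>/agemark/exec/agemark run --outdir report/ --config sim.yaml
```

`run` writes deterministic TSV report tables (peaks, dynamic classes,
L3 contrast, gene assignment, clusters, enrichment, RNA differential,
coupling pairs, summary); running it twice with the same config produces
byte-identical files.

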