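# Shared small-scale configurations and fixture builders.

# fast config: 1 Mb, 100 genes -- used wherever the full default scale is
# not the point of the test
small_config <- function(...) {
  sim_config(n_genes = 100L, chrom_length = 1e6, chip_depth = 4e5,
             rna_depth = 2e5, ...)
}

# single-chromosome coverage track from a plain counts vector
track1 <- function(counts, bin_size = 25L, chrom = "chr1") {
  coverage_track(stats::setNames(list(counts), chrom), bin_size)
}

# minimal annotation data.frame builder (0-based half-open)
make_annotation <- function(start, end, strand = "+", chrom = "chr1",
                            gene_id = sprintf("g%05d", seq_along(start))) {
  ann <- data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
                    strand = strand, biotype = "protein_coding",
                    stringsAsFactors = FALSE)
  ann <- ann[order(ann$chrom, ann$start), ]
  rownames(ann) <- NULL
  class(ann) <- c("AnnotationSet", "data.frame")
  ann
}

# minimal peak set builder
make_peaks <- function(start, end, chrom = "chr1", score = 1, mode = "narrow") {
  n <- length(start)
  df <- data.frame(chrom = rep_len(chrom, n), start = start, end = end,
                   summit = (start + end) / 2, score = rep_len(score, n),
                   fold = rep_len(2, n), mode = rep_len(mode, n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), ]
  rownames(df) <- NULL
  class(df) <- c("PeakSet", "data.frame")
  df
}

# independent enumeration oracle for the two-sided Fisher exact p of a 2x2
# table: sums hypergeometric point masses <= the observed one (same
# floating-point tie tolerance convention as stats::fisher.test)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (k == 0 || k == m + n || m == 0 || n == 0) return(1)
  x <- max(0, k - n):min(k, m)
  dens <- dhyper(x, m, n, k)
  min(1, sum(dens[dens <= dhyper(a, m, n, k) * (1 + 1e-7)]))
}

# independent brute-force GSEA running-sum oracle (same tie convention as
# the implementation: +/- ties resolve to the positive extreme)
es_oracle <- function(ids, scores, members, weight = 1) {
  n <- length(ids)
  hit <- ids %in% members
  nh <- sum(hit)
  denom <- sum(abs(scores[hit])^weight)
  run <- numeric(n); acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + if (hit[i]) abs(scores[i])^weight / denom else -1 / (n - nh)
    run[i] <- acc
  }
  mx <- max(run); mn <- min(run)
  if (mx + mn >= -1e-12 * max(mx, -mn, 1)) mx else mn
}

# the full pipeline run at default scale is shared by several acceptance
# checks; compute it once per session
default_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(sim_config(), n_perm = 500)
    cache
  }
})
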