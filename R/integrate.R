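#' Pool replicate coverage tracks
#'
#' Bin-wise sum of replicate libraries (the pooled track used for peak
#' calling).
#'
#' @param track_list list of \code{CoverageTrack}s with identical binning.
#' @return A \code{CoverageTrack}.
#' @export
pool_tracks <- function(track_list) {
  stopifnot(length(track_list) >= 1L)
  for (t in track_list[-1L]) check_same_binning(track_list[[1L]], t)
  counts <- lapply(stats::setNames(nm = names(track_list[[1L]]$counts)), function(chrom)
    Reduce(`+`, lapply(track_list, function(t) t$counts[[chrom]])))
  coverage_track(counts, track_list[[1L]]$bin_size)
}

#' RNA-seq differential expression between two timepoints
#'
#' TMM library scaling followed by the NB GLM likelihood-ratio test
#' (common, trended and tagwise dispersion estimation), BH-corrected;
#' genes at FDR < \code{fdr} are classed up/down by the sign of the fold
#' change.
#'
#' @param counts raw integer count matrix, genes x libraries.
#' @param groups two-level factor over columns (earlier level first; logFC
#'   is second vs first).
#' @param fdr FDR cutoff for the up/down classes.
#' @return An \code{RnaDiffResult} data.frame: \code{logFC}, \code{p},
#'   \code{fdr}, \code{class} in \{up, down, stable\}, rownames = gene ids.
#' @export
rna_differential <- function(counts, groups, fdr = 0.05) {
  counts <- as.matrix(counts)
  if (any(counts != round(counts))) stop("raw integer counts required")
  groups <- factor(groups)
  if (nlevels(groups) != 2L || any(table(groups) < 2L))
    stop("two groups with >= 2 replicates each required")
  y <- edgeR::DGEList(counts = counts, group = groups)
  y <- edgeR::calcNormFactors(y)
  design <- stats::model.matrix(~0 + groups, data = y$samples)
  y <- edgeR::estimateGLMCommonDisp(y, design)
  y <- suppressWarnings(edgeR::estimateGLMTrendedDisp(y, design))
  y <- edgeR::estimateGLMTagwiseDisp(y, design)
  fit <- edgeR::glmFit(y, design)
  lrt <- edgeR::glmLRT(fit, contrast = c(-1, 1))
  res <- data.frame(logFC = lrt$table$logFC, p = lrt$table$PValue,
                    fdr = stats::p.adjust(lrt$table$PValue, "BH"),
                    row.names = rownames(counts))
  res$class <- ifelse(res$fdr < fdr, ifelse(res$logFC > 0, "up", "down"), "stable")
  class(res) <- c("RnaDiffResult", "data.frame")
  res
}

#' Aggregate per-peak log fold changes to genes
#'
#' Genes carrying several peaks get the weighted mean of their peaks'
#' fold changes (weights default to equal; pass depth-normalized peak levels
#' for depth weighting).
#'
#' @param peak_logfc named numeric vector (by peak id).
#' @param assignment a [assign_peaks()] result.
#' @param weights optional named weights per peak id.
#' @return Named numeric vector per gene.
#' @export
aggregate_gene_logfc <- function(peak_logfc, assignment, weights = NULL) {
  asg <- assignment[assignment$peak_id %in% names(peak_logfc), , drop = FALSE]
  if (nrow(asg) == 0L) return(stats::setNames(numeric(0), character(0)))
  w <- if (is.null(weights)) rep(1, nrow(asg)) else weights[asg$peak_id]
  x <- peak_logfc[asg$peak_id]
  num <- tapply(x * w, asg$gene_id, sum)
  den <- tapply(w, asg$gene_id, sum)
  out <- num / den
  stats::setNames(as.numeric(out), names(out))
}

#' Spearman correlation of chromatin and expression changes
#'
#' @param k4_logfc named per-gene H3K4me3 log2 fold changes (aggregate
#'   multi-peak genes with [aggregate_gene_logfc()] first).
#' @param rna_logfc named per-gene RNA log2 fold changes.
#' @param restrict optional gene set to intersect with.
#' @return A \code{ChangeCorrelation} list: \code{rho}, \code{p}, \code{n},
#'   \code{pairs} (the paired table).
#' @export
correlate_changes <- function(k4_logfc, rna_logfc, restrict = NULL) {
  genes <- intersect(names(k4_logfc), names(rna_logfc))
  if (!is.null(restrict)) genes <- intersect(genes, restrict)
  if (length(genes) < 3L) stop("need at least 3 genes in the intersection")
  x <- k4_logfc[genes]; y <- rna_logfc[genes]
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = length(genes) <= 10L))
  structure(list(rho = unname(ct$estimate), p = ct$p.value, n = length(genes),
                 pairs = data.frame(gene_id = genes, k4_logfc = unname(x),
                                    rna_logfc = unname(y))),
            class = "ChangeCorrelation")
}

#' Venn partition of marked / dynamic-mark / dynamic-RNA gene sets
#'
#' Counts all 8 cells of the three-set partition over a declared gene
#' universe plus direction-resolved concordance among genes dynamic in both
#' chromatin and RNA.
#'
#' @param marked character vector of marked genes.
#' @param dyn_k4 named character vector of directions ("up"/"down", or
#'   "increased"/"decreased") for genes with dynamic H3K4me3.
#' @param dyn_rna named character vector of directions ("up"/"down") for
#'   genes with dynamic RNA.
#' @param universe character vector containing every gene referenced.
#' @return An \code{OverlapPartition} list: \code{cells} (named 8-cell
#'   counts), \code{concordant_up}, \code{concordant_down},
#'   \code{discordant}, \code{universe_size}.
#' @export
overlap_partition <- function(marked, dyn_k4, dyn_rna, universe) {
  sets <- list(marked = marked, k4 = names(dyn_k4), rna = names(dyn_rna))
  for (nm in names(sets))
    if (!all(sets[[nm]] %in% universe))
      stop("gene(s) in '", nm, "' outside the declared universe")
  inm <- universe %in% sets$marked
  ink <- universe %in% sets$k4
  inr <- universe %in% sets$rna
  key <- paste0(ifelse(inm, "M", "m"), ifelse(ink, "K", "k"), ifelse(inr, "R", "r"))
  lv <- c("MKR", "MKr", "MkR", "Mkr", "mKR", "mKr", "mkR", "mkr")
  cells <- table(factor(key, levels = lv))
  both <- intersect(names(dyn_k4), names(dyn_rna))
  up_map <- c(up = "up", increased = "up", down = "down", decreased = "down")
  dk <- up_map[dyn_k4[both]]; dr <- up_map[dyn_rna[both]]
  structure(list(cells = stats::setNames(as.integer(cells), lv),
                 concordant_up = sum(dk == "up" & dr == "up"),
                 concordant_down = sum(dk == "down" & dr == "down"),
                 discordant = sum(dk != dr),
                 universe_size = length(universe)),
            class = "OverlapPartition")
}

#' Fraction of RNA-dynamic genes by peak-length bin
#'
#' Bins (single-gene) dynamic peaks by length and computes the fraction of
#' their genes with an RNA expression change per bin, plus a monotone-trend
#' statistic (Spearman rho of bin midpoint vs fraction) with a permutation
#' p-value obtained by shuffling the RNA flags across peaks.
#'
#' @param peak_lengths named numeric vector of peak lengths in bp.
#' @param rna_change named logical vector over the same peaks (does the
#'   peak's gene change in RNA).
#' @param edges length-bin edges in bp (default geometric, 0.2-10 kb).
#' @param n_perm permutations for the trend p-value.
#' @param seed RNG seed.
#' @return A \code{LengthTrend} list: \code{bins} (data.frame midpoint,
#'   n, fraction), \code{rho}, \code{p} (NA with a \code{note} when the
#'   trend is degenerate).
#' @export
length_trend <- function(peak_lengths, rna_change,
                         edges = exp(seq(log(200), log(10000), length.out = 7)),
                         n_perm = 1000L, seed = 7L) {
  stopifnot(identical(names(peak_lengths), names(rna_change)))
  bin <- cut(peak_lengths, edges, include.lowest = TRUE)
  keep <- !is.na(bin)
  bin <- droplevels(bin[keep])
  flag <- rna_change[keep]
  if (!length(flag)) stop("no peaks fall inside the length bins")
  mids <- vapply(levels(bin), function(l) {
    i <- match(l, levels(cut(peak_lengths, edges, include.lowest = TRUE)))
    (edges[i] + edges[i + 1L]) / 2
  }, numeric(1))
  frac <- as.numeric(tapply(flag, bin, mean))
  nper <- as.integer(table(bin))
  bins <- data.frame(midpoint = mids, n = nper, fraction = frac)
  if (nrow(bins) < 2L || stats::sd(frac) == 0) {
    return(structure(list(bins = bins, rho = NA_real_, p = NA_real_,
                          note = "trend degenerate: fewer than 2 bins or constant fractions"),
                     class = "LengthTrend"))
  }
  rho <- stats::cor(mids, frac, method = "spearman")
  rho_null <- with_local_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      f <- sample(flag)
      fr <- as.numeric(tapply(f, bin, mean))
      if (stats::sd(fr) == 0) 0 else stats::cor(mids, fr, method = "spearman")
    }, numeric(1))
  })
  p <- (1 + sum(abs(rho_null) >= abs(rho))) / (1 + n_perm)
  structure(list(bins = bins, rho = rho, p = p, note = NULL),
            class = "LengthTrend")
}

#' Fisher overlap test between a gene flag and a target gene set
#'
#' @param flag named logical vector over the universe (or a character vector
#'   of flagged genes).
#' @param target_set character vector of target genes (non-empty subset of
#'   the universe).
#' @param universe character vector of all genes considered.
#' @return list(\code{odds_ratio}, \code{p}, \code{table}).
#' @export
geneset_overlap_test <- function(flag, target_set, universe) {
  if (!length(target_set)) stop("empty target set")
  if (!all(target_set %in% universe)) stop("target set outside the universe")
  flagged <- if (is.logical(flag)) names(flag)[flag] else as.character(flag)
  f <- universe %in% flagged
  t <- universe %in% target_set
  tab <- c(a = sum(t & f), b = sum(t & !f), c = sum(!t & f), d = sum(!t & !f))
  ft <- fisher_2x2(tab["a"], tab["b"], tab["c"], tab["d"])
  list(odds_ratio = ft$odds_ratio, p = ft$p, table = tab)
}

#' Score pipeline output against the simulated ground truth
#'
#' A truth-dynamic gene counts as recovered when some peak assigned to it is
#' classified dynamic in the matching direction; precision is the fraction
#' of dynamic peaks assigned to at least one truth gene of matching
#' direction.  Onset agreement is the fraction of adult-onset genes whose
#' assigned peaks include one classified \code{"D2>L3"}.  The fold-change
#' correlation is Pearson between per-gene estimated and injected log2 fold
#' changes.
#'
#' @param dynamic a \code{DiffResult} over the peaks (D12 vs D2 classes).
#' @param contrast a [timepoint_contrast()] result over the same peaks
#'   (L3 vs D2).
#' @param assignment a [assign_peaks()] result for the same peaks.
#' @param experiment the \code{SimulatedExperiment} the outputs came from.
#' @param fingerprint optional fingerprint carried by the outputs; must match
#'   the experiment's if given.
#' @return A \code{RecoveryReport} list: \code{precision}, \code{recall},
#'   \code{onset_recall}, \code{logfc_cor}, \code{n_dynamic_peaks},
#'   \code{n_truth_dynamic}.
#' @export
recover_truth <- function(dynamic, contrast, assignment, experiment,
                          fingerprint = NULL) {
  if (!is.null(fingerprint) && !identical(fingerprint, experiment$fingerprint))
    stop("outputs and truth come from different experiments")
  truth <- experiment$truth
  pid <- rownames(dynamic)
  dir_map <- c(increased = "up", decreased = "down")
  dyn_peaks <- pid[dynamic$class %in% names(dir_map)]
  peak_dir <- stats::setNames(dir_map[dynamic$class[dynamic$class %in% names(dir_map)]],
                              dyn_peaks)
  truth_dyn <- truth$gene_id[truth$trend != "stable"]
  truth_dir <- stats::setNames(truth$trend, truth$gene_id)
  asg_dyn <- assignment[assignment$peak_id %in% dyn_peaks, , drop = FALSE]
  match_dir <- truth_dir[asg_dyn$gene_id] == peak_dir[asg_dyn$peak_id]
  recovered <- unique(asg_dyn$gene_id[match_dir])
  recall <- if (length(truth_dyn)) length(intersect(recovered, truth_dyn)) /
              length(truth_dyn) else NA_real_
  precision <- if (length(dyn_peaks))
    length(unique(asg_dyn$peak_id[match_dir])) / length(dyn_peaks) else NA_real_
  # onset: adult-onset genes should read D2 > L3
  adult <- truth$gene_id[truth$onset == "adult"]
  cls_l3 <- stats::setNames(contrast$class, rownames(contrast))
  up_peaks <- names(cls_l3)[grepl(">", cls_l3)]
  genes_up <- unique(assignment$gene_id[assignment$peak_id %in% up_peaks])
  onset_recall <- if (length(adult)) length(intersect(adult, genes_up)) /
                    length(adult) else NA_real_
  est <- aggregate_gene_logfc(stats::setNames(dynamic$logFC, pid), assignment)
  common <- intersect(names(est), truth$gene_id)
  inj <- truth$effect[match(common, truth$gene_id)]
  logfc_cor <- if (length(common) >= 3L && stats::sd(inj) > 0 &&
                   stats::sd(est[common]) > 0)
    stats::cor(est[common], inj) else NA_real_
  structure(list(precision = precision, recall = recall,
                 onset_recall = onset_recall, logfc_cor = logfc_cor,
                 n_dynamic_peaks = length(dyn_peaks),
                 n_truth_dynamic = length(truth_dyn)),
            class = "RecoveryReport")
}
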