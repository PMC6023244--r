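#' Run the full age-dynamic H3K4me3 analysis on a simulated experiment
#'
#' Executes simulate -> track QC -> peak calling (narrow + broad, per adult
#' timepoint, 1-bp union merge, replicate-consistency gate) -> peak counting
#' -> D12-vs-D2 NB GLM with ratio and fold-change filters -> L3-vs-D2
#' contrast -> peak-to-gene assignment -> metagene k-means clustering and
#' cluster enrichment -> pre-ranked GSEA of the D2/L3 ranking against the
#' dynamic peaks -> RNA differential expression -> chromatin/RNA coupling
#' statistics -> truth recovery.  Fully deterministic for a given config.
#'
#' @param config a [sim_config()] object.
#' @param outdir optional directory; when given, report tables are written
#'   as TSV (same content on every run with the same config).
#' @param k number of metagene clusters.
#' @param n_perm GSEA permutations.
#' @return A named list with every intermediate and final result (see the
#'   package vignette for a walk-through).
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL, k = 25L,
                         n_perm = 1000L) {
  exp <- simulate_experiment(config)
  tr <- exp$tracks
  tps <- config$timepoints
  reps <- seq_len(config$n_chip_reps)

  # --- replicate QC over 2-kb windows ------------------------------------
  pairs <- list()
  for (tp in tps) for (r in reps)
    pairs[[sprintf("%s_r%d", tp, r)]] <-
      list(mark = tr$H3K4me3[[tp]][[r]], control = tr$H3[[tp]][[r]])
  wm <- window_matrix(pairs, window = 2000)
  qc <- qc_correlation_pca(wm)

  # --- peak calling on pooled adult libraries ----------------------------
  pooled <- lapply(stats::setNames(nm = tps), function(tp) list(
    mark = pool_tracks(tr$H3K4me3[[tp]]), control = pool_tracks(tr$H3[[tp]])))
  params <- peak_call_params()
  called <- list()
  for (tp in c("D2", "D12")) for (mode in c("narrow", "broad"))
    called[[paste(tp, mode)]] <-
      call_peaks(pooled[[tp]]$mark, pooled[[tp]]$control, params, mode)
  merged <- Reduce(merge_peaksets, called)
  cons <- lapply(c(D2 = "D2", D12 = "D12"), function(tp)
    replicate_consistency(merged, tr$H3K4me3[[tp]], tr$H3[[tp]], min_reps = 2L))
  keep_ids <- union(peak_ids(cons$D2), peak_ids(cons$D12))
  peaks <- new_peakset(as.data.frame(merged)[peak_ids(merged) %in% keep_ids, ,
                                             drop = FALSE], "pipeline")

  # --- counting, levels, differential ------------------------------------
  track_list <- list(); meta <- list()
  for (ab in c("H3K4me3", "H3")) for (tp in tps) for (r in reps) {
    track_list[[length(track_list) + 1L]] <- tr[[ab]][[tp]][[r]]
    meta[[length(meta) + 1L]] <- data.frame(antibody = ab, timepoint = tp,
                                            replicate = r)
  }
  meta <- do.call(rbind, meta)
  pcm <- count_in_peaks(peaks, track_list, meta)
  levels <- normalized_peak_levels(pcm)
  sel <- pcm$meta$antibody == "H3K4me3" & pcm$meta$timepoint %in% c("D2", "D12")
  diff <- nb_glm_test(pcm$raw[, sel, drop = FALSE],
                      factor(pcm$meta$timepoint[sel], levels = c("D2", "D12")),
                      lib_sizes = pcm$lib_sizes[sel])
  rownames(diff) <- peak_ids(peaks)
  dynamic <- classify_dynamic(diff, levels)
  contrast <- timepoint_contrast(pcm, tp_a = "L3", tp_b = "D2", levels = levels,
                                 min_ratio = 0)
  rownames(contrast) <- peak_ids(peaks)

  # --- gene assignment ---------------------------------------------------
  assignment <- assign_peaks(peaks, exp$annotation)
  marked_genes <- unique(assignment$gene_id)

  # --- metagene clustering and enrichment --------------------------------
  norm <- lapply(pooled, function(p) normalize_subtract(p$mark, p$control))
  mg <- lapply(norm[c("D2", "D12")], function(nt)
    metagene_matrix(exp$annotation[exp$annotation$gene_id %in% marked_genes, ,
                                   drop = FALSE], nt))
  mg_cat <- cbind(mg$D2, mg$D12)
  clusters <- kmeans_cluster(mg_cat, k = k, seed = config$seed)
  dyn_genes <- unique(assignment$gene_id[
    assignment$peak_id %in% rownames(dynamic)[dynamic$class != "stable"]])
  flag <- stats::setNames(marked_genes %in% dyn_genes, marked_genes)
  enrich <- cluster_enrichment(clusters, flag)

  # --- GSEA: D2/L3 ranking vs dynamic peaks ------------------------------
  lev_mean <- function(tp) rowMeans(levels[[tp]], na.rm = TRUE)
  eps <- 0.05
  ranked <- rank_by_difference(
    stats::setNames(lev_mean("D2") + eps, peak_ids(peaks)),
    stats::setNames(lev_mean("L3") + eps, peak_ids(peaks)))
  dyn_set <- new_peakset(as.data.frame(peaks)[dynamic$class != "stable", ,
                                              drop = FALSE], "dynamic")
  gsea <- if (nrow(dyn_set) > 0 && nrow(dyn_set) < nrow(peaks)) {
    permutation_significance(ranked, membership_by_overlap(ranked, dyn_set),
                             n_perm = n_perm, seed = config$seed)
  } else NULL

  # --- RNA and integration ----------------------------------------------
  rna_groups <- factor(sub("_r\\d+$", "", colnames(exp$rna_counts)),
                       levels = c("D2", "D12"))
  rna <- rna_differential(exp$rna_counts, rna_groups)
  k4_gene <- aggregate_gene_logfc(stats::setNames(dynamic$logFC, rownames(dynamic)),
                                  assignment)
  rna_lfc <- stats::setNames(rna$logFC, rownames(rna))
  coupling <- correlate_changes(k4_gene, rna_lfc)
  dyn_dir <- stats::setNames(
    ifelse(dynamic$class == "increased", "up", "down")[dynamic$class != "stable"],
    rownames(dynamic)[dynamic$class != "stable"])
  gene_dir <- tapply(dyn_dir[assignment$peak_id[assignment$peak_id %in% names(dyn_dir)]],
                     assignment$gene_id[assignment$peak_id %in% names(dyn_dir)],
                     function(d) names(sort(table(d), decreasing = TRUE))[1])
  dyn_k4_genes <- stats::setNames(as.character(gene_dir), names(gene_dir))
  dyn_rna_genes <- stats::setNames(rna$class[rna$class != "stable"],
                                   rownames(rna)[rna$class != "stable"])
  partition <- overlap_partition(marked_genes, dyn_k4_genes, dyn_rna_genes,
                                 universe = exp$truth$gene_id)
  # single-gene dynamic peaks for the length trend
  n_genes_per_peak <- table(assignment$peak_id)
  single <- names(n_genes_per_peak)[n_genes_per_peak == 1L]
  lt_peaks <- intersect(names(dyn_dir), single)
  trend <- if (length(lt_peaks) >= 3L) {
    plen <- stats::setNames(peaks$end - peaks$start, peak_ids(peaks))[lt_peaks]
    gene_of <- stats::setNames(assignment$gene_id, assignment$peak_id)[lt_peaks]
    rflag <- stats::setNames(gene_of %in% names(dyn_rna_genes), lt_peaks)
    length_trend(plen, rflag, seed = config$seed)
  } else NULL

  recovery <- recover_truth(dynamic, contrast, assignment, exp)

  res <- list(experiment = exp, window_matrix = wm, qc = qc, peaks = peaks,
              counts = pcm, levels = levels, dynamic = dynamic,
              contrast = contrast, assignment = assignment,
              clusters = clusters, cluster_enrichment = enrich,
              metagene = mg, ranked = ranked, gsea = gsea, rna = rna,
              coupling = coupling, partition = partition,
              length_trend = trend, recovery = recovery)
  if (!is.null(outdir)) write_report(res, outdir)
  res
}

#' Write the pipeline report tables
#'
#' Writes deterministic TSV tables (peaks, dynamic classes, L3 contrast,
#' gene assignment, cluster labels, cluster enrichment, RNA differential,
#' coupling pairs, recovery summary) plus the truth table, into
#' \code{outdir}.
#'
#' @param res a [run_pipeline()] result.
#' @param outdir output directory (created if missing).
#' @export
write_report <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    df, file.path(outdir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  pk <- as.data.frame(res$peaks)
  pk$peak_id <- peak_ids(res$peaks)
  wt(pk, "peaks.tsv")
  dyn <- cbind(peak_id = rownames(res$dynamic), as.data.frame(res$dynamic))
  wt(format(dyn, digits = 10), "dynamic.tsv")
  ctr <- cbind(peak_id = rownames(res$contrast), as.data.frame(res$contrast))
  wt(format(ctr, digits = 10), "contrast_l3_d2.tsv")
  wt(as.data.frame(res$assignment), "assignment.tsv")
  wt(data.frame(gene_id = names(res$clusters$labels),
                cluster = unname(res$clusters$labels)), "clusters.tsv")
  wt(format(as.data.frame(res$cluster_enrichment), digits = 10),
     "cluster_enrichment.tsv")
  rna <- cbind(gene_id = rownames(res$rna), as.data.frame(res$rna))
  wt(format(rna, digits = 10), "rna_differential.tsv")
  wt(format(res$coupling$pairs, digits = 10), "coupling_pairs.tsv")
  wt(data.frame(metric = c("precision", "recall", "onset_recall", "logfc_cor",
                           "rho", "gsea_es"),
                value = format(c(res$recovery$precision, res$recovery$recall,
                                 res$recovery$onset_recall, res$recovery$logfc_cor,
                                 res$coupling$rho,
                                 if (is.null(res$gsea)) NA else res$gsea$es),
                               digits = 10)),
     "summary.tsv")
  wt(res$experiment$truth, "truth.tsv")
  invisible(outdir)
}
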