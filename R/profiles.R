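#' Metagene signal matrix
#'
#' Builds a genes x position-bins matrix of normalized signal: a fixed number
#' of upstream-flank bins (2 kb / 50 bins = 40 bp each by default), the gene
#' body linearly rescaled to a fixed number of bins, and downstream-flank
#' bins, oriented 5' to 3' (minus-strand genes are reversed).  Values are
#' bp-weighted means of the \code{NormalizedTrack} signal; flank positions
#' beyond chromosome ends read as 0.  Genes shorter than \code{min_gene} are
#' skipped with a warning.
#'
#' @param annotation an \code{AnnotationSet}.
#' @param track a \code{NormalizedTrack} from [normalize_subtract()].
#' @param flank flank width in bp on each side.
#' @param body_bins,flank_bins numbers of gene-body and per-flank bins.
#' @param min_gene minimum gene length in bp.
#' @return A \code{MetageneMatrix}: numeric matrix with gene ids as row
#'   names and \code{2 * flank_bins + body_bins} columns.
#' @export
metagene_matrix <- function(annotation, track, flank = 2000, body_bins = 100L,
                            flank_bins = 50L, min_gene = 200L) {
  keep <- (annotation$end - annotation$start) >= min_gene
  if (any(!keep))
    warning(sum(!keep), " gene(s) shorter than ", min_gene, " bp skipped")
  ann <- annotation[keep, , drop = FALSE]
  ncols <- 2L * flank_bins + body_bins
  out <- matrix(NA_real_, nrow(ann), ncols, dimnames = list(ann$gene_id, NULL))
  fw <- flank / flank_bins
  for (chrom in unique(ann$chrom)) {
    if (!chrom %in% names(track$values))
      stop("gene chromosome ", chrom, " absent from track")
    v <- track$values[[chrom]]
    L <- length(v) * track$bin_size
    sel <- which(ann$chrom == chrom)
    if (any(ann$start[sel] < 0 | ann$end[sel] > L))
      stop("gene outside track bounds on ", chrom)
    for (i in sel) {
      s <- ann$start[i]; e <- ann$end[i]
      up_edges <- seq(s - flank, s, by = fw)
      body_edges <- seq(s, e, length.out = body_bins + 1L)
      dn_edges <- seq(e, e + flank, by = fw)
      a <- c(up_edges[-length(up_edges)], body_edges[-length(body_edges)],
             dn_edges[-length(dn_edges)])
      b <- c(up_edges[-1L], body_edges[-1L], dn_edges[-1L])
      # clip to track; fully outside bins read 0
      ca <- pmax(a, 0); cb <- pmin(b, L)
      vals <- numeric(length(a))
      ok <- cb > ca
      vals[ok] <- prorated_sum(v, track$bin_size, ca[ok], cb[ok]) *
        track$bin_size / (b[ok] - a[ok])
      if (ann$strand[i] == "-") vals <- rev(vals)
      out[match(ann$gene_id[i], rownames(out)), ] <- vals
    }
  }
  attr(out, "layout") <- list(flank = flank, body_bins = body_bins,
                              flank_bins = flank_bins)
  class(out) <- c("MetageneMatrix", class(out))
  out
}

# k-means++ seeding
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    pick <- if (all(d2 == 0)) sample.int(n, 1L)
            else sample.int(n, 1L, prob = d2 / sum(d2))
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' Cluster metagene profiles by k-means
#'
#' Euclidean k-means with k-means++ seeding and multiple restarts (best
#' within-cluster sum of squares kept), deterministic for a given seed.
#' Cluster labels are canonicalized by descending centroid mean signal, so
#' label \code{"a"} is always the strongest-marked cluster.
#'
#' @param matrix numeric matrix (e.g. timepoint-concatenated
#'   \code{MetageneMatrix}) with at least \code{k} rows.
#' @param k number of clusters (letters are used for labels when
#'   \code{k <= 26}).
#' @param seed RNG seed.
#' @param restarts number of k-means++ restarts.
#' @return A \code{ClusterAssignment} list: \code{labels} (named by gene),
#'   \code{centroids} (k x cols, rows named by label), \code{inertia},
#'   \code{k}, \code{seed}.
#' @export
kmeans_cluster <- function(matrix, k = 25L, seed = 7L, restarts = 10L) {
  x <- as.matrix(matrix)
  if (nrow(x) < k) stop("need at least k rows to form k clusters")
  best <- NULL
  with_local_seed(as.integer(seed), {
    for (r in seq_len(restarts)) {
      init <- kmeanspp_init(x, k)
      km <- suppressWarnings(stats::kmeans(x, centers = init, iter.max = 100L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  lab_names <- if (k <= 26L) letters[seq_len(k)] else sprintf("c%02d", seq_len(k))
  ord <- order(rowMeans(best$centers), decreasing = TRUE)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- stats::setNames(lab_names[relabel[best$cluster]], rownames(x))
  centroids <- best$centers[ord, , drop = FALSE]
  rownames(centroids) <- lab_names
  structure(list(labels = labels, centroids = centroids,
                 inertia = best$tot.withinss, k = k, seed = seed),
            class = "ClusterAssignment")
}

#' Per-cluster enrichment of a binary gene flag
#'
#' For each cluster, a two-sided Fisher exact test of the 2x2 table
#' (in-cluster vs out-of-cluster) x (flagged vs not), BH-adjusted across
#' clusters.
#'
#' @param assignment a [kmeans_cluster()] result.
#' @param flag named logical vector, defined for every clustered gene.
#' @return A \code{ClusterEnrichment} data.frame: \code{cluster},
#'   \code{n_total}, \code{n_flagged}, \code{odds_ratio}, \code{p},
#'   \code{p_adj}.
#' @export
cluster_enrichment <- function(assignment, flag) {
  genes <- names(assignment$labels)
  if (!all(genes %in% names(flag)))
    stop("flag must be defined for every clustered gene")
  f <- flag[genes]
  labs <- sort(unique(assignment$labels))
  tot_f <- sum(f)
  n <- length(f)
  tab <- t(vapply(labs, function(cl) {
    inc <- assignment$labels == cl
    c(a = sum(inc & f), b = sum(inc & !f),
      c = tot_f - sum(inc & f), d = sum(!inc & !f))
  }, numeric(4)))
  ft <- fisher_2x2(tab[, "a"], tab[, "b"], tab[, "c"], tab[, "d"])
  out <- data.frame(cluster = labs, n_total = tab[, "a"] + tab[, "b"],
                    n_flagged = tab[, "a"], odds_ratio = ft$odds_ratio,
                    p = ft$p, p_adj = stats::p.adjust(ft$p, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ClusterEnrichment", "data.frame")
  out
}

#' Fisher test of a flag against a group of clusters
#'
#' Single two-sided Fisher exact test comparing flag frequency in genes from
#' the clusters in \code{group_a} against genes from all other clusters.
#'
#' @param assignment a [kmeans_cluster()] result.
#' @param group_a character vector of cluster labels (non-empty, proper
#'   subset of the occupied labels).
#' @param flag named logical vector over the clustered genes.
#' @return list(\code{odds_ratio}, \code{p}).
#' @export
group_contrast <- function(assignment, group_a, flag) {
  labs <- unique(assignment$labels)
  if (!length(group_a) || !all(group_a %in% labs))
    stop("group_a must be a non-empty set of occupied cluster labels")
  if (all(labs %in% group_a)) stop("group_a must be a proper subset of clusters")
  genes <- names(assignment$labels)
  f <- flag[genes]
  ing <- assignment$labels %in% group_a
  ft <- fisher_2x2(sum(ing & f), sum(ing & !f), sum(!ing & f), sum(!ing & !f))
  list(odds_ratio = ft$odds_ratio, p = ft$p)
}

#' Average metagene profile of a gene subset
#'
#' @param matrix a \code{MetageneMatrix}.
#' @param genes character vector of gene ids (non-empty, present as rows).
#' @return list with \code{mean} (column-wise mean profile) and \code{iqr}
#'   (2 x cols matrix of the 25\%/75\% quantile band).
#' @export
average_profile <- function(matrix, genes) {
  if (!length(genes)) stop("empty gene subset")
  if (!all(genes %in% rownames(matrix))) stop("unknown gene id(s) in subset")
  m <- matrix[genes, , drop = FALSE]
  list(mean = colMeans(m),
       iqr = apply(m, 2, stats::quantile, probs = c(0.25, 0.75)))
}
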