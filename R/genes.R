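#' Gene TSS / TES positions (strand-aware)
#'
#' For a \code{+} gene the TSS is \code{start} and the TES is \code{end};
#' for a \code{-} gene the orientation is reversed.
#'
#' @param annotation an \code{AnnotationSet}.
#' @return data.frame with \code{gene_id}, \code{tss}, \code{tes} (bp).
#' @export
gene_tss_tes <- function(annotation) {
  plus <- annotation$strand == "+"
  data.frame(gene_id = annotation$gene_id,
             tss = ifelse(plus, annotation$start, annotation$end),
             tes = ifelse(plus, annotation$end, annotation$start))
}

peak_ids <- function(peaks) sprintf("%s:%d-%d", peaks$chrom,
                                    as.integer(peaks$start), as.integer(peaks$end))

#' Assign peaks to gene models
#'
#' Peaks overlapping one or more gene spans by at least 1 bp are assigned to
#' every overlapped gene (\code{relation = "overlap"}, distance 0).  Wholly
#' intergenic peaks are assigned to the nearest gene whose TSS lies
#' downstream of the peak in the gene's reading orientation (the peak is
#' upstream of the gene; \code{relation = "upstream_intergenic"}); ties at
#' equal distance on opposite strands keep both genes.  Candidates for which
#' the peak lies entirely 3' of the gene's TES are discarded; peaks with no
#' surviving candidate are unassigned (absent from the result).
#'
#' @param peaks a \code{PeakSet}.
#' @param annotation an \code{AnnotationSet} (sorted per chromosome).
#' @return A \code{GeneAssignment} data.frame: \code{peak_id}, \code{gene_id},
#'   \code{relation}, \code{distance} (bp gap; 0 for overlap or touching).
#' @export
assign_peaks <- function(peaks, annotation) {
  if (nrow(annotation) > 0) {
    o <- order(annotation$chrom, annotation$start)
    if (!identical(o, seq_len(nrow(annotation))))
      stop("annotation must be sorted by (chrom, start)")
  }
  empty <- data.frame(peak_id = character(), gene_id = character(),
                      relation = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L || nrow(annotation) == 0L) {
    class(empty) <- c("GeneAssignment", "data.frame")
    return(empty)
  }
  pid <- peak_ids(peaks)
  pgr <- peaks_to_granges(peaks)
  ggr <- GenomicRanges::GRanges(annotation$chrom,
    IRanges::IRanges(annotation$start + 1L, annotation$end))
  hit <- GenomicRanges::findOverlaps(pgr, ggr)
  qh <- S4Vectors::queryHits(hit)
  ov <- data.frame(peak_id = pid[qh],
                   gene_id = annotation$gene_id[S4Vectors::subjectHits(hit)],
                   relation = rep("overlap", length(qh)),
                   distance = rep(0, length(qh)), stringsAsFactors = FALSE)
  inter_idx <- setdiff(seq_len(nrow(peaks)), unique(qh))
  rows <- list(ov)
  for (i in inter_idx) {
    chrom <- peaks$chrom[i]
    s <- peaks$start[i]; e <- peaks$end[i]
    cand_gene <- character(0); cand_dist <- numeric(0)
    # nearest +-strand gene starting at/after the peak (peak 5' of its TSS)
    gp <- annotation[annotation$chrom == chrom & annotation$strand == "+" &
                       annotation$start >= e, , drop = FALSE]
    if (nrow(gp)) {
      j <- which.min(gp$start)
      cand_gene <- c(cand_gene, gp$gene_id[j])
      cand_dist <- c(cand_dist, gp$start[j] - e)
    }
    # nearest --strand gene ending at/before the peak (peak 5' of its TSS)
    gm <- annotation[annotation$chrom == chrom & annotation$strand == "-" &
                       annotation$end <= s, , drop = FALSE]
    if (nrow(gm)) {
      j <- which.max(gm$end)
      cand_gene <- c(cand_gene, gm$gene_id[j])
      cand_dist <- c(cand_dist, s - gm$end[j])
    }
    if (!length(cand_gene)) next
    keep <- which(cand_dist == min(cand_dist))  # ties on opposite strands: keep both
    rows[[length(rows) + 1L]] <- data.frame(
      peak_id = rep(pid[i], length(keep)), gene_id = cand_gene[keep],
      relation = rep("upstream_intergenic", length(keep)),
      distance = cand_dist[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$peak_id, pid)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("GeneAssignment", "data.frame")
  out
}

#' Fraction of query peaks overlapping a reference set
#'
#' @param query,reference \code{PeakSet}s.
#' @param min_overlap minimum overlap in bp to count.
#' @return Fraction in [0, 1] of query peaks with at least one qualifying
#'   reference overlap.
#' @export
overlap_fraction <- function(query, reference, min_overlap = 1L) {
  if (nrow(query) == 0L) stop("overlap fraction undefined for an empty query")
  if (nrow(reference) == 0L) return(0)
  # disjoint chromosome sets are a legitimate zero-overlap case
  n_hit <- suppressWarnings(
    GenomicRanges::countOverlaps(peaks_to_granges(query),
                                 peaks_to_granges(reference),
                                 minoverlap = as.integer(min_overlap)))
  mean(n_hit > 0)
}

#' Read a gene annotation from GFF3 or BED12
#'
#' Thin wrapper over \code{rtracklayer::import} retaining gene-level records;
#' coordinates are converted to the package's 0-based half-open convention.
#'
#' @param path file path (format from extension: .gff3/.gff or .bed).
#' @param feature_type GFF3 \code{type} value to keep (default "gene").
#' @return An \code{AnnotationSet}.
#' @export
read_annotation <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$type)) gr <- gr[md$type == feature_type]
  md <- S4Vectors::mcols(gr)
  ids <- if (!is.null(md$ID)) as.character(md$ID)
         else if (!is.null(md$name)) as.character(md$name)
         else sprintf("g%05d", seq_along(gr))
  ann <- data.frame(gene_id = ids,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    biotype = if (!is.null(md$biotype)) as.character(md$biotype)
                              else "protein_coding",
                    stringsAsFactors = FALSE)
  ann$strand[!ann$strand %in% c("+", "-")] <- "+"
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("AnnotationSet", "data.frame")
  ann
}

#' Write an annotation as GFF3
#' @param annotation an \code{AnnotationSet}.
#' @param path output path.
#' @export
write_annotation <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1L, annotation$end),
    strand = annotation$strand,
    type = "gene", ID = annotation$gene_id, biotype = annotation$biotype)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
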