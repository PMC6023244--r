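#' Peak-calling parameters
#'
#' Parameters of the dual-mode enrichment-domain caller: fragment-scale
#' smoothing (no model building, fixed extension), a local Poisson background
#' taken as the maximum of genome-wide, small-window and large-window control
#' rates, a BH q-value cutoff for narrow calls and a p-value core/linking
#' scheme for broad calls.
#'
#' @param extsize smoothing width in bp (moving sum, in place of fragment
#'   extension).
#' @param narrow_q BH q-value cutoff for narrow peaks.
#' @param broad_p p-value cutoff for broad-peak core bins.
#' @param broad_link_p p-value cutoff for extending a broad core through
#'   flanking bins; must be >= \code{broad_p}.
#' @param slocal,llocal small/large local-background window widths in bp.
#' @param min_len minimum peak length in bp (default = \code{extsize}).
#' @param merge_gap maximum gap between significant bins merged into one
#'   peak, in bp (default = one bin).
#' @return A \code{PeakCallParams} list.
#' @export
peak_call_params <- function(extsize = 200L, narrow_q = 0.01, broad_p = 0.05,
                             broad_link_p = 0.1, slocal = 1000L, llocal = 10000L,
                             min_len = extsize, merge_gap = NULL) {
  if (broad_link_p < broad_p) stop("broad_link_p must be >= broad_p")
  if (any(c(extsize, slocal, llocal, min_len) <= 0)) stop("lengths must be > 0")
  structure(list(extsize = as.integer(extsize), narrow_q = narrow_q,
                 broad_p = broad_p, broad_link_p = broad_link_p,
                 slocal = as.integer(slocal), llocal = as.integer(llocal),
                 min_len = as.integer(min_len), merge_gap = merge_gap),
            class = "PeakCallParams")
}

new_peakset <- function(df, provenance = "") {
  if (nrow(df) > 0) {
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "provenance") <- provenance
  class(df) <- c("PeakSet", "data.frame")
  df
}

empty_peakset <- function(provenance = "") {
  new_peakset(data.frame(chrom = character(), start = numeric(), end = numeric(),
                         summit = numeric(), score = numeric(), fold = numeric(),
                         mode = character(), stringsAsFactors = FALSE), provenance)
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
}

# collapse a logical vector of significant bins into [start,end) bin-index
# runs, merging runs separated by <= gap_bins non-significant bins
sig_runs <- function(sig, gap_bins) {
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) <= 1L) return(runs)
  keep <- runs[-1L, 1L] - runs[-nrow(runs), 2L] - 1L > gap_bins
  grp <- cumsum(c(TRUE, keep))
  cbind(tapply(runs[, 1L], grp, min), tapply(runs[, 2L], grp, max))
}

#' Call enrichment domains against a local Poisson background
#'
#' Smooths the mark track with a moving sum of width \code{extsize}, computes
#' a local background rate per bin from the control as the depth-scaled
#' maximum of the genome-wide rate and the \code{slocal}/\code{llocal} window
#' rates, and assigns each bin a Poisson upper-tail p-value.  Narrow mode
#' keeps bins at BH q < \code{narrow_q}; broad mode keeps cores at
#' p < \code{broad_p} extended through flanking bins at p <
#' \code{broad_link_p}.  Adjacent retained bins (gap <= \code{merge_gap})
#' are merged; domains shorter than \code{min_len} are dropped.
#'
#' @param mark \code{CoverageTrack} of the mark library (replicates pooled).
#' @param control matching control \code{CoverageTrack}, or \code{NULL} for a
#'   genome-wide background estimated from the mark itself.
#' @param params a [peak_call_params()] object.
#' @param mode \code{"narrow"} or \code{"broad"}.
#' @return A \code{PeakSet} data.frame (sorted, non-overlapping) with columns
#'   chrom, start, end (0-based half-open), summit, score (-log10 q at the
#'   summit for narrow, -log10 p for broad), fold (smoothed mark over local
#'   lambda at the summit) and mode.
#' @export
call_peaks <- function(mark, control = NULL, params = peak_call_params(),
                       mode = c("narrow", "broad")) {
  mode <- match.arg(mode)
  if (params$extsize < mark$bin_size) stop("extsize must be >= bin_size")
  if (!is.null(control)) check_same_binning(mark, control)
  bs <- mark$bin_size
  w <- params$extsize %/% bs
  gap_bins <- max(0L, (if (is.null(params$merge_gap)) bs else params$merge_gap) %/% bs)
  prov <- sprintf("call_peaks:%s:ext%d:q%g:p%g", mode, params$extsize,
                  params$narrow_q, params$broad_p)
  if (mark$library_size == 0) return(empty_peakset(prov))
  total_bins <- sum(n_bins(mark))
  ratio <- if (is.null(control)) 1 else mark$library_size / control$library_size
  lam_genome <- if (is.null(control)) mark$library_size / total_bins * w
                else control$library_size / total_bins * w * ratio
  per_chrom <- lapply(names(mark$counts), function(chrom) {
    x <- mark$counts[[chrom]]
    sm <- moving_sum(x, w)
    if (is.null(control)) {
      lam <- rep(lam_genome, length(x))
    } else {
      cc <- control$counts[[chrom]]
      ws <- max(w, params$slocal %/% bs)
      wl <- max(w, params$llocal %/% bs)
      lam_s <- moving_sum(cc, ws) * (w / ws) * ratio
      lam_l <- moving_sum(cc, wl) * (w / wl) * ratio
      lam <- pmax(lam_genome, lam_s, lam_l)
    }
    p <- stats::ppois(sm - 1, lam, lower.tail = FALSE)
    list(chrom = chrom, sm = sm, lam = lam, p = p)
  })
  p_all <- unlist(lapply(per_chrom, `[[`, "p"), use.names = FALSE)
  q_all <- stats::p.adjust(p_all, method = "BH")
  offs <- cumsum(c(0, vapply(per_chrom, function(z) length(z$p), numeric(1))))
  rows <- list()
  for (i in seq_along(per_chrom)) {
    z <- per_chrom[[i]]
    q <- q_all[(offs[i] + 1L):offs[i + 1L]]
    if (mode == "narrow") {
      sig <- q < params$narrow_q
    } else {
      core <- z$p < params$broad_p
      link <- z$p < params$broad_link_p
      # keep linked runs that contain at least one core bin
      lr <- sig_runs(link, 0L)
      sig <- rep(FALSE, length(link))
      if (length(lr)) for (j in seq_len(nrow(lr))) {
        if (any(core[lr[j, 1L]:lr[j, 2L]])) sig[lr[j, 1L]:lr[j, 2L]] <- TRUE
      }
    }
    if (!any(sig)) next
    runs <- sig_runs(sig, gap_bins)
    st <- (runs[, 1L] - 1L) * bs
    en <- runs[, 2L] * bs
    keep <- en - st >= params$min_len
    if (!any(keep)) next
    runs <- runs[keep, , drop = FALSE]; st <- st[keep]; en <- en[keep]
    summit_bin <- vapply(seq_len(nrow(runs)), function(j) {
      idx <- runs[j, 1L]:runs[j, 2L]
      idx[which.max(z$sm[idx])]   # leftmost maximum
    }, numeric(1))
    stat <- if (mode == "narrow") pmax(q[summit_bin], 1e-300)
            else pmax(z$p[summit_bin], 1e-300)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = z$chrom, start = st, end = en,
      summit = (summit_bin - 0.5) * bs,
      score = -log10(stat),
      fold = z$sm[summit_bin] / pmax(z$lam[summit_bin], 1e-12),
      mode = mode, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_peakset(prov))
  new_peakset(do.call(rbind, rows), prov)
}

#' Merge two peak sets by coordinate overlap
#'
#' Intervals overlapping by at least \code{min_overlap} bp are coalesced into
#' their hull (transitively); the merged peak takes the maximum score of its
#' constituents, the summit of its best-scoring constituent, and mode
#' \code{"merged"} when constituents of different modes are combined.
#' Idempotent and commutative.
#'
#' @param a,b \code{PeakSet}s.
#' @param min_overlap minimum overlap in bp for two intervals to merge.
#' @return A \code{PeakSet}.
#' @export
merge_peaksets <- function(a, b, min_overlap = 1L) {
  all <- rbind(as.data.frame(a), as.data.frame(b))
  if (nrow(all) == 0L) return(empty_peakset("merge"))
  gr <- peaks_to_granges(all)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 1L - as.integer(min_overlap))
  hit <- GenomicRanges::findOverlaps(red, gr)
  best <- tapply(S4Vectors::subjectHits(hit), S4Vectors::queryHits(hit), function(js) {
    js[which.max(all$score[js])]
  })
  modes <- tapply(S4Vectors::subjectHits(hit), S4Vectors::queryHits(hit), function(js) {
    m <- unique(all$mode[js])
    if (length(m) == 1L) m else "merged"
  })
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                   start = GenomicRanges::start(red) - 1L,
                   end = GenomicRanges::end(red),
                   summit = all$summit[best],
                   score = vapply(split(all$score[S4Vectors::subjectHits(hit)],
                                        S4Vectors::queryHits(hit)), max, numeric(1)),
                   fold = all$fold[best],
                   mode = as.character(modes), stringsAsFactors = FALSE)
  new_peakset(df, "merge")
}

#' Replicate-consistency gate for a peak set
#'
#' For each peak and each replicate, tests enrichment of the replicate's mark
#' counts over its depth-scaled control counts within the peak interval
#' (Poisson upper tail, BH-corrected across peaks); retains peaks significant
#' (q < \code{alpha}) in at least \code{min_reps} replicates.  The control
#' rate is floored at the genome-wide control density over the peak so that
#' empty control windows do not produce spurious enrichment.
#'
#' @param peaks a \code{PeakSet}.
#' @param mark_reps,control_reps lists of per-replicate \code{CoverageTrack}s
#'   (same length, >= 2).
#' @param min_reps minimum number of significant replicates.
#' @param alpha per-replicate BH q cutoff.
#' @return The retained \code{PeakSet}, with an \code{n_consistent} column.
#' @export
replicate_consistency <- function(peaks, mark_reps, control_reps,
                                  min_reps = 2L, alpha = 0.05) {
  if (length(mark_reps) < 2L || length(mark_reps) < min_reps)
    stop("need at least max(2, min_reps) replicates")
  if (length(mark_reps) != length(control_reps))
    stop("mark and control replicate lists differ in length")
  if (nrow(peaks) == 0L) return(peaks)
  sig <- vapply(seq_along(mark_reps), function(r) {
    m <- mark_reps[[r]]; ctl <- control_reps[[r]]
    check_same_binning(m, ctl)
    x <- peak_raw_counts(peaks, m)
    cc <- peak_raw_counts(peaks, ctl)
    width_bins <- (peaks$end - peaks$start) / m$bin_size
    dens <- ctl$library_size / sum(n_bins(ctl))
    lam <- pmax(cc, width_bins * dens) * m$library_size / ctl$library_size
    p <- stats::ppois(ceiling(x) - 1, lam, lower.tail = FALSE)
    stats::p.adjust(p, "BH") < alpha
  }, logical(nrow(peaks)))
  if (!is.matrix(sig)) sig <- matrix(sig, nrow = nrow(peaks))
  n_cons <- rowSums(sig)
  out <- peaks[n_cons >= min_reps, , drop = FALSE]
  out$n_consistent <- n_cons[n_cons >= min_reps]
  new_peakset(as.data.frame(out), attr(peaks, "provenance"))
}

# raw (pro-rated) counts of one track over each peak interval
peak_raw_counts <- function(peaks, track) {
  out <- numeric(nrow(peaks))
  for (chrom in unique(peaks$chrom)) {
    sel <- peaks$chrom == chrom
    if (!chrom %in% names(track$counts))
      stop("peak chromosome ", chrom, " not present in track")
    v <- track$counts[[chrom]]
    if (any(peaks$end[sel] > length(v) * track$bin_size))
      stop("peak outside chromosome bounds on ", chrom)
    out[sel] <- prorated_sum(v, track$bin_size, peaks$start[sel], peaks$end[sel])
  }
  out
}
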