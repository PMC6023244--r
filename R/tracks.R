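#' Binned coverage track
#'
#' Container for per-chromosome binned read counts of one sequencing library.
#'
#' @param counts named list (by chromosome) of non-negative per-bin counts.
#' @param bin_size bin width in bp.
#' @return A \code{CoverageTrack}: list with \code{bin_size}, \code{counts}
#'   and \code{library_size} (the sum of all bins).
#' @export
coverage_track <- function(counts, bin_size) {
  stopifnot(is.list(counts), !is.null(names(counts)), bin_size >= 1)
  counts <- lapply(counts, function(x) {
    if (any(x < 0)) stop("negative bin count")
    as.numeric(x)
  })
  structure(list(bin_size = as.integer(bin_size), counts = counts,
                 library_size = sum(vapply(counts, sum, numeric(1)))),
            class = "CoverageTrack")
}

n_bins <- function(track) vapply(track$counts, length, integer(1))

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack: %d chromosome(s), bin %d bp, library size %.0f\n",
              length(x$counts), x$bin_size, x$library_size))
  invisible(x)
}

#' Read a bedGraph file into a coverage track
#'
#' Expects the 4-column bedGraph dialect (0-based, half-open), with intervals
#' sorted, non-overlapping and aligned to \code{bin_size} boundaries; an
#' interval may span several bins (the value is replicated per bin).  Bins not
#' covered by any interval read as 0.
#'
#' @param path file path.
#' @param bin_size bin width in bp.
#' @param chrom_lengths optional named vector of chromosome lengths in bp; if
#'   omitted, each chromosome's length is the largest end coordinate seen.
#' @return A [coverage_track()] object.
#' @export
read_bedgraph <- function(path, bin_size, chrom_lengths = NULL) {
  cols <- c("character", "numeric", "numeric", "numeric")
  df <- tryCatch(
    utils::read.table(path, sep = "\t", col.names = c("chrom", "start", "end", "value"),
                      colClasses = cols, comment.char = "#"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL else stop(e)
    })
  if (is.null(df) || nrow(df) == 0L) {
    if (is.null(chrom_lengths)) chrom_lengths <- c(chr1 = bin_size)
    return(coverage_track(lapply(chrom_lengths, function(L)
      rep(0, ceiling(L / bin_size))), bin_size))
  }
  if (any(df$start %% bin_size != 0 | df$end %% bin_size != 0)) {
    bad <- which(df$start %% bin_size != 0 | df$end %% bin_size != 0)[1]
    stop("bedGraph line ", bad, ": interval not aligned to ", bin_size, "-bp bins")
  }
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(df$end, df$chrom, max)
  counts <- lapply(stats::setNames(nm = names(chrom_lengths)), function(chrom) {
    v <- rep(0, ceiling(chrom_lengths[[chrom]] / bin_size))
    sub <- df[df$chrom == chrom, , drop = FALSE]
    if (nrow(sub) == 0L) return(v)
    sub <- sub[order(sub$start), , drop = FALSE]
    if (any(sub$start[-1] < sub$end[-nrow(sub)])) {
      bad <- which(sub$start[-1] < sub$end[-nrow(sub)])[1]
      stop("bedGraph: overlapping intervals on ", chrom, " near line ", bad + 1L)
    }
    for (i in seq_len(nrow(sub))) {
      idx <- (sub$start[i] %/% bin_size + 1L):(sub$end[i] %/% bin_size)
      v[idx] <- sub$value[i]
    }
    v
  })
  coverage_track(counts, bin_size)
}

#' Write a coverage track as bedGraph
#'
#' Zero bins are omitted; runs of equal values are collapsed into one
#' interval, so \code{read_bedgraph(write_bedgraph(x))} round-trips.
#'
#' @param track a \code{CoverageTrack} (or \code{NormalizedTrack} with
#'   \code{values} in place of counts).
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  vals <- if (!is.null(track$counts)) track$counts else track$values
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (chrom in names(vals)) {
    v <- vals[[chrom]]
    if (length(v) == 0L) next
    r <- rle(v)
    ends <- cumsum(r$lengths) * bs
    starts <- ends - r$lengths * bs
    keep <- r$values != 0
    if (!any(keep)) next
    utils::write.table(
      data.frame(chrom, starts[keep], ends[keep],
                 format(r$values[keep], trim = TRUE, scientific = FALSE)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Control-subtracted RPKM-normalized track
#'
#' Per bin: \code{RPKM(mark) - RPKM(control)}, where
#' \code{RPKM = 1e9 * count / (library_size * bin_width)}; a bin where mark
#' and control RPKM agree is exactly 0.
#'
#' @param mark,control \code{CoverageTrack}s with identical binning and
#'   chromosomes.
#' @return A \code{NormalizedTrack}: list with \code{bin_size} and
#'   \code{values} (floats per chromosome).
#' @export
normalize_subtract <- function(mark, control) {
  check_same_binning(mark, control)
  if (mark$library_size == 0 || control$library_size == 0)
    stop("cannot normalize a library with zero total reads")
  w <- mark$bin_size
  f_m <- 1e9 / (mark$library_size * w)
  f_c <- 1e9 / (control$library_size * w)
  values <- stats::setNames(lapply(names(mark$counts), function(chrom)
    mark$counts[[chrom]] * f_m - control$counts[[chrom]] * f_c), names(mark$counts))
  structure(list(bin_size = mark$bin_size, values = values),
            class = "NormalizedTrack")
}

check_same_binning <- function(a, b) {
  if (a$bin_size != b$bin_size) stop("tracks differ in bin_size")
  if (!identical(names(a$counts), names(b$counts)) ||
      !identical(n_bins(a), n_bins(b)))
    stop("tracks differ in chromosomes or lengths")
  invisible(TRUE)
}

#' Windowed log2 CPM mark/control matrix for replicate QC
#'
#' Aggregates each (mark, control) library pair into non-overlapping genomic
#' windows and computes \code{log2(CPM_mark + eps) - log2(CPM_control + eps)}
#' per window (eps = 0.5 CPM), the representation used for replicate
#' correlation and PCA.
#'
#' @param pairs list of \code{list(mark = CoverageTrack, control =
#'   CoverageTrack)} pairs (at least 2), optionally named.
#' @param window window width in bp; must be a multiple of the bin size.
#' @return A \code{WindowMatrix}: numeric matrix windows x libraries with a
#'   \code{windows} attribute (data.frame of window coordinates).
#' @export
window_matrix <- function(pairs, window = 2000) {
  if (length(pairs) < 2L) stop("need at least 2 library pairs")
  bs <- pairs[[1]]$mark$bin_size
  if (window %% bs != 0) stop("window must be a multiple of bin_size")
  k <- window %/% bs
  agg <- function(track) {
    unlist(lapply(track$counts, function(v) {
      n <- ceiling(length(v) / k)
      grp <- rep(seq_len(n), each = k)[seq_along(v)]
      as.vector(tapply(v, grp, sum))
    }), use.names = FALSE)
  }
  cols <- lapply(pairs, function(p) {
    check_same_binning(p$mark, p$control)
    m <- agg(p$mark) / p$mark$library_size * 1e6
    c0 <- agg(p$control) / p$control$library_size * 1e6
    log2(m + 0.5) - log2(c0 + 0.5)
  })
  mat <- do.call(cbind, unname(cols))
  colnames(mat) <- if (!is.null(names(pairs))) names(pairs)
                   else sprintf("lib%d", seq_along(pairs))
  win <- do.call(rbind, lapply(names(pairs[[1]]$mark$counts), function(chrom) {
    nb <- length(pairs[[1]]$mark$counts[[chrom]])
    n <- ceiling(nb / k)
    data.frame(chrom = chrom, start = (seq_len(n) - 1L) * window,
               end = pmin(seq_len(n) * window, nb * bs))
  }))
  attr(mat, "windows") <- win
  class(mat) <- c("WindowMatrix", class(mat))
  mat
}

#' Replicate QC: pairwise correlation and PCA over window profiles
#'
#' Pearson correlation between all library columns of a [window_matrix()],
#' pass flags at the configured threshold, and a PCA of the (centered)
#' library profiles.  A constant library column has no defined correlation;
#' it is flagged as failing rather than propagating NaN.
#'
#' @param matrix a \code{WindowMatrix}.
#' @param threshold minimum Pearson correlation with at least one other
#'   library for a library to pass QC.
#' @return A \code{QCReport} list: \code{correlation} (symmetric matrix,
#'   unit diagonal; NA against constant libraries), \code{pass} (named
#'   logical per library), \code{pca} (library scores on the PCs) and
#'   \code{explained} (proportion of variance per PC, non-increasing).
#' @export
qc_correlation_pca <- function(matrix, threshold = 0.8) {
  if (ncol(matrix) < 2L) stop("need at least 2 libraries")
  sds <- apply(matrix, 2, stats::sd)
  cmat <- suppressWarnings(stats::cor(matrix))
  cmat[sds == 0, ] <- NA_real_
  cmat[, sds == 0] <- NA_real_
  diag(cmat) <- 1
  off <- cmat
  diag(off) <- NA
  pass <- apply(off, 2, function(r) any(!is.na(r) & r >= threshold))
  pass[sds == 0] <- FALSE
  pca <- stats::prcomp(t(matrix), center = TRUE, scale. = FALSE)
  expl <- pca$sdev^2 / sum(pca$sdev^2)
  structure(list(correlation = cmat, pass = pass,
                 pca = pca$x, explained = expl, threshold = threshold),
            class = "QCReport")
}
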