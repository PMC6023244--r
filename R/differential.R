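#' Count track signal within peaks across libraries
#'
#' Sums per-bin counts over each peak interval (partial bins pro-rated by
#' overlap fraction) for every library, and carries per-million depth-scaled
#' counts alongside the raw ones.
#'
#' @param peaks a \code{PeakSet}.
#' @param tracks named list of \code{CoverageTrack}s.
#' @param meta data.frame describing the track list, one row per track, with
#'   columns \code{antibody}, \code{timepoint}, \code{replicate}.
#' @return A \code{PeakCountMatrix} list: \code{raw} and \code{cpm} matrices
#'   (peaks x libraries), \code{meta}, \code{lib_sizes}, \code{peaks}.
#' @export
count_in_peaks <- function(peaks, tracks, meta) {
  stopifnot(length(tracks) == nrow(meta),
            all(c("antibody", "timepoint", "replicate") %in% names(meta)))
  raw <- vapply(tracks, function(tr) peak_raw_counts(peaks, tr),
                numeric(nrow(peaks)))
  if (nrow(peaks) == 1L) raw <- matrix(raw, nrow = 1L)
  lib <- vapply(tracks, `[[`, numeric(1), "library_size")
  cn <- sprintf("%s_%s_r%s", meta$antibody, meta$timepoint, meta$replicate)
  colnames(raw) <- cn
  names(lib) <- cn
  cpm <- sweep(raw, 2, lib / 1e6, "/")
  structure(list(raw = raw, cpm = cpm, meta = meta, lib_sizes = lib,
                 peaks = peaks), class = "PeakCountMatrix")
}

#' Per-peak H3K4me3/H3 level ratios
#'
#' Depth-normalized mark counts divided by depth-normalized control counts
#' per peak, replicate and timepoint; the ratio is only defined where the
#' control count is positive (NA otherwise).
#'
#' @param pcm a [count_in_peaks()] result containing both antibodies.
#' @param mark,control antibody labels.
#' @return Named list (by timepoint) of peaks x replicates ratio matrices.
#' @export
normalized_peak_levels <- function(pcm, mark = "H3K4me3", control = "H3") {
  meta <- pcm$meta
  tps <- unique(meta$timepoint)
  out <- lapply(stats::setNames(nm = tps), function(tp) {
    reps <- sort(unique(meta$replicate[meta$timepoint == tp & meta$antibody == mark]))
    m <- vapply(reps, function(r) {
      im <- which(meta$antibody == mark & meta$timepoint == tp & meta$replicate == r)
      ic <- which(meta$antibody == control & meta$timepoint == tp & meta$replicate == r)
      if (length(im) != 1L || length(ic) != 1L)
        stop("missing ", mark, "/", control, " pair for ", tp, " replicate ", r)
      num <- pcm$cpm[, im]
      den <- pcm$cpm[, ic]
      ifelse(den > 0, num / den, NA_real_)
    }, numeric(nrow(pcm$raw)))
    if (nrow(pcm$raw) == 1L) m <- matrix(m, nrow = 1L)
    colnames(m) <- sprintf("r%s", reps)
    m
  })
  structure(out, class = "NormalizedPeakLevel")
}

#' Negative-binomial GLM test for differential counts
#'
#' Fits a per-feature NB log-linear model with a two-level group effect on
#' raw counts with full library sizes as offsets, estimating a common
#' dispersion by adjusted profile likelihood over all features and shrinking
#' tagwise estimates toward it (prior df 10), and computes likelihood-ratio
#' p-values for the group effect (second level vs first).
#'
#' @param counts raw count matrix, features x libraries.
#' @param groups factor (or coercible) of length \code{ncol(counts)} with
#'   exactly two levels, each with >= 2 replicates.
#' @param lib_sizes full library sizes used as offsets (default: column
#'   sums; pass total library read counts to reproduce full-library-size
#'   normalization).
#' @param dispersion optional fixed dispersion overriding estimation (e.g. 0
#'   reduces the model to Poisson).
#' @return data.frame with \code{logFC} (log2, second vs first level),
#'   \code{p} and \code{fdr} (BH).
#' @export
nb_glm_test <- function(counts, groups, lib_sizes = colSums(counts),
                        dispersion = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 replicates")
  counts <- round(as.matrix(counts))
  y <- edgeR::DGEList(counts = counts, group = groups, lib.size = lib_sizes)
  design <- stats::model.matrix(~groups)
  if (is.null(dispersion)) {
    y <- edgeR::estimateGLMCommonDisp(y, design)
    y <- edgeR::estimateGLMTagwiseDisp(y, design, prior.df = 10)
    disp <- y$tagwise.dispersion
  } else {
    disp <- pmax(dispersion, 1e-8)
  }
  fit <- edgeR::glmFit(y, design, dispersion = disp)
  lrt <- edgeR::glmLRT(fit, coef = 2)
  data.frame(logFC = lrt$table$logFC, p = lrt$table$PValue,
             fdr = stats::p.adjust(lrt$table$PValue, "BH"),
             row.names = rownames(counts))
}

#' Classify peaks as increased / decreased / stable with age
#'
#' Applies the filter stack on top of the GLM test: a peak is dynamic only if
#' (1) FDR < \code{fdr}, (2) its fold change is at least \code{min_fc} (>=
#' 30\% by default) in either direction, and (3) its mark/control level ratio
#' exceeds \code{min_ratio} in every replicate of at least one timepoint.
#'
#' @param diff a [nb_glm_test()] result (logFC oriented later vs earlier
#'   timepoint).
#' @param levels a [normalized_peak_levels()] result; ratios are checked for
#'   the timepoints in \code{timepoints}.  \code{NULL} skips the ratio filter.
#' @param fdr FDR cutoff.
#' @param min_fc minimum fold change (linear scale, e.g. 1.3 = 30\%).
#' @param min_ratio minimum mark/control ratio.
#' @param timepoints timepoints whose replicates are screened by the ratio
#'   rule.
#' @return A \code{DiffResult} data.frame: \code{logFC}, \code{p},
#'   \code{fdr}, \code{ratio_ok}, \code{class} in
#'   \{increased, decreased, stable\}.
#' @export
classify_dynamic <- function(diff, levels = NULL, fdr = 0.05, min_fc = 1.3,
                             min_ratio = 1.0, timepoints = c("D2", "D12")) {
  n <- nrow(diff)
  if (is.null(levels)) {
    ratio_ok <- rep(TRUE, n)
  } else {
    use <- levels[intersect(timepoints, names(levels))]
    if (!length(use)) stop("none of the requested timepoints present in levels")
    if (any(vapply(use, nrow, integer(1)) != n))
      stop("levels and diff are indexed by different peaks")
    ratio_ok <- Reduce(`|`, lapply(use, function(m)
      apply(m, 1, function(r) all(!is.na(r) & r > min_ratio))))
  }
  lfc_cut <- log2(min_fc)
  cls <- rep("stable", n)
  cls[diff$fdr < fdr & diff$logFC >= lfc_cut & ratio_ok] <- "increased"
  cls[diff$fdr < fdr & diff$logFC <= -lfc_cut & ratio_ok] <- "decreased"
  out <- cbind(diff, ratio_ok = ratio_ok, class = cls)
  class(out) <- c("DiffResult", "data.frame")
  out
}

#' Differential marking between two timepoints
#'
#' Runs [nb_glm_test()] on the mark libraries of two timepoints from a peak
#' count matrix and classifies peaks with [classify_dynamic()], relabeling
#' the classes by the contrast (e.g. \code{"D2>L3"}, \code{"D2<L3"},
#' \code{"ns"}).
#'
#' @param pcm a [count_in_peaks()] result.
#' @param tp_a,tp_b earlier and later timepoint labels; logFC is
#'   \code{tp_b} vs \code{tp_a}.
#' @param levels optional [normalized_peak_levels()] for the ratio filter
#'   (checked at \code{tp_a}/\code{tp_b}).
#' @param antibody mark antibody label.
#' @inheritParams classify_dynamic
#' @return A \code{DiffResult} with classes
#'   \code{"<tp_b>><tp_a>"}, \code{"<tp_b><<tp_a>"}, \code{"ns"}.
#' @export
timepoint_contrast <- function(pcm, tp_a = "L3", tp_b = "D2", levels = NULL,
                               antibody = "H3K4me3", fdr = 0.05, min_fc = 1.3,
                               min_ratio = 1.0) {
  sel <- pcm$meta$antibody == antibody & pcm$meta$timepoint %in% c(tp_a, tp_b)
  if (!any(sel)) stop("no libraries for the requested contrast")
  groups <- factor(pcm$meta$timepoint[sel], levels = c(tp_a, tp_b))
  diff <- nb_glm_test(pcm$raw[, sel, drop = FALSE], groups,
                      lib_sizes = pcm$lib_sizes[sel])
  res <- classify_dynamic(diff, levels, fdr = fdr, min_fc = min_fc,
                          min_ratio = min_ratio, timepoints = c(tp_a, tp_b))
  map <- c(increased = sprintf("%s>%s", tp_b, tp_a),
           decreased = sprintf("%s<%s", tp_b, tp_a), stable = "ns")
  res$class <- unname(map[res$class])
  res
}
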