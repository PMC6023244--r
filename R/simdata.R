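#' Configuration for the synthetic aging ChIP-seq/RNA-seq experiment
#'
#' Defines the study design the generator emulates: three ChIP replicates per
#' timepoint (L3 larvae, day-2 and day-12 adults) for an H3K4me3 antibody and
#' an H3 control antibody, plus two RNA-seq replicates at D2 and D12, over a
#' toy genome with per-gene ground truth.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp (all chromosomes equal).
#' @param n_genes total number of genes across the genome.
#' @param bin_size coverage bin width in bp.
#' @param frag_len fragment length in bp; counts are smoothed with a
#'   moving-average kernel of this width in place of fragment extension.
#' @param chip_depth expected total reads per ChIP library.
#' @param rna_depth expected total counts per RNA library.
#' @param n_chip_reps ChIP replicates per (antibody, timepoint).
#' @param n_rna_reps RNA replicates per timepoint.
#' @param timepoints ordered timepoint labels; RNA is generated for the last
#'   two (adult) timepoints.
#' @param nb_dispersion negative-binomial dispersion of per-bin ChIP counts.
#' @param rna_dispersion negative-binomial dispersion of per-gene RNA counts.
#' @param dynamic_frac fraction of genes with an age trend in H3K4me3.
#' @param effect_size |log2 fold change| (D12 vs D2) for dynamic genes.
#' @param coupling probability that a gene's H3K4me3 trend is mirrored in its
#'   RNA trend; otherwise the RNA trend is stable.
#' @param p_gene_body probability a gene's marking spans the gene body
#'   (otherwise it is TSS-peaked).
#' @param p_adult probability a gene's marking is deposited at the adult
#'   stage (low L3 signal) rather than during development.
#' @param seed integer seed; all libraries derive substream seeds from it.
#' @return A validated list of class \code{SimConfig}.
#' @export
sim_config <- function(n_chrom = 1L, chrom_length = 5e6, n_genes = 500L,
                       bin_size = 25L, frag_len = 200L,
                       chip_depth = 2e6, rna_depth = 1e6,
                       n_chip_reps = 3L, n_rna_reps = 2L,
                       timepoints = c("L3", "D2", "D12"),
                       nb_dispersion = 0.1, rna_dispersion = 0.02,
                       dynamic_frac = 0.3, effect_size = 1,
                       coupling = 0.8, p_gene_body = 0.4, p_adult = 0.5,
                       seed = 7L) {
  cfg <- list(n_chrom = as.integer(n_chrom), chrom_length = as.numeric(chrom_length),
              n_genes = as.integer(n_genes), bin_size = as.integer(bin_size),
              frag_len = as.integer(frag_len), chip_depth = as.numeric(chip_depth),
              rna_depth = as.numeric(rna_depth), n_chip_reps = as.integer(n_chip_reps),
              n_rna_reps = as.integer(n_rna_reps), timepoints = as.character(timepoints),
              nb_dispersion = as.numeric(nb_dispersion),
              rna_dispersion = as.numeric(rna_dispersion),
              dynamic_frac = as.numeric(dynamic_frac), effect_size = as.numeric(effect_size),
              coupling = as.numeric(coupling), p_gene_body = as.numeric(p_gene_body),
              p_adult = as.numeric(p_adult), seed = as.integer(seed))
  if (cfg$n_genes > 0 && cfg$n_chrom * cfg$chrom_length < cfg$n_genes * 4000)
    stop("genome too small: need chrom_length * n_chrom >= n_genes * 4 kb")
  if (cfg$chrom_length <= 0 || cfg$chip_depth <= 0 || cfg$rna_depth <= 0)
    stop("all sizes and depths must be positive")
  if (cfg$bin_size <= 0 || cfg$chrom_length %% cfg$bin_size != 0)
    stop("chrom_length must be a positive multiple of bin_size")
  if (cfg$nb_dispersion < 0 || cfg$rna_dispersion < 0) stop("dispersion must be >= 0")
  if (cfg$coupling < 0 || cfg$coupling > 1) stop("coupling must be in [0, 1]")
  for (p in c("dynamic_frac", "p_gene_body", "p_adult"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  if (length(cfg$timepoints) != 3L) stop("exactly three ordered timepoints expected")
  structure(cfg, class = "SimConfig")
}

chrom_names <- function(config) sprintf("chr%d", seq_len(config$n_chrom))

# fold multipliers of the marked region relative to background
LEVEL_FOLD <- c(low = 2, mid = 4, high = 8)
# residual fraction of adult marking present at L3 for adult-onset genes
L3_ADULT_RESIDUAL <- 0.1

#' Generate a toy gene annotation
#'
#' Places non-overlapping genes on both strands with lengths drawn uniformly
#' from 0.5-6 kb and intergenic gaps of at least 1 kb, deterministically for a
#' given seed.
#'
#' @param config a [sim_config()] object.
#' @return An \code{AnnotationSet}: a data.frame with columns \code{gene_id},
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open), \code{strand}
#'   and \code{biotype}, sorted by (chrom, start).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), biotype = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("AnnotationSet", "data.frame")
  if (config$n_genes == 0L) return(empty)
  chroms <- chrom_names(config)
  per <- diff(round(seq(0, config$n_genes, length.out = config$n_chrom + 1L)))
  with_local_seed(substream_seed(config$seed, "annotation"), {
    rows <- vector("list", config$n_chrom)
    idx0 <- 0L
    for (ci in seq_len(config$n_chrom)) {
      n_c <- per[ci]
      if (n_c == 0L) next
      len <- round(stats::runif(n_c, 500, 6000))
      need <- sum(len) + (n_c + 1L) * 1000
      if (need > config$chrom_length)
        stop("genome too small to place ", n_c, " genes on ", chroms[ci])
      extra <- config$chrom_length - need
      g <- stats::runif(n_c + 1L)
      pad <- floor(extra * g / sum(g))
      gaps <- 1000 + pad
      starts <- cumsum(gaps[seq_len(n_c)]) + cumsum(c(0, len[-n_c]))
      rows[[ci]] <- data.frame(
        gene_id = sprintf("g%05d", idx0 + seq_len(n_c)),
        chrom = chroms[ci], start = starts, end = starts + len,
        strand = sample(c("+", "-"), n_c, replace = TRUE),
        biotype = "protein_coding", stringsAsFactors = FALSE)
      idx0 <- idx0 + n_c
    }
    ann <- do.call(rbind, rows)
  })
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("AnnotationSet", "data.frame")
  ann
}

#' Assign ground-truth marking regimes to genes
#'
#' Samples, per gene, the marking geometry (TSS-peaked vs gene-body), marking
#' level, deposition onset (larval vs adult) and the age trend of the mark,
#' with a built-in dependency that makes gene-body, adult-onset marking more
#' likely to be age-dynamic than TSS, larval-onset marking.  The RNA trend
#' mirrors the H3K4me3 trend with probability \code{coupling} and is stable
#' otherwise.
#'
#' @param annotation an \code{AnnotationSet} from [generate_annotation()].
#' @param config a [sim_config()] object.
#' @return A \code{TruthTable} data.frame with one row per gene: columns
#'   \code{gene_id}, \code{pattern}, \code{level}, \code{onset}, \code{trend},
#'   \code{effect}, \code{rna_trend}, \code{rna_effect}, \code{rna_baseline}.
#' @export
assign_truth <- function(annotation, config) {
  stopifnot(inherits(config, "SimConfig"))
  if (nrow(annotation) == 0L) stop("annotation is empty")
  n <- nrow(annotation)
  # dynamic probability per (pattern, onset) group, scaled so the marginal
  # equals dynamic_frac; gene_body+adult genes are 4x as likely dynamic as
  # tss+larval genes
  w <- c(tss.larval = 1, tss.adult = 2, gene_body.larval = 2, gene_body.adult = 4)
  pg <- c(tss.larval = (1 - config$p_gene_body) * (1 - config$p_adult),
          tss.adult = (1 - config$p_gene_body) * config$p_adult,
          gene_body.larval = config$p_gene_body * (1 - config$p_adult),
          gene_body.adult = config$p_gene_body * config$p_adult)
  scale <- config$dynamic_frac / sum(pg * w)
  if (any(w * scale > 1))
    stop("dynamic_frac too large for the configured pattern/onset mix")
  with_local_seed(substream_seed(config$seed, "truth"), {
    pattern <- ifelse(stats::runif(n) < config$p_gene_body, "gene_body", "tss")
    onset <- ifelse(stats::runif(n) < config$p_adult, "adult", "larval")
    level <- sample(names(LEVEL_FOLD), n, replace = TRUE)
    p_dyn <- w[paste(pattern, onset, sep = ".")] * scale
    dynamic <- stats::runif(n) < p_dyn
    trend <- ifelse(dynamic, ifelse(stats::runif(n) < 0.5, "up", "down"), "stable")
    effect <- ifelse(trend == "up", config$effect_size,
                     ifelse(trend == "down", -config$effect_size, 0))
    coupled <- stats::runif(n) < config$coupling
    rna_trend <- ifelse(coupled, trend, "stable")
    rna_effect <- ifelse(coupled, effect, 0)
    base <- stats::rlnorm(n, meanlog = log(200), sdlog = 1)
  })
  base <- base / sum(base) * config$rna_depth
  truth <- data.frame(gene_id = annotation$gene_id, pattern = pattern,
                      level = level, onset = onset, trend = trend,
                      effect = effect, rna_trend = rna_trend,
                      rna_effect = rna_effect, rna_baseline = base,
                      stringsAsFactors = FALSE)
  class(truth) <- c("TruthTable", "data.frame")
  truth
}

# timepoint multiplier of the enrichment (above-background) component
timepoint_multiplier <- function(onset, effect, timepoint) {
  m <- rep(1, length(onset))
  if (timepoint == "L3") m <- ifelse(onset == "adult", L3_ADULT_RESIDUAL, 1)
  if (timepoint == "D12") m <- 2^effect
  m
}

#' Expected per-bin ChIP signal (the generator's mean function)
#'
#' Returns, per chromosome, the expected count in every bin for one library
#' condition: a flat background of 1 relative unit plus, for H3K4me3, a
#' TSS-centred Gaussian kernel (sd 250 bp, truncated at 1 kb) or a flat
#' plateau across the gene body, with amplitude \code{(fold - 1)} set by the
#' marking level, attenuated at L3 for adult-onset genes and scaled by
#' \code{2^effect} at D12.  H3 sees the background only.  The profile is
#' smoothed with the fragment-length kernel and scaled so its genome-wide sum
#' equals \code{chip_depth}.
#'
#' @param truth,annotation,config the simulated experiment components.
#' @param antibody \code{"H3K4me3"} or \code{"H3"}.
#' @param timepoint one of \code{config$timepoints}.
#' @return Named list (by chromosome) of expected per-bin counts.
#' @export
chip_mean_profile <- function(truth, annotation, config, antibody, timepoint) {
  if (!antibody %in% c("H3K4me3", "H3")) stop("unknown antibody: ", antibody)
  if (!timepoint %in% config$timepoints) stop("unknown timepoint: ", timepoint)
  bs <- config$bin_size
  nb <- as.integer(config$chrom_length / bs)
  prof <- stats::setNames(rep(list(rep(1, nb)), config$n_chrom), chrom_names(config))
  if (antibody == "H3K4me3" && nrow(annotation) > 0L) {
    amp <- (LEVEL_FOLD[truth$level] - 1) *
      timepoint_multiplier(truth$onset, truth$effect, timepoint)
    centers <- (seq_len(nb) - 0.5) * bs
    for (i in seq_len(nrow(annotation))) {
      chrom <- annotation$chrom[i]
      if (truth$pattern[i] == "tss") {
        tss <- if (annotation$strand[i] == "+") annotation$start[i] else annotation$end[i]
        lo <- max(1L, as.integer((tss - 1000) %/% bs) + 1L)
        hi <- min(nb, as.integer((tss + 1000) %/% bs) + 1L)
        d <- centers[lo:hi] - tss
        prof[[chrom]][lo:hi] <- prof[[chrom]][lo:hi] + amp[i] * exp(-d^2 / (2 * 250^2))
      } else {
        lo <- as.integer(annotation$start[i] %/% bs) + 1L
        hi <- min(nb, as.integer((annotation$end[i] - 1) %/% bs) + 1L)
        prof[[chrom]][lo:hi] <- prof[[chrom]][lo:hi] + amp[i]
      }
    }
  }
  w <- max(1L, config$frag_len %/% bs)
  prof <- lapply(prof, function(v) moving_sum(v, w) / w)
  tot <- sum(vapply(prof, sum, numeric(1)))
  lapply(prof, function(v) v * config$chip_depth / tot)
}

#' Simulate one binned ChIP coverage library
#'
#' Draws per-bin counts from a negative-binomial law around the generator's
#' mean function ([chip_mean_profile()]); the substream seed is derived from
#' (antibody, timepoint, replicate), so libraries are reproducible regardless
#' of generation order.
#'
#' @inheritParams chip_mean_profile
#' @param replicate replicate number (1-based).
#' @return A [coverage_track()] object.
#' @export
simulate_chip <- function(truth, annotation, config, antibody, timepoint, replicate) {
  mu <- chip_mean_profile(truth, annotation, config, antibody, timepoint)
  disp <- config$nb_dispersion
  with_local_seed(substream_seed(config$seed, "chip", antibody, timepoint, replicate), {
    counts <- lapply(mu, function(m) {
      if (disp > 0) stats::rnbinom(length(m), mu = m, size = 1 / disp)
      else stats::rpois(length(m), m)
    })
  })
  coverage_track(counts, config$bin_size)
}

#' Expected per-gene RNA mean for a timepoint
#' @keywords internal
rna_mean <- function(truth, timepoint) {
  truth$rna_baseline * 2^(truth$rna_effect * (timepoint == "D12"))
}

#' Simulate one RNA-seq count library
#'
#' Per-gene counts are negative binomial around the gene's baseline, scaled
#' by \code{2^rna_effect} at D12.
#'
#' @param truth a \code{TruthTable}.
#' @param config a [sim_config()] object.
#' @param timepoint \code{"D2"} or \code{"D12"}.
#' @param replicate replicate number.
#' @return Named integer vector of gene counts.
#' @export
simulate_rna <- function(truth, config, timepoint, replicate) {
  if (!timepoint %in% c("D2", "D12")) stop("RNA timepoint must be D2 or D12")
  mu <- rna_mean(truth, timepoint)
  disp <- config$rna_dispersion
  with_local_seed(substream_seed(config$seed, "rna", timepoint, replicate), {
    counts <- if (disp > 0) stats::rnbinom(length(mu), mu = mu, size = 1 / disp)
              else stats::rpois(length(mu), mu)
  })
  stats::setNames(as.integer(counts), truth$gene_id)
}

#' Simulate the complete experiment
#'
#' Generates the annotation, ground truth, all configured ChIP libraries
#' (both antibodies, all timepoints and replicates) and the RNA-seq count
#' table at D2/D12.
#'
#' @param config a [sim_config()] object.
#' @return A \code{SimulatedExperiment} list with elements \code{tracks}
#'   (nested \code{tracks[[antibody]][[timepoint]][[replicate]]}),
#'   \code{rna_counts} (genes x libraries integer matrix with
#'   \code{<timepoint>_r<k>} column names), \code{annotation}, \code{truth}
#'   and \code{config}.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  annotation <- generate_annotation(config)
  truth <- assign_truth(annotation, config)
  tracks <- list()
  for (ab in c("H3K4me3", "H3")) {
    tracks[[ab]] <- list()
    for (tp in config$timepoints) {
      tracks[[ab]][[tp]] <- lapply(seq_len(config$n_chip_reps), function(r)
        simulate_chip(truth, annotation, config, ab, tp, r))
    }
  }
  rna_tps <- c("D2", "D12")
  rna <- do.call(cbind, lapply(rna_tps, function(tp)
    vapply(seq_len(config$n_rna_reps), function(r)
      simulate_rna(truth, config, tp, r), integer(nrow(truth)))))
  colnames(rna) <- as.vector(outer(seq_len(config$n_rna_reps), rna_tps,
                                   function(r, tp) sprintf("%s_r%d", tp, r)))
  rownames(rna) <- truth$gene_id
  structure(list(tracks = tracks, rna_counts = rna, annotation = annotation,
                 truth = truth, config = config,
                 fingerprint = substream_seed(config$seed, "fingerprint",
                                              config$n_genes, config$chrom_length)),
            class = "SimulatedExperiment")
}

#' Monte-Carlo oracle for the coupling-induced chromatin/RNA correlation
#'
#' Computes the Spearman correlation between measured H3K4me3 and RNA log2
#' fold changes (D12 vs D2) that the generator itself induces, independently
#' of the analysis pipeline: genes are resampled from the generator's truth
#' law, replicate counts are drawn from its negative-binomial noise model at
#' its own expected per-gene means, and fold changes are taken as ratios of
#' replicate-mean counts.
#'
#' @param config a [sim_config()] object.
#' @param n number of Monte-Carlo gene draws.
#' @param seed seed for the oracle's own RNG stream.
#' @return Spearman rho (single number).
#' @export
coupling_rho <- function(config, n = 1e5, seed = 1L) {
  annotation <- generate_annotation(config)
  truth <- assign_truth(annotation, config)
  prof <- lapply(c(D2 = "D2", D12 = "D12"), function(tp)
    chip_mean_profile(truth, annotation, config, "H3K4me3", tp))
  bs <- config$bin_size
  # expected K4 count summed over each gene's marked region
  region <- data.frame(
    start = ifelse(truth$pattern == "tss",
                   ifelse(annotation$strand == "+", annotation$start - 500,
                          annotation$end - 500),
                   annotation$start),
    end = ifelse(truth$pattern == "tss",
                 ifelse(annotation$strand == "+", annotation$start + 500,
                        annotation$end + 500),
                 annotation$end))
  mu_k4 <- lapply(prof, function(p) {
    out <- numeric(nrow(truth))
    for (chrom in names(p)) {
      sel <- annotation$chrom == chrom
      out[sel] <- prorated_sum(p[[chrom]], bs, region$start[sel], region$end[sel])
    }
    out
  })
  mu_rna <- lapply(c(D2 = "D2", D12 = "D12"), function(tp) rna_mean(truth, tp))
  # a region count is a sum over independent bins, so its effective NB size
  # is (bins in region) / per-bin dispersion
  k4_size <- pmax(1, (region$end - region$start) / bs) / max(config$nb_dispersion, 1e-8)
  with_local_seed(as.integer(seed), {
    g <- sample.int(nrow(truth), n, replace = TRUE)
    nbm <- function(mu, reps, size) {
      tot <- 0
      for (r in seq_len(reps)) tot <- tot + stats::rnbinom(length(mu), mu = mu, size = size)
      tot / reps
    }
    k4_2 <- nbm(mu_k4$D2[g], config$n_chip_reps, k4_size[g])
    k4_12 <- nbm(mu_k4$D12[g], config$n_chip_reps, k4_size[g])
    rna_2 <- nbm(mu_rna$D2[g], config$n_rna_reps, 1 / max(config$rna_dispersion, 1e-8))
    rna_12 <- nbm(mu_rna$D12[g], config$n_rna_reps, 1 / max(config$rna_dispersion, 1e-8))
  })
  dk4 <- log2((k4_12 + 0.5) / (k4_2 + 0.5))
  drna <- log2((rna_12 + 0.5) / (rna_2 + 0.5))
  stats::cor(dk4, drna, method = "spearman")
}
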