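test_that("generate_annotation respects gaps, determinism and empty case", {
  cfg <- sim_config(n_genes = 0L, chrom_length = 1e5)
  expect_equal(nrow(generate_annotation(cfg)), 0L)

  cfg <- sim_config(n_genes = 500L, chrom_length = 5e6)
  ann <- generate_annotation(cfg)
  expect_identical(ann, generate_annotation(cfg))   # same seed, same output
  expect_equal(nrow(ann), 500L)
  # exhaustive sweep over sorted intervals: all gaps >= 1 kb, no overlap,
  # lengths within 0.5-6 kb
  for (chrom in unique(ann$chrom)) {
    a <- ann[ann$chrom == chrom, ]
    gaps <- a$start[-1] - a$end[-nrow(a)]
    expect_true(all(gaps >= 1000))
    expect_true(all(a$end - a$start >= 500 & a$end - a$start <= 6000))
    expect_true(all(a$start >= 0 & a$end <= cfg$chrom_length))
  }
})

test_that("annotation sizing errors when the genome is too small", {
  expect_error(sim_config(n_genes = 1000L, chrom_length = 1e6), "too small")
})

test_that("assign_truth enforces coupling semantics", {
  cfg <- small_config(coupling = 1)
  truth <- assign_truth(generate_annotation(cfg), cfg)
  expect_true(all(truth$rna_trend[truth$trend == "down"] == "down"))
  expect_true(all(truth$rna_trend == truth$trend))
  expect_true(all(truth$effect[truth$trend == "stable"] == 0))

  # coupling = 0: rna_trend constant stable, so trend/rna agreement sits at
  # the chance level P(trend = stable); check against a binomial CI at n = 2000
  big <- make_annotation(start = seq(0, by = 8000, length.out = 2000),
                         end = seq(4000, by = 8000, length.out = 2000))
  cfg0 <- sim_config(n_genes = 2000L, chrom_length = 2e7, coupling = 0)
  t0 <- assign_truth(big, cfg0)
  expect_true(all(t0$rna_trend == "stable"))
  agree <- mean(t0$trend == t0$rna_trend)
  p0 <- mean(t0$trend == "stable")
  expect_equal(agree, p0)             # exact under coupling = 0
  # chance level for the configured 30% dynamic fraction
  expect_lt(abs(agree - 0.7), 3 * sqrt(0.7 * 0.3 / 2000))
})

test_that("configured dynamic fraction is recovered within 3% at n = 2000", {
  big <- make_annotation(start = seq(0, by = 8000, length.out = 2000),
                         end = seq(4000, by = 8000, length.out = 2000))
  cfg <- sim_config(n_genes = 2000L, chrom_length = 2e7, dynamic_frac = 0.3)
  truth <- assign_truth(big, cfg)
  expect_lt(abs(mean(truth$trend != "stable") - 0.3), 0.03)
})

test_that("dynamic propensity depends on pattern and onset as designed", {
  big <- make_annotation(start = seq(0, by = 8000, length.out = 4000),
                         end = seq(4000, by = 8000, length.out = 4000))
  cfg <- sim_config(n_genes = 4000L, chrom_length = 4e7)
  truth <- assign_truth(big, cfg)
  p_gb_ad <- mean(truth$trend[truth$pattern == "gene_body" & truth$onset == "adult"] != "stable")
  p_tss_lv <- mean(truth$trend[truth$pattern == "tss" & truth$onset == "larval"] != "stable")
  expect_gt(p_gb_ad, p_tss_lv)
})

test_that("adult-onset genes have expected L3/D2 signal ratio <= 0.2 (mean function)", {
  cfg <- small_config()
  ann <- generate_annotation(cfg)
  truth <- assign_truth(ann, cfg)
  l3 <- chip_mean_profile(truth, ann, cfg, "H3K4me3", "L3")$chr1
  d2 <- chip_mean_profile(truth, ann, cfg, "H3K4me3", "D2")$chr1
  bg_l3 <- median(l3); bg_d2 <- median(d2)
  sel <- which(truth$onset == "adult" & truth$pattern == "gene_body")
  expect_gt(length(sel), 5)
  for (i in sel) {
    a <- ann[ann$gene_id == truth$gene_id[i], ]
    mid <- ((a$start + 300) %/% 25):((a$end - 300) %/% 25)  # core, kernel-free
    enr_l3 <- mean(l3[mid]) / bg_l3 - 1
    enr_d2 <- mean(d2[mid]) / bg_d2 - 1
    expect_lte(enr_l3 / enr_d2, 0.2 + 1e-6)
  }
})

test_that("simulated ChIP enriches TSS of high-level genes and is depth-linear", {
  cfg <- sim_config(n_genes = 30L, chrom_length = 3e5, chip_depth = 2e5)
  ann <- generate_annotation(cfg)
  truth <- assign_truth(ann, cfg)
  hi <- which(truth$level == "high" & truth$pattern == "tss")
  expect_gt(length(hi), 0)
  # mean over 50 replicates: TSS window mean > 4x background mean
  acc <- 0
  for (r in 1:50) acc <- acc + simulate_chip(truth, ann, cfg, "H3K4me3", "D2", r)$counts$chr1
  acc <- acc / 50
  tt <- gene_tss_tes(ann)
  tss_bins <- unlist(lapply(hi, function(i) {
    tss <- tt$tss[match(truth$gene_id[i], tt$gene_id)]
    pmax(1, ((tss - 500) %/% 25)):pmin(length(acc), ((tss + 500) %/% 25))
  }))
  ggr <- unlist(lapply(seq_len(nrow(ann)), function(i)
    ((ann$start[i] - 1200) %/% 25):((ann$end[i] + 1200) %/% 25)))
  bg_bins <- setdiff(seq_along(acc), ggr)
  expect_gt(mean(acc[tss_bins]), 4 * mean(acc[bg_bins]))

  # doubling chip_depth doubles total counts within 2%
  cfg2 <- sim_config(n_genes = 30L, chrom_length = 3e5, chip_depth = 4e5)
  t1 <- simulate_chip(truth, ann, cfg, "H3K4me3", "D2", 1)
  t2 <- simulate_chip(truth, ann, cfg2, "H3K4me3", "D2", 1)
  expect_lt(abs(t2$library_size / t1$library_size - 2), 0.02 * 2)
})

test_that("H3 coverage is blind to the truth", {
  big <- make_annotation(start = seq(0, by = 8000, length.out = 2000),
                         end = seq(4000, by = 8000, length.out = 2000))
  cfg <- sim_config(n_genes = 2000L, chrom_length = 2e7, chip_depth = 2e6)
  truth <- assign_truth(big, cfg)
  h3_d2 <- simulate_chip(truth, big, cfg, "H3", "D2", 1)$counts$chr1
  h3_d12 <- simulate_chip(truth, big, cfg, "H3", "D12", 1)$counts$chr1
  delta <- sapply(seq_len(nrow(big)), function(i) {
    idx <- (big$start[i] %/% 25 + 1):(big$end[i] %/% 25)
    mean(h3_d12[idx]) - mean(h3_d2[idx])
  })
  tr <- c(up = 1, stable = 0, down = -1)[truth$trend]
  expect_lt(abs(cor(delta, tr)), 0.05)
})

test_that("simulated RNA respects effects, null case and determinism", {
  cfg <- small_config()
  ann <- generate_annotation(cfg)
  truth <- assign_truth(ann, cfg)
  expect_identical(simulate_rna(truth, cfg, "D2", 1),
                   simulate_rna(truth, cfg, "D2", 1))
  expect_error(simulate_rna(truth, cfg, "L3", 1), "D2 or D12")

  # all-stable truth: library means equal within sampling error
  t0 <- truth; t0$rna_effect <- 0; t0$rna_trend <- "stable"
  m2 <- mean(simulate_rna(t0, cfg, "D2", 1))
  m12 <- mean(simulate_rna(t0, cfg, "D12", 1))
  expect_lt(abs(m12 / m2 - 1), 0.1)

  # rna_effect = 1 doubles the mean over 100 replicate draws
  t1 <- truth; t1$rna_effect <- 1
  g <- which.max(truth$rna_baseline)
  r2 <- sapply(1:100, function(r) simulate_rna(t1, cfg, "D2", r)[g])
  r12 <- sapply(1:100, function(r) simulate_rna(t1, cfg, "D12", r)[g])
  expect_lt(abs(mean(r12) / mean(r2) - 2), 0.25)
})

test_that("the simulated experiment is deterministic and complete", {
  cfg <- sim_config(n_genes = 20L, chrom_length = 2e5, chip_depth = 1e5,
                    rna_depth = 5e4)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$tracks, e2$tracks)
  expect_identical(e1$rna_counts, e2$rna_counts)
  expect_identical(e1$truth, e2$truth)
  for (ab in c("H3K4me3", "H3")) for (tp in cfg$timepoints)
    expect_length(e1$tracks[[ab]][[tp]], cfg$n_chip_reps)
  expect_equal(ncol(e1$rna_counts), 2L * cfg$n_rna_reps)
  expect_true(all(e1$rna_counts >= 0))
  # marginal bin means match the configured library depth within 3 SE
  tr <- e1$tracks$H3$D2[[1]]
  expect_lt(abs(tr$library_size - cfg$chip_depth),
            3 * sqrt(cfg$chip_depth * (1 + cfg$nb_dispersion * 12.5)))
})
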