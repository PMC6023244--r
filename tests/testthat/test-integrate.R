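test_that("rna_differential: null data yields no calls; effects are recovered", {
  set.seed(22)
  base <- matrix(rnbinom(400 * 2, mu = 300, size = 20), ncol = 2)
  null_counts <- cbind(base, base)   # identical libraries duplicated
  res0 <- rna_differential(null_counts, factor(c("D2", "D2", "D12", "D12"),
                                               levels = c("D2", "D12")))
  expect_equal(sum(res0$fdr < 0.05), 0L)

  # injected +/-1 log2 effects at the generator's default depth/dispersion
  cfg <- small_config()
  truth <- assign_truth(generate_annotation(cfg), cfg)
  counts <- do.call(cbind, lapply(1:2, function(r)
    cbind(simulate_rna(truth, cfg, "D2", r), simulate_rna(truth, cfg, "D12", r + 10))))
  counts <- counts[, c(1, 3, 2, 4)]
  res <- rna_differential(counts, factor(c("D2", "D2", "D12", "D12"),
                                         levels = c("D2", "D12")))
  truly <- truth$rna_trend != "stable"
  recall <- mean(res$fdr[truly] < 0.05)
  fdr_emp <- sum(res$fdr < 0.05 & !truly) / max(1, sum(res$fdr < 0.05))
  expect_gte(recall, 0.8)
  expect_lte(fdr_emp, 0.1)
  # direction classes follow the injected sign
  up <- truth$rna_trend == "up"
  expect_gt(mean(res$class[up] == "up"), 0.75)

  expect_error(rna_differential(matrix(1.5, 2, 4), c("a", "a", "b", "b")),
               "integer")
})

test_that("TMM absorbs a library-depth distortion", {
  set.seed(23)
  counts <- matrix(rnbinom(600 * 4, mu = 250, size = 20), ncol = 4)
  counts[1:60, 3:4] <- rnbinom(120, mu = 1000, size = 20)
  scaled <- counts; scaled[, 2] <- scaled[, 2] * 3L
  r1 <- rna_differential(counts, c("a", "a", "b", "b"))
  r2 <- rna_differential(scaled, c("a", "a", "b", "b"))
  # TMM compensates the depth shift; only FDR-boundary genes may flip
  expect_gte(mean((r1$fdr < 0.05) == (r2$fdr < 0.05)), 0.97)
  expect_gte(mean(r2$fdr[1:60] < 0.05), 0.9)   # the true block stays called
})

test_that("correlate_changes handles monotone pairs and aggregation", {
  x <- setNames(1:10, letters[1:10])
  y <- setNames((1:10)^3, letters[1:10])
  expect_equal(correlate_changes(x, y)$rho, 1.0)
  expect_equal(correlate_changes(x, setNames(-(1:10), letters[1:10]))$rho, -1.0)
  expect_error(correlate_changes(x[1:2], y[1:2]), "at least 3")

  # depth-weighted aggregation of multi-peak genes
  asg <- data.frame(peak_id = c("p1", "p2", "p3"), gene_id = c("g1", "g1", "g2"),
                    relation = "overlap", distance = 0)
  lfc <- c(p1 = 2, p2 = 0, p3 = 1)
  agg <- aggregate_gene_logfc(lfc, asg, weights = c(p1 = 3, p2 = 1, p3 = 1))
  expect_equal(unname(agg["g1"]), 1.5)
  expect_equal(unname(agg["g2"]), 1)
})

test_that("overlap_partition enumerates all cells and concordance", {
  universe <- sprintf("g%d", 1:10)
  marked <- universe[1:6]
  dyn_k4 <- setNames(c("up", "down", "up"), universe[c(1, 2, 7)])
  dyn_rna <- setNames(c("up", "up", "down"), universe[c(1, 3, 7)])
  op <- overlap_partition(marked, dyn_k4, dyn_rna, universe)
  expect_equal(sum(op$cells), 10L)
  expect_equal(unname(op$cells["MKR"]), 1L)  # g1
  expect_equal(unname(op$cells["MKr"]), 1L)  # g2
  expect_equal(unname(op$cells["MkR"]), 1L)  # g3
  expect_equal(unname(op$cells["mKR"]), 1L)  # g7
  expect_equal(unname(op$cells["Mkr"]), 3L)  # g4-g6
  expect_equal(unname(op$cells["mkr"]), 3L)  # g8-g10
  expect_equal(op$concordant_up, 1L)         # g1 up/up
  expect_equal(op$discordant, 1L)            # g7 up/down
  expect_equal(op$concordant_up + op$concordant_down + op$discordant,
               length(intersect(names(dyn_k4), names(dyn_rna))))
  # disjoint sets leave the triple intersection empty
  op2 <- overlap_partition(universe[1:2],
                           setNames("up", universe[3]),
                           setNames("up", universe[4]), universe)
  expect_equal(unname(op2$cells["MKR"]), 0L)
  expect_error(overlap_partition(c("zz"), dyn_k4, dyn_rna, universe), "universe")
})

test_that("length_trend measures the fraction per bin and degenerates safely", {
  lens <- setNames(c(300, 400, 1500, 1800, 6000, 8000), sprintf("p%d", 1:6))
  # all flagged: fractions 1, trend degenerate
  all_on <- setNames(rep(TRUE, 6), names(lens))
  lt <- length_trend(lens, all_on)
  expect_true(all(lt$bins$fraction == 1))
  expect_true(is.na(lt$rho))
  expect_match(lt$note, "degenerate")
  # single occupied bin: not applicable
  one <- length_trend(setNames(c(300, 310), c("a", "b")),
                      setNames(c(TRUE, FALSE), c("a", "b")))
  expect_true(is.na(one$rho))
  # longer peaks more often flagged: positive trend with small p
  set.seed(24)
  n <- 300
  L <- exp(runif(n, log(250), log(9000)))
  fl <- runif(n) < (log(L) - log(250)) / (log(9000) - log(250))
  names(L) <- names(fl) <- sprintf("q%03d", 1:n)
  lt2 <- length_trend(L, fl, seed = 1)
  expect_gt(lt2$rho, 0.5)
  expect_lt(lt2$p, 0.05)
})

test_that("geneset_overlap_test matches the enumeration oracle and calibrates", {
  universe <- sprintf("g%d", 1:200)
  flag <- universe[1:40]
  target <- universe[c(1:8, 101:132)]   # 8 flagged of 40 in target
  got <- geneset_overlap_test(flag, target, universe)
  a <- 8; b <- 32; c <- 32; d <- 128
  expect_equal(got$p, fisher_oracle(a, b, c, d))
  expect_equal(unname(got$table), c(a, b, c, d))
  # degenerate: target entirely flagged
  got2 <- geneset_overlap_test(universe[1:40], universe[1:10], universe)
  expect_true(is.infinite(got2$odds_ratio))
  expect_equal(got2$p, fisher_oracle(10, 0, 30, 160))
  # null calibration: p approximately uniform
  set.seed(25)
  ps <- replicate(300, {
    f <- sample(universe, 50)
    t <- sample(universe, 30)
    geneset_overlap_test(f, t, universe)$p
  })
  expect_gt(mean(ps > 0.5), 0.35)   # discrete p, roughly half above the median
  expect_error(geneset_overlap_test(flag, character(0), universe), "empty")
})

test_that("recover_truth: noise-free limit, null truth, determinism", {
  # near noise-free: Poisson noise only, strong effects, deep libraries
  cfg <- sim_config(n_genes = 100L, chrom_length = 1e6, chip_depth = 2e6,
                    rna_depth = 5e5, nb_dispersion = 0, effect_size = 2)
  res <- run_pipeline(cfg, n_perm = 200)
  expect_gte(res$recovery$recall, 0.95)
  expect_gte(res$recovery$precision, 0.95)

  # zero dynamic genes: precision undefined, false calls bounded by the FDR
  cfg0 <- small_config(dynamic_frac = 0)
  res0 <- run_pipeline(cfg0, n_perm = 200)
  expect_true(is.na(res0$recovery$precision) || res0$recovery$n_dynamic_peaks == 0)
  expect_lte(res0$recovery$n_dynamic_peaks / nrow(res0$peaks), 0.05)

  # determinism of the report object
  r1 <- run_pipeline(cfg0, n_perm = 100)
  r2 <- run_pipeline(cfg0, n_perm = 100)
  expect_identical(r1$recovery, r2$recovery)
  expect_identical(r1$dynamic, r2$dynamic)

  # fingerprint mismatch is a provenance error
  other <- simulate_experiment(small_config(seed = 99))
  expect_error(recover_truth(res0$dynamic, res0$contrast, res0$assignment,
                             res0$experiment, fingerprint = other$fingerprint),
               "different experiments")
})
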