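norm_track <- function(values, bin_size = 25L) {
  structure(list(bin_size = bin_size, values = list(chr1 = values)),
            class = "NormalizedTrack")
}

test_that("metagene matrix: uniform signal, strand mirroring, mean conservation", {
  nt <- norm_track(rep(3, 4000))
  ann <- make_annotation(start = c(10000, 30000), end = c(14000, 34000),
                         strand = c("+", "-"))
  mm <- metagene_matrix(ann, nt)
  expect_equal(ncol(mm), 200L)
  expect_true(all(abs(mm - 3) < 1e-9))

  # an asymmetric profile on mirrored strands gives mirror-image rows
  v <- rep(0, 4000)
  v[((10000 %/% 25) + 1):((11000 %/% 25))] <- 5   # 1 kb block at the + gene 5' end
  v[((33000 %/% 25) + 1):((34000 %/% 25))] <- 5   # same block at the - gene 5' end
  mm2 <- metagene_matrix(ann, norm_track(v))
  expect_equal(unname(mm2[1, ]), unname(mm2[2, ]), tolerance = 1e-9)

  # rebinned body mean equals the original interval mean
  set.seed(14)
  w <- rnorm(4000)
  mm3 <- metagene_matrix(ann, norm_track(w))
  body <- mm3[1, 51:150]
  orig <- mean(w[((10000 %/% 25) + 1):(14000 %/% 25)])
  expect_equal(mean(body), orig, tolerance = 1e-9)

  # genes shorter than the minimum are skipped with a warning
  ann_short <- make_annotation(start = c(1000, 30000), end = c(1100, 34000))
  expect_warning(mm4 <- metagene_matrix(ann_short, nt), "skipped")
  expect_equal(nrow(mm4), 1L)
  # genes beyond the track bounds are coordinate errors
  expect_error(metagene_matrix(make_annotation(99000, 1.2e5), nt), "bounds")
})

test_that("TSS-patterned genes peak near the 5' end of the metagene average", {
  res <- default_pipeline()
  truth <- res$experiment$truth
  tssg <- intersect(truth$gene_id[truth$pattern == "tss" & truth$level == "high"],
                    rownames(res$metagene$D2))
  prof <- average_profile(res$metagene$D2, tssg)$mean
  expect_lte(which.max(prof), 60)   # flank (50 bins) + first 10 body bins
})

test_that("k-means clustering is deterministic, exact on blobs, canonical", {
  set.seed(15)
  blob <- rbind(matrix(rnorm(20 * 4, mean = 10, sd = 0.2), ncol = 4),
                matrix(rnorm(20 * 4, mean = 0, sd = 0.2), ncol = 4))
  rownames(blob) <- sprintf("gene%02d", 1:40)
  cl <- kmeans_cluster(blob, k = 2, seed = 3)
  expect_identical(cl$labels, kmeans_cluster(blob, k = 2, seed = 3)$labels)
  # exact partition recovery; label "a" is the strongest cluster
  expect_true(all(cl$labels[1:20] == "a"))
  expect_true(all(cl$labels[21:40] == "b"))
  expect_gt(mean(cl$centroids["a", ]), mean(cl$centroids["b", ]))

  # k = 1: single cluster whose centroid is the column means
  cl1 <- kmeans_cluster(blob, k = 1, seed = 3)
  expect_true(all(cl1$labels == "a"))
  expect_equal(unname(cl1$centroids[1, ]), unname(colMeans(blob)))

  expect_error(kmeans_cluster(blob[1:3, ], k = 5), "at least k")
})

test_that("cluster labels are stable under row permutation", {
  set.seed(16)
  x <- rbind(matrix(rnorm(30, 8, 0.1), ncol = 3),
             matrix(rnorm(30, 4, 0.1), ncol = 3),
             matrix(rnorm(30, 0, 0.1), ncol = 3))
  rownames(x) <- sprintf("g%02d", 1:30)
  cl <- kmeans_cluster(x, k = 3, seed = 5)
  perm <- sample(nrow(x))
  clp <- kmeans_cluster(x[perm, ], k = 3, seed = 5)
  expect_identical(cl$labels[rownames(x)], clp$labels[rownames(x)])
})

test_that("cluster_enrichment: constant flags, exact p, flag accounting", {
  labels <- setNames(rep(c("a", "b"), each = 4), sprintf("g%d", 1:8))
  asg <- list(labels = labels)
  # constant-false flag: all p = 1
  f0 <- setNames(rep(FALSE, 8), names(labels))
  expect_true(all(cluster_enrichment(asg, f0)$p == 1))
  # [[3,1],[1,3]] -> two-sided p = 0.4857 (4 dp)
  f <- setNames(c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE), names(labels))
  ce <- cluster_enrichment(asg, f)
  expect_equal(round(ce$p[ce$cluster == "a"], 4), 0.4857)
  # flagged counts sum to the total number of flagged genes
  expect_equal(sum(ce$n_flagged), sum(f))
  expect_error(cluster_enrichment(asg, f0[1:3]), "every clustered gene")
})

test_that("group_contrast reduces to cluster_enrichment for one cluster", {
  labels <- setNames(sample(letters[1:3], 60, replace = TRUE), sprintf("g%d", 1:60))
  asg <- list(labels = labels)
  set.seed(17)
  f <- setNames(runif(60) < 0.3, names(labels))
  gc <- group_contrast(asg, "b", f)
  ce <- cluster_enrichment(asg, f)
  expect_equal(gc$p, ce$p[ce$cluster == "b"])
  # all flags inside group_a: infinite odds ratio, exact p
  f2 <- setNames(labels == "a", names(labels))
  gc2 <- group_contrast(asg, "a", f2)
  expect_true(is.infinite(gc2$odds_ratio))
  expect_equal(gc2$p, fisher_oracle(sum(labels == "a"), 0, 0, sum(labels != "a")))
  expect_error(group_contrast(asg, letters[1:3], f), "proper subset")
})

test_that("average_profile is linear and handles singletons", {
  m <- matrix(1:12, nrow = 3, dimnames = list(c("x", "y", "z"), NULL))
  expect_equal(unname(average_profile(m, "y")$mean), unname(m["y", ]))
  a <- average_profile(m, c("x"))$mean
  b <- average_profile(m, c("y", "z"))$mean
  ab <- average_profile(m, c("x", "y", "z"))$mean
  expect_equal((a + 2 * b) / 3, ab)
  expect_error(average_profile(m, character(0)), "empty")
})

test_that("adult-onset dynamic genes show depressed L3 metagene signal", {
  res <- default_pipeline()
  exp <- res$experiment
  norm_l3 <- normalize_subtract(pool_tracks(exp$tracks$H3K4me3$L3),
                                pool_tracks(exp$tracks$H3$L3))
  norm_d2 <- normalize_subtract(pool_tracks(exp$tracks$H3K4me3$D2),
                                pool_tracks(exp$tracks$H3$D2))
  adult_dyn <- exp$truth$gene_id[exp$truth$onset == "adult" &
                                   exp$truth$trend != "stable"]
  ann <- exp$annotation[exp$annotation$gene_id %in% adult_dyn, ]
  l3 <- average_profile(metagene_matrix(ann, norm_l3), ann$gene_id)$mean
  d2 <- average_profile(metagene_matrix(ann, norm_d2), ann$gene_id)$mean
  body <- 51:150
  expect_lt(mean(l3[body]), 0.5 * mean(d2[body]))
})
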