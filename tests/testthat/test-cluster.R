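test_that("profile matrix averages log2 RPKM over replicates", {
  d <- mini_design(doses = c(0, 1000), reps = 3)
  m <- rbind(c(1, 1, 1, 1, 3, 2), c(0, 0, 0, 0, 0, 0))
  rpkm <- as_counts(m, d)
  prof <- build_profile_matrix(rpkm, d, c("g001", "g002"), pseudocount = 1)
  expect_equal(prof[["WT|0"]], c(1, 0))        # log2(1+1) = 1; log2(0+1) = 0
  expect_equal(prof[["WT|1000"]][1], mean(log2(c(1, 3, 2) + 1)))
  expect_error(build_profile_matrix(rpkm, d, "missing_gene"), "absent")
  # columns are genotype-major, dose ascending
  expect_equal(names(prof)[-1], c("WT|0", "WT|1000"))
})

test_that("Ward clustering separates blobs and is permutation-stable", {
  set.seed(8)
  blob <- rbind(
    matrix(rnorm(30 * 5, 0, 1), ncol = 5),
    matrix(rnorm(30 * 5, 20, 1), ncol = 5)
  )
  prof <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%03d", 1:60)),
    tibble::as_tibble(blob, .name_repair = ~paste0("c", 1:5))
  )
  hc <- hierarchical_cluster(prof, k = 2)
  truth <- rep(1:2, each = 30)
  expect_equal(length(unique(paste(hc$assignment$cluster, truth))), 2)

  # shuffling rows relabels but preserves the partition
  perm <- sample(60)
  hc2 <- hierarchical_cluster(prof[perm, ], k = 2)
  a <- hc$assignment$cluster[match(hc2$assignment$gene_id,
                                   hc$assignment$gene_id)]
  expect_equal(length(unique(paste(a, hc2$assignment$cluster))), 2)

  # k = n gives singletons; duplicated rows co-cluster below that
  hc3 <- hierarchical_cluster(prof, k = 60)
  expect_equal(sort(unique(hc3$assignment$cluster)), 1:60)
  dup <- prof
  dup[2, -1] <- dup[1, -1]
  hc4 <- hierarchical_cluster(dup, k = 30)
  expect_equal(hc4$assignment$cluster[1], hc4$assignment$cluster[2])
  expect_error(hierarchical_cluster(prof, k = 61), "exceeds")
})

test_that("direction calls compare top dose to zero dose strictly", {
  d <- mini_design(doses = c(0, 100, 1000), reps = 1)
  m <- rbind(c(1, 3, 5), c(5, 3, 1), c(2, 9, 2))
  r <- as_counts(m, d)
  dir <- classify_direction(r, d)
  expect_equal(dir$direction, c("up", "down", "unchanged"))
  expect_error(classify_direction(r, d, genotype = "T58A"), "lacks samples")
})

test_that("resampling median test handles extremes and degenerate B", {
  set.seed(1)
  bg <- rnorm(500, 1000, 10)
  out <- resampling_median_test(rep(100, 20), bg, B = 999, seed = 3)
  expect_equal(out$p_value, 2 / 1000)
  expect_equal(out$direction, "lower")
  expect_error(resampling_median_test(1:10, 1:5), "background smaller")
  degenerate <- resampling_median_test(rnorm(5), rnorm(10), B = 1, seed = 1)
  expect_lte(degenerate$p_value, 1)
  # reproducible under a fixed seed
  a <- resampling_median_test(bg[1:20], bg, B = 200, seed = 7)
  b <- resampling_median_test(bg[1:20], bg, B = 200, seed = 7)
  expect_identical(a, b)
})

test_that("categorical enrichment covers equal, extreme and empty cases", {
  even <- categorical_enrichment_test(rep(c(TRUE, FALSE), 50),
                                      rep(c(TRUE, FALSE), 500))
  expect_gt(even$p_value, 0.9)
  expect_equal(even$direction, "none")

  extreme <- categorical_enrichment_test(rep(c(TRUE, FALSE), c(25, 25)),
                                         rep(c(TRUE, FALSE), c(5, 995)))
  expect_lt(extreme$p_value, 1e-6)
  expect_equal(extreme$direction, "over")

  empty <- categorical_enrichment_test(rep(FALSE, 30), rep(FALSE, 300))
  expect_equal(empty$p_value, 1)
})

test_that("cluster table reports the characterization battery", {
  sim <- tiny_sim()
  lens <- setNames(sim$truth$gene_length, sim$truth$gene_id)
  rpkm <- compute_rpkm(sim$counts, lens)
  genes <- sim$truth$gene_id
  # two synthetic clusters: genes with E-boxes at 100 bp vs genes at 5000 bp
  assignment <- tibble::tibble(gene_id = genes[1:40],
                               cluster = rep(1:2, each = 20))
  distances <- tibble::tibble(
    gene_id = genes,
    min_distance_bp = c(rep(100, 20), rep(5000, 20), rep(5000, 80)),
    ebox_within_1kb = c(rep(TRUE, 20), rep(FALSE, 100))
  )
  ann <- sim$truth[, c("gene_id", "gene_length", "biotype")]
  tab <- build_cluster_table(assignment, rpkm, sim$design, ann, distances,
                             background_genes = genes[41:120],
                             B = 500, seed = 5)
  expect_equal(nrow(tab), 2)
  expect_equal(sum(tab$n_genes), 40)
  expect_true(abs(tab$pct_up + tab$pct_down - 100)[1] <= 100) # bounded shares
  # cluster 1 has planted-near E-boxes: flagged shorter and significant
  expect_equal(tab$distance_direction[1], "lower")
  expect_lt(tab$distance_padj[1], 0.02)
  expect_equal(tab$median_min_tss_ebox_bp[1], 100)
  expect_gt(tab$pct_with_ebox_1kb[1], 99)
  expect_equal(tab$pct_with_ebox_1kb[2], 0)
  # with a single cluster, BH leaves p unchanged
  tab1 <- build_cluster_table(assignment[1:20, ], rpkm, sim$design, ann,
                              distances, background_genes = genes[41:120],
                              B = 200, seed = 5)
  expect_equal(tab1$length_padj, tab1$length_p)
})
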