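test_that("saturated factorial fit reproduces condition averages", {
  # equal offsets: the NB cell MLE has the closed form mean(y) / lam
  s <- simulate_experiment(sim_config(n_genes = 60, rng_seed = 21))
  lib <- setNames(rep(1e6, nrow(s$design)), s$design$sample_id)
  fits <- fit_gene_models(s$counts, s$design, dispersion = 0.3,
                          library_sizes = lib)
  Y <- as.matrix(s$counts[, -1])
  rownames(Y) <- s$counts$gene_id
  for (j in sample(nrow(fits$cells), 5)) {
    idx <- s$design$genotype == fits$cells$genotype[j] &
      s$design$dose == fits$cells$dose[j]
    expected <- rowMeans(Y[, idx])
    got <- fits$fitted_cpm[, j]
    ok <- expected > 0
    expect_equal(got[ok], expected[ok], tolerance = 1e-6)
  }
})

test_that("dispersion estimator recovers the truth and respects the floor", {
  # Poisson-like data: median estimate near zero
  cfg <- sim_config(n_genes = 400, frac_regulated = 0,
                    dispersion_shape = 2, dispersion_rate = 2e7, rng_seed = 31)
  sim <- simulate_experiment(cfg)
  d0 <- estimate_dispersion(sim$counts, sim$design)
  expect_lt(median(d0$dispersion), 0.05)
  expect_true(all(d0$dispersion >= 0))

  # data at true dispersion 0.4: median inside [0.2, 0.6]
  cfg <- sim_config(n_genes = 800, frac_regulated = 0,
                    dispersion_shape = 4e6, dispersion_rate = 1e7, rng_seed = 32)
  sim <- simulate_experiment(cfg)
  d4 <- estimate_dispersion(sim$counts, sim$design)
  expect_gt(median(d4$dispersion), 0.2)
  expect_lt(median(d4$dispersion), 0.6)
})

test_that("constant counts give a zero gene-wise dispersion estimate", {
  d <- mini_design(doses = c(0, 25, 1000), reps = 3)
  m <- rbind(rep(50, 9), rep(c(10, 20, 400), each = 3))
  cts <- as_counts(m, d)
  est <- estimate_dispersion(cts, d, library_sizes = setNames(rep(1e6, 9),
                                                              d$sample_id))
  expect_lt(est$dispersion_genewise[1], 1e-4)
  expect_true(all(est$dispersion >= 0))
})

test_that("no-replicate designs demand the common-dispersion fallback", {
  d <- mini_design(doses = c(0, 25, 1000), reps = 1)
  cts <- as_counts(matrix(rpois(9, 50), nrow = 3), d)
  expect_error(estimate_dispersion(cts, d), "common_dispersion")
  est <- estimate_dispersion(cts, d, common_dispersion = TRUE)
  expect_equal(length(unique(est$dispersion_genewise)), 1)
})

test_that("mutant-only responders hit the differential test, not the WT test", {
  # WT flat, T58A strongly dose-responsive for every gene
  cfg <- sim_config(n_genes = 50, frac_regulated = 0,
                    frac_mutant_differential = 1,
                    amplitude_range = c(2, 2),
                    dispersion_shape = 5e5, dispersion_rate = 1e7,
                    rng_seed = 41)
  sim <- simulate_experiment(cfg)
  tr <- sim$truth
  a_only <- grepl("^T58A$", tr$differential_in) & !tr$regulated
  expect_gte(sum(a_only), 10)
  # true library sizes: with nearly every gene responding, column sums would
  # confound normalization with the planted signal
  fit <- fit_dose_response(sim$counts, sim$design,
                           library_sizes = sim$library_sizes)
  r <- tidy(fit)[match(tr$gene_id[a_only], tidy(fit)$gene_id), ]
  expect_true(all(r$q_t58a < 0.01))
  expect_gt(median(r$p_wt), 0.1)
})

test_that("BH machinery behaves on degenerate inputs", {
  sim <- tiny_sim()
  fits <- fit_gene_models(sim$counts[1, , drop = FALSE], sim$design,
                          dispersion = 0.1)
  res <- test_and_adjust(fits)
  expect_equal(res$q_wt, res$p_wt) # single gene: q = p
  # monotone p implies monotone q on a larger table
  full <- test_and_adjust(fit_gene_models(sim$counts, sim$design,
                                          dispersion = 0.1))
  ord <- order(full$p_wt)
  expect_true(all(diff(full$q_wt[ord]) >= -1e-12))
})

test_that("the selection rule applies both thresholds with correct bounds", {
  res <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    q_wt = c(0.005, 0.005, 0.02),
    fold_wt = log2(c(2.0, 1.9, 10))
  )
  flags <- select_models(res, q_max = 0.01, min_fold = 2)
  expect_equal(flags$regulated_wt, c(TRUE, FALSE, FALSE))
})

test_that("selection is invariant to gene and sample order", {
  sim <- tiny_sim()
  fit <- fit_dose_response(sim$counts, sim$design)
  perm_genes <- sample(nrow(sim$counts))
  perm_samples <- c("gene_id", sample(setdiff(names(sim$counts), "gene_id")))
  counts2 <- sim$counts[perm_genes, perm_samples]
  fit2 <- fit_dose_response(counts2, sim$design)
  a <- tidy(fit)[order(tidy(fit)$gene_id), c("gene_id", "regulated_wt",
                                             "diff_t58a", "diff_t58i")]
  b <- tidy(fit2)[order(tidy(fit2)$gene_id), c("gene_id", "regulated_wt",
                                               "diff_t58a", "diff_t58i")]
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("QL F-tests broadly agree with the reference NB framework", {
  skip_if_not_installed("edgeR")
  cfg <- sim_config(n_genes = 300, rng_seed = 51)
  sim <- simulate_experiment(cfg)
  fit <- fit_dose_response(sim$counts, sim$design)
  r <- tidy(fit)

  Y <- as.matrix(sim$counts[, -1])
  rownames(Y) <- sim$counts$gene_id
  wt <- sim$design$genotype == "WT"
  dge <- edgeR::DGEList(Y[r$gene_id, wt])
  dge <- edgeR::calcNormFactors(dge, method = "none")
  mm <- stats::model.matrix(~factor(sim$design$dose[wt]))
  dge <- edgeR::estimateDisp(dge, mm)
  qf <- edgeR::glmQLFit(dge, mm)
  et <- edgeR::glmQLFTest(qf, coef = 2:ncol(mm))
  expect_gt(cor(-log10(r$p_wt + 1e-300),
                -log10(et$table$PValue + 1e-300),
                method = "spearman"), 0.9)
  # the same genes are called at a permissive threshold
  agree <- mean((r$p_wt < 0.01) == (et$table$PValue < 0.01))
  expect_gt(agree, 0.85)
})

test_that("tidy and glance expose the fit consistently", {
  sim <- tiny_sim()
  fit <- fit_dose_response(sim$counts, sim$design)
  td <- tidy(fit)
  gl <- glance(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_retained, length(fit$retained))
  expect_equal(gl$n_regulated_wt, sum(td$regulated_wt))
  expect_true(all(td$q_wt >= td$p_wt - 1e-12))
  expect_true(all(td$p_wt >= 0 & td$p_wt <= 1, na.rm = TRUE))
})
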