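test_that("Venn regions follow the three-flag truth table", {
  flags <- tibble::tibble(
    gene_id = paste0("g", 1:8),
    regulated_wt = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    diff_t58a = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE),
    diff_t58i = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  )
  v <- venn_decompose(flags)
  expect_equal(as.character(v$venn_set), c("A", "B", "C", "D", "E", "F", "G"))
  expect_equal(nrow(v), 7) # the all-FALSE gene is excluded
})

test_that("Venn decomposition partitions flagged genes on random inputs", {
  set.seed(12)
  for (i in 1:20) {
    flags <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:200),
      regulated_wt = runif(200) < 0.4,
      diff_t58a = runif(200) < 0.2,
      diff_t58i = runif(200) < 0.2
    )
    v <- venn_decompose(flags)
    n_flagged <- sum(flags$regulated_wt | flags$diff_t58a | flags$diff_t58i)
    expect_equal(nrow(v), n_flagged)              # union = flagged genes
    expect_equal(anyDuplicated(v$gene_id), 0)     # disjoint regions
    # idempotent recomputation
    expect_identical(v, venn_decompose(flags))
    # B+C+F = flagged-not-WT, D+E+G = flagged-and-WT
    tab <- table(v$venn_set)
    expect_equal(sum(tab[c("B", "C", "F")]),
                 sum(!flags$regulated_wt & (flags$diff_t58a | flags$diff_t58i)))
    expect_equal(sum(tab[c("D", "E", "G")]),
                 sum(flags$regulated_wt & (flags$diff_t58a | flags$diff_t58i)))
  }
})

test_that("Fisher overlap matches closed forms and boundary cases", {
  # |x| = |y| = 3, universe 6, overlap 3: p = 1/C(6,3) = 0.05
  r <- fisher_overlap(letters[1:3], letters[1:3], letters[1:6])
  expect_equal(r$p_value, 0.05)
  expect_equal(r$n_overlap, 3)

  # forced overlap: x subset of y = universe
  r2 <- fisher_overlap(letters[1:3], letters[1:10], letters[1:10])
  expect_equal(r2$p_value, 1)

  # independence-scale overlap is unremarkable
  set.seed(3)
  univ <- sprintf("g%03d", 1:200)
  x <- sample(univ, 50)
  y <- sample(univ, 40)
  r3 <- fisher_overlap(x, y, univ)
  expect_gt(r3$p_value, 0.05)
  expect_error(fisher_overlap(x, y, character(0)), "empty universe")
})

test_that("hypergeometric tails agree with explicit summation and fisher.test", {
  set.seed(4)
  for (i in 1:30) {
    N <- sample(5:25, 1)
    nx <- sample(0:N, 1)
    ny <- sample(0:N, 1)
    ks <- max(0, nx + ny - N):min(nx, ny)
    k <- ks[sample.int(length(ks), 1)]
    pg <- dosegrade:::overlap_pvalue(k, nx, ny, N, "greater")
    pl <- dosegrade:::overlap_pvalue(k, nx, ny, N, "less")
    expect_equal(pg, sum_hyper(k, nx, ny, N, "greater"), tolerance = 1e-12)
    expect_equal(pl, sum_hyper(k, nx, ny, N, "less"), tolerance = 1e-12)
    tab <- matrix(c(k, nx - k, ny - k, N - nx - ny + k), 2)
    expect_equal(dosegrade:::overlap_pvalue(k, nx, ny, N, "two.sided"),
                 fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("set-by-cluster heatmap flags planted structure with signed scores", {
  set.seed(21)
  universe <- sprintf("g%03d", 1:300)
  clusters <- tibble::tibble(gene_id = universe,
                             cluster = rep(1:3, each = 100))
  # a Venn set built inside cluster 1
  venn <- tibble::tibble(gene_id = c(universe[1:40], universe[201:205]),
                         venn_set = factor(rep(c("A", "B"), c(40, 5)),
                                           levels = LETTERS[1:7]))
  hm <- sets_by_clusters_heatmap(venn, clusters)
  cell <- hm[hm$venn_set == "A" & hm$cluster == "1", ]
  expect_equal(cell$direction, "over")
  expect_gt(cell$signed_log10_padj, 2)
  other <- hm[hm$venn_set == "A" & hm$cluster != "1", ]
  expect_true(all(other$signed_log10_padj <= 0 | other$padj > 0.05))

  # single set x single cluster: adjusted p is the raw minimum tail
  v1 <- venn[venn$venn_set == "A", ]
  c1 <- clusters[clusters$cluster == 1, ]
  hm1 <- sets_by_clusters_heatmap(v1, c1, universe = universe)
  expect_equal(nrow(hm1), 1)
  expect_equal(hm1$padj, min(hm1$p_over, hm1$p_under) * 2, tolerance = 1e-9)
})

test_that("random assignments rarely produce significant heatmap cells", {
  set.seed(31)
  universe <- sprintf("g%03d", 1:400)
  n_bad <- 0
  for (i in 1:25) {
    clusters <- tibble::tibble(gene_id = universe,
                               cluster = sample(rep(1:4, each = 100)))
    venn <- tibble::tibble(
      gene_id = sample(universe, 120),
      venn_set = factor(sample(LETTERS[1:3], 120, replace = TRUE),
                        levels = LETTERS[1:7])
    )
    hm <- sets_by_clusters_heatmap(venn, clusters, universe = universe)
    if (any(hm$padj < 0.05)) n_bad <- n_bad + 1
  }
  expect_lte(n_bad, 3) # >= ~95% of runs clean
})

test_that("GMT over-representation matches its closed form", {
  universe <- sprintf("g%03d", 1:100)
  collection <- list(hit = universe[1:3], miss = c("x1", "x2"),
                     broad = universe[1:50])
  expect_message(
    res <- ora_gmt(universe[1:3], collection, universe),
    "skipped"
  )
  expect_equal(res$p_value[res$set == "hit"], 1 / choose(100, 3),
               tolerance = 1e-12)
  disjoint <- ora_gmt(universe[60:62], list(s = universe[1:3]), universe)
  expect_equal(disjoint$p_value, 1)
})

test_that("external overlaps apply ortholog maps and guard empty input", {
  universe <- sprintf("mg%03d", 1:100)
  setA <- universe[1:20]
  # external list in a foreign namespace, 12 of 100 entries unmappable and
  # only 30 of the mapped orthologs detected in the universe
  ext <- c(sprintf("HS%03d", 1:88), sprintf("NOPE%02d", 1:12))
  map <- tibble::tibble(from = sprintf("HS%03d", 1:88),
                        to = c(universe[1:30], sprintf("undetected%02d", 1:58)))
  expect_message(
    r <- external_overlap(setA, ext, universe, ortholog_map = map),
    "12/100"
  )
  expect_equal(r$n_mapped, 88)
  expect_equal(r$n_overlap, 20)
  expect_lt(r$p_value, 1e-4)

  expect_error(external_overlap(setA, sprintf("ZZ%02d", 1:5), universe),
               "disjoint")
  expect_error(
    external_overlap(setA, sprintf("ZZ%02d", 1:5), universe,
                     ortholog_map = map),
    "mapped"
  )
})
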