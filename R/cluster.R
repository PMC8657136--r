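#' Build the replicate-averaged log2 RPKM profile matrix
#'
#' One row per selected gene, one column per (genotype, dose) condition in
#' genotype-major order with doses ascending; entries are the mean over
#' replicates of `log2(RPKM + pseudocount)`.
#'
#' @param rpkm RPKM tibble from [compute_rpkm()].
#' @param design Design tibble.
#' @param genes Gene ids to include (must all be present in `rpkm`).
#' @param pseudocount Added before the log transform (default 1).
#' @return A tibble with `gene_id` and one column per condition
#'   (`"<genotype>|<dose>"`).
#' @export
build_profile_matrix <- function(rpkm, design, genes, pseudocount = 1) {
  missing <- setdiff(genes, rpkm$gene_id)
  if (length(missing) > 0) {
    stop("genes absent from rpkm: ", paste(head(missing, 5), collapse = ", "))
  }
  m <- counts_matrix(rpkm)[genes, design$sample_id, drop = FALSE]
  lg <- log2(m + pseudocount)
  cells <- cell_layout(design)
  prof <- vapply(seq_len(nrow(cells)), function(j) {
    idx <- design$genotype == cells$genotype[j] & design$dose == cells$dose[j]
    rowMeans(lg[, idx, drop = FALSE])
  }, numeric(length(genes)))
  if (length(genes) == 1) prof <- matrix(prof, nrow = 1)
  colnames(prof) <- cells$cell
  dplyr::bind_cols(tibble::tibble(gene_id = genes), tibble::as_tibble(prof))
}

#' Ward hierarchical clustering of expression profiles
#'
#' Agglomerative clustering with Euclidean distances and Ward's method
#' (`ward.D2`, which operates on the unsquared distances as Ward's criterion
#' requires), cut to exactly `k` flat clusters. Deterministic for a fixed
#' row order.
#'
#' @param profiles Profile tibble from [build_profile_matrix()].
#' @param k Number of clusters (default 12).
#' @return A list with `assignment` (tibble `gene_id`, `cluster`) and `tree`
#'   (the `hclust` object).
#' @export
hierarchical_cluster <- function(profiles, k = 12) {
  m <- counts_matrix(profiles)
  if (k > nrow(m)) stop("k exceeds the number of genes")
  tree <- hclust(dist(m, method = "euclidean"), method = "ward.D2")
  cl <- cutree(tree, k = k)
  list(
    assignment = tibble::tibble(gene_id = rownames(m), cluster = unname(cl)),
    tree = tree
  )
}

#' Export a dendrogram in Newick format
#'
#' @param tree An `hclust` object.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the ape package is required for Newick export")
  }
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Classify the regulation direction of each gene
#'
#' Compares the replicate-mean RPKM at the top dose against the zero dose
#' (strict inequalities; equality gives `"unchanged"`), by default on the
#' reference genotype's samples.
#'
#' @param rpkm RPKM tibble.
#' @param design Design tibble.
#' @param genotype Genotype whose profile is classified (default `"WT"`).
#' @return Tibble with `gene_id`, `rpkm_zero`, `rpkm_top`, `direction`
#'   (`"up"`, `"down"` or `"unchanged"`).
#' @export
classify_direction <- function(rpkm, design, genotype = "WT") {
  m <- counts_matrix(rpkm)
  doses <- sort(unique(design$dose))
  lo <- design$sample_id[design$genotype == genotype & design$dose == doses[1]]
  hi <- design$sample_id[design$genotype == genotype &
                           design$dose == doses[length(doses)]]
  if (length(lo) == 0 || length(hi) == 0) {
    stop("genotype ", genotype, " lacks samples at an endpoint dose")
  }
  v0 <- rowMeans(m[, lo, drop = FALSE])
  v1 <- rowMeans(m[, hi, drop = FALSE])
  tibble::tibble(
    gene_id = rownames(m),
    rpkm_zero = v0,
    rpkm_top = v1,
    direction = dplyr::case_when(v1 > v0 ~ "up", v1 < v0 ~ "down",
                                 TRUE ~ "unchanged")
  )
}

#' Resampling test for a cluster median against a background
#'
#' Draws `B` samples of the cluster's size without replacement from the
#' background values and compares the observed cluster median with the
#' resampled medians. The empirical two-sided p-value is
#' `2 * min(r_low + 1, r_high + 1) / (B + 1)`, capped at 1, where
#' `r_low`/`r_high` count resampled medians at or below/above the observed
#' one.
#'
#' @param cluster_values Numeric values for the cluster's genes.
#' @param background_values Values for the background (non-regulated) genes;
#'   must be at least as many as the cluster's.
#' @param B Number of resamples (default 1000).
#' @param seed Seed for the resampling generator.
#' @return Tibble with `observed_median`, `background_median`, `p_value`,
#'   `direction` (`"shorter"`/`"longer"` style handled by the caller via
#'   sign: here `"lower"`/`"higher"`).
#' @export
resampling_median_test <- function(cluster_values, background_values,
                                   B = 1000, seed = 1L) {
  n <- length(cluster_values)
  if (length(background_values) < n) {
    stop("background smaller than cluster")
  }
  obs <- median(cluster_values)
  set.seed(seed)
  meds <- vapply(seq_len(B), function(b) {
    median(sample(background_values, n))
  }, numeric(1))
  r_low <- sum(meds <= obs)
  r_high <- sum(meds >= obs)
  p <- min(1, 2 * min(r_low + 1, r_high + 1) / (B + 1))
  tibble::tibble(
    observed_median = obs,
    background_median = median(background_values),
    p_value = p,
    direction = dplyr::case_when(obs < median(meds) ~ "lower",
                                 obs > median(meds) ~ "higher",
                                 TRUE ~ "none")
  )
}

#' Categorical enrichment of a flag in a cluster versus background
#'
#' 2x2 chi-squared test (with continuity correction) comparing the fraction
#' of flagged genes in the cluster against the background; falls back to
#' Fisher's exact test when any expected cell is below 1.
#'
#' @param cluster_flags Logical vector for the cluster's genes.
#' @param background_flags Logical vector for the background genes.
#' @return Tibble with `cluster_fraction`, `background_fraction`, `p_value`,
#'   `direction` (`"over"`, `"under"` or `"none"`), `method`.
#' @export
categorical_enrichment_test <- function(cluster_flags, background_flags) {
  tab <- rbind(
    c(sum(cluster_flags), sum(!cluster_flags)),
    c(sum(background_flags), sum(!background_flags))
  )
  fc <- mean(cluster_flags)
  fb <- mean(background_flags)
  if (all(tab == 0)) {
    return(tibble::tibble(cluster_fraction = fc, background_fraction = fb,
                          p_value = 1, direction = "none", method = "degenerate"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1) || any(colSums(tab) == 0)) {
    p <- fisher.test(tab)$p.value
    method <- "fisher"
  } else {
    p <- suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
    method <- "chisq"
  }
  tibble::tibble(
    cluster_fraction = fc,
    background_fraction = fb,
    p_value = p,
    direction = dplyr::case_when(fc > fb ~ "over", fc < fb ~ "under",
                                 TRUE ~ "none"),
    method = method
  )
}

#' Cluster characterization table
#'
#' One row per cluster with the quantitative characterization battery:
#' size, percent up/down-regulated (top dose vs zero dose on the reference
#' genotype), overall pattern (direction of more than half the genes),
#' median RPKM, percent non-coding with chi-squared enrichment, median gene
#' length with a resampling test, percent of genes with an E-box within
#' `ebox_window` bp of the TSS with chi-squared enrichment, and median
#' minimal TSS-E-box distance with a resampling test. Enrichment p-values
#' are BH-adjusted across clusters within each statistic; significance
#' thresholds are 0.05 (categorical) and 0.02 (resampling) on the adjusted
#' scale.
#'
#' @param assignment Tibble `gene_id`, `cluster` from
#'   [hierarchical_cluster()].
#' @param rpkm RPKM tibble.
#' @param design Design tibble.
#' @param annotation Tibble with `gene_id`, `gene_length`, `biotype`.
#' @param distances Tibble from [gene_min_distance()] (`gene_id`,
#'   `min_distance_bp`, `ebox_within_1kb`).
#' @param background_genes Gene ids of the non-regulated background.
#' @param genotype Genotype used for direction calls.
#' @param B Resamples per resampling test.
#' @param seed Resampling seed.
#' @return Tibble with one row per cluster.
#' @export
build_cluster_table <- function(assignment, rpkm, design, annotation,
                                distances, background_genes,
                                genotype = "WT", B = 1000, seed = 1L) {
  dirs <- classify_direction(rpkm, design, genotype = genotype)
  m <- counts_matrix(rpkm)
  med_rpkm <- apply(m, 1, median)
  ann <- annotation |>
    dplyr::left_join(distances, by = "gene_id") |>
    dplyr::left_join(dirs[, c("gene_id", "direction")], by = "gene_id") |>
    dplyr::mutate(median_rpkm = med_rpkm[.data$gene_id])

  bg <- ann |> dplyr::filter(.data$gene_id %in% background_genes)
  clusters <- sort(unique(assignment$cluster))

  rows <- purrr::map_dfr(seq_along(clusters), function(i) {
    cl <- clusters[i]
    genes <- assignment$gene_id[assignment$cluster == cl]
    a <- ann |> dplyr::filter(.data$gene_id %in% genes)
    pct_up <- 100 * mean(a$direction == "up")
    pct_down <- 100 * mean(a$direction == "down")
    pattern <- dplyr::case_when(pct_up > 50 ~ "up", pct_down > 50 ~ "down",
                                TRUE ~ "mixed")
    nc <- categorical_enrichment_test(a$biotype == "non_coding",
                                      bg$biotype == "non_coding")
    len <- resampling_median_test(a$gene_length, bg$gene_length, B = B,
                                  seed = derive_seed(seed, paste0("len", cl)))
    eb <- categorical_enrichment_test(
      !is.na(a$ebox_within_1kb) & a$ebox_within_1kb,
      !is.na(bg$ebox_within_1kb) & bg$ebox_within_1kb
    )
    dv <- a$min_distance_bp[!is.na(a$min_distance_bp)]
    bv <- bg$min_distance_bp[!is.na(bg$min_distance_bp)]
    if (length(dv) > 0 && length(bv) >= length(dv)) {
      dist_test <- resampling_median_test(dv, bv, B = B,
                                          seed = derive_seed(seed, paste0("dist", cl)))
    } else {
      dist_test <- tibble::tibble(observed_median = NA_real_,
                                  background_median = NA_real_,
                                  p_value = NA_real_, direction = "none")
    }
    tibble::tibble(
      cluster = cl,
      n_genes = length(genes),
      overall_pattern = pattern,
      pct_up = pct_up,
      pct_down = pct_down,
      median_rpkm = median(a$median_rpkm),
      pct_noncoding = 100 * mean(a$biotype == "non_coding"),
      noncoding_direction = nc$direction,
      noncoding_p = nc$p_value,
      median_gene_length_bp = len$observed_median,
      length_direction = len$direction,
      length_p = len$p_value,
      pct_with_ebox_1kb = 100 * mean(!is.na(a$ebox_within_1kb) & a$ebox_within_1kb),
      ebox_direction = eb$direction,
      ebox_p = eb$p_value,
      median_min_tss_ebox_bp = dist_test$observed_median,
      distance_direction = dist_test$direction,
      distance_p = dist_test$p_value
    )
  })

  rows |>
    dplyr::mutate(
      noncoding_padj = p.adjust(.data$noncoding_p, "BH"),
      length_padj = p.adjust(.data$length_p, "BH"),
      ebox_padj = p.adjust(.data$ebox_p, "BH"),
      distance_padj = p.adjust(.data$distance_p, "BH"),
      noncoding_significant = .data$noncoding_padj < 0.05,
      length_significant = .data$length_padj < 0.02,
      ebox_significant = .data$ebox_padj < 0.05,
      distance_significant = .data$distance_padj < 0.02
    )
}
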