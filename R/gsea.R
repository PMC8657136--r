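#' MYC-level sensitivity scores and the between-mutant rank metric
#'
#' For each genotype computes the low-dose fold change (dose 25 vs 0) and
#' the high-dose fold change (dose 600 vs 300) on replicate-mean RPKM
#' (pseudocount-floored), their ratio `s = fc_low / fc_high` (the dose
#' sensitivity: large when a gene responds already at low inducer levels),
#' and the preranked metric `log2(s[numerator] / s[denominator])`
#' contrasting the two mutants.
#'
#' @param rpkm RPKM tibble.
#' @param design Design tibble; every genotype must be observed at doses
#'   0, 25, 300 and 600.
#' @param pseudocount Added to replicate-mean RPKM before ratios (default
#'   0.125).
#' @param numerator,denominator Genotypes contrasted in the rank metric
#'   (default T58A vs T58I).
#' @param doses_low,doses_high Dose pairs `(to, from)` for the two fold
#'   changes.
#' @return Tibble with `gene_id`, per-genotype `fc_low_*`, `fc_high_*`,
#'   `s_*`, and `rank_metric`.
#' @export
sensitivity_scores <- function(rpkm, design, pseudocount = 0.125,
                               numerator = "T58A", denominator = "T58I",
                               doses_low = c(25, 0), doses_high = c(600, 300)) {
  m <- counts_matrix(rpkm)
  genotypes <- unique(design$genotype)
  need <- c(doses_low, doses_high)
  out <- tibble::tibble(gene_id = rownames(m))
  for (g in genotypes) {
    have <- unique(design$dose[design$genotype == g])
    if (!all(need %in% have)) {
      stop("genotype ", g, " is missing a dose required for the ",
           "sensitivity score")
    }
    mean_at <- function(d) {
      idx <- design$sample_id[design$genotype == g & design$dose == d]
      rowMeans(m[, idx, drop = FALSE])
    }
    fc_low <- (mean_at(doses_low[1]) + pseudocount) /
      (mean_at(doses_low[2]) + pseudocount)
    fc_high <- (mean_at(doses_high[1]) + pseudocount) /
      (mean_at(doses_high[2]) + pseudocount)
    out[[paste0("fc_low_", g)]] <- unname(fc_low)
    out[[paste0("fc_high_", g)]] <- unname(fc_high)
    out[[paste0("s_", g)]] <- unname(fc_low / fc_high)
  }
  out$rank_metric <- log2(out[[paste0("s_", numerator)]] /
                            out[[paste0("s_", denominator)]])
  out
}

# Enrichment score of one set. ranks: sorted hit positions (ascending) in
# the ranked list; w: |metric|^p over the whole ranked list. Hits add
# w/N_R, misses subtract 1/(N - n). Returns the signed maximum-magnitude
# running-sum deviation plus the leading-edge index range.
running_es <- function(ranks, w, N) {
  n <- length(ranks)
  NR <- sum(w[ranks])
  hit_inc <- if (NR > 0) w[ranks] / NR else rep(1 / n, n)
  miss_dec <- 1 / (N - n)
  cum_hit <- cumsum(hit_inc)
  after <- cum_hit - (ranks - seq_len(n)) * miss_dec
  before <- c(0, cum_hit[-n]) - (ranks - 1 - (seq_len(n) - 1)) * miss_dec
  max_after <- max(after)
  min_before <- min(before)
  if (max_after >= -min_before) {
    j <- which.max(after)
    list(es = max_after, leading = seq_len(j))
  } else {
    j <- which.min(before)
    list(es = min_before, leading = seq(j, n))
  }
}

#' Preranked gene-set enrichment analysis
#'
#' From-scratch preranked GSEA: genes are sorted by the metric (descending,
#' ties broken by gene id), the weighted Kolmogorov-Smirnov running sum is
#' computed for each set (hits add `|metric|^p / N_R`, misses subtract
#' `1 / (N - n)`), and the enrichment score is the signed
#' maximum-magnitude deviation. The null distribution comes from random
#' same-size gene sets (gene-label permutation); NES divides ES by the mean
#' magnitude of same-sign null scores, the permutation p-value is
#' `(r + 1) / (n_same_sign + 1)`, and BH adjustment is applied across sets.
#' The leading edge contains the members at or before the score's extremum
#' (after it for negative scores).
#'
#' @param stats Tibble with `gene_id` and `rank_metric` (or a named numeric
#'   vector). All values must be finite.
#' @param collection Named list of gene-id vectors.
#' @param n_perm Number of permutations (default 1000).
#' @param weight Exponent `p` on `|metric|` (default 1).
#' @param min_size Minimal set size after universe intersection (default 2).
#' @param seed Permutation seed.
#' @return Tibble with `set`, `size`, `es`, `nes`, `p_perm`, `padj`,
#'   `leading_edge` (list column).
#' @export
gsea_preranked <- function(stats, collection, n_perm = 1000, weight = 1,
                           min_size = 2, seed = 1L) {
  if (is.data.frame(stats)) {
    metric <- setNames(stats$rank_metric, stats$gene_id)
  } else {
    metric <- stats
  }
  if (any(!is.finite(metric))) stop("rank metric must be finite for all genes")
  ord <- order(-metric, names(metric))
  metric <- metric[ord]
  genes <- names(metric)
  N <- length(genes)
  w <- abs(metric)^weight

  sets <- lapply(collection, function(s) which(genes %in% s))
  keep <- vapply(sets, function(idx) {
    length(idx) >= min_size && length(idx) < N
  }, logical(1))
  if (any(!keep)) {
    message(sum(!keep), " set(s) outside the allowed size range dropped")
  }
  sets <- lapply(sets[keep], sort)

  set.seed(seed)
  res <- purrr::imap_dfr(sets, function(idx, name) {
    obs <- running_es(idx, w, N)
    n <- length(idx)
    null_es <- vapply(seq_len(n_perm), function(b) {
      running_es(sort(sample.int(N, n)), w, N)$es
    }, numeric(1))
    if (obs$es >= 0) {
      pool <- null_es[null_es >= 0]
      r <- sum(pool >= obs$es)
    } else {
      pool <- null_es[null_es < 0]
      r <- sum(pool <= obs$es)
    }
    nes <- if (length(pool) > 0) obs$es / mean(abs(pool)) else NA_real_
    tibble::tibble(
      set = name,
      size = n,
      es = obs$es,
      nes = nes,
      p_perm = (r + 1) / (length(pool) + 1),
      leading_edge = list(genes[idx[obs$leading]])
    )
  })
  if (nrow(res) == 0) return(res)
  res$padj <- p.adjust(res$p_perm, "BH")
  res[, c("set", "size", "es", "nes", "p_perm", "padj", "leading_edge")]
}

#' Select significantly enriched gene sets
#'
#' Applies the joint significance rule, both bounds inclusive: adjusted
#' p-value at most `padj_max` and absolute NES at least `abs_nes_min`.
#'
#' @param results Tibble from [gsea_preranked()].
#' @param padj_max Adjusted-p threshold (default 0.05).
#' @param abs_nes_min Minimal absolute normalized enrichment score
#'   (default 1.7).
#' @return The significant subset of `results`.
#' @export
select_enriched <- function(results, padj_max = 0.05, abs_nes_min = 1.7) {
  results |>
    dplyr::filter(!is.na(.data$nes),
                  .data$padj <= padj_max,
                  abs(.data$nes) >= abs_nes_min)
}

#' Running-sum profile of one gene set (for plotting)
#'
#' @inheritParams gsea_preranked
#' @param members Gene ids of the set.
#' @return Tibble with `position`, `running_sum`, `hit`.
#' @export
gsea_running_profile <- function(stats, members, weight = 1) {
  if (is.data.frame(stats)) {
    metric <- setNames(stats$rank_metric, stats$gene_id)
  } else {
    metric <- stats
  }
  ord <- order(-metric, names(metric))
  metric <- metric[ord]
  genes <- names(metric)
  N <- length(genes)
  hit <- genes %in% members
  n <- sum(hit)
  if (n == 0 || n == N) stop("set must be a proper non-empty subset")
  w <- abs(metric)^weight
  NR <- sum(w[hit])
  inc <- rep(-1 / (N - n), N)
  inc[hit] <- if (NR > 0) w[hit] / NR else 1 / n
  tibble::tibble(position = seq_len(N), running_sum = cumsum(inc), hit = hit)
}
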