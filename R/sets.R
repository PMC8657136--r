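#' Venn decomposition of selection flags into sets A-G
#'
#' Partitions the flagged genes of a three-way selection (reference-
#' regulated; differential in each of two mutants) into the seven disjoint
#' Venn regions: A reference only, B first-mutant only, C second-mutant
#' only, D reference and first mutant, E reference and second mutant, F
#' both mutants without reference, G all three. Unflagged genes belong to
#' no set.
#'
#' @param flags Tibble from [select_models()] with `gene_id`, a
#'   `regulated_*` column and two `diff_*` columns (in mutant order).
#' @return Tibble with `gene_id`, `venn_set` (factor A-G), one row per
#'   flagged gene.
#' @export
#' @examples
#' flags <- tibble::tibble(gene_id = c("g1", "g2"),
#'                         regulated_wt = c(TRUE, FALSE),
#'                         diff_t58a = c(FALSE, TRUE),
#'                         diff_t58i = c(TRUE, TRUE))
#' venn_decompose(flags)$venn_set # E, F
venn_decompose <- function(flags) {
  ref_col <- grep("^regulated_", names(flags), value = TRUE)
  mut_cols <- grep("^diff_", names(flags), value = TRUE)
  if (length(ref_col) != 1 || length(mut_cols) != 2) {
    stop("flags must contain one regulated_* and two diff_* columns")
  }
  w <- flags[[ref_col]]
  a <- flags[[mut_cols[1]]]
  b <- flags[[mut_cols[2]]]
  set <- dplyr::case_when(
    w & !a & !b ~ "A",
    !w & a & !b ~ "B",
    !w & !a & b ~ "C",
    w & a & !b ~ "D",
    w & !a & b ~ "E",
    !w & a & b ~ "F",
    w & a & b ~ "G",
    TRUE ~ NA_character_
  )
  out <- tibble::tibble(gene_id = flags$gene_id,
                        venn_set = factor(set, levels = LETTERS[1:7]))
  out[!is.na(out$venn_set), , drop = FALSE]
}

# Hypergeometric overlap p-value, vectorized. k observed overlap, nx/ny set
# sizes, N universe. "greater"/"less" are one-tailed; "two.sided" sums all
# tables at most as likely as the observed one (the fisher.test convention).
overlap_pvalue <- function(k, nx, ny, N,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (alternative == "greater") {
    phyper(k - 1, nx, N - nx, ny, lower.tail = FALSE)
  } else if (alternative == "less") {
    phyper(k, nx, N - nx, ny)
  } else {
    mapply(function(k1, nx1, ny1, N1) {
      support <- max(0, nx1 + ny1 - N1):min(nx1, ny1)
      d <- dhyper(support, nx1, N1 - nx1, ny1)
      sum(d[d <= dhyper(k1, nx1, N1 - nx1, ny1) * (1 + 1e-7)])
    }, k, nx, ny, N)
  }
}

#' Fisher overlap test between two gene sets
#'
#' Hypergeometric tail probability for the overlap of two gene sets within
#' a universe, with the sample odds ratio of the 2x2 table.
#'
#' @param x,y Character vectors of gene ids (subsets of `universe`).
#' @param universe Character vector defining the test universe.
#' @param alternative `"greater"` (over-representation, default), `"less"`
#'   or `"two.sided"`.
#' @return One-row tibble: `n_x`, `n_y`, `n_overlap`, `n_universe`,
#'   `odds_ratio`, `p_value`, `direction`.
#' @export
#' @examples
#' fisher_overlap(c("a", "b", "c"), c("a", "b", "c"),
#'                letters[1:6])$p_value # 0.05
fisher_overlap <- function(x, y, universe,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(universe) == 0) stop("empty universe")
  x <- intersect(unique(x), universe)
  y <- intersect(unique(y), universe)
  k <- length(intersect(x, y))
  nx <- length(x)
  ny <- length(y)
  N <- length(universe)
  a <- k
  b <- nx - k
  c <- ny - k
  d <- N - nx - ny + k
  odds <- (a * d) / (b * c)
  expected <- nx * ny / N
  tibble::tibble(
    n_x = nx, n_y = ny, n_overlap = k, n_universe = N,
    odds_ratio = odds,
    p_value = overlap_pvalue(k, nx, ny, N, alternative),
    direction = dplyr::case_when(k > expected ~ "over", k < expected ~ "under",
                                 TRUE ~ "none")
  )
}

#' Signed significance matrix of Venn sets against clusters
#'
#' For every (Venn set, cluster) pair runs both one-tailed Fisher tests
#' (over- and under-representation) on the shared universe, BH-adjusts all
#' p-values jointly across cells and tails, and reports the signed
#' significance `-log10(adjusted p)` with a positive sign for
#' over-representation and negative for under-representation (the tail with
#' the smaller adjusted p defines the cell).
#'
#' @param venn Tibble from [venn_decompose()].
#' @param clusters Tibble `gene_id`, `cluster`.
#' @param universe Character vector of gene ids (defaults to the cluster
#'   universe).
#' @return Tibble with `venn_set`, `cluster`, `n_overlap`, `p_over`,
#'   `p_under`, `padj`, `direction`, `signed_log10_padj`.
#' @export
sets_by_clusters_heatmap <- function(venn, clusters, universe = NULL) {
  if (is.null(universe)) universe <- unique(clusters$gene_id)
  sets <- split(venn$gene_id, venn$venn_set, drop = TRUE)
  cls <- split(clusters$gene_id, clusters$cluster)
  grid <- tidyr::expand_grid(venn_set = names(sets), cluster = names(cls))
  cells <- purrr::pmap_dfr(grid, function(venn_set, cluster) {
    over <- fisher_overlap(sets[[venn_set]], cls[[cluster]], universe, "greater")
    under <- overlap_pvalue(over$n_overlap, over$n_x, over$n_y,
                            over$n_universe, "less")
    tibble::tibble(venn_set = venn_set, cluster = cluster,
                   n_overlap = over$n_overlap,
                   p_over = over$p_value, p_under = under)
  })
  padj_all <- p.adjust(c(cells$p_over, cells$p_under), "BH")
  nc <- nrow(cells)
  cells$padj_over <- padj_all[seq_len(nc)]
  cells$padj_under <- padj_all[nc + seq_len(nc)]
  cells |>
    dplyr::mutate(
      direction = ifelse(.data$padj_over <= .data$padj_under, "over", "under"),
      padj = pmin(.data$padj_over, .data$padj_under),
      signed_log10_padj = ifelse(.data$direction == "over", 1, -1) *
        -log10(pmax(.data$padj, 1e-300))
    ) |>
    dplyr::select("venn_set", "cluster", "n_overlap", "p_over", "p_under",
                  "padj", "direction", "signed_log10_padj")
}

#' Over-representation analysis against a GMT collection
#'
#' Hypergeometric over-representation test of a query gene set against each
#' set of a collection (each intersected with the universe first), with BH
#' adjustment across the collection.
#'
#' @param query Character vector of gene ids (subset of `universe`).
#' @param collection Named list of gene-id vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of gene ids.
#' @param fdr Significance threshold on the adjusted p (default 0.1,
#'   inclusive).
#' @return Tibble with one row per collection set: overlap counts, odds
#'   ratio, `p_value`, `padj`, `significant`. Sets with no member in the
#'   universe are skipped with a message.
#' @export
ora_gmt <- function(query, collection, universe, fdr = 0.1) {
  query <- intersect(unique(query), universe)
  kept <- purrr::keep(collection, ~ length(intersect(.x, universe)) > 0)
  if (length(kept) < length(collection)) {
    message(length(collection) - length(kept),
            " set(s) with no member in the universe skipped")
  }
  res <- purrr::imap_dfr(kept, function(members, name) {
    dplyr::bind_cols(tibble::tibble(set = name),
                     fisher_overlap(query, members, universe, "greater"))
  })
  if (nrow(res) == 0) return(res)
  res$padj <- p.adjust(res$p_value, "BH")
  res$significant <- res$padj <= fdr
  dplyr::arrange(res, .data$p_value)
}

#' Overlap with an external gene list
#'
#' Reads a plain-text gene list (one identifier per line), optionally maps
#' it through a two-column ortholog table (exact lookup; unmapped entries
#' dropped with a count report), and tests its overlap with a gene set by a
#' one-tailed Fisher test on the detected-gene universe.
#'
#' @param x Character vector of gene ids (e.g. a Venn set or all flagged
#'   genes).
#' @param external Path to a plain-text list, or a character vector.
#' @param universe Character vector of detected gene ids.
#' @param ortholog_map Optional path to (or tibble of) a two-column TSV
#'   `from`, `to`; external identifiers are translated before testing.
#' @return One-row tibble as [fisher_overlap()], plus `n_external_raw`,
#'   `n_mapped`, `n_in_universe`.
#' @export
external_overlap <- function(x, external, universe, ortholog_map = NULL) {
  ext <- if (length(external) == 1 && file.exists(external)) {
    readLines(external)
  } else {
    as.character(external)
  }
  ext <- unique(ext[nzchar(ext)])
  n_raw <- length(ext)
  if (!is.null(ortholog_map)) {
    map <- if (is.character(ortholog_map)) {
      readr::read_tsv(ortholog_map, col_names = c("from", "to"),
                      show_col_types = FALSE)
    } else {
      ortholog_map
    }
    mapped <- map$to[match(ext, map$from)]
    dropped <- sum(is.na(mapped))
    if (dropped > 0) {
      message(dropped, "/", n_raw, " external identifiers had no ortholog ",
              "mapping and were dropped")
    }
    ext <- unique(mapped[!is.na(mapped)])
    if (length(ext) == 0) stop("no external identifiers could be mapped")
  }
  n_mapped <- length(ext)
  in_univ <- intersect(ext, universe)
  if (length(in_univ) == 0) stop("external list is disjoint from the universe")
  res <- fisher_overlap(x, in_univ, universe, "greater")
  dplyr::bind_cols(res, tibble::tibble(n_external_raw = n_raw,
                                       n_mapped = n_mapped,
                                       n_in_universe = length(in_univ)))
}
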