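#' Dose-response profile plot for selected genes
#'
#' Replicate-mean RPKM against dose, one line per genotype, facetted by
#' gene. Dose is shown on a pseudo-log axis so the 0 dose remains visible.
#'
#' @param rpkm RPKM tibble.
#' @param design Design tibble.
#' @param genes Gene ids to plot.
#' @return A ggplot object.
#' @export
plot_dose_profiles <- function(rpkm, design, genes) {
  df <- rpkm |>
    dplyr::filter(.data$gene_id %in% genes) |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "rpkm") |>
    dplyr::left_join(design, by = "sample_id") |>
    dplyr::group_by(.data$gene_id, .data$genotype, .data$dose) |>
    dplyr::summarise(rpkm = mean(.data$rpkm), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$dose + 10),
                                   y = .data$rpkm,
                                   colour = .data$genotype)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~gene_id, scales = "free_y") +
    ggplot2::labs(x = "log10(dose + 10) [ng/mL]", y = "mean RPKM",
                  colour = "genotype") +
    ggplot2::theme_minimal()
}

#' Autoplot method for a dose-response fit
#'
#' MA-style overview: average log2 CPM against the maximal absolute log2
#' fold change, coloured by the reference-regulation call.
#'
#' @param object A `dose_response_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dose_response_fit
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  res <- object$results
  flag_col <- grep("^regulated_", names(res), value = TRUE)[1]
  ggplot2::ggplot(res, ggplot2::aes(x = .data$ave_log_cpm,
                                    y = .data$max_abs_log2fc,
                                    colour = .data[[flag_col]])) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "average log2 CPM", y = "max |log2 fold change|",
                  colour = flag_col) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of clustered expression profiles
#'
#' @param profiles Profile tibble from [build_profile_matrix()].
#' @param assignment Tibble `gene_id`, `cluster`.
#' @return A ggplot object (tile heatmap, rows grouped by cluster).
#' @export
plot_cluster_heatmap <- function(profiles, assignment) {
  df <- profiles |>
    dplyr::left_join(assignment, by = "gene_id") |>
    dplyr::arrange(.data$cluster) |>
    dplyr::mutate(row = dplyr::row_number()) |>
    tidyr::pivot_longer(cols = -c("gene_id", "cluster", "row"),
                        names_to = "condition", values_to = "log2_rpkm") |>
    dplyr::mutate(condition = factor(.data$condition,
                                     levels = unique(.data$condition)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$row,
                                   fill = .data$log2_rpkm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = "genes (grouped by cluster)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' GSEA running-sum plot for one gene set
#'
#' @inheritParams gsea_running_profile
#' @param title Plot title (e.g. the set name).
#' @return A ggplot object.
#' @export
plot_gsea_running_sum <- function(stats, members, weight = 1, title = NULL) {
  prof <- gsea_running_profile(stats, members, weight = weight)
  es_idx <- which.max(abs(prof$running_sum))
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$position,
                                     y = .data$running_sum)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = prof$position[prof$hit],
                        alpha = 0.3, colour = "steelblue") +
    ggplot2::geom_point(data = prof[es_idx, ], colour = "red") +
    ggplot2::labs(x = "rank position", y = "running enrichment score",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Signed-significance heatmap of Venn sets by clusters
#'
#' @param heatmap Tibble from [sets_by_clusters_heatmap()].
#' @return A ggplot object.
#' @export
plot_sets_heatmap <- function(heatmap) {
  ggplot2::ggplot(heatmap, ggplot2::aes(x = factor(.data$cluster),
                                        y = .data$venn_set,
                                        fill = .data$signed_log10_padj)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "cluster", y = "Venn set",
                  fill = "signed -log10 adj p") +
    ggplot2::theme_minimal()
}
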