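#' Default pipeline configuration
#'
#' Assembles the run configuration consumed by [run_pipeline()]: stage
#' toggles, simulation parameters, analysis thresholds and the global seed.
#' Any part can be overridden by the caller or by a YAML file with the same
#' structure.
#'
#' @param outdir Output directory.
#' @param seed Global seed; all stage-level generators derive from it.
#' @return Nested list (`seed`, `outdir`, `stages`, `simulate`, `inputs`,
#'   `thresholds`).
#' @export
default_run_config <- function(outdir = "dosegrade_run", seed = 1L) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    stages = list(simulate = TRUE, de = TRUE, ebox = TRUE, cluster = TRUE,
                  sets = TRUE, gsea = TRUE),
    simulate = list(n_genes = 800),
    inputs = list(counts = NULL, design = NULL, genome = NULL,
                  genes_bed = NULL, gene_lengths = NULL, gmt = NULL,
                  biotypes = NULL),
    thresholds = list(
      cpm_min = 0.95, cpm_min_samples = 3,
      q_max = 0.01, min_fold = 2,
      k = 12,
      ebox_window = 1000,
      ora_fdr = 0.1,
      gsea_padj = 0.05, gsea_abs_nes = 1.7,
      gsea_nperm = 500, gsea_min_size = 5,
      resample_B = 1000
    )
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full dose-graded analysis pipeline
#'
#' Executes simulate, differential expression, E-box scanning, profile
#' clustering, set enrichment and sensitivity GSEA in dependency order,
#' writing every stage's tables under the configured output directory and a
#' JSON run summary with per-stage gene counts, an md5 file manifest, the
#' echoed configuration and the package version. Reruns with an identical
#' configuration reproduce identical outputs.
#'
#' @param config A list as from [default_run_config()], a partial override
#'   of it, or a path to a YAML file with the same structure.
#' @param outdir,seed Convenience overrides of the corresponding config
#'   entries.
#' @return The run summary (list), invisibly; also written as
#'   `run_summary.json`.
#' @export
run_pipeline <- function(config = NULL, outdir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), config %||% list())
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  th <- cfg$thresholds
  summary <- list(package_version = as.character(utils::packageVersion("dosegrade")),
                  seed = cfg$seed, config = cfg, stage_counts = list())
  files <- character()
  out <- function(name) file.path(cfg$outdir, name)
  fail <- function(stage, e) {
    summary$failed_stage <- stage
    summary$files <- manifest(files)
    jsonlite::write_json(summary, out("run_summary.json"), auto_unbox = TRUE,
                         pretty = TRUE, force = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  sim <- NULL; genome <- NULL; annotation <- NULL; collection <- NULL

  # --- simulate -------------------------------------------------------
  if (isTRUE(cfg$stages$simulate)) {
    tryCatch({
      scfg <- do.call(sim_config, c(cfg$simulate, list(rng_seed = cfg$seed)))
      sim <- simulate_experiment(scfg)
      write_simulation(sim, cfg$outdir)
      gen <- simulate_genome(scfg, sim$truth)
      genome <- gen$genome
      annotation <- gen$genes
      write_genome_fasta(genome, out("genome.fa"))
      write_genes_bed(annotation, out("genes.bed"))
      write_genes_gtf(annotation, out("genes.gtf"))
      gs <- simulate_gene_sets(sim$truth, scfg)
      collection <- gs$sets
      write_gmt(collection, out("sets.gmt"), gs$info$description)
      files <- c(files, out(c("counts.tsv", "design.tsv", "truth.tsv",
                              "genome.fa", "genes.bed", "genes.gtf",
                              "sets.gmt")))
      counts <- sim$counts
      design <- sim$design
      summary$stage_counts$simulate <- list(
        n_genes = nrow(sim$truth), n_samples = nrow(design),
        n_regulated_truth = sum(sim$truth$regulated),
        n_differential_truth = sum(sim$truth$differential_in != ""))
    }, error = function(e) fail("synthetic_data", e))
  }
  tryCatch({
    counts <- if (!is.null(sim)) sim$counts else read_counts(cfg$inputs$counts)
    design <- if (!is.null(sim)) sim$design else read_design(cfg$inputs$design)
    if (is.null(annotation) && !is.null(cfg$inputs$genes_bed)) {
      annotation <- read_genes_bed(cfg$inputs$genes_bed)
      annotation$gene_length <- annotation$end - annotation$start
    }
    if (is.null(collection) && !is.null(cfg$inputs$gmt)) {
      collection <- read_gmt(cfg$inputs$gmt)
    }
  }, error = function(e) fail("inputs", e))

  lib <- colSums(counts_matrix(counts)[, design$sample_id, drop = FALSE])
  gene_lengths <- if (!is.null(annotation)) {
    setNames(annotation$gene_length, annotation$gene_id)
  } else if (!is.null(sim)) {
    setNames(sim$truth$gene_length, sim$truth$gene_id)
  } else {
    NULL
  }

  # --- differential expression ---------------------------------------
  fit <- NULL; flags <- NULL; selected <- NULL
  if (isTRUE(cfg$stages$de)) {
    tryCatch({
      fit <- fit_dose_response(counts, design,
                               min_cpm = th$cpm_min,
                               min_samples = th$cpm_min_samples,
                               q_max = th$q_max, min_fold = th$min_fold)
      res <- tidy(fit)
      readr::write_tsv(res, out("de_results.tsv"))
      fitted <- tibble::as_tibble(fit$fitted_cpm, rownames = "gene_id")
      readr::write_tsv(fitted, out("fitted_means.tsv"))
      files <- c(files, out(c("de_results.tsv", "fitted_means.tsv")))
      flags <- res[, c("gene_id", grep("^(regulated|diff)_", names(res),
                                       value = TRUE))]
      selected <- flags$gene_id[Reduce(`|`, flags[-1])]
      summary$stage_counts$de <- c(list(n_input = nrow(counts)),
                                   as.list(glance(fit)))
    }, error = function(e) fail("dose_response_de", e))
  }

  # --- E-box proximity ------------------------------------------------
  distances <- NULL
  if (isTRUE(cfg$stages$ebox)) {
    tryCatch({
      if (is.null(genome)) {
        if (is.null(cfg$inputs$genome)) {
          stop("no genome available (enable simulate or provide inputs$genome)")
        }
        genome <- read_genome_fasta(cfg$inputs$genome)
      }
      if (is.null(annotation)) stop("no gene annotation available")
      hits <- scan_motif(genome)
      bed <- tibble::tibble(chrom = hits$chrom, start = hits$start,
                            end = hits$start + 6L, name = "CACGTG",
                            score = 0L, strand = hits$strand)
      readr::write_tsv(bed, out("eboxes.bed"), col_names = FALSE)
      distances <- gene_min_distance(hits, annotation, window = th$ebox_window)
      readr::write_tsv(distances, out("gene_distances.tsv"))
      files <- c(files, out(c("eboxes.bed", "gene_distances.tsv")))
      summary$stage_counts$ebox <- list(
        n_hits = nrow(hits),
        n_genes_with_ebox_1kb = sum(distances$ebox_within_1kb))
    }, error = function(e) fail("motif_proximity", e))
  }

  # --- clustering -----------------------------------------------------
  clusters <- NULL; rpkm <- NULL
  if (isTRUE(cfg$stages$cluster)) {
    tryCatch({
      if (is.null(fit)) stop("clustering requires the de stage")
      if (is.null(gene_lengths)) stop("clustering requires gene lengths")
      rpkm <- compute_rpkm(counts, gene_lengths, library_sizes = lib)
      prof <- build_profile_matrix(rpkm, design, selected)
      k <- th$k
      hc <- hierarchical_cluster(prof, k = k)
      clusters <- hc$assignment
      readr::write_tsv(clusters, out("clusters.tsv"))
      if (requireNamespace("ape", quietly = TRUE)) {
        write_dendrogram_newick(hc$tree, out("dendrogram.nwk"))
        files <- c(files, out("dendrogram.nwk"))
      }
      background <- setdiff(fit$retained, selected)
      ann_tbl <- if (!is.null(annotation)) {
        annotation[, c("gene_id", "gene_length", "biotype")]
      } else {
        sim$truth[, c("gene_id", "gene_length", "biotype")]
      }
      tab <- build_cluster_table(clusters, rpkm, design, ann_tbl,
                                 distances %||%
                                   tibble::tibble(gene_id = character(),
                                                  min_distance_bp = numeric(),
                                                  ebox_within_1kb = logical()),
                                 background, B = th$resample_B,
                                 seed = derive_seed(cfg$seed, "cluster_table"))
      readr::write_tsv(tab, out("cluster_table.tsv"))
      files <- c(files, out(c("clusters.tsv", "cluster_table.tsv")))
      summary$stage_counts$cluster <- list(
        k = k, n_clustered = nrow(clusters),
        size_range = range(table(clusters$cluster)))
    }, error = function(e) fail("cluster_profile", e))
  }

  # --- set enrichment -------------------------------------------------
  if (isTRUE(cfg$stages$sets)) {
    tryCatch({
      if (is.null(flags)) stop("set enrichment requires the de stage")
      venn <- venn_decompose(flags)
      readr::write_tsv(venn, out("venn_sets.tsv"))
      files <- c(files, out("venn_sets.tsv"))
      summary$stage_counts$sets <- as.list(table(venn$venn_set))
      if (!is.null(clusters)) {
        hm <- sets_by_clusters_heatmap(venn, clusters)
        readr::write_tsv(hm, out("heatmap_matrix.tsv"))
        files <- c(files, out("heatmap_matrix.tsv"))
      }
      if (!is.null(collection)) {
        query <- flags$gene_id[Reduce(`|`, flags[grep("^diff_", names(flags))])]
        ora <- ora_gmt(query, collection, universe = fit$retained,
                       fdr = th$ora_fdr)
        readr::write_tsv(ora, out("ora_results.tsv"))
        files <- c(files, out("ora_results.tsv"))
        summary$stage_counts$ora <- list(n_sets = nrow(ora),
                                         n_significant = sum(ora$significant))
      }
    }, error = function(e) fail("set_enrichment", e))
  }

  # --- sensitivity GSEA -----------------------------------------------
  if (isTRUE(cfg$stages$gsea)) {
    tryCatch({
      if (is.null(rpkm)) {
        if (is.null(gene_lengths)) stop("gsea requires gene lengths for RPKM")
        rpkm <- compute_rpkm(counts, gene_lengths, library_sizes = lib)
      }
      univ <- if (!is.null(fit)) fit$retained else rpkm$gene_id
      sens <- sensitivity_scores(
        rpkm[rpkm$gene_id %in% univ, , drop = FALSE], design)
      readr::write_tsv(sens, out("sensitivity.tsv"))
      rnk <- sens[order(-sens$rank_metric), c("gene_id", "rank_metric")]
      readr::write_tsv(rnk, out("ranked_list.rnk"), col_names = FALSE)
      files <- c(files, out(c("sensitivity.tsv", "ranked_list.rnk")))
      if (!is.null(collection)) {
        gsea <- gsea_preranked(sens, collection, n_perm = th$gsea_nperm,
                               min_size = th$gsea_min_size,
                               seed = derive_seed(cfg$seed, "gsea"))
        enr <- select_enriched(gsea, padj_max = th$gsea_padj,
                               abs_nes_min = th$gsea_abs_nes)
        gsea_out <- gsea |>
          dplyr::mutate(leading_edge = vapply(.data$leading_edge, paste,
                                              character(1), collapse = ","),
                        significant = .data$set %in% enr$set)
        readr::write_tsv(gsea_out, out("gsea_results.tsv"))
        files <- c(files, out("gsea_results.tsv"))
        summary$stage_counts$gsea <- list(n_sets = nrow(gsea),
                                          n_enriched = nrow(enr))
      }
    }, error = function(e) fail("sensitivity_gsea", e))
  }

  summary$files <- manifest(files)
  jsonlite::write_json(summary, out("run_summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(summary)
}

manifest <- function(files) {
  files <- unique(files[file.exists(files)])
  lapply(setNames(as.list(unname(tools::md5sum(files))), basename(files)),
         identity)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
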