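#' Read and write pipeline tables and formats
#'
#' Plain-text I/O for the pipeline's interchange files: TSV count/design
#' tables, GMT gene-set collections, BED6/GTF gene annotation and FASTA
#' genomes.
#'
#' @param path File path.
#' @return `read_counts()` a tibble with `gene_id` plus one column per
#'   sample; `read_design()` a tibble with `sample_id`, `genotype`, `dose`,
#'   `replicate`; `read_gmt()` a named list of character vectors.
#' @name dosegrade-io
NULL

#' @rdname dosegrade-io
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    dplyr::rename(gene_id = 1)
}

#' @rdname dosegrade-io
#' @param counts Counts tibble (`gene_id` + sample columns).
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname dosegrade-io
#' @export
read_design <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = readr::col_character(),
                    genotype = readr::col_character(),
                    dose = readr::col_double(),
                    replicate = readr::col_integer()
                  ))
}

#' @rdname dosegrade-io
#' @param design Design tibble.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

#' @rdname dosegrade-io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  sets
}

#' @rdname dosegrade-io
#' @param sets Named list of gene-id vectors.
#' @param descriptions Optional character vector of set descriptions
#'   (recycled; defaults to "na").
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (length(sets) == 0) stop("no sets to write")
  if (any(lengths(sets) == 0)) stop("GMT sets must be non-empty")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname dosegrade-io
#' @param genes Annotation tibble with `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open) and, for GTF, `biotype`.
#' @export
write_genes_bed <- function(genes, path) {
  bed <- genes |>
    dplyr::transmute(.data$chrom, .data$start, .data$end, name = .data$gene_id,
                     score = 0L, .data$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname dosegrade-io
#' @export
write_genes_gtf <- function(genes, path) {
  lines <- sprintf(
    "%s\tdosegrade\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"%s\";",
    genes$chrom, genes$start + 1L, genes$end, genes$strand,
    genes$gene_id, genes$biotype
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname dosegrade-io
#' @export
read_genes_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene_id",
                                      "score", "strand"),
                  show_col_types = FALSE) |>
    dplyr::mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L)) |>
    dplyr::select(-"score")
}

#' @rdname dosegrade-io
#' @param genome A [Biostrings::DNAStringSet].
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60)
  invisible(path)
}

#' @rdname dosegrade-io
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a simulated experiment to a directory
#'
#' Emits `counts.tsv`, `design.tsv` and `truth.tsv`.
#'
#' @param sim A `dose_sim` from [simulate_experiment()].
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "dose_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_design(sim$design, file.path(dir, "design.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

# counts tibble -> integer matrix with gene_id rownames
counts_matrix <- function(counts) {
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}
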