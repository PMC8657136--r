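#' Library-size normalization: CPM and RPKM
#'
#' `compute_cpm()` scales counts to counts-per-million using per-sample
#' library sizes (column sums unless overridden). `compute_rpkm()`
#' additionally normalizes by gene length in kb:
#' `RPKM = count * 1e9 / (library_size * length_bp)`.
#'
#' @param counts Counts tibble (`gene_id` + one integer column per sample).
#' @param library_sizes Optional named vector of library sizes (reads); must
#'   be positive. Defaults to column sums.
#' @return A tibble shaped like `counts` holding CPM (or RPKM) values, with
#'   attributes `unit` and `library_sizes`.
#' @export
#' @examples
#' cts <- tibble::tibble(gene_id = "g1", s1 = 10L)
#' compute_cpm(cts, library_sizes = c(s1 = 1e6))$s1 # 10
compute_cpm <- function(counts, library_sizes = NULL) {
  m <- counts_matrix(counts)
  lib <- resolve_library_sizes(m, library_sizes)
  cpm <- sweep(m, 2, lib / 1e6, "/")
  out <- tibble::as_tibble(cpm, rownames = "gene_id")
  attr(out, "unit") <- "CPM"
  attr(out, "library_sizes") <- lib
  out
}

#' @rdname compute_cpm
#' @param gene_lengths Named numeric vector of gene lengths (bp), or a
#'   tibble with `gene_id` and `gene_length` columns. Genes without a length
#'   are dropped with a warning.
#' @export
compute_rpkm <- function(counts, gene_lengths, library_sizes = NULL) {
  if (is.data.frame(gene_lengths)) {
    gene_lengths <- setNames(gene_lengths$gene_length, gene_lengths$gene_id)
  }
  if (any(gene_lengths <= 0, na.rm = TRUE)) stop("gene lengths must be positive")
  m <- counts_matrix(counts)
  lib <- resolve_library_sizes(m, library_sizes)
  len <- gene_lengths[rownames(m)]
  missing <- is.na(len)
  if (any(missing)) {
    warning(sum(missing), " gene(s) without a length dropped from RPKM")
    m <- m[!missing, , drop = FALSE]
    len <- len[!missing]
  }
  rpkm <- sweep(m, 2, lib, "/") * 1e9 / len
  out <- tibble::as_tibble(rpkm, rownames = "gene_id")
  attr(out, "unit") <- "RPKM"
  attr(out, "library_sizes") <- lib
  out
}

resolve_library_sizes <- function(m, library_sizes) {
  if (is.null(library_sizes)) {
    lib <- colSums(m)
  } else {
    lib <- library_sizes[colnames(m)]
    if (any(is.na(lib))) stop("library_sizes missing for some samples")
  }
  if (any(lib <= 0)) stop("library sizes must be positive (zero library size)")
  lib
}

#' Expression filter on CPM
#'
#' A gene is retained when its CPM is at or above `min_cpm` in at least
#' `min_samples` samples (both bounds inclusive).
#'
#' @param cpm CPM tibble from [compute_cpm()].
#' @param min_cpm CPM threshold (default 0.95).
#' @param min_samples Minimum number of samples at or above the threshold
#'   (default 3).
#' @return Character vector of retained gene ids.
#' @export
filter_genes <- function(cpm, min_cpm = 0.95, min_samples = 3) {
  m <- counts_matrix(cpm)
  keep <- rowSums(m >= min_cpm) >= min_samples
  rownames(m)[keep]
}
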