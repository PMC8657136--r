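#' Scan a genome for exact canonical E-box occurrences
#'
#' Finds every exact, case-insensitive occurrence of the motif on both
#' strands (positions containing N never match). Because the canonical
#' E-box CACGTG is its own reverse complement, the forward and reverse
#' alignments at one genomic start are the same hexamer; in the default
#' `"positions"` mode they are collapsed to a single record with strand
#' `"+"` and `palindromic = TRUE`. `"alignments"` mode reports both strand
#' alignments separately, mirroring an exhaustive aligner's output
#' convention.
#'
#' @param genome A [Biostrings::DNAStringSet] (or path to a FASTA file).
#' @param motif Motif string over A/C/G/T (default `"CACGTG"`).
#' @param count_mode `"positions"` (unique genomic starts) or
#'   `"alignments"` (one record per strand alignment).
#' @return Tibble with `chrom`, `start` (0-based offset of the first motif
#'   base), `strand`, `palindromic`.
#' @export
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "TTCACGTGTT"))
#' scan_motif(g)$start # 2
scan_motif <- function(genome, motif = "CACGTG",
                       count_mode = c("positions", "alignments")) {
  count_mode <- match.arg(count_mode)
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be over A/C/G/T")
  fwd <- Biostrings::DNAString(motif)
  rev <- Biostrings::reverseComplement(fwd)
  palindrome <- as.character(rev) == motif

  hits <- purrr::map_dfr(seq_along(genome), function(i) {
    chrom <- names(genome)[i]
    if (is.null(chrom)) chrom <- as.character(i)
    f <- Biostrings::start(Biostrings::matchPattern(fwd, genome[[i]],
                                                    fixed = TRUE)) - 1L
    out <- tibble::tibble(chrom = chrom, start = f, strand = "+",
                          palindromic = palindrome)
    if (palindrome) {
      if (count_mode == "alignments") {
        out <- dplyr::bind_rows(out, dplyr::mutate(out, strand = "-"))
      }
    } else {
      r <- Biostrings::start(Biostrings::matchPattern(rev, genome[[i]],
                                                      fixed = TRUE)) - 1L
      out <- dplyr::bind_rows(
        out,
        tibble::tibble(chrom = chrom, start = r, strand = "-",
                       palindromic = FALSE)
      )
    }
    out
  })
  dplyr::arrange(hits, .data$chrom, .data$start, .data$strand)
}

#' Minimal TSS-to-E-box distance per gene
#'
#' For each gene, the minimum over same-chromosome motif hits of the
#' unsigned distance between the TSS and the motif midpoint
#' (`start + floor(motif_length / 2)`); upstream and downstream are
#' equivalent. Genes on a chromosome without hits get `NA` and a `FALSE`
#' window flag.
#'
#' @param hits Tibble from [scan_motif()] (positions mode).
#' @param tss Tibble with `gene_id`, `chrom`, `tss` (0-based position),
#'   e.g. the annotation from [simulate_genome()] or [read_genes_bed()].
#' @param window Window (bp) for the proximity flag (default 1000,
#'   inclusive).
#' @param motif_length Motif length used for the midpoint (default 6).
#' @return Tibble with `gene_id`, `min_distance_bp`, `ebox_within_1kb`.
#' @export
gene_min_distance <- function(hits, tss, window = 1000, motif_length = 6) {
  mid_off <- motif_length %/% 2
  mids <- lapply(split(hits$start + mid_off, hits$chrom), function(x) sort(unique(x)))
  res <- purrr::map_dfr(seq_len(nrow(tss)), function(i) {
    m <- mids[[tss$chrom[i]]]
    if (is.null(m) || length(m) == 0) {
      return(tibble::tibble(gene_id = tss$gene_id[i],
                            min_distance_bp = NA_real_,
                            ebox_within_1kb = FALSE))
    }
    d <- min(abs(m - tss$tss[i]))
    tibble::tibble(gene_id = tss$gene_id[i], min_distance_bp = d,
                   ebox_within_1kb = d <= window)
  })
  res
}

#' Nearest gene for each motif hit
#'
#' Assigns each hit the gene whose TSS is closest to the motif midpoint on
#' the hit's chromosome; ties are broken by lexicographically smallest
#' `gene_id`. Hits on chromosomes without genes are reported unassigned
#' (`NA`).
#'
#' @inheritParams gene_min_distance
#' @return Tibble with `chrom`, `start`, `gene_id`, `distance_bp`.
#' @export
nearest_tss_per_motif <- function(hits, tss, motif_length = 6) {
  mid_off <- motif_length %/% 2
  purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    g <- tss[tss$chrom == hits$chrom[i], , drop = FALSE]
    mid <- hits$start[i] + mid_off
    if (nrow(g) == 0) {
      return(tibble::tibble(chrom = hits$chrom[i], start = hits$start[i],
                            gene_id = NA_character_, distance_bp = NA_real_))
    }
    d <- abs(g$tss - mid)
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[order(g$gene_id[best])][1]
    tibble::tibble(chrom = hits$chrom[i], start = hits$start[i],
                   gene_id = g$gene_id[best], distance_bp = d[best])
  })
}
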