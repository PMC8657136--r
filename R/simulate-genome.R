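#' Simulate a genome with E-boxes planted at controlled TSS distances
#'
#' Lays the simulated genes out on a single chromosome (one fixed-width
#' window per gene, TSS at the window centre, random strand) and plants
#' canonical E-box motifs (CACGTG) at controlled distances from TSSs
#' according to the configured placement scheme. The background sequence is
#' rejection-resampled so that it contains no CACGTG occurrence other than
#' the planted ones; because the motif is its own reverse complement a
#' forward-strand scan sees every occurrence.
#'
#' @param config A [sim_config()] object (supplies the placement scheme and
#'   seed).
#' @param truth Truth tibble from [simulate_experiment()].
#' @param spacing Window width per gene (bp). Planted distances must stay
#'   below `spacing / 2` so that a gene's own motif is always its nearest.
#' @return A list with `genome` (a [Biostrings::DNAStringSet] of one
#'   chromosome), `genes` (annotation tibble: `gene_id`, `chrom`, `start`,
#'   `end` 0-based half-open, `strand`, `tss`, `gene_length`, `biotype`,
#'   `planted_distance` in bp or `NA`).
#' @export
simulate_genome <- function(config, truth, spacing = 10000) {
  validate_sim_config(config)
  set.seed(derive_seed(config$rng_seed, "genome"))
  n <- nrow(truth)
  chrom_len <- n * spacing
  scheme <- config$motif_distance_scheme
  if (max(scheme$far_range) >= spacing / 2) {
    stop("far_range must stay below spacing/2 so planted motifs are nearest")
  }

  half <- spacing %/% 2
  tss <- (seq_len(n) - 1) * spacing + half
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- pmin(truth$gene_length, half - 10)
  start <- ifelse(strand == "+", tss, tss + 1 - len)
  end <- ifelse(strand == "+", tss + len, tss + 1)

  cat3 <- ifelse(!truth$regulated | is.na(truth$direction), "unregulated",
                 truth$direction)
  planted <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    probs <- switch(cat3[i],
                    up = scheme$prob_up,
                    down = scheme$prob_down,
                    scheme$prob_unregulated)
    cls <- sample(names(probs), 1, prob = probs)
    if (cls == "near") {
      planted[i] <- sample(seq(scheme$near_range[1], scheme$near_range[2]), 1)
    } else if (cls == "far") {
      planted[i] <- sample(seq(scheme$far_range[1], scheme$far_range[2]), 1)
    }
  }

  # motif midpoint = start + 3; place midpoint at tss +/- distance
  motif_start <- rep(NA_integer_, n)
  for (i in which(!is.na(planted))) {
    side <- sample(c(-1L, 1L), 1)
    mid <- tss[i] + side * planted[i]
    ms <- mid - 3L
    if (ms < 0 || ms + 6 > chrom_len) {
      side <- -side
      mid <- tss[i] + side * planted[i]
      ms <- mid - 3L
    }
    if (ms < 0 || ms + 6 > chrom_len) {
      stop("impossible motif placement for gene ", truth$gene_id[i],
           ": requested distance exceeds chromosome bounds")
    }
    motif_start[i] <- ms
  }

  seq <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  motif <- c("C", "A", "C", "G", "T", "G")
  planted_pos <- motif_start[!is.na(motif_start)] # 0-based
  for (ms in planted_pos) seq[(ms + 1):(ms + 6)] <- motif

  planted_bases <- unique(unlist(lapply(planted_pos, function(ms) (ms + 1):(ms + 6))))
  chrom <- Biostrings::DNAString(paste(seq, collapse = ""))
  for (iter in 1:100) {
    hits <- Biostrings::start(Biostrings::matchPattern("CACGTG", chrom)) - 1L
    stray <- setdiff(hits, planted_pos)
    if (length(stray) == 0) break
    redraw <- setdiff(unlist(lapply(stray, function(ms) (ms + 1):(ms + 6))),
                      planted_bases)
    seq[redraw] <- sample(c("A", "C", "G", "T"), length(redraw), replace = TRUE)
    chrom <- Biostrings::DNAString(paste(seq, collapse = ""))
  }

  genome <- Biostrings::DNAStringSet(chrom)
  names(genome) <- "chr1"
  genes <- tibble::tibble(
    gene_id = truth$gene_id,
    chrom = "chr1",
    start = as.integer(start),
    end = as.integer(end),
    strand = strand,
    tss = as.integer(tss),
    gene_length = as.integer(len),
    biotype = truth$biotype,
    planted_distance = planted
  )
  list(genome = genome, genes = genes)
}
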