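# Shared fixtures, built once per test run.

# Small default-condition simulation reused across module tests.
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_experiment(sim_config(n_genes = 120, rng_seed = 42))
    }
    cache
  }
})

# Minimal single-genotype design helper for hand-built matrices.
mini_design <- function(doses = c(0, 1000), genotype = "WT", reps = 3) {
  tidyr::expand_grid(genotype = genotype, dose = doses,
                     replicate = seq_len(reps)) |>
    dplyr::mutate(sample_id = paste(genotype, dose, replicate, sep = "_")) |>
    dplyr::select(sample_id, genotype, dose, replicate)
}

# counts tibble from a genes x samples matrix
as_counts <- function(m, design) {
  colnames(m) <- design$sample_id
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  tibble::as_tibble(m, rownames = "gene_id")
}

# Independent naive motif scanner: slides a window over the sequence string
# and its reverse complement, character by character.
naive_scan <- function(seq, motif) {
  seq <- toupper(seq)
  motif <- toupper(motif)
  revcomp <- function(x) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  k <- nchar(motif)
  n <- nchar(seq)
  if (n < k) return(tibble::tibble(start = integer(), strand = character()))
  windows <- substring(seq, 1:(n - k + 1), k:n)
  fwd <- which(windows == motif) - 1L
  rev <- which(windows == revcomp(motif)) - 1L
  out <- dplyr::bind_rows(
    tibble::tibble(start = fwd, strand = "+"),
    tibble::tibble(start = rev, strand = "-")
  )
  if (motif == revcomp(motif)) {
    out <- out[out$strand == "+", , drop = FALSE]
  }
  dplyr::arrange(out, start, strand)
}

# Independent brute-force GSEA enrichment score: literal running sum over
# every rank position.
brute_es <- function(metric, members, p = 1) {
  ord <- order(-metric, names(metric))
  metric <- metric[ord]
  genes <- names(metric)
  hit <- genes %in% members
  N <- length(genes)
  n <- sum(hit)
  w <- abs(metric)^p
  NR <- sum(w[hit])
  step <- ifelse(hit, if (NR > 0) w / NR else 1 / n, 0)
  step[hit] <- if (NR > 0) w[hit] / NR else 1 / n
  step[!hit] <- -1 / (N - n)
  rs <- cumsum(step)
  mx <- max(rs)
  mn <- min(c(0, rs[-N]))
  if (mx >= -mn) mx else mn
}

# Exact hypergeometric tail by explicit summation of binomial products.
sum_hyper <- function(k, nx, ny, N, tail = c("greater", "less")) {
  tail <- match.arg(tail)
  support <- max(0, nx + ny - N):min(nx, ny)
  probs <- choose(nx, support) * choose(N - nx, ny - support) / choose(N, ny)
  if (tail == "greater") sum(probs[support >= k]) else sum(probs[support <= k])
}
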