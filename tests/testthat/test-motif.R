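dna <- function(...) {
  x <- c(...)
  g <- Biostrings::DNAStringSet(x)
  names(g) <- names(x) %||% paste0("chr", seq_along(x))
  g
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("scanner finds exact, overlapping, case-insensitive occurrences", {
  expect_equal(scan_motif(dna(chr1 = "CACGTG"))$start, 0)
  expect_equal(scan_motif(dna(chr1 = "CACGTGCACGTG"))$start, c(0, 6))
  expect_equal(scan_motif(dna(chr1 = "cacGTGtt"))$start, 0)
  expect_equal(nrow(scan_motif(dna(chr1 = "CANGTGAAA"))), 0)
  expect_equal(nrow(scan_motif(dna(chr1 = ""))), 0)
  # palindrome: one record per genomic start in positions mode, two in
  # alignments mode
  pos <- scan_motif(dna(chr1 = "TTCACGTGTT"))
  expect_equal(nrow(pos), 1)
  expect_true(pos$palindromic)
  ali <- scan_motif(dna(chr1 = "TTCACGTGTT"), count_mode = "alignments")
  expect_equal(nrow(ali), 2)
  expect_setequal(ali$strand, c("+", "-"))
})

test_that("scanner matches a naive sliding-window oracle on random sequences", {
  set.seed(99)
  for (i in 1:100) {
    seq <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                 collapse = "")
    hits <- scan_motif(dna(chr1 = seq))
    oracle <- naive_scan(seq, "CACGTG")
    expect_equal(hits$start, oracle$start)
  }
  # non-palindromic motif: both strands reported
  seq <- "AAACGTGATTTCACGTTT" # fwd ACGTGA at 2; rc(ACGTGA)=TCACGT at 10
  hits <- scan_motif(dna(chr1 = seq), motif = "ACGTGA")
  oracle <- naive_scan(seq, "ACGTGA")
  expect_equal(hits$start[hits$strand == "+"],
               oracle$start[oracle$strand == "+"])
  expect_equal(hits$start[hits$strand == "-"],
               oracle$start[oracle$strand == "-"])
  set.seed(100)
  for (i in 1:20) {
    seq <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                 collapse = "")
    hits <- scan_motif(dna(chr1 = seq), motif = "ACGTGA")
    oracle <- naive_scan(seq, "ACGTGA")
    expect_equal(
      hits[order(hits$start, hits$strand), c("start", "strand")],
      oracle[order(oracle$start, oracle$strand), c("start", "strand")],
      ignore_attr = TRUE
    )
  }
})

test_that("minimum TSS distance uses the motif midpoint, unsigned", {
  tss <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 1000)
  hits <- tibble::tibble(chrom = "chr1", start = 1197, strand = "+",
                         palindromic = TRUE)
  d <- gene_min_distance(hits, tss)
  expect_equal(d$min_distance_bp, 200) # midpoint 1200
  expect_true(d$ebox_within_1kb)

  hits2 <- tibble::tibble(chrom = "chr1", start = 997, strand = "+",
                          palindromic = TRUE)
  expect_equal(gene_min_distance(hits2, tss)$min_distance_bp, 0)

  hits3 <- tibble::tibble(chrom = "chr1", start = c(597, 4997), strand = "+",
                          palindromic = TRUE)
  d3 <- gene_min_distance(hits3, tss)
  expect_equal(d3$min_distance_bp, 400)
  expect_true(d3$ebox_within_1kb)

  # no hit on the gene's chromosome
  tss2 <- tibble::tibble(gene_id = c("g1", "g2"), chrom = c("chr1", "chr2"),
                         tss = c(1000, 1000))
  d4 <- gene_min_distance(hits3, tss2)
  expect_true(is.na(d4$min_distance_bp[2]))
  expect_false(d4$ebox_within_1kb[2])
})

test_that("distances are invariant to a coordinate translation", {
  set.seed(7)
  tss <- tibble::tibble(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                        tss = sample(1e6, 20))
  hits <- tibble::tibble(chrom = "chr1", start = sample(1e6, 30),
                         strand = "+", palindromic = TRUE)
  d1 <- gene_min_distance(hits, tss)
  d2 <- gene_min_distance(dplyr::mutate(hits, start = start + 1234),
                          dplyr::mutate(tss, tss = tss + 1234))
  expect_equal(d1$min_distance_bp, d2$min_distance_bp)
})

test_that("nearest gene per motif matches brute force with lexicographic ties", {
  one <- nearest_tss_per_motif(
    tibble::tibble(chrom = "chr1", start = 100, strand = "+", palindromic = TRUE),
    tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 500)
  )
  expect_equal(one$gene_id, "g1")

  tie <- nearest_tss_per_motif(
    tibble::tibble(chrom = "chr1", start = 497, strand = "+", palindromic = TRUE),
    tibble::tibble(gene_id = c("zz", "aa"), chrom = "chr1", tss = c(400, 600))
  )
  expect_equal(tie$gene_id, "aa")

  set.seed(17)
  tss <- tibble::tibble(gene_id = sprintf("g%02d", 1:50), chrom = "chr1",
                        tss = sample(1e5, 50))
  hits <- tibble::tibble(chrom = "chr1", start = sample(1e5, 50),
                         strand = "+", palindromic = TRUE)
  got <- nearest_tss_per_motif(hits, tss)
  for (i in seq_len(nrow(hits))) {
    d <- abs(tss$tss - (hits$start[i] + 3))
    best <- tss$gene_id[d == min(d)]
    expect_equal(got$gene_id[i], sort(best)[1])
    expect_equal(got$distance_bp[i], min(d))
  }

  unassigned <- nearest_tss_per_motif(
    tibble::tibble(chrom = "chrX", start = 1, strand = "+", palindromic = TRUE),
    tss
  )
  expect_true(is.na(unassigned$gene_id))
})
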