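#' Simulation configuration
#'
#' Assembles and validates the parameter set that drives the synthetic-data
#' generator. Defaults emulate the study conditions of a doxycycline-titrated
#' MYC induction experiment: three genotypes (WT, T58A, T58I), seven doses,
#' three replicates, and gene-wise monotone Hill dose-response curves whose
#' half-maximal dose (EC50) differs by genotype for a labelled subset of
#' genes (T58A more sensitive than WT, T58I less).
#'
#' @param n_genes Number of genes to simulate.
#' @param frac_regulated Fraction of genes with a non-zero dose response in WT.
#' @param frac_mutant_differential Fraction of genes whose response differs
#'   between a mutant and WT (drawn partly from regulated genes, partly as
#'   mutant-only responders).
#' @param doses Doxycycline doses (ng/mL); must be sorted ascending and
#'   include 0.
#' @param genotypes Genotype labels; first element is the reference (WT).
#' @param n_replicates Replicates per genotype x dose combination (>= 2 for
#'   the dispersion estimator).
#' @param baseline_log_mean_range Range (natural-log scale) of baseline
#'   expression, in expected reads at a library size of 1e6 (i.e. CPM).
#' @param amplitude_range Range of absolute response amplitudes (log2 units)
#'   for regulated genes.
#' @param ec50_by_genotype Named vector of half-maximal doses (ng/mL), one
#'   per genotype.
#' @param hill_slope Hill coefficient of the dose-response curve (> 0).
#' @param dispersion_shape,dispersion_rate Shape and rate of the gamma
#'   distribution from which gene-wise NB dispersions are drawn.
#' @param library_size_range Range of per-sample library sizes (reads);
#'   sampled log-uniformly.
#' @param frac_noncoding Fraction of genes labelled `non_coding`.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal parameters of the
#'   gene length distribution (bp).
#' @param motif_distance_scheme Named list controlling E-box placement.
#'   `near_range`/`far_range` give distance windows (bp from the TSS) and
#'   `prob_up`, `prob_down`, `prob_unregulated` give `(near, far, none)`
#'   probabilities for up-regulated, down-regulated and unregulated genes.
#' @param rng_seed Integer seed from which all randomness flows.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 100, rng_seed = 1)
#' cfg$doses
sim_config <- function(n_genes = 2000,
                       frac_regulated = 0.3,
                       frac_mutant_differential = 0.15,
                       doses = c(0, 25, 50, 100, 300, 600, 1000),
                       genotypes = c("WT", "T58A", "T58I"),
                       n_replicates = 3,
                       baseline_log_mean_range = c(2.5, 6.5),
                       amplitude_range = c(1, 3),
                       ec50_by_genotype = c(WT = 100, T58A = 25, T58I = 450),
                       hill_slope = 4,
                       dispersion_shape = 2,
                       dispersion_rate = 20,
                       library_size_range = c(8e5, 1.5e6),
                       frac_noncoding = 0.2,
                       gene_length_meanlog = 8,
                       gene_length_sdlog = 0.8,
                       motif_distance_scheme = list(
                         near_range = c(50, 800),
                         far_range = c(2000, 4500),
                         prob_up = c(near = 0.7, far = 0.2, none = 0.1),
                         prob_down = c(near = 0.2, far = 0.3, none = 0.5),
                         prob_unregulated = c(near = 0.2, far = 0.3, none = 0.5)
                       ),
                       rng_seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    frac_regulated = frac_regulated,
    frac_mutant_differential = frac_mutant_differential,
    doses = as.numeric(doses),
    genotypes = as.character(genotypes),
    n_replicates = as.integer(n_replicates),
    baseline_log_mean_range = baseline_log_mean_range,
    amplitude_range = amplitude_range,
    ec50_by_genotype = ec50_by_genotype,
    hill_slope = hill_slope,
    dispersion_shape = dispersion_shape,
    dispersion_rate = dispersion_rate,
    library_size_range = library_size_range,
    frac_noncoding = frac_noncoding,
    gene_length_meanlog = gene_length_meanlog,
    gene_length_sdlog = gene_length_sdlog,
    motif_distance_scheme = motif_distance_scheme,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1) stop("n_genes must be positive")
  fracs <- c(cfg$frac_regulated, cfg$frac_mutant_differential, cfg$frac_noncoding)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (is.unsorted(cfg$doses, strictly = TRUE)) {
    stop("doses must be sorted ascending without duplicates")
  }
  if (cfg$doses[1] != 0) stop("doses must include 0 as the lowest dose")
  if (cfg$n_replicates < 2) stop("n_replicates must be >= 2")
  missing_ec50 <- setdiff(cfg$genotypes, names(cfg$ec50_by_genotype))
  if (length(missing_ec50) > 0) {
    stop("ec50_by_genotype missing genotypes: ", paste(missing_ec50, collapse = ", "))
  }
  if (any(cfg$ec50_by_genotype <= 0)) stop("EC50 values must be positive")
  if (cfg$hill_slope <= 0) stop("hill_slope must be positive")
  if (any(cfg$library_size_range <= 0)) stop("library sizes must be positive")
  invisible(cfg)
}

# Derive a deterministic sub-seed (< 2^31) from the master seed and a label,
# so each output stream gets its own reproducible generator.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) %% 7919)
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483629)
}
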