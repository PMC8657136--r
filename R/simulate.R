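#' Build the sample design for a titration experiment
#'
#' One sample per genotype x dose x replicate combination.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `sample_id`, `genotype`, `dose`, `replicate`.
#' @export
#' @examples
#' nrow(simulate_design(sim_config(n_genes = 10))) # 3 * 7 * 3 = 63
simulate_design <- function(config) {
  validate_sim_config(config)
  design <- tidyr::expand_grid(
    genotype = config$genotypes,
    dose = config$doses,
    replicate = seq_len(config$n_replicates)
  )
  design |>
    dplyr::mutate(
      sample_id = paste(.data$genotype, .data$dose, .data$replicate, sep = "_")
    ) |>
    dplyr::select("sample_id", "genotype", "dose", "replicate")
}

#' Hill dose-response mean
#'
#' Expected expression (reads at library size 1e6, i.e. CPM scale) of a gene
#' with a monotone Hill response:
#' `mean = exp(baseline) * 2^(amplitude * h(dose))` with
#' `h(d) = d^s / (d^s + ec50^s)`. The amplitude carries the sign of the
#' response direction; unregulated genes have amplitude 0.
#'
#' @param baseline_log Baseline log mean (natural log of the dose-0 mean).
#' @param amplitude Signed response amplitude in log2 units.
#' @param ec50 Half-maximal dose (ng/mL), > 0.
#' @param dose Dose (ng/mL), >= 0. Vectorized with the other arguments.
#' @param hill_slope Hill coefficient, > 0.
#' @return Expected expression on the CPM scale.
#' @export
#' @examples
#' dose_response_mean(log(10), amplitude = 1, ec50 = 100, dose = 100) # 10 * sqrt(2)
dose_response_mean <- function(baseline_log, amplitude, ec50, dose, hill_slope = 1) {
  if (any(ec50 <= 0)) stop("EC50 must be positive")
  if (any(dose < 0)) stop("dose must be non-negative")
  n <- max(length(baseline_log), length(amplitude), length(ec50), length(dose))
  baseline_log <- rep_len(baseline_log, n)
  amplitude <- rep_len(amplitude, n)
  ec50 <- rep_len(ec50, n)
  dose <- rep_len(dose, n)
  h <- numeric(n)
  nz <- dose > 0
  h[nz] <- dose[nz]^hill_slope / (dose[nz]^hill_slope + ec50[nz]^hill_slope)
  exp(baseline_log) * 2^(amplitude * h)
}

# Gene-level ground truth: who is regulated, in which direction, with which
# genotype-specific amplitude/EC50, and which genes respond differently in a
# mutant. Differential genes are of two kinds: "shift" genes (regulated in
# all genotypes, but with the mutant's own EC50 and a scaled amplitude) and
# "mutant-only" genes (flat in WT, responsive in the mutant).
simulate_truth <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$rng_seed, "truth"))
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  wt <- config$genotypes[1]
  mutants <- setdiff(config$genotypes, wt)

  regulated <- rep(FALSE, n)
  n_reg <- round(n * config$frac_regulated)
  regulated[sample.int(n, n_reg)] <- TRUE
  direction <- rep(NA_character_, n)
  direction[regulated] <- sample(c("up", "down"), n_reg, replace = TRUE)

  base_amp <- runif(n, config$amplitude_range[1], config$amplitude_range[2])
  base_amp <- ifelse(regulated, base_amp * ifelse(direction == "down", -1, 1), 0)

  # differential genes: 70% drawn from regulated ("shift"), 30% mutant-only
  n_diff <- if (length(mutants) == 0) 0L else
    round(n * config$frac_mutant_differential)
  n_shift <- min(round(0.7 * n_diff), n_reg)
  n_only <- min(n_diff - n_shift, n - n_reg)
  shift_idx <- sample(which(regulated), n_shift)
  only_idx <- sample(which(!regulated), n_only)
  diff_idx <- c(shift_idx, only_idx)
  diff_kind <- rep(c("shift", "mutant_only"), c(n_shift, n_only))

  # which mutant(s) the gene is differential in: 40/40/20 one/other/both
  which_mut <- character(length(diff_idx))
  if (length(diff_idx) > 0 && length(mutants) >= 2) {
    which_mut <- sample(c(mutants, "both"), length(diff_idx),
                        replace = TRUE, prob = c(0.4, 0.4, 0.2))
  } else if (length(diff_idx) > 0) {
    which_mut <- rep(mutants[1], length(diff_idx))
  }

  amp <- matrix(base_amp, nrow = n, ncol = length(config$genotypes),
                dimnames = list(gene_id, config$genotypes))
  ec50 <- matrix(config$ec50_by_genotype[wt], nrow = n,
                 ncol = length(config$genotypes),
                 dimnames = list(gene_id, config$genotypes))
  amp_scale <- c(T58A = 1.5, T58I = 0.6)
  differential_in <- rep("", n)

  for (j in seq_along(diff_idx)) {
    i <- diff_idx[j]
    muts <- if (which_mut[j] == "both") mutants else which_mut[j]
    differential_in[i] <- paste(muts, collapse = ",")
    for (m in muts) {
      ec50[i, m] <- config$ec50_by_genotype[[m]]
      if (diff_kind[j] == "shift") {
        scl <- if (m %in% names(amp_scale)) amp_scale[[m]] else 1.5
        amp[i, m] <- amp[i, m] * scl
      } else {
        a <- runif(1, config$amplitude_range[1], config$amplitude_range[2])
        amp[i, m] <- a * sample(c(-1, 1), 1)
      }
    }
  }

  biotype <- ifelse(runif(n) < config$frac_noncoding, "non_coding", "protein_coding")
  gene_length <- pmax(200, round(rlnorm(n, config$gene_length_meanlog,
                                        config$gene_length_sdlog)))

  truth <- tibble::tibble(
    gene_id = gene_id,
    regulated = regulated,
    direction = direction,
    differential_in = differential_in,
    baseline_log = runif(n, config$baseline_log_mean_range[1],
                         config$baseline_log_mean_range[2]),
    dispersion = rgamma(n, config$dispersion_shape, config$dispersion_rate),
    biotype = biotype,
    gene_length = gene_length
  )
  for (g in config$genotypes) {
    truth[[paste0("amplitude_", g)]] <- amp[, g]
    truth[[paste0("ec50_", g)]] <- ec50[, g]
  }
  truth
}

#' Simulate a dose-graded titration experiment
#'
#' Draws negative-binomial counts for every gene and sample around
#' genotype-specific Hill dose-response means, with log-uniform library
#' sizes. Identical configurations (including the seed) give byte-identical
#' output.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `dose_sim` with elements `counts` (tibble,
#'   `gene_id` plus one column per sample), `design`, `truth` (per-gene
#'   ground truth including amplitudes, EC50s, dispersion, biotype and
#'   length) and `library_sizes` (named vector of target sizes used for
#'   scaling).
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 50, rng_seed = 7))
#' dim(sim$counts)
simulate_experiment <- function(config) {
  validate_sim_config(config)
  design <- simulate_design(config)
  truth <- simulate_truth(config)
  set.seed(derive_seed(config$rng_seed, "counts"))

  lib <- exp(runif(nrow(design), log(config$library_size_range[1]),
                   log(config$library_size_range[2])))
  names(lib) <- design$sample_id

  n <- nrow(truth)
  counts <- matrix(0L, nrow = n, ncol = nrow(design),
                   dimnames = list(truth$gene_id, design$sample_id))
  for (s in seq_len(nrow(design))) {
    g <- design$genotype[s]
    mu_cpm <- dose_response_mean(
      truth$baseline_log,
      truth[[paste0("amplitude_", g)]],
      truth[[paste0("ec50_", g)]],
      design$dose[s],
      config$hill_slope
    )
    mu <- mu_cpm * lib[s] / 1e6
    phi <- truth$dispersion
    y <- integer(n)
    pois <- phi < 1e-10
    if (any(pois)) y[pois] <- stats::rpois(sum(pois), mu[pois])
    if (any(!pois)) y[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = 1 / phi[!pois])
    counts[, s] <- y
  }

  out <- list(
    counts = tibble::as_tibble(counts, rownames = "gene_id"),
    design = design,
    truth = truth,
    library_sizes = lib,
    config = config
  )
  class(out) <- "dose_sim"
  out
}

#' Simulate gene-set collections tied to the ground truth
#'
#' Emits gene sets enriched in a known truth category (by default drawn 80%
#' from genes whose dose response is more sensitive in T58A) alongside
#' uniformly drawn control sets, in the spirit of a GMT collection.
#'
#' @param truth Truth tibble from [simulate_experiment()].
#' @param config The [sim_config()] used.
#' @param n_enriched,n_control Numbers of enriched and control sets.
#' @param set_size Genes per set (>= 1). The default keeps the truth
#'   fraction within the size of the labelled category at default
#'   simulation sizes.
#' @param frac_from_truth Fraction of each enriched set drawn from the truth
#'   category.
#' @param category Truth category for enriched sets: genes whose
#'   `differential_in` contains this genotype label.
#' @return A list with `sets` (named list of gene-id vectors) and `info`
#'   (tibble with `name`, `kind`, `description`).
#' @export
simulate_gene_sets <- function(truth, config, n_enriched = 3, n_control = 3,
                               set_size = 25, frac_from_truth = 0.8,
                               category = "T58A") {
  if (set_size < 1) stop("set_size must be >= 1; empty sets are not allowed")
  set.seed(derive_seed(config$rng_seed, "gene_sets"))
  pool <- truth$gene_id
  # directionally coherent truth category: genes whose response differs in
  # the chosen mutant and goes up there, so a set's members share a
  # rank-metric tail (as members of a real pathway set do)
  amp_col <- paste0("amplitude_", category)
  up_in_cat <- if (amp_col %in% names(truth)) truth[[amp_col]] > 0 else TRUE
  cat_genes <- truth$gene_id[grepl(category, truth$differential_in,
                                   fixed = TRUE) & up_in_cat]
  if (n_enriched > 0 && length(cat_genes) == 0) {
    stop("no genes in truth category '", category, "'")
  }
  sets <- list()
  info <- list()
  for (i in seq_len(n_enriched)) {
    n_cat <- min(round(frac_from_truth * set_size), length(cat_genes))
    members <- c(sample(cat_genes, n_cat),
                 sample(setdiff(pool, cat_genes), set_size - n_cat))
    nm <- sprintf("enriched_%s_%d", tolower(category), i)
    sets[[nm]] <- sort(members)
    info[[nm]] <- tibble::tibble(name = nm, kind = "enriched",
                                 description = paste0(category, "-sensitive truth set"))
  }
  for (i in seq_len(n_control)) {
    nm <- sprintf("control_%d", i)
    sets[[nm]] <- sort(sample(pool, min(set_size, length(pool))))
    info[[nm]] <- tibble::tibble(name = nm, kind = "control",
                                 description = "uniform control set")
  }
  list(sets = sets, info = dplyr::bind_rows(info))
}
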