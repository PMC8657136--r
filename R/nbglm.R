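# Vectorized negative-binomial GLM machinery for the genotype x dose
# factorial model. All fits operate on a genes x samples count matrix at
# once; the factorial (saturated-in-cells) and WT-collapsed models reduce to
# per-group mean fits, while the mutant shift model (mutant dose profile =
# WT profile + intercept shift) is fitted by blockwise Fisher scoring.

# NB residual deviance per gene. Y, MU: genes x s matrices; phi: per-gene
# dispersion. phi ~ 0 falls back to the Poisson deviance.
nb_deviance <- function(Y, MU, phi) {
  MU <- pmax(MU, 1e-10)
  t1 <- ifelse(Y > 0, Y * log(Y / MU), 0)
  pois <- phi < 1e-10
  dev <- matrix(0, nrow(Y), ncol(Y))
  if (any(pois)) {
    dev[pois, ] <- 2 * (t1[pois, , drop = FALSE] -
                          (Y[pois, , drop = FALSE] - MU[pois, , drop = FALSE]))
  }
  if (any(!pois)) {
    ph <- phi[!pois]
    Yn <- Y[!pois, , drop = FALSE]
    Mn <- MU[!pois, , drop = FALSE]
    dev[!pois, ] <- 2 * (t1[!pois, , drop = FALSE] -
                           (Yn + 1 / ph) * log((1 + ph * Yn) / (1 + ph * Mn)))
  }
  rowSums(dev)
}

# MLE of a common log-mean (CPM scale) for a group of samples, per gene.
# LAM: per-gene exposure matrix (genes x s) or a length-s vector.
# Returns beta with exp(beta) the fitted group mean; -Inf for all-zero rows.
nb_group_beta <- function(Y, LAM, phi, max_iter = 50L, tol = 1e-10) {
  if (is.null(dim(LAM))) {
    LAM <- matrix(LAM, nrow(Y), ncol(Y), byrow = TRUE)
  }
  tot <- rowSums(Y)
  beta <- ifelse(tot > 0, log(tot / rowSums(LAM)), -Inf)
  act <- which(tot > 0)
  for (it in seq_len(max_iter)) {
    if (length(act) == 0) break
    MU <- exp(beta[act]) * LAM[act, , drop = FALSE]
    ph <- phi[act]
    U <- rowSums((Y[act, , drop = FALSE] - MU) / (1 + ph * MU))
    I <- rowSums(MU / (1 + ph * MU))
    step <- pmax(pmin(U / pmax(I, 1e-12), 5), -5)
    beta[act] <- beta[act] + step
    act <- act[abs(U) > tol * (I + 1)]
  }
  beta
}

# sample cells in canonical order: genotype order of first appearance,
# doses ascending within genotype
cell_layout <- function(design) {
  genotypes <- unique(design$genotype)
  doses <- sort(unique(design$dose))
  cells <- tidyr::expand_grid(genotype = genotypes, dose = doses)
  cells$cell <- paste(cells$genotype, cells$dose, sep = "|")
  cells
}

# Saturated factorial fit: one fitted mean (CPM scale) per genotype x dose
# cell. Returns fitted CPM matrix (genes x cells) and per-cell deviances.
fit_factorial_cells <- function(Y, design, lam, phi) {
  cells <- cell_layout(design)
  beta <- matrix(NA_real_, nrow(Y), nrow(cells),
                 dimnames = list(rownames(Y), cells$cell))
  dev_cell <- matrix(0, nrow(Y), nrow(cells),
                     dimnames = list(rownames(Y), cells$cell))
  for (j in seq_len(nrow(cells))) {
    idx <- which(design$genotype == cells$genotype[j] & design$dose == cells$dose[j])
    b <- nb_group_beta(Y[, idx, drop = FALSE], lam[idx], phi)
    beta[, j] <- b
    MU <- exp(b) * matrix(lam[idx], nrow(Y), length(idx), byrow = TRUE)
    dev_cell[, j] <- nb_deviance(Y[, idx, drop = FALSE], MU, phi)
  }
  list(cells = cells, fitted_cpm = exp(beta), deviance_cell = dev_cell)
}

# Reduced model (a): WT means collapsed across dose. Only WT samples enter
# the deviance difference (mutant cells are saturated in both models).
deviance_wt_collapsed <- function(Y, design, lam, phi, reference) {
  idx <- which(design$genotype == reference)
  b <- nb_group_beta(Y[, idx, drop = FALSE], lam[idx], phi)
  MU <- exp(b) * matrix(lam[idx], nrow(Y), length(idx), byrow = TRUE)
  nb_deviance(Y[, idx, drop = FALSE], MU, phi)
}

# Reduced model (b): mutant dose profile constrained to the reference
# profile up to an intercept shift. Blockwise Fisher scoring: dose means
# given the shift are per-dose group fits with exposure lam * exp(c * I_mut);
# the shift given the means is a group fit over mutant samples with exposure
# lam * fitted dose mean. Deviance decreases at every block update.
fit_shift_model <- function(Y, design, lam, phi, reference, mutant,
                            max_iter = 100L, tol = 1e-8) {
  idx <- which(design$genotype %in% c(reference, mutant))
  Ys <- Y[, idx, drop = FALSE]
  lams <- lam[idx]
  dsub <- design[idx, , drop = FALSE]
  doses <- sort(unique(dsub$dose))
  is_mut <- dsub$genotype == mutant
  n <- nrow(Ys)
  cc <- rep(0, n)
  beta <- matrix(-Inf, n, length(doses))
  dev_old <- rep(Inf, n)
  LAMg <- matrix(lams, n, length(lams), byrow = TRUE)
  for (it in seq_len(max_iter)) {
    for (d in seq_along(doses)) {
      jd <- which(dsub$dose == doses[d])
      LAM <- LAMg[, jd, drop = FALSE] *
        exp(outer(cc, as.numeric(is_mut[jd])))
      beta[, d] <- nb_group_beta(Ys[, jd, drop = FALSE], LAM, phi)
    }
    jm <- which(is_mut)
    dpos <- match(dsub$dose[jm], doses)
    LAMm <- LAMg[, jm, drop = FALSE] * exp(beta[, dpos, drop = FALSE])
    ok <- is.finite(rowSums(LAMm))
    if (any(ok)) {
      cc[ok] <- nb_group_beta(Ys[ok, jm, drop = FALSE],
                              LAMm[ok, , drop = FALSE], phi[ok])
      cc[!is.finite(cc)] <- 0
    }
    dall <- match(dsub$dose, doses)
    MU <- exp(beta[, dall, drop = FALSE] + outer(cc, as.numeric(is_mut))) * LAMg
    MU[!is.finite(MU)] <- 0
    dev <- nb_deviance(Ys, MU, phi)
    if (all(abs(dev_old - dev) <= tol * (abs(dev) + 1))) {
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  dev_old
}
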