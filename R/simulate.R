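#' Configuration for the sparse polygenic phenotype simulator
#'
#' Defines the two simulation designs with known truth. In Case 1
#' (`spike_sd = 0`) a fraction `mixture_p` of SNPs carries normal effects
#' with variance `slab_var` and the rest have exactly zero effect; in
#' Case 2 (`spike_sd > 0`, e.g. 0.01) the non-associative SNPs instead
#' carry small noisy normal effects with standard deviation `spike_sd`.
#' The residual variance is calibrated so that the proportion of
#' phenotypic variance explained by the slab (associative) genetic values
#' equals `target_pve`.
#'
#' @param n_samples Number of individuals.
#' @param n_snps Number of SNPs.
#' @param mixture_p Fraction of associative SNPs; exactly
#'   `round(mixture_p * n_snps)` slab SNPs are drawn.
#' @param slab_var Variance of the associative (slab) effects.
#' @param spike_sd Standard deviation of non-associative effects
#'   (0 = Case 1, point mass).
#' @param target_pve Target proportion of variance explained, in (0, 1).
#' @param maf_range Range of the uniform minor-allele-frequency
#'   distribution. Default c(0.05, 0.5).
#' @param seed Optional integer seed.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_samples, n_snps, mixture_p = 0.01, slab_var = 0.1,
                       spike_sd = 0, target_pve = 0.5,
                       maf_range = c(0.05, 0.5), seed = NULL) {
  stopifnot(n_samples >= 2, n_snps >= 1,
            mixture_p > 0, mixture_p < 1,
            slab_var > 0, spike_sd >= 0,
            target_pve > 0, target_pve < 1,
            length(maf_range) == 2L, maf_range[1L] > 0, maf_range[2L] < 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps),
                 mixture_p = mixture_p, slab_var = slab_var,
                 spike_sd = spike_sd, target_pve = target_pve,
                 maf_range = maf_range, seed = seed),
            class = "sim_config")
}

#' Simulate Hardy-Weinberg genotypes in linkage equilibrium
#'
#' Per SNP, a minor allele frequency is drawn uniformly from
#' `cfg$maf_range` and allele counts are i.i.d. Binomial(2, MAF) across
#' samples. Columns that come out monomorphic in a finite sample are
#' redrawn (up to 25 attempts) so the matrix is standardizable.
#' `ld_rho > 0` switches on an autoregressive LD-block mode in which the
#' latent allele draws of adjacent SNPs are correlated.
#'
#' @param cfg A [sim_config()].
#' @param ld_rho Adjacent-SNP allele correlation in `[0, 1)`. Default 0
#'   (linkage equilibrium).
#' @return A [`genotype_matrix`].
#' @export
simulate_genotypes <- function(cfg, ld_rho = 0) {
  stopifnot(inherits(cfg, "sim_config"), ld_rho >= 0, ld_rho < 1)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_samples; N <- cfg$n_snps
  maf <- stats::runif(N, cfg$maf_range[1L], cfg$maf_range[2L])
  if (ld_rho == 0) {
    counts <- matrix(stats::rbinom(n * N, 2L, rep(maf, each = n)), n, N)
  } else {
    # latent Gaussian AR(1) across SNPs, thresholded to per-allele draws
    counts <- matrix(0L, n, N)
    for (a in 1:2) {
      Z <- matrix(stats::rnorm(n * N), n, N)
      for (j in 2:N) Z[, j] <- ld_rho * Z[, j - 1L] + sqrt(1 - ld_rho^2) * Z[, j]
      counts <- counts + (Z < stats::qnorm(rep(maf, each = n)))
    }
  }
  for (j in which(apply(counts, 2L, function(x) length(unique(x))) == 1L)) {
    for (try in 1:25) {
      counts[, j] <- stats::rbinom(n, 2L, maf[j])
      if (length(unique(counts[, j])) > 1L) break
    }
  }
  new_genotype_matrix(counts)
}

#' Draw ground-truth SNP effects for a simulation
#'
#' Exactly `round(mixture_p * n_snps)` SNPs, chosen uniformly, receive
#' slab effects `N(0, slab_var)`; the rest are exactly zero (Case 1) or
#' `N(0, spike_sd^2)` (Case 2).
#'
#' @param cfg A [sim_config()].
#' @return A `sim_truth` object: list with `b_true`, `I_true`
#'   (1 = associative), and the config fields used. The residual variance
#'   and realized PVE slots are filled in by [simulate_gwas()].
#' @export
simulate_effects <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  N <- cfg$n_snps
  k <- round(cfg$mixture_p * N)
  if (k < 1L) stop("round(mixture_p * n_snps) is zero: no signal to simulate")
  idx <- sample.int(N, k)
  b <- if (cfg$spike_sd > 0) stats::rnorm(N, 0, cfg$spike_sd) else numeric(N)
  b[idx] <- stats::rnorm(k, 0, sqrt(cfg$slab_var))
  I <- integer(N); I[idx] <- 1L
  structure(list(b_true = b, I_true = I, n_assoc = k,
                 slab_var = cfg$slab_var, spike_sd = cfg$spike_sd,
                 sigma_e2_used = NA_real_, realized_pve = NA_real_,
                 genetic_values = NULL),
            class = "sim_truth")
}

#' Residual variance achieving a target PVE
#'
#' Given realized genetic values g, returns
#' `sigma_e2 = Var(g) * (1 - target_pve) / target_pve`, so that
#' `Var(g) / (Var(g) + sigma_e2) = target_pve`.
#'
#' @param genetic_values Vector of realized genetic values (`W b` over the
#'   associative SNPs).
#' @param target_pve Target PVE in (0, 1).
#' @return The residual variance.
#' @export
error_variance_for_target_pve <- function(genetic_values, target_pve) {
  stopifnot(target_pve > 0, target_pve < 1)
  vg <- stats::var(as.numeric(genetic_values))
  if (!is.finite(vg) || vg <= 0) stop("genetic values have zero variance")
  vg * (1 - target_pve) / target_pve
}

#' Assemble a phenotype from genotypes, effects and noise
#'
#' `y = W b + e` with `e ~ N(0, sigma_e2 I)`. An optional fixed-effect
#' contribution `X beta` can be added.
#'
#' @param W Standardized genotype matrix or [`standardized_genotypes`].
#' @param truth A `sim_truth` (its `b_true` is used).
#' @param sigma_e2 Residual variance.
#' @param X,beta Optional fixed-effect design and coefficients.
#' @return Numeric phenotype vector.
#' @export
simulate_phenotype <- function(W, truth, sigma_e2, X = NULL, beta = NULL) {
  if (inherits(W, "standardized_genotypes")) W <- W$W
  stopifnot(inherits(truth, "sim_truth"), ncol(W) == length(truth$b_true),
            sigma_e2 >= 0)
  y <- drop(W %*% truth$b_true) + stats::rnorm(nrow(W), 0, sqrt(sigma_e2))
  if (!is.null(X)) y <- y + drop(as.matrix(X) %*% beta)
  y
}

#' Simulate a complete GWAS data set with known truth
#'
#' Runs the full pipeline: Hardy-Weinberg genotypes, standardization,
#' mixture effects, residual-variance calibration to the target PVE, and
#' the phenotype. The PVE calibration uses the empirical variance of the
#' slab-only genetic values (the associative SNPs), matching the
#' convention that the genetic variance is `slab_var` times the number of
#' slab SNPs; in Case 2 the small noisy effects of non-associative SNPs
#' are additional variance not counted as the target signal.
#'
#' @param cfg A [sim_config()].
#' @param ld_rho Passed to [simulate_genotypes()].
#' @return List with `genotypes` ([`genotype_matrix`]), `std`
#'   ([`standardized_genotypes`]), `y`, `truth` (a completed `sim_truth`
#'   with `sigma_e2_used`, `realized_pve`, `genetic_values`), and `cfg`.
#' @export
simulate_gwas <- function(cfg, ld_rho = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  geno <- simulate_genotypes(cfg, ld_rho = ld_rho)   # sets the seed
  std <- standardize_genotypes(geno)
  truth <- simulate_effects(cfg)
  slab <- truth$I_true == 1L
  g_slab <- drop(std$W[, slab, drop = FALSE] %*% truth$b_true[slab])
  sigma_e2 <- error_variance_for_target_pve(g_slab, cfg$target_pve)
  y <- simulate_phenotype(std$W, truth, sigma_e2)
  truth$sigma_e2_used <- sigma_e2
  truth$realized_pve <- stats::var(g_slab) / (stats::var(g_slab) + sigma_e2)
  truth$genetic_values <- drop(std$W %*% truth$b_true)
  list(genotypes = geno, std = std, y = y, truth = truth, cfg = cfg)
}

#' Cross-tabulate selected SNPs against the simulation truth
#'
#' @param selected Character vector of selected SNP IDs, or integer/logical
#'   index into the SNP universe.
#' @param truth A `sim_truth`.
#' @param snps SNP IDs of the universe (needed when `selected` is
#'   character).
#' @return List with `tpr`, `fnr`, `fpr`, `tnr` (proportions), the
#'   underlying 2 x 2 count `table`, and counts of true/null SNPs.
#' @export
benchmark_detection <- function(selected, truth, snps = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  N <- length(truth$I_true)
  sel <- logical(N)
  if (is.character(selected)) {
    if (is.null(snps)) stop("snps required when selected is a character vector")
    sel[match(selected, snps)] <- TRUE
  } else if (is.logical(selected)) {
    sel <- selected
  } else sel[selected] <- TRUE
  true_set <- truth$I_true == 1L
  if (!any(true_set)) stop("truth contains no associative SNPs")
  tp <- sum(sel & true_set);  fn <- sum(!sel & true_set)
  fp <- sum(sel & !true_set); tn <- sum(!sel & !true_set)
  tab <- matrix(c(tp, fn, fp, tn), 2L, 2L, byrow = TRUE,
                dimnames = list(c("assoc", "non_assoc"),
                                c("identified", "not_identified")))
  list(tpr = tp / (tp + fn), fnr = fn / (tp + fn),
       fpr = fp / (fp + tn), tnr = tn / (fp + tn),
       table = tab, n_true = tp + fn, n_null = fp + tn)
}
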