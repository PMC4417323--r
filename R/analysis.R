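#' Single-SNP marginal association scan
#'
#' Ordinary least squares of the phenotype on each SNP's raw allele counts
#' plus the covariates, one SNP at a time; reports the SNP slope, its
#' standard error and the Wald (t) p-value. Computed by residualizing the
#' phenotype and each SNP on the covariates, which is algebraically
#' identical to the full OLS fit and vectorizes over SNPs. Missing
#' genotypes are mean-imputed per SNP. Constant SNP columns get slope 0,
#' p-value 1 and a flag.
#'
#' @param y Phenotype vector.
#' @param X Covariate design matrix (include an intercept column).
#' @param g A [`genotype_matrix`], or a plain n x N numeric dosage matrix.
#' @return A data.frame (`marginal_scan` class) with columns `snp`,
#'   `slope`, `se`, `p_value`, `constant`.
#' @export
marginal_scan <- function(y, X, g) {
  G <- if (inherits(g, "genotype_matrix")) g$counts else as.matrix(g)
  snps <- colnames(G)
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(G)))
  storage.mode(G) <- "double"
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    miss <- which(is.na(G), arr.ind = TRUE)
    G[miss] <- mu[miss[, 2L]]
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y); q <- ncol(X)
  qrX <- qr(X)
  ry <- qr.resid(qrX, y)
  RG <- qr.resid(qrX, G)
  ss_w <- colSums(RG^2)
  constant <- ss_w < 1e-12
  xy <- colSums(RG * ry)
  slope <- ifelse(constant, 0, xy / ss_w)
  df <- n - q - 1L
  rss <- sum(ry^2) - slope^2 * ss_w
  sigma2 <- pmax(rss, 0) / df
  se <- ifelse(constant, NA_real_, sqrt(sigma2 / ss_w))
  tval <- slope / se
  p <- ifelse(constant, 1, 2 * stats::pt(-abs(tval), df))
  p <- pmax(p, .Machine$double.xmin)
  out <- data.frame(snp = snps, slope = slope, se = se, p_value = p,
                    constant = constant, row.names = NULL)
  class(out) <- c("marginal_scan", "data.frame")
  out
}

#' Multiscale PVE: REML on SNP subsets defined by p-value thresholds
#'
#' For each threshold, restricts to SNPs whose marginal-scan p-value is
#' strictly below it, rebuilds the GRM on that subset, fits the REML mixed
#' model, and records the variance components and PVE. Thresholds are
#' processed from loosest to tightest, so SNP counts are non-increasing
#' down the table. Subsets with fewer than 2 SNPs give a not-estimable
#' row.
#'
#' @param scan A [marginal_scan()] result on the same SNP universe as `g`.
#' @param y,X Phenotype and covariates.
#' @param g The [`genotype_matrix`].
#' @param thresholds Decreasing p-value grid; default `10^-(1:7)`.
#' @return A data.frame (`multiscale_report`) with one row per threshold:
#'   `threshold`, `n_snps`, `sigma_g2`, `sigma_e2`, `total_var`, `pve`,
#'   `pve_se`, `estimable`.
#' @export
multiscale_pve <- function(scan, y, X, g, thresholds = 10^-(1:7)) {
  stopifnot(inherits(scan, "marginal_scan"), inherits(g, "genotype_matrix"))
  thresholds <- sort(thresholds, decreasing = TRUE)
  rows <- lapply(thresholds, function(th) {
    keep <- scan$p_value < th & !scan$constant
    n_snps <- sum(keep)
    base <- data.frame(threshold = th, n_snps = n_snps,
                       sigma_g2 = NA_real_, sigma_e2 = NA_real_,
                       total_var = NA_real_, pve = NA_real_,
                       pve_se = NA_real_, estimable = FALSE)
    if (n_snps < 2L) return(base)
    sub <- new_genotype_matrix(g$counts[, keep, drop = FALSE],
                               metadata = g$metadata)
    fit <- tryCatch(
      suppressWarnings(fit_mlm_reml(y, X, compute_grm(sub))),
      error = function(e) NULL)
    if (is.null(fit)) return(base)
    pve <- estimate_pve_mlm(fit)
    base$sigma_g2 <- fit$sigma_g2
    base$sigma_e2 <- fit$sigma_e2
    base$total_var <- fit$sigma_g2 + fit$sigma_e2
    base$pve <- pve$pve
    base$pve_se <- pve$se
    base$estimable <- TRUE
    base
  })
  out <- do.call(rbind, rows)
  stopifnot(!is.unsorted(rev(out$n_snps)))   # counts monotone in threshold
  class(out) <- c("multiscale_report", "data.frame")
  out
}

#' Side-by-side comparison of the hierarchical model and the MLM baseline
#'
#' Builds a parameter table (mixture probability, per-SNP variance,
#' genetic variance, residual variance, PVE; each with its uncertainty)
#' and a per-SNP effect table (posterior-mean effects versus BLUP
#' effects), optionally with truth columns and absolute errors when a
#' `sim_truth` is supplied.
#'
#' @param hbm An `hbm_posterior`.
#' @param mlm A `reml_fit` on the same data.
#' @param W Standardized genotypes (for the MLM BLUP effects).
#' @param y,X The shared data.
#' @param truth Optional `sim_truth`.
#' @return List with data.frames `parameters` and `effects`.
#' @export
compare_models <- function(hbm, mlm, W, y, X, truth = NULL) {
  stopifnot(inherits(hbm, "hbm_posterior"), inherits(mlm, "reml_fit"))
  N <- length(hbm$snps)
  pve_h <- estimate_pve_hbm(hbm)
  pve_m <- estimate_pve_mlm(mlm)
  sg_h <- hbm$sigma_b2 * hbm$k_active
  parameters <- data.frame(
    parameter = c("p", "sigma_b2", "sigma_g2", "sigma_e2", "pve"),
    hbm = c(mean(hbm$p), mean(hbm$sigma_b2), mean(sg_h),
            mean(hbm$sigma_e2), pve_h$mean),
    hbm_sd = c(stats::sd(hbm$p), stats::sd(hbm$sigma_b2), stats::sd(sg_h),
               stats::sd(hbm$sigma_e2), pve_h$sd),
    mlm = c(1, mlm$sigma_g2 / N, mlm$sigma_g2, mlm$sigma_e2, pve_m$pve),
    mlm_sd = c(NA, mlm$se[1L] / N, mlm$se[1L], mlm$se[2L], pve_m$se))
  effects <- data.frame(
    snp = hbm$snps,
    pip = compute_pip(hbm),
    hbm_effect = rowMeans(hbm$b),
    mlm_effect = blup_snp_effects(mlm, W, y, X),
    row.names = NULL)
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "sim_truth"))
    slab_var_true <- truth$slab_var
    true_par <- c(length(which(truth$I_true == 1L)) / N, slab_var_true,
                  slab_var_true * truth$n_assoc, truth$sigma_e2_used,
                  truth$realized_pve)
    parameters$truth <- true_par
    parameters$hbm_abs_err <- abs(parameters$hbm - true_par)
    parameters$mlm_abs_err <- abs(parameters$mlm - true_par)
    effects$true_effect <- truth$b_true
    effects$is_assoc <- truth$I_true == 1L
  }
  list(parameters = parameters, effects = effects)
}
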