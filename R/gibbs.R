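#' Prior specification for the hierarchical spike-and-slab model
#'
#' Defaults follow the model's standard conjugate setup: a Beta(1, 1) prior
#' on the mixture probability p, Inverse-Gamma(0.001, 0.001) priors on the
#' slab variance and the residual variance, independent zero-mean normal
#' priors with standard deviation `1e5` on each fixed effect, and an exact
#' point mass at zero for excluded SNP effects (`spike_sd = 0`). Setting
#' `spike_sd > 0` (e.g. 0.01) replaces the point mass by a small-variance
#' normal, the continuous approximation under which the mixture is a pair
#' of normals.
#'
#' @param p_alpha,p_beta Beta prior parameters for p.
#' @param a1,b1 Inverse-Gamma shape/rate for the slab variance.
#' @param a2,b2 Inverse-Gamma shape/rate for the residual variance.
#' @param beta_sd Prior standard deviation of each fixed effect.
#' @param spike_sd Standard deviation of the spike component; 0 = exact
#'   point mass.
#' @return An `hbm_priors` object.
#' @export
hbm_priors <- function(p_alpha = 1, p_beta = 1,
                       a1 = 0.001, b1 = 0.001,
                       a2 = 0.001, b2 = 0.001,
                       beta_sd = 1e5, spike_sd = 0) {
  stopifnot(p_alpha > 0, p_beta > 0, a1 > 0, b1 > 0, a2 > 0, b2 > 0,
            beta_sd > 0, spike_sd >= 0)
  structure(list(p_alpha = p_alpha, p_beta = p_beta,
                 a1 = a1, b1 = b1, a2 = a2, b2 = b2,
                 beta_sd = beta_sd, spike_sd = spike_sd),
            class = "hbm_priors")
}

#' MCMC chain settings
#'
#' Defaults are 5,000 burn-in sweeps followed by 2,000 retained draws,
#' no thinning, and a sequential SNP scan order.
#'
#' @param n_burnin Number of discarded warm-up sweeps.
#' @param n_keep Number of retained draws.
#' @param seed Optional integer seed; when given, the chain is fully
#'   reproducible.
#' @param thinning Keep every `thinning`-th post-burn-in sweep.
#' @param scan_order `"sequential"` (default) or `"random"` (re-shuffled
#'   each sweep).
#' @param block_refresh If `TRUE`, after each component-wise scan the
#'   active-set effects are re-drawn jointly ([sample_active_block()]);
#'   this forces the pure-R engine.
#' @param fix Named list pinning any of `p`, `sigma_b2`, `sigma_e2`,
#'   `beta` at fixed values instead of sampling them (used for oracle
#'   comparisons and diagnostics).
#' @return A `chain_config` object.
#' @export
chain_config <- function(n_burnin = 5000, n_keep = 2000, seed = NULL,
                         thinning = 1,
                         scan_order = c("sequential", "random"),
                         block_refresh = FALSE,
                         fix = list()) {
  scan_order <- match.arg(scan_order)
  stopifnot(n_burnin >= 0, n_keep >= 1, thinning >= 1)
  bad <- setdiff(names(fix), c("p", "sigma_b2", "sigma_e2", "beta"))
  if (length(bad)) stop("unknown fixed parameters: ", paste(bad, collapse = ", "))
  structure(list(n_burnin = as.integer(n_burnin), n_keep = as.integer(n_keep),
                 seed = seed, thinning = as.integer(thinning),
                 scan_order = scan_order, block_refresh = block_refresh,
                 fix = fix),
            class = "chain_config")
}

.init_state <- function(y, X, W, priors, cfg) {
  N <- ncol(W)
  q <- if (is.null(X)) 0L else ncol(X)
  beta <- if (q > 0L) stats::lm.fit(X, y)$coefficients else numeric(0)
  beta[is.na(beta)] <- 0
  state <- list(beta = as.numeric(beta),
                b = numeric(N),
                I = integer(N),
                p = 0.01,
                sigma_b2 = 0.1,
                sigma_e2 = stats::var(y) / 2)
  for (nm in names(cfg$fix)) state[[nm]] <- cfg$fix[[nm]]
  state$r <- y - (if (q > 0L) drop(X %*% state$beta) else 0) - drop(W %*% state$b)
  state
}

#' Fit the hierarchical spike-and-slab model by Gibbs sampling
#'
#' Runs the component-wise Gibbs sampler for the model
#' `y = X beta + W b + e`, where each SNP effect `b_j` is, conditional on a
#' latent Bernoulli(p) indicator `I_j`, drawn from `N(0, sigma_b2)` when
#' `I_j = 1` and equal to zero (or a small-variance spike) when `I_j = 0`.
#' Each sweep updates the indicator and effect of every SNP (indicator
#' collapsed over the effect, then the effect from its normal full
#' conditional), then the fixed effects, the two variances, and the mixture
#' probability, all from their conjugate full conditionals.
#'
#' @param y Numeric phenotype vector (length n).
#' @param X Fixed-effect design matrix (n x q, full rank), or `NULL` for no
#'   fixed effects. An intercept is not added automatically.
#' @param W Standardized genotype matrix (n x N), e.g. from
#'   [standardize_genotypes()].
#' @param priors An [hbm_priors()] object.
#' @param cfg A [chain_config()] object.
#' @param engine `"auto"` (compiled unless `block_refresh`), `"cpp"`, or
#'   `"r"` (pure-R reference implementation; slow, for small problems).
#' @return An `hbm_posterior` object holding the retained draws: `b`
#'   (N x n_draws), `I`, `beta` (q x n_draws), `p`, `sigma_b2`, `sigma_e2`,
#'   `k_active`, `var_g` (per-draw empirical variance of the genetic values
#'   `W b`), plus SNP IDs and the final sampler state.
#' @export
run_gibbs <- function(y, X, W, priors = hbm_priors(), cfg = chain_config(),
                      engine = c("auto", "cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(priors, "hbm_priors"), inherits(cfg, "chain_config"))
  snps <- colnames(W)
  if (inherits(W, "standardized_genotypes")) { snps <- W$snps; W <- W$W }
  y <- as.numeric(y)
  n <- length(y); N <- ncol(W)
  if (nrow(W) != n) stop("nrow(W) must equal length(y)")
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("nrow(X) must equal length(y)")
    if (qr(X)$rank < ncol(X)) stop("X is rank deficient; drop collinear columns")
  }
  if (is.null(snps)) snps <- paste0("snp", seq_len(N))
  if (engine == "auto") engine <- if (cfg$block_refresh) "r" else "cpp"
  if (cfg$block_refresh && engine == "cpp")
    stop("block_refresh is only available with engine = 'r'")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  state <- .init_state(y, X, W, priors, cfg)
  Xmat <- if (is.null(X)) matrix(0, n, 0L) else X
  cfg_cpp <- list(n_burnin = cfg$n_burnin, n_keep = cfg$n_keep,
                  thinning = cfg$thinning,
                  random_scan = cfg$scan_order == "random",
                  fix_p = "p" %in% names(cfg$fix),
                  fix_sigma_b2 = "sigma_b2" %in% names(cfg$fix),
                  fix_sigma_e2 = "sigma_e2" %in% names(cfg$fix),
                  fix_beta = "beta" %in% names(cfg$fix))
  init <- list(beta = state$beta, b = state$b, I = state$I,
               p = state$p, sigma_b2 = state$sigma_b2,
               sigma_e2 = state$sigma_e2)

  raw <- if (engine == "cpp") {
    .gibbs_chain_cpp(y, Xmat, W, unclass(priors), cfg_cpp, init)
  } else {
    .gibbs_chain_r(y, X, W, priors, cfg, state)
  }

  q <- ncol(Xmat)
  beta_draws <- raw$beta
  if (q > 0L) {
    beta_draws <- matrix(beta_draws, nrow = q)
    rownames(beta_draws) <- if (!is.null(colnames(Xmat))) colnames(Xmat)
                            else paste0("x", seq_len(q))
  } else beta_draws <- matrix(numeric(0), nrow = 0L, ncol = cfg$n_keep)
  structure(
    list(b = raw$b, I = raw$I, beta = beta_draws,
         p = as.numeric(raw$p), sigma_b2 = as.numeric(raw$sigma_b2),
         sigma_e2 = as.numeric(raw$sigma_e2),
         k_active = as.numeric(raw$k_active), var_g = as.numeric(raw$var_g),
         snps = snps, n_draws = cfg$n_keep,
         final_r = as.numeric(raw$final_r), final_state = raw$final_state,
         priors = priors, cfg = cfg, engine = engine),
    class = "hbm_posterior")
}

#' @export
print.hbm_posterior <- function(x, ...) {
  pve <- estimate_pve_hbm(x)
  cat(sprintf(paste0(
    "hbm_posterior: %d SNPs, %d retained draws (%s engine)\n",
    "  p        %.4f (sd %.4f)\n  sigma_b2 %.4f (sd %.4f)\n",
    "  sigma_e2 %.4f (sd %.4f)\n  PVE      %.3f (sd %.3f)\n"),
    length(x$snps), x$n_draws, x$engine,
    mean(x$p), stats::sd(x$p),
    mean(x$sigma_b2), stats::sd(x$sigma_b2),
    mean(x$sigma_e2), stats::sd(x$sigma_e2), pve$mean, pve$sd))
  invisible(x)
}

#' Posterior inclusion probabilities
#'
#' The PIP of SNP j is the fraction of retained draws in which its
#' indicator equals 1.
#'
#' @param samples An `hbm_posterior`.
#' @return Named numeric vector of PIPs in `[0, 1]`.
#' @export
compute_pip <- function(samples) {
  stopifnot(inherits(samples, "hbm_posterior"), samples$n_draws >= 1L)
  pip <- rowMeans(samples$I == 1L)
  names(pip) <- samples$snps
  pip
}

#' Select associated SNPs by PIP threshold
#'
#' @param samples An `hbm_posterior`.
#' @param threshold PIP cutoff in (0, 1]; SNPs with PIP >= threshold are
#'   selected. Default 0.5 (the median probability model).
#' @return Character vector of SNP IDs, sorted by decreasing PIP.
#' @export
select_association_snps <- function(samples, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  pip <- compute_pip(samples)
  sel <- pip[pip >= threshold]
  names(sel)[order(-sel)]
}

#' Posterior summary of the proportion of variance explained (PVE)
#'
#' For each retained draw t the genetic variance is taken as
#' `sigma_g2(t) = sigma_b2(t) * k(t)`, with `k(t)` the number of active
#' SNPs, and `PVE(t) = sigma_g2(t) / (sigma_g2(t) + sigma_e2(t))`.
#' `method = "empirical"` instead uses the per-draw empirical variance of
#' the genetic values `W b(t)` as the genetic variance.
#'
#' @param samples An `hbm_posterior`.
#' @param method `"slab"` (default) or `"empirical"`.
#' @return List with `mean`, `sd`, and the per-draw `draws`.
#' @export
estimate_pve_hbm <- function(samples, method = c("slab", "empirical")) {
  method <- match.arg(method)
  stopifnot(inherits(samples, "hbm_posterior"))
  sg2 <- if (method == "slab") samples$sigma_b2 * samples$k_active
         else samples$var_g
  draws <- ifelse(sg2 == 0, 0, sg2 / (sg2 + samples$sigma_e2))
  list(mean = mean(draws), sd = stats::sd(draws), draws = draws)
}
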