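# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is stored on disk.

write_tsv_fixture <- function(counts, samples = NULL, snps = NULL,
                              path = tempfile(fileext = ".tsv")) {
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(counts)))
  if (is.null(snps)) snps <- paste0("rs", seq_len(ncol(counts)))
  df <- data.frame(sample_id = samples, counts, check.names = FALSE)
  colnames(df) <- c("sample_id", snps)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_plink_raw_fixture <- function(counts, path = tempfile(fileext = ".raw")) {
  n <- nrow(counts)
  snps <- paste0("rs", seq_len(ncol(counts)), "_A")
  df <- data.frame(FID = paste0("F", 1:n), IID = paste0("I", 1:n),
                   PAT = 0, MAT = 0, SEX = 1, PHENOTYPE = -9,
                   counts, check.names = FALSE)
  colnames(df) <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE", snps)
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  path
}

# a small standardized design with controlled signal, for sampler tests
small_gwas <- function(n = 200, N = 60, k = 3, slab_var = 0.1, pve = 0.5,
                       seed = 1, spike_sd = 0) {
  cfg <- sim_config(n_samples = n, n_snps = N, mixture_p = k / N,
                    slab_var = slab_var, spike_sd = spike_sd,
                    target_pve = pve, seed = seed)
  simulate_gwas(cfg)
}

intercept_X <- function(n) matrix(1, n, 1L, dimnames = list(NULL, "intercept"))

# Exact posterior over all 2^N indicator configurations with the effects
# integrated out and (p, sigma_b2, sigma_e2) held fixed; the brute-force
# oracle for the collapsed Gibbs sampler.
enumerate_pips <- function(y, W, p, sigma_b2, sigma_e2) {
  n <- length(y); N <- ncol(W)
  configs <- as.matrix(expand.grid(rep(list(0:1), N)))
  logw <- apply(configs, 1L, function(g) {
    kk <- sum(g)
    V <- diag(sigma_e2, n)
    if (kk > 0) V <- V + sigma_b2 * tcrossprod(W[, g == 1, drop = FALSE])
    U <- chol(V)
    ll <- -sum(log(diag(U))) - 0.5 * sum(backsolve(U, y, transpose = TRUE)^2)
    ll + kk * log(p) + (N - kk) * log1p(-p)
  })
  w <- exp(logw - max(logw)); w <- w / sum(w)
  colSums(configs * w)
}
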