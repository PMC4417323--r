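#' Read a genotype matrix from a PLINK .raw or plain TSV file
#'
#' Parses additive-coded genotypes (minor-allele counts in \{0, 1, 2\}) into a
#' [`genotype_matrix`] object. Two dialects are supported: PLINK's
#' whitespace-delimited `.raw` export (six leading metadata columns
#' `FID IID PAT MAT SEX PHENOTYPE`, then one dosage column per SNP named
#' `rsID_allele`) and a generic TSV whose first column holds sample IDs and
#' whose remaining header names are SNP IDs.
#'
#' Missing genotypes may be encoded as `NA`, `-9`, `NA` strings, or empty
#' fields. Allele frequencies are recomputed from the non-missing counts
#' (`mean/2` per SNP), never taken from file metadata.
#'
#' @param path Path to the genotype file.
#' @param dialect Either `"plink_raw"` or `"tsv"`.
#' @return A `genotype_matrix`: a list with components
#'   \describe{
#'     \item{counts}{n x N integer matrix of allele counts, `NA` = missing;
#'       rownames are sample IDs, colnames are SNP IDs.}
#'     \item{samples}{character vector of sample IDs (row order preserved).}
#'     \item{snps}{character vector of SNP IDs (column order preserved).}
#'     \item{allele_freq}{per-SNP reference-allele frequency computed from
#'       non-missing entries; `NA` for all-missing SNPs.}
#'     \item{metadata}{data.frame of leading PLINK columns, if present.}
#'   }
#' @export
read_genotypes <- function(path, dialect = c("plink_raw", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, na.strings = c("NA", "-9", ""),
                          colClasses = "character", sep = "auto")
  if (nrow(dt) == 0L) stop("genotype file is empty: ", path)
  cn <- colnames(dt)
  metadata <- NULL
  if (dialect == "plink_raw") {
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(lead %in% cn[seq_len(6)])) {
      stop("plink_raw dialect expects leading columns ",
           paste(lead, collapse = " "))
    }
    metadata <- as.data.frame(dt[, lead, with = FALSE])
    samples <- as.character(dt[["IID"]])
    snp_cols <- setdiff(cn, lead)
    snps <- sub("_[ACGT0-9]+$", "", snp_cols)
  } else {
    samples <- as.character(dt[[1L]])
    snp_cols <- cn[-1L]
    snps <- snp_cols
  }
  if (anyDuplicated(snps)) {
    stop("duplicate SNP IDs in ", path, ": ",
         paste(unique(snps[duplicated(snps)]), collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample IDs in ", path)
  }
  counts <- matrix(NA_integer_, nrow = length(samples), ncol = length(snps),
                   dimnames = list(samples, snps))
  for (k in seq_along(snp_cols)) {
    v <- dt[[snp_cols[k]]]
    bad <- !is.na(v) & !v %in% c("0", "1", "2")
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("invalid genotype '%s' at sample '%s', SNP '%s' (row %d, column %s)",
                   v[i], samples[i], snps[k], i, snp_cols[k]))
    }
    counts[, k] <- as.integer(v)
  }
  new_genotype_matrix(counts, metadata = metadata)
}

#' Construct a genotype_matrix from an allele-count matrix
#'
#' @param counts n x N matrix of counts in \{0, 1, 2, NA\}; dimnames supply
#'   sample and SNP IDs (generated if absent).
#' @param metadata optional per-sample metadata data.frame.
#' @return A `genotype_matrix` object.
#' @export
new_genotype_matrix <- function(counts, metadata = NULL) {
  counts <- as.matrix(counts)
  ok <- is.na(counts) | counts == 0 | counts == 1 | counts == 2
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype value %s at row %d, column %d",
                 format(counts[idx[1L], idx[2L]]), idx[1L], idx[2L]))
  }
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("snp", seq_len(ncol(counts)))
  structure(
    list(counts = counts,
         samples = rownames(counts),
         snps = colnames(counts),
         allele_freq = colMeans(counts, na.rm = TRUE) / 2,
         metadata = metadata),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$counts), ncol(x$counts),
              100 * mean(is.na(x$counts))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Column-standardize a genotype matrix
#'
#' Produces the standardized design matrix W used by the hierarchical model
#' and the genomic relationship matrix: missing entries are imputed at the
#' column mean `2*p_i`, then column i is transformed as
#' `(x - 2*p_i) / sqrt(2*p_i*(1 - p_i))` with `p_i` the empirical
#' reference-allele frequency. The Hardy-Weinberg denominator
#' `2*p_i*(1 - p_i)` is the default; `scale = "empirical"` divides by the
#' empirical column standard deviation instead (the two agree asymptotically
#' under Hardy-Weinberg equilibrium).
#'
#' @param g A [`genotype_matrix`].
#' @param scale `"hwe"` (default) or `"empirical"`.
#' @return A `standardized_genotypes` object: list with `W` (n x N numeric
#'   matrix, no missing values, columns mean-centred), `allele_freq`,
#'   `scale`, and `n_imputed` (count of mean-imputed entries).
#' @export
standardize_genotypes <- function(g, scale = c("hwe", "empirical")) {
  scale <- match.arg(scale)
  stopifnot(inherits(g, "genotype_matrix"))
  p <- g$allele_freq
  mono <- is.na(p) | p <= 0 | p >= 1
  if (any(mono)) {
    stop("monomorphic or all-missing SNPs present (",
         paste(utils::head(g$snps[mono], 5L), collapse = ", "),
         if (sum(mono) > 5L) ", ..." else "",
         "); filter with filter_snps() before standardizing")
  }
  W <- g$counts
  storage.mode(W) <- "double"
  n_imputed <- sum(is.na(W))
  if (n_imputed > 0L) {
    miss <- which(is.na(W), arr.ind = TRUE)
    W[miss] <- 2 * p[miss[, 2L]]
  }
  W <- sweep(W, 2L, 2 * p, `-`)
  denom <- if (scale == "hwe") sqrt(2 * p * (1 - p)) else apply(W, 2L, stats::sd)
  W <- sweep(W, 2L, denom, `/`)
  structure(
    list(W = W, allele_freq = p, scale = scale, n_imputed = n_imputed,
         samples = g$samples, snps = g$snps),
    class = "standardized_genotypes")
}

#' Align genotype and phenotype tables on shared sample IDs
#'
#' Restricts both objects to the intersection of their sample IDs, in the
#' order the IDs appear in the genotype matrix (a canonical order shared by
#' both outputs regardless of the phenotype table's original order).
#'
#' @param g A [`genotype_matrix`].
#' @param ph A data.frame with a `sample_id` column, a phenotype column and
#'   optional covariate columns.
#' @return List with `genotypes`, `phenotypes` (both restricted and ordered
#'   identically) and `n_dropped` (samples dropped from each input).
#' @export
align_samples <- function(g, ph) {
  stopifnot(inherits(g, "genotype_matrix"), is.data.frame(ph))
  if (!"sample_id" %in% colnames(ph))
    stop("phenotype table must have a 'sample_id' column")
  ids <- intersect(g$samples, as.character(ph$sample_id))
  if (length(ids) == 0L) stop("no shared sample IDs between genotypes and phenotypes")
  keep <- g$samples[g$samples %in% ids]   # genotype order is canonical
  gi <- match(keep, g$samples)
  pidx <- match(keep, as.character(ph$sample_id))
  g2 <- new_genotype_matrix(g$counts[gi, , drop = FALSE],
                            metadata = if (!is.null(g$metadata)) g$metadata[gi, , drop = FALSE])
  list(genotypes = g2,
       phenotypes = ph[pidx, , drop = FALSE],
       n_dropped = c(genotypes = length(g$samples) - length(keep),
                     phenotypes = nrow(ph) - length(keep)))
}

#' Write genotypes to a TSV file (first column sample_id)
#'
#' Inverse of `read_genotypes(..., dialect = "tsv")`.
#'
#' @param g A [`genotype_matrix`].
#' @param path Output path.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  dt <- data.table::data.table(sample_id = g$samples)
  dt <- cbind(dt, data.table::as.data.table(g$counts))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Write per-SNP and scalar posterior summaries to TSV reports
#'
#' Writes two files: `<prefix>_snps.tsv` with one row per SNP (SNP ID,
#' posterior inclusion probability, posterior-mean effect on the phenotype
#' scale per standardized allele dose) and `<prefix>_params.tsv` with the
#' posterior mean and s.d. of the mixture probability p, the slab variance,
#' the residual variance, each fixed effect, and the PVE.
#'
#' @param samples An `hbm_posterior` object from [run_gibbs()].
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths written.
#' @export
write_posterior_report <- function(samples, prefix) {
  stopifnot(inherits(samples, "hbm_posterior"))
  if (samples$n_draws < 1L) stop("posterior sample is empty")
  snp_tab <- data.table::data.table(
    snp = samples$snps,
    pip = compute_pip(samples),
    effect_mean = rowMeans(samples$b))
  pve <- estimate_pve_hbm(samples)
  beta_mean <- rowMeans(samples$beta)
  beta_sd <- apply(samples$beta, 1L, stats::sd)
  par_tab <- data.table::data.table(
    parameter = c("p", "sigma_b2", "sigma_e2",
                  paste0("beta_", rownames(samples$beta)),
                  "pve"),
    mean = c(mean(samples$p), mean(samples$sigma_b2), mean(samples$sigma_e2),
             beta_mean, pve$mean),
    sd = c(stats::sd(samples$p), stats::sd(samples$sigma_b2),
           stats::sd(samples$sigma_e2), beta_sd, pve$sd))
  paths <- paste0(prefix, c("_snps.tsv", "_params.tsv"))
  data.table::fwrite(snp_tab, paths[1L], sep = "\t", quote = FALSE)
  data.table::fwrite(par_tab, paths[2L], sep = "\t", quote = FALSE)
  invisible(paths)
}
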