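#' Remove samples with too many missing genotypes
#'
#' Drops every sample whose fraction of missing genotype calls is greater
#' than or equal to `max_missing` (the threshold is inclusive: a sample at
#' exactly 5\% missingness is removed at the default). Surviving samples
#' keep their original order.
#'
#' @param g A [`genotype_matrix`].
#' @param max_missing Maximum tolerated missing fraction, in (0, 1).
#'   Default 0.05.
#' @return List with the filtered `genotypes` and a `report` (class
#'   `qc_report`) recording counts and the threshold.
#' @export
filter_sample_missingness <- function(g, max_missing = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"),
            max_missing > 0, max_missing < 1)
  miss <- rowMeans(is.na(g$counts))
  keep <- miss < max_missing
  if (!any(keep)) stop("all samples removed by missingness filter")
  g2 <- new_genotype_matrix(g$counts[keep, , drop = FALSE],
                            metadata = if (!is.null(g$metadata)) g$metadata[keep, , drop = FALSE])
  report <- structure(
    list(filter = "sample_missingness", threshold = max_missing,
         n_input = length(keep), n_removed = sum(!keep), n_retained = sum(keep),
         removed_ids = g$samples[!keep]),
    class = "qc_report")
  list(genotypes = g2, report = report)
}

#' Remove SNPs with low call rate or low minor allele frequency
#'
#' Drops every SNP whose call rate is less than or equal to `min_call_rate`
#' or whose minor allele frequency is less than or equal to `min_maf`
#' (both thresholds inclusive, so a SNP at exactly MAF 0.01 is removed at
#' the default). The MAF is `min(p, 1 - p)` with `p` the empirical
#' reference-allele frequency over non-missing calls; this also removes
#' monomorphic SNPs.
#'
#' @param g A [`genotype_matrix`].
#' @param min_call_rate Call-rate threshold in (0, 1). Default 0.99.
#' @param min_maf MAF threshold in (0, 1). Default 0.01.
#' @return List with filtered `genotypes` and a `qc_report`.
#' @export
filter_snps <- function(g, min_call_rate = 0.99, min_maf = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"),
            min_call_rate > 0, min_call_rate < 1,
            min_maf > 0, min_maf < 1)
  call_rate <- colMeans(!is.na(g$counts))
  p <- g$allele_freq
  maf <- pmin(p, 1 - p)
  maf[is.na(maf)] <- 0   # all-missing SNP: treat as monomorphic
  keep <- call_rate > min_call_rate & maf > min_maf
  if (!any(keep)) stop("all SNPs removed by call-rate/MAF filter")
  g2 <- new_genotype_matrix(g$counts[, keep, drop = FALSE],
                            metadata = g$metadata)
  report <- structure(
    list(filter = "snp_callrate_maf",
         threshold = c(min_call_rate = min_call_rate, min_maf = min_maf),
         n_input = length(keep), n_removed = sum(!keep), n_retained = sum(keep),
         removed_ids = g$snps[!keep]),
    class = "qc_report")
  list(genotypes = g2, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report [%s]: %d in, %d removed, %d retained\n",
              x$filter, x$n_input, x$n_removed, x$n_retained))
  invisible(x)
}

#' Compute the genomic relationship matrix (GRM)
#'
#' The relationship between individuals j and k is the average over SNPs of
#' `(x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`, i.e. `A = W W' / N`
#' on the column-standardized, mean-imputed genotype matrix. Allele
#' frequencies are recomputed from the current (post-filter) samples.
#'
#' @param g A [`genotype_matrix`] (monomorphic SNPs must be filtered first)
#'   or a [`standardized_genotypes`] object.
#' @return A `grm` object: list with the n x n symmetric matrix `A`
#'   (dimnames = sample IDs) and `n_snps_used`.
#' @export
compute_grm <- function(g) {
  if (inherits(g, "genotype_matrix")) {
    if (ncol(g$counts) < 2L) stop("need at least 2 SNPs to compute a GRM")
    g <- standardize_genotypes(g)
  }
  stopifnot(inherits(g, "standardized_genotypes"))
  N <- ncol(g$W)
  A <- tcrossprod(g$W) / N
  dimnames(A) <- list(g$samples, g$samples)
  structure(list(A = A, n_snps_used = N, samples = g$samples), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d samples, %d SNPs averaged\n",
              nrow(x$A), x$n_snps_used))
  invisible(x)
}

#' Greedily prune related samples from a GRM
#'
#' While any off-diagonal relationship exceeds `threshold` (strictly), one
#' member of the currently worst (largest-relationship) pair is removed:
#' the member with the larger number of above-threshold partners, so that
#' few removals clean many pairs; ties go to the smaller index. The
#' returned set contains no pair above the threshold.
#'
#' @param A A `grm` object or a symmetric relationship matrix.
#' @param threshold Relationship cutoff; pairs strictly above it are broken.
#'   Default 0.025.
#' @return Integer vector of retained sample indices (ascending). If `A`
#'   has sample names they are attached as names.
#' @export
prune_related <- function(A, threshold = 0.025) {
  M <- if (inherits(A, "grm")) A$A else as.matrix(A)
  stopifnot(isSymmetric(unname(M), tol = 1e-8))
  n <- nrow(M)
  alive <- rep(TRUE, n)
  V <- M
  diag(V) <- -Inf
  repeat {
    Vsub <- V[alive, alive, drop = FALSE]
    if (all(Vsub <= threshold)) break
    idx_alive <- which(alive)
    deg <- rowSums(Vsub > threshold)
    worst <- which(Vsub == max(Vsub), arr.ind = TRUE)[1L, ]
    cand <- idx_alive[c(worst[["row"]], worst[["col"]])]
    cand_deg <- deg[c(worst[["row"]], worst[["col"]])]
    # remove the member with more violating partners; tie -> smaller index
    drop_local <- if (cand_deg[1L] > cand_deg[2L]) 1L
      else if (cand_deg[2L] > cand_deg[1L]) 2L
      else which.min(cand)
    alive[cand[drop_local]] <- FALSE
  }
  kept <- which(alive)
  if (!is.null(rownames(M))) names(kept) <- rownames(M)[kept]
  kept
}

#' Write a GRM as a plain TSV matrix (sample IDs as header and first column)
#'
#' @param grm A `grm` object.
#' @param path Output path.
#' @export
write_grm <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  dt <- data.table::data.table(sample_id = grm$samples)
  dt <- cbind(dt, data.table::as.data.table(grm$A))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
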