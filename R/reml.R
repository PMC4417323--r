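#' Fit the mixed linear model y ~ N(X beta, A sigma_g2 + I sigma_e2) by REML
#'
#' Average-information REML with EM fallback, the all-SNPs-causal baseline
#' (the p = 1 special case of the hierarchical model). The genomic
#' relationship matrix is eigendecomposed once, after which every iteration
#' works in the rotated basis where the covariance is diagonal. The first
#' step is an EM update; subsequent steps use the average-information
#' (AI) direction, falling back to EM whenever an AI step would leave the
#' parameter space or decrease the restricted likelihood. Variances are
#' clamped at a small positive boundary rather than reparameterized.
#'
#' @param y Phenotype vector (length n).
#' @param X Fixed-effect design (n x q, full rank). An intercept column is
#'   not added automatically.
#' @param A A `grm` object or n x n symmetric relationship matrix.
#' @param tol Convergence tolerance on the change in restricted
#'   log-likelihood. Default 1e-8.
#' @param max_iter Maximum iterations. Default 100.
#' @return A `reml_fit`: list with `sigma_g2`, `sigma_e2`, `beta`,
#'   `se` (delta-ready standard errors of the two variances, from the
#'   inverse AI matrix), `beta_se`, `AI` (2 x 2 average-information matrix
#'   at the optimum), `loglik` (restricted log-likelihood), `loglik_trace`,
#'   `converged`, `n`, `n_snps` (SNPs behind the GRM if known, else `NA`),
#'   and the eigendecomposition reused by [blup_snp_effects()].
#' @export
fit_mlm_reml <- function(y, X, A, tol = 1e-8, max_iter = 100L) {
  n_snps <- NA_integer_
  if (inherits(A, "grm")) { n_snps <- A$n_snps_used; A <- A$A }
  A <- as.matrix(A)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(A) == n, isSymmetric(unname(A), tol = 1e-6))
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient")
  q <- ncol(X)

  eig <- eigen(A, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  yt <- drop(crossprod(eig$vectors, y))
  Xt <- crossprod(eig$vectors, X)

  vary <- stats::var(y)
  bound <- 1e-8 * vary
  theta <- c(sigma_g2 = vary / 2, sigma_e2 = vary / 2)

  # Restricted log-likelihood and the P-operator pieces in the eigenbasis.
  reml_parts <- function(theta) {
    v <- theta[1L] * d + theta[2L]
    if (any(v <= 0)) return(NULL)
    XtVX <- crossprod(Xt, Xt / v)
    C <- solve(XtVX)
    Vy <- yt / v
    betahat <- drop(C %*% crossprod(Xt, Vy))
    Py <- Vy - (Xt %*% (C %*% crossprod(Xt, Vy))) / v
    Py <- drop(Py)
    ll <- -0.5 * (sum(log(v)) + determinant(XtVX, logarithm = TRUE)$modulus +
                    sum(yt * Py))
    Pmul <- function(x) {            # apply P to a vector in the eigenbasis
      Vx <- x / v
      drop(Vx - (Xt %*% (C %*% crossprod(Xt, Vx))) / v)
    }
    trPA <- sum(d / v) - sum((crossprod(Xt, (d / v^2) * Xt)) * C)
    trP  <- sum(1 / v) - sum((crossprod(Xt, Xt / v^2)) * C)
    list(v = v, C = C, beta = betahat, Py = Py, ll = as.numeric(ll),
         Pmul = Pmul, trPA = trPA, trP = trP)
  }

  parts <- reml_parts(theta)
  trace <- parts$ll
  converged <- FALSE
  AI <- NULL
  for (iter in seq_len(max_iter)) {
    Py <- parts$Py
    APy <- d * Py
    PAPy <- parts$Pmul(APy)
    PPy <- parts$Pmul(Py)
    score <- -0.5 * c(parts$trPA - sum(Py * APy),
                      parts$trP - sum(Py * Py))
    AI <- 0.5 * matrix(c(sum(APy * PAPy), sum(APy * PPy),
                         sum(APy * PPy), sum(Py * PPy)), 2L, 2L)
    step_ok <- FALSE
    if (iter > 1L && all(is.finite(AI)) && det(AI) > 1e-12) {
      cand <- theta + drop(solve(AI, score))
      cand <- pmax(cand, bound)
      cand_parts <- reml_parts(cand)
      if (!is.null(cand_parts) && cand_parts$ll >= parts$ll - 1e-10) {
        step_ok <- TRUE
      }
    }
    if (!step_ok) {
      # EM step: guaranteed ascent direction for each variance component
      cand <- c(theta[1L] + theta[1L]^2 * (sum(Py * APy) - parts$trPA) / n,
                theta[2L] + theta[2L]^2 * (sum(Py * Py) - parts$trP) / n)
      cand <- pmax(cand, bound)
      cand_parts <- reml_parts(cand)
      if (is.null(cand_parts)) break
    }
    delta_ll <- cand_parts$ll - parts$ll
    theta <- cand
    parts <- cand_parts
    trace <- c(trace, parts$ll)
    if (abs(delta_ll) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("REML did not converge in ", max_iter, " iterations")

  se <- rep(NA_real_, 2L)
  ai_ok <- all(is.finite(AI)) && det(AI) > 1e-12
  if (ai_ok) se <- sqrt(diag(solve(AI)))
  near_singular <- !ai_ok || kappa(AI) > 1e8

  beta_se <- sqrt(diag(parts$C))
  structure(
    list(sigma_g2 = unname(theta[1L]), sigma_e2 = unname(theta[2L]),
         beta = parts$beta, beta_se = beta_se,
         se = c(sigma_g2 = se[1L], sigma_e2 = se[2L]),
         AI = AI, near_singular = near_singular,
         loglik = parts$ll, loglik_trace = trace, converged = converged,
         n = n, n_snps = n_snps,
         eigen = list(vectors = eig$vectors, values = d)),
    class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(paste0("reml_fit: n = %d%s\n",
                     "  sigma_g2 %.4f (se %.4f)\n  sigma_e2 %.4f (se %.4f)\n",
                     "  converged: %s%s\n"),
              x$n,
              if (!is.na(x$n_snps)) sprintf(", GRM over %d SNPs", x$n_snps) else "",
              x$sigma_g2, x$se[1L], x$sigma_e2, x$se[2L],
              x$converged,
              if (x$near_singular) " (information matrix near-singular)" else ""))
  invisible(x)
}

#' PVE from a REML fit, with a delta-method standard error
#'
#' `PVE = sigma_g2 / (sigma_g2 + sigma_e2)`; the standard error propagates
#' the inverse average-information matrix through the ratio.
#'
#' @param fit A `reml_fit`.
#' @return List with `pve` and `se`.
#' @export
estimate_pve_mlm <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  sg <- fit$sigma_g2; se2 <- fit$sigma_e2
  tot <- sg + se2
  if (tot <= 0) stop("both variance components at the boundary; PVE undefined")
  pve <- sg / tot
  se <- NA_real_
  if (all(is.finite(fit$AI)) && det(fit$AI) > 1e-12) {
    grad <- c(se2, -sg) / tot^2
    se <- sqrt(drop(t(grad) %*% solve(fit$AI) %*% grad))
  }
  list(pve = pve, se = se)
}

#' BLUP per-SNP effects from a REML fit
#'
#' Backsolves the best linear unbiased predictions of the SNP effects from
#' the individual-level genetic values:
#' `b_hat = (sigma_g2 / N) W' V^{-1} (y - X beta_hat)` with
#' `V = A sigma_g2 + I sigma_e2`. The per-SNP variance implied by the MLM
#' is `sigma_g2 / N`, i.e. the genetic variance diluted over all SNPs.
#'
#' @param fit A `reml_fit` (from a GRM computed over the columns of `W`).
#' @param W Standardized genotype matrix (n x N) or
#'   [`standardized_genotypes`].
#' @param y,X The data the model was fitted to.
#' @return Named numeric vector of per-SNP BLUP effects.
#' @export
blup_snp_effects <- function(fit, W, y, X) {
  stopifnot(inherits(fit, "reml_fit"))
  snps <- colnames(W)
  if (inherits(W, "standardized_genotypes")) { snps <- W$snps; W <- W$W }
  N <- ncol(W)
  v <- fit$sigma_g2 * fit$eigen$values + fit$sigma_e2
  res <- y - drop(as.matrix(X) %*% fit$beta)
  rt <- drop(crossprod(fit$eigen$vectors, res))
  Vinv_res <- drop(fit$eigen$vectors %*% (rt / v))
  bhat <- (fit$sigma_g2 / N) * drop(crossprod(W, Vinv_res))
  names(bhat) <- if (!is.null(snps)) snps else paste0("snp", seq_len(N))
  bhat
}
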