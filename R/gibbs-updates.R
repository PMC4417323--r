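# Pure-R full-conditional updates. These are the reference implementation of
# each Gibbs step; the compiled engine in src/gibbs.cpp performs the same
# updates. The R engine is used on small problems and in tests.
#
# A sampler `state` is a list(beta, b, I, p, sigma_b2, sigma_e2, r) with the
# residual cache r = y - X beta - W b. The `data` list carries y, X, W and
# the precomputed column squared norms wtw.

.make_gibbs_data <- function(y, X, W) {
  list(y = y, X = X, W = W, wtw = colSums(W^2),
       n = length(y), N = ncol(W))
}

#' Update one SNP's indicator and effect from their full conditionals
#'
#' The indicator `I_j` is drawn with the effect integrated out: the
#' posterior odds are the prior odds `p/(1-p)` times the ratio of marginal
#' likelihoods of the partial residual under the slab versus the spike,
#' computed in log space. Given `I_j = 1`, `b_j` is drawn from its normal
#' full conditional `N(z/d, 1/d)` with `d = w_j'w_j/sigma_e2 + 1/sigma_b2`
#' and `z = w_j' r_{-j} / sigma_e2`; given `I_j = 0` it is set to zero
#' (point-mass spike) or drawn from the analogous small-variance
#' conditional when `spike_sd > 0`. The residual cache is updated
#' incrementally in O(n).
#'
#' @param j SNP index.
#' @param state Sampler state list (see [run_gibbs()] internals).
#' @param data List with `y`, `X`, `W`, `wtw` from the fitting problem.
#' @param priors An [hbm_priors()] object.
#' @return The updated state.
#' @keywords internal
#' @export
sample_indicator_and_effect <- function(j, state, data, priors) {
  w <- data$W[, j]
  if (state$b[j] != 0) state$r <- state$r + w * state$b[j]
  z <- sum(w * state$r) / state$sigma_e2
  d1 <- data$wtw[j] / state$sigma_e2 + 1 / state$sigma_b2
  lm1 <- -0.5 * log(state$sigma_b2 * d1) + 0.5 * z^2 / d1
  spike_var <- priors$spike_sd^2
  if (spike_var > 0) {
    d0 <- data$wtw[j] / state$sigma_e2 + 1 / spike_var
    lm0 <- -0.5 * log(spike_var * d0) + 0.5 * z^2 / d0
  } else lm0 <- 0
  logit <- log(state$p) - log1p(-state$p) + lm1 - lm0
  prob1 <- if (logit > 0) 1 / (1 + exp(-logit)) else exp(logit) / (1 + exp(logit))
  active <- stats::runif(1) < prob1
  bnew <- 0
  if (active) {
    bnew <- z / d1 + stats::rnorm(1) / sqrt(d1)
    state$I[j] <- 1L
  } else {
    state$I[j] <- 0L
    if (spike_var > 0) bnew <- z / d0 + stats::rnorm(1) / sqrt(d0)
  }
  if (bnew != 0) state$r <- state$r - w * bnew
  state$b[j] <- bnew
  state
}

#' Update the fixed effects from their normal full conditional
#'
#' Given the SNP effects, `beta` has the conjugate normal full conditional
#' with precision `X'X/sigma_e2 + I/sigma_a^2` (prior sd `sigma_a` per
#' coefficient) and mean the correspondingly ridge-shrunk least-squares
#' solution on `y - W b`.
#'
#' @inheritParams sample_indicator_and_effect
#' @return The updated state.
#' @keywords internal
#' @export
sample_fixed_effects <- function(state, data, priors) {
  X <- data$X
  if (is.null(X) || ncol(X) == 0L) return(state)
  rb <- state$r + drop(X %*% state$beta)    # y - W b
  P <- crossprod(X) / state$sigma_e2
  diag(P) <- diag(P) + 1 / priors$beta_sd^2
  m <- solve(P, crossprod(X, rb) / state$sigma_e2)
  U <- chol(P)
  beta_new <- drop(m + backsolve(U, stats::rnorm(ncol(X))))
  state$beta <- beta_new
  state$r <- rb - drop(X %*% beta_new)
  state
}

#' Update the slab and residual variances from their Inverse-Gamma full
#' conditionals
#'
#' `sigma_b2 ~ IG(a1 + k/2, b1 + sum_{I_j=1} b_j^2 / 2)` over the `k`
#' active effects (when `k = 0` this is a draw from the prior), and
#' `sigma_e2 ~ IG(a2 + n/2, b2 + ||r||^2 / 2)`. Draws are clamped to
#' `[1e-12, 1e12]` to keep the chain numerically finite under the very
#' diffuse default prior.
#'
#' @inheritParams sample_indicator_and_effect
#' @return The updated state.
#' @keywords internal
#' @export
sample_variances <- function(state, priors) {
  act <- state$I == 1L
  k <- sum(act)
  ssb <- sum(state$b[act]^2)
  state$sigma_b2 <- .rinvgamma(priors$a1 + k / 2, priors$b1 + ssb / 2)
  state$sigma_e2 <- .rinvgamma(priors$a2 + length(state$r) / 2,
                               priors$b2 + sum(state$r^2) / 2)
  state
}

.rinvgamma <- function(shape, rate) {
  v <- 1 / stats::rgamma(1, shape = shape, rate = rate)
  min(max(v, 1e-12), 1e12)
}

#' Update the mixture probability from its Beta full conditional
#'
#' `p ~ Beta(alpha + k, beta + N - k)` with `k` the number of active
#' indicators.
#'
#' @inheritParams sample_indicator_and_effect
#' @return The updated state.
#' @keywords internal
#' @export
sample_mixture_probability <- function(state, priors) {
  k <- sum(state$I == 1L)
  N <- length(state$I)
  p <- stats::rbeta(1, priors$p_alpha + k, priors$p_beta + N - k)
  state$p <- min(max(p, 1e-12), 1 - 1e-12)
  state
}

#' Posterior moments of the active-effect block
#'
#' The joint full conditional of the active effects `b_A` is
#' `N(Sigma W_A' rstar / sigma_e2, Sigma)` with
#' `Sigma = (W_A'W_A/sigma_e2 + I/sigma_b2)^{-1}`. The `"direct"` route
#' inverts the k x k precision; the `"woodbury"` route applies the
#' Sherman-Morrison-Woodbury identity so the factorized matrix has rank n,
#' which is cheaper when the active set is larger than the sample size.
#'
#' @param WA n x k matrix of active standardized genotype columns.
#' @param rstar Residual excluding the active genetic values (`y - X beta`
#'   for a full refresh).
#' @param sigma_e2,sigma_b2 Current variance values.
#' @param method `"direct"` or `"woodbury"`.
#' @return List with `mean` (length k) and `cov` (k x k).
#' @keywords internal
#' @export
active_block_moments <- function(WA, rstar, sigma_e2, sigma_b2,
                                 method = c("direct", "woodbury")) {
  method <- match.arg(method)
  k <- ncol(WA)
  if (method == "direct") {
    P <- crossprod(WA) / sigma_e2
    diag(P) <- diag(P) + 1 / sigma_b2
    Sigma <- chol2inv(chol(P))
    list(mean = drop(Sigma %*% crossprod(WA, rstar)) / sigma_e2, cov = Sigma)
  } else {
    n <- nrow(WA)
    M <- tcrossprod(WA) * (sigma_b2 / sigma_e2)
    diag(M) <- diag(M) + 1
    Minv_W <- solve(M, WA)
    Sigma <- diag(sigma_b2, k) -
      (sigma_b2^2 / sigma_e2) * crossprod(WA, Minv_W)
    mean <- (sigma_b2 / sigma_e2) * drop(crossprod(WA, solve(M, rstar)))
    list(mean = mean, cov = Sigma)
  }
}

#' Jointly re-draw all active SNP effects
#'
#' Draws the active block `b_A` from its joint normal full conditional.
#' When `k <= n` (or `method = "direct"`) this uses a Cholesky factor of
#' the k x k precision; otherwise the rank-n Woodbury route of
#' Bhattacharya, Chakraborty and Mallick (2016) is used, which never forms
#' a k x k factor. Offered as an optional refresh step after the
#' component-wise scan (`chain_config(block_refresh = TRUE)`).
#'
#' @inheritParams sample_indicator_and_effect
#' @param method `"auto"` (Woodbury when k > n), `"direct"`, or
#'   `"woodbury"`.
#' @return The updated state (residual cache refreshed).
#' @keywords internal
#' @export
sample_active_block <- function(state, data, priors,
                                method = c("auto", "direct", "woodbury")) {
  method <- match.arg(method)
  act <- which(state$I == 1L)
  k <- length(act)
  if (k == 0L) return(state)
  WA <- data$W[, act, drop = FALSE]
  rstar <- state$r + drop(WA %*% state$b[act])   # y - X beta - W_inactive b
  n <- length(rstar)
  if (method == "auto") method <- if (k > n) "woodbury" else "direct"
  if (method == "direct") {
    P <- crossprod(WA) / state$sigma_e2
    diag(P) <- diag(P) + 1 / state$sigma_b2
    U <- tryCatch(chol(P), error = function(e) {
      diag(P) <- diag(P) + 1e-8
      chol(P)
    })
    m <- drop(chol2inv(U) %*% crossprod(WA, rstar)) / state$sigma_e2
    bA <- m + backsolve(U, stats::rnorm(k))
  } else {
    u <- stats::rnorm(k, sd = sqrt(state$sigma_b2))
    delta <- stats::rnorm(n)
    se <- sqrt(state$sigma_e2)
    M <- tcrossprod(WA) * (state$sigma_b2 / state$sigma_e2)
    diag(M) <- diag(M) + 1
    v <- drop(WA %*% u) / se + delta
    w <- solve(M, rstar / se - v)
    bA <- u + (state$sigma_b2 / se) * drop(crossprod(WA, w))
  }
  state$b[act] <- bA
  state$r <- rstar - drop(WA %*% bA)
  state
}

# Pure-R chain driver mirroring the compiled engine.
.gibbs_chain_r <- function(y, X, W, priors, cfg, state) {
  data <- .make_gibbs_data(y, X, W)
  n <- data$n; N <- data$N
  q <- if (is.null(X)) 0L else ncol(X)
  total <- cfg$n_burnin + cfg$n_keep * cfg$thinning
  keep <- list(b = matrix(0, N, cfg$n_keep), I = matrix(0L, N, cfg$n_keep),
               beta = matrix(0, max(q, 1L), cfg$n_keep),
               p = numeric(cfg$n_keep), sigma_b2 = numeric(cfg$n_keep),
               sigma_e2 = numeric(cfg$n_keep), k_active = numeric(cfg$n_keep),
               var_g = numeric(cfg$n_keep))
  stored <- 0L
  fixed <- names(cfg$fix)
  for (it in seq_len(total)) {
    ord <- if (cfg$scan_order == "random") sample.int(N) else seq_len(N)
    for (j in ord) state <- sample_indicator_and_effect(j, state, data, priors)
    if (cfg$block_refresh) state <- sample_active_block(state, data, priors)
    if (!"beta" %in% fixed) state <- sample_fixed_effects(state, data, priors)
    st <- sample_variances(state, priors)
    if (!"sigma_b2" %in% fixed) state$sigma_b2 <- st$sigma_b2
    if (!"sigma_e2" %in% fixed) state$sigma_e2 <- st$sigma_e2
    if (!"p" %in% fixed) state <- sample_mixture_probability(state, priors)
    if (it > cfg$n_burnin && (it - cfg$n_burnin - 1L) %% cfg$thinning == 0L &&
        stored < cfg$n_keep) {
      stored <- stored + 1L
      keep$b[, stored] <- state$b
      keep$I[, stored] <- state$I
      if (q > 0L) keep$beta[, stored] <- state$beta
      keep$p[stored] <- state$p
      keep$sigma_b2[stored] <- state$sigma_b2
      keep$sigma_e2[stored] <- state$sigma_e2
      keep$k_active[stored] <- sum(state$I == 1L)
      g <- y - state$r - (if (q > 0L) drop(X %*% state$beta) else 0)
      keep$var_g[stored] <- stats::var(g)
    }
  }
  c(keep, list(final_r = state$r,
               final_state = state[c("beta", "b", "I", "p",
                                     "sigma_b2", "sigma_e2")]))
}
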