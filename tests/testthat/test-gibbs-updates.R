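# Unit tests for the conjugate full-conditional updates, against closed
# forms and Monte-Carlo standard errors.

make_state <- function(y, X, W, b = NULL, beta = NULL, p = 0.1,
                       sigma_b2 = 0.25, sigma_e2 = 1) {
  N <- ncol(W)
  if (is.null(b)) b <- numeric(N)
  q <- if (is.null(X)) 0L else ncol(X)
  if (is.null(beta)) beta <- numeric(q)
  r <- y - (if (q > 0) drop(X %*% beta) else 0) - drop(W %*% b)
  list(beta = beta, b = b, I = as.integer(b != 0), p = p,
       sigma_b2 = sigma_b2, sigma_e2 = sigma_e2, r = r)
}

test_that("mixture probability update is Beta(alpha + k, beta + N - k)", {
  pr <- hbm_priors()
  st <- list(I = c(rep(1L, 100), rep(0L, 9900)))
  set.seed(1)
  draws <- replicate(1e5, sample_mixture_probability(st, pr)$p)
  m <- (1 + 100) / (2 + 10000)            # Beta(101, 9901) mean ~ 0.0102
  v <- m * (1 - m) / (2 + 10000 + 1)
  expect_equal(mean(draws), m, tolerance = 3 * sqrt(v / 1e5) / m)
  # all-zero indicators -> Beta(1, N + 1)
  st0 <- list(I = rep(0L, 50))
  set.seed(2)
  d0 <- replicate(2e4, sample_mixture_probability(st0, pr)$p)
  expect_equal(mean(d0), 1 / 52, tolerance = 0.05)
})

test_that("variance updates follow their Inverse-Gamma full conditionals", {
  # k = 2 active effects (1, -1): sigma_b2 ~ IG(a1 + 1, b1 + 1)
  n <- 4
  W <- diag(1, n, 3)
  y <- rep(0, n)
  st <- make_state(y, NULL, W, b = c(1, -1, 0))
  st$I <- c(1L, 1L, 0L)
  pr <- hbm_priors(a1 = 3, b1 = 4, a2 = 3, b2 = 4)
  set.seed(3)
  sb <- replicate(2e4, sample_variances(st, pr)$sigma_b2)
  # IG(3 + 1, 4 + 1) has mean 5/3
  expect_equal(mean(sb), 5 / 3, tolerance = 3 * sqrt(var(sb) / 2e4) / (5 / 3))
  # zero residual: sigma_e2 ~ IG(a2 + n/2, b2), mean 4 / (3 + 2 - 1)
  st$r <- rep(0, n)
  set.seed(4)
  se <- replicate(2e4, sample_variances(st, pr)$sigma_e2)
  expect_equal(mean(se), 4 / (3 + n / 2 - 1),
               tolerance = 3 * sqrt(var(se) / 2e4))
  # long-run mean of IG(3, 4) draws matches b/(a-1) = 2 (prior draw at k = 0)
  st$I <- rep(0L, 3); st$b <- rep(0, 3)
  set.seed(5)
  prior_draws <- replicate(4e4, sample_variances(st, pr)$sigma_b2)
  expect_equal(mean(prior_draws), 2, tolerance = 3 * sqrt(var(prior_draws) / 4e4))
})

test_that("fixed-effect update matches the conjugate normal closed form", {
  set.seed(6)
  n <- 80
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(2, -1)) + rnorm(n)
  W <- matrix(0, n, 1); W[1, 1] <- 1e-12   # no genetic signal
  pr <- hbm_priors(beta_sd = 1e5)
  st <- make_state(y, X, W, sigma_e2 = 1)
  data <- hbmgwas:::.make_gibbs_data(y, X, W)
  draws <- replicate(2e4, sample_fixed_effects(st, data, pr)$beta)
  P <- crossprod(X) / 1 + diag(1e-10, 2)
  m <- solve(P, crossprod(X, y))
  expect_equal(rowMeans(draws), drop(m),
               tolerance = 3 * max(sqrt(diag(solve(P)) / 2e4)))
  emp_cov <- cov(t(draws))
  expect_equal(emp_cov, solve(P), tolerance = 0.1)
  # intercept-only, huge prior sd: posterior mean -> ybar
  X1 <- matrix(1, n, 1)
  st1 <- make_state(y, X1, W, sigma_e2 = 1)
  data1 <- hbmgwas:::.make_gibbs_data(y, X1, W)
  d1 <- replicate(2e4, sample_fixed_effects(st1, data1, pr)$beta)
  expect_equal(mean(d1), mean(y), tolerance = 3 / sqrt(n * 2e4) * 10)
  # tiny prior sd pins beta at 0
  st0 <- make_state(y, X1, W, sigma_e2 = 1)
  pr0 <- hbm_priors(beta_sd = 1e-8)
  expect_lt(abs(sample_fixed_effects(st0, data1, pr0)$beta), 1e-6)
})

test_that("indicator update reduces to the prior odds when the SNP carries no evidence", {
  set.seed(7)
  n <- 400
  W <- matrix(rnorm(n), n, 1); W <- scale(W)[, , drop = FALSE]
  y <- rnorm(n)
  r_orth <- y - W[, 1] * sum(W[, 1] * y) / sum(W[, 1]^2)  # orthogonal residual
  pr <- hbm_priors()
  p0 <- 0.3
  # with z = 0 the log marginal ratio is -0.5 log(sigma_b2 d1); choose
  # sigma_b2 tiny so the penalty vanishes and P(I=1) -> p0
  st <- make_state(r_orth, NULL, W, p = p0, sigma_b2 = 1e-12, sigma_e2 = 1)
  st$r <- r_orth
  data <- hbmgwas:::.make_gibbs_data(r_orth, NULL, W)
  draws <- replicate(2e4, sample_indicator_and_effect(1, st, data, pr)$I[1])
  expect_equal(mean(draws), p0, tolerance = 3 * sqrt(p0 * (1 - p0) / 2e4))
})

test_that("slab variance -> 0 degenerates to I ~ Bernoulli(p) with b ~ 0", {
  set.seed(8)
  n <- 100
  W <- scale(matrix(rnorm(n), n, 1))[, , drop = FALSE]
  y <- rnorm(n) + W[, 1]
  pr <- hbm_priors()
  st <- make_state(y, NULL, W, p = 0.25, sigma_b2 = 1e-14, sigma_e2 = 1)
  data <- hbmgwas:::.make_gibbs_data(y, NULL, W)
  out <- replicate(1e4, {
    s <- sample_indicator_and_effect(1, st, data, pr)
    c(s$I[1], s$b[1])
  })
  expect_lt(abs(mean(out[1, ]) - 0.25), 0.02)
  expect_lt(max(abs(out[2, ])), 1e-5)
})

test_that("active-block moments agree between direct and Woodbury routes", {
  set.seed(9)
  n <- 200; k <- 50
  WA <- matrix(rnorm(n * k), n, k)
  rstar <- rnorm(n)
  d <- active_block_moments(WA, rstar, sigma_e2 = 1.3, sigma_b2 = 0.4,
                            method = "direct")
  w <- active_block_moments(WA, rstar, sigma_e2 = 1.3, sigma_b2 = 0.4,
                            method = "woodbury")
  expect_lt(max(abs(d$mean - w$mean)), 1e-8)
  expect_lt(max(abs(d$cov - w$cov)), 1e-8)
  # k > n regime
  WA2 <- matrix(rnorm(30 * 60), 30, 60)
  r2 <- rnorm(30)
  d2 <- active_block_moments(WA2, r2, 1, 0.2, "direct")
  w2 <- active_block_moments(WA2, r2, 1, 0.2, "woodbury")
  expect_lt(max(abs(d2$mean - w2$mean)), 1e-8)
  expect_lt(max(abs(d2$cov - w2$cov)), 1e-8)
})

test_that("joint block draw matches its analytic moments and the k = 1 conditional", {
  set.seed(10)
  n <- 60; k <- 3
  W <- matrix(rnorm(n * k), n, k)
  y <- drop(W %*% c(1, -1, 0.5)) + rnorm(n)
  st <- make_state(y, NULL, W, b = c(1, -1, 0.5), p = 0.5,
                   sigma_b2 = 0.5, sigma_e2 = 1)
  st$I <- rep(1L, k)
  data <- hbmgwas:::.make_gibbs_data(y, NULL, W)
  mom <- active_block_moments(W, y, 1, 0.5, "direct")
  for (method in c("direct", "woodbury")) {
    draws <- replicate(6000, sample_active_block(st, data, hbm_priors(),
                                                 method = method)$b)
    mc_se <- sqrt(diag(mom$cov) / 6000)
    expect_equal(rowMeans(draws), mom$mean, tolerance = max(4 * mc_se))
    expect_equal(cov(t(draws)), mom$cov, tolerance = 0.15)
    # residual cache stays consistent after the joint draw
    s2 <- sample_active_block(st, data, hbm_priors(), method = method)
    expect_lt(max(abs(s2$r - (y - drop(W %*% s2$b)))), 1e-10)
  }
  # sigma_b2 -> infinity: posterior mean -> least squares
  mom_flat <- active_block_moments(W, y, 1, 1e8, "direct")
  expect_equal(mom_flat$mean, drop(qr.solve(W, y)), tolerance = 1e-4)
})

test_that("block draw of size 1 matches the component-wise conditional law", {
  set.seed(11)
  n <- 150
  W <- scale(matrix(rnorm(n), n, 1))[, , drop = FALSE]
  y <- drop(W) * 0.7 + rnorm(n)
  sb2 <- 0.3; se2 <- 1.1
  d <- sum(W^2) / se2 + 1 / sb2
  z <- sum(W * y) / se2
  mom <- active_block_moments(W, y, se2, sb2, "direct")
  expect_equal(mom$mean, z / d, tolerance = 1e-12)
  expect_equal(drop(mom$cov), 1 / d, tolerance = 1e-12)
})
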