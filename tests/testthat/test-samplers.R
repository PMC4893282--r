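# Gibbs sampler kernels: truncation, conjugacy, LASSO conditionals,
# determinism, and joint-distribution (prior invariance) behaviour.

test_that("liability draws respect truncation and stay finite in the tail", {
  set.seed(1)
  ex <- data.frame(patient = 1:4, interval = c(1, 1, 1, 1),
                   outcome = c(0, 1, 0, 1))
  gamma <- 0
  u <- sample_liabilities(ex, gamma, eta = rep(0, 4))
  expect_lt(u[1], 0); expect_gte(u[2], 0)
  # truncation region of negligible mass: gamma - eta = 10, y = 1
  ex2 <- data.frame(patient = 1, interval = 1, outcome = 1)
  u2 <- sample_liabilities(ex2, gamma = 10, eta = 0)
  expect_true(is.finite(u2))
  expect_gte(u2, 10)
  u3 <- sample_liabilities(data.frame(patient = 1, interval = 1,
                                      outcome = 0),
                           gamma = -12, eta = 0)
  expect_true(is.finite(u3))
  expect_lt(u3, -12)
})

test_that("augmentation draws match closed-form truncated-normal moments", {
  set.seed(2)
  n <- 2e4
  ex1 <- data.frame(patient = seq_len(n), interval = rep(1, n),
                    outcome = rep(1, n))
  u <- sample_liabilities(ex1, gamma = 0, eta = rep(0, n))
  # E[N(0,1) | u >= 0] = sqrt(2/pi)
  m <- sqrt(2 / pi)
  se <- sqrt(1 - m^2) / sqrt(n)
  expect_lt(abs(mean(u) - m), 3 * se)

  ex0 <- data.frame(patient = seq_len(n), interval = rep(1, n),
                    outcome = rep(0, n))
  u0 <- sample_liabilities(ex0, gamma = 1, eta = rep(0.5, n))
  # u < 1, mean eta + truncated-normal mean below a = 0.5
  a <- 0.5
  m0 <- 0.5 - dnorm(a) / pnorm(a)
  expect_lt(abs(mean(u0) - m0), 0.02)
})

test_that("cutoff draws follow the conjugate normal conditional", {
  set.seed(3)
  # one record with latent v: conditional is N(v, 1)
  draws <- replicate(4000, sample_gamma(2.2, 1L, K = 1))
  expect_lt(abs(mean(draws) - 2.2), 3 * 1 / sqrt(4000))
  expect_lt(abs(sd(draws) - 1), 0.05)
  # many centred latents: posterior mean near 0, sd near 1/sqrt(n)
  v <- rnorm(400)
  d2 <- replicate(2000, sample_gamma(v, rep(1L, 400), K = 1))
  expect_lt(abs(mean(d2) - mean(v)), 0.02)
  expect_warning(sample_gamma(v, rep(1L, 400), K = 2,
                              current = c(0, 0.5)),
                 "no records")
})

test_that("covariate-effect draws match the closed-form conditional", {
  set.seed(4)
  n <- 20
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4), x3 = rnorm(n, 0, 2))
  beta_true <- c(1.5, -1, 0.5)
  y <- drop(X %*% beta_true) + rnorm(n)
  pv <- 100
  V <- solve(crossprod(X) + diag(1 / pv, 3))
  m <- drop(V %*% crossprod(X, y))
  draws <- t(replicate(1e4, sample_beta(y, X, prior_var = pv)))
  mc_se <- sqrt(diag(V)) / sqrt(1e4)
  expect_true(all(abs(colMeans(draws) - m) < 4 * mc_se))
  expect_equal(cov(draws), V, tolerance = 0.05, ignore_attr = TRUE)
  # vague prior limit: posterior mean ~ OLS
  d2 <- t(replicate(4000, sample_beta(y, X, prior_var = 1e8)))
  ols <- drop(solve(crossprod(X), crossprod(X, y)))
  expect_equal(colMeans(d2), ols, tolerance = 0.05, ignore_attr = TRUE)
  # prior domination
  d3 <- replicate(500, sample_beta(y, X, prior_var = 1e-8))
  expect_lt(max(abs(d3)), 0.01)
})

test_that("orthonormal designs give a diagonal posterior covariance", {
  set.seed(5)
  X <- qr.Q(qr(matrix(rnorm(40 * 3), 40, 3)))
  y <- rnorm(40)
  draws <- t(replicate(6000, sample_beta(y, X, prior_var = 50)))
  cv <- cov(draws)
  expect_lt(max(abs(cv[upper.tri(cv)])), 0.02)
  # closed form: 1 / (1 + 1/pv) on the diagonal
  expect_equal(unname(diag(cv)), rep(1 / (1 + 1 / 50), 3), tolerance = 0.05)
})

test_that("rank-deficient covariates are reported by name", {
  X <- cbind(a = c(1, 0, 1, 0), b = c(2, 0, 2, 0))
  expect_error(sample_beta(rnorm(4), X), "collinear.*b")
})

test_that("the LASSO sweep reproduces the hand-derived conditionals", {
  # P = 2: replay the sampler's RNG stream against conditionals written out
  # by hand — scalar normal for each effect, inverse-Gaussian for 1/tau2,
  # and Gamma(P + a, sum(tau2)/2 + b) for lambda2.
  set.seed(6)
  n <- 12; p <- 2
  G <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n, 0, 1.5)
  a <- 0.4; b <- 0.3
  tau2_0 <- c(0.7, 1.9)

  set.seed(99)
  upd <- sample_snp_effects(y, G, effects = c(0, 0), tau2 = tau2_0,
                            lambda2 = 1, lasso_prior = c(a, b))

  set.seed(99)
  eff <- c(0, 0); tau2 <- tau2_0; lambda2 <- 1
  xtx <- colSums(G^2)
  r <- y
  for (j in 1:p) {
    r <- r + G[, j] * eff[j]
    prec <- xtx[j] + 1 / tau2[j]
    m <- sum(G[, j] * r) / prec
    eff[j] <- rnorm(1, m, sqrt(1 / prec))
    r <- r - G[, j] * eff[j]
  }
  mu <- pmin(sqrt(lambda2 / pmax(eff^2, 1e-12)), 1e8)
  tau2_new <- 1 / seqthresh:::rinvgauss(p, mu, lambda2)
  lam_new <- rgamma(1, shape = p + a, rate = sum(tau2_new) / 2 + b)

  expect_equal(upd$effects, eff)
  expect_equal(upd$tau2, tau2_new)
  expect_equal(upd$lambda2, lam_new)
})

test_that("LASSO shrinkage: tiny tau2 forces effects to zero", {
  set.seed(8)
  G <- matrix(rnorm(60), 20, 3)
  y <- drop(G %*% c(2, -2, 1)) + rnorm(20)
  upd <- sample_snp_effects(y, G, effects = c(0, 0, 0),
                            tau2 = rep(1e-10, 3), lambda2 = 1)
  expect_lt(max(abs(upd$effects)), 1e-3)
  # zero-variance marker gets effect 0
  G2 <- cbind(G[, 1], 0)
  upd2 <- sample_snp_effects(y, G2, effects = c(0.5, 0.5),
                             tau2 = c(1, 1), lambda2 = 1)
  expect_equal(upd2$effects[2], 0)
})

test_that("fits are bit-reproducible under a fixed seed", {
  co <- tiny_cohort()
  ctl <- quick_control(n_iter = 120, n_burnin = 40, seed = 7)
  f1 <- seqthresh_fit(co, K = 3, model = "cpp_snp", control = ctl)
  f2 <- seqthresh_fit(co, K = 3, model = "cpp_snp", control = ctl)
  expect_identical(f1$gamma, f2$gamma)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$snp_effects, f2$snp_effects)
  expect_identical(f1$lambda2, f2$lambda2)
  f3 <- seqthresh_fit(co, K = 3, model = "cpp_snp",
                      control = quick_control(n_iter = 120, n_burnin = 40,
                                              seed = 8))
  expect_false(identical(f1$beta, f3$beta))
})

test_that("residual variance is fixed at one in every fit", {
  co <- tiny_cohort()
  for (m in c("cpp", "snp", "cpp_snp")) {
    f <- seqthresh_fit(co, K = 2, model = m, control = quick_control(
      n_iter = 60, n_burnin = 20))
    expect_identical(f$sigma2_e, 1)
  }
})

test_that("LASSO shrinks null SNP effects harder than a flat prior", {
  set.seed(10)
  co <- simulate_cohort("tp", n = 250, p = 40, n_causal = 0, snp_h2 = 0,
                        cpp_effects = rep(0, 6), seed = 31)
  ctl <- quick_control(n_iter = 250, n_burnin = 80, seed = 2)
  f_lasso <- seqthresh_fit(co, K = 2, model = "snp", control = ctl)
  # flat-prior comparator: same expanded data, ridge with huge prior var
  g <- build_grid(co$time, co$event, 2)
  ex <- expand_cohort(co$time, co$event, g)
  G <- sweep(co$genotypes, 2, colMeans(co$genotypes))[ex$patient, ]
  colnames(G) <- colnames(co$genotypes)
  set.seed(2)
  state <- list(gamma = c(1.5, 1.5), beta = numeric(0), b = rep(0, 40))
  flat_sum <- rep(0, 40)
  n_it <- 250
  for (i in seq_len(n_it)) {
    eta_r <- drop(G %*% state$b)
    u <- sample_liabilities(ex, state$gamma, eta_r)
    z <- u - state$gamma[ex$interval]
    state$gamma <- sample_gamma(eta_r - z, ex$interval, 2,
                                current = state$gamma)
    u <- z + state$gamma[ex$interval]
    state$b <- sample_beta(u, G, prior_var = 1e6, check_rank = FALSE)
    if (i > 80) flat_sum <- flat_sum + state$b
  }
  flat_mean <- flat_sum / (n_it - 80)
  expect_lt(mean(abs(f_lasso$snp_effects)), mean(abs(flat_mean)))
})

test_that("the Gibbs kernel leaves the prior invariant (joint test)", {
  # successive-conditional simulator on a tiny instance: alternately draw
  # person-interval records from the record-level model given the current
  # parameters, then apply one full kernel sweep; the parameter marginals
  # must match their priors.
  set.seed(12)
  n <- 30; p <- 5; K <- 2
  ctl <- st_control(n_iter = 2, n_burnin = 0, thin = 1, seed = 12,
                    beta_prior_var = 1, lasso_prior = c(3, 3),
                    gamma_prior_var = 1)
  X <- cbind(x = rnorm(n))
  sg <- simulate_genotypes(n, p, maf_range = c(0.3, 0.5))
  G <- sweep(sg$genotypes, 2, colMeans(sg$genotypes))
  M <- 5000
  beta_chain <- lambda_chain <- gamma_chain <- numeric(M)
  state <- list(gamma = rnorm(K), beta = rnorm(1), b = rnorm(p),
                tau2 = rep(1, p), lambda2 = rgamma(1, 3, 3))
  for (m in seq_len(M)) {
    eta <- drop(X %*% state$beta) + drop(G %*% state$b)
    pat <- integer(0); kk <- integer(0); yy <- integer(0)
    for (i in seq_len(n)) {
      for (k in seq_len(K)) {
        if (runif(1) < 0.15) break            # censored before interval k
        ev <- runif(1) >= pnorm(state$gamma[k] - eta[i])
        pat <- c(pat, i); kk <- c(kk, k); yy <- c(yy, as.integer(ev))
        if (ev) break
      }
    }
    if (length(unique(kk)) < K) {             # identity move: no update
      beta_chain[m] <- state$beta; lambda_chain[m] <- state$lambda2
      gamma_chain[m] <- state$gamma[1]; next
    }
    dat <- list(y = yy, k = kk, X = X[pat, , drop = FALSE],
                G = G[pat, , drop = FALSE], K = K,
                xtx = colSums(G[pat, , drop = FALSE]^2))
    state <- seqthresh:::st_gibbs_sweep(state, dat, ctl)
    beta_chain[m] <- state$beta
    lambda_chain[m] <- state$lambda2
    gamma_chain[m] <- state$gamma[1]
  }
  keep <- 1001:M
  bse <- function(x, nb = 10) {              # batch-means standard error
    bm <- colMeans(matrix(x, ncol = nb))
    sd(bm) / sqrt(nb)
  }
  b_ <- beta_chain[keep]
  expect_lt(abs(mean(b_) - 0), 3 * bse(b_) + 0.02)   # prior N(0, 1)
  g_ <- gamma_chain[keep]
  expect_lt(abs(mean(g_) - 0), 3 * bse(g_) + 0.02)   # prior N(0, 1)
  l_ <- lambda_chain[keep]
  expect_lt(abs(mean(l_) - 1), 3 * bse(l_) + 0.05)   # Gamma(3,3), mean 1
})
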