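# Gibbs sampler building blocks for the sequential threshold probit model.
#
# Data augmentation: each person-interval record r (patient i, interval k,
# outcome y) gets a latent liability u_r ~ N(eta_i, 1), with y = 1 iff
# u_r >= gamma_k.  Conditional on the liabilities, the cutoffs behave as
# interval-specific intercepts (flat priors, unordered), covariate effects
# are a conjugate normal block, and SNP effects follow the Park-Casella
# Bayesian LASSO hierarchy: b_j ~ N(0, tau2_j), tau2_j ~ Exp(lambda2 / 2),
# lambda2 ~ Gamma(a, b).  The residual variance is fixed at 1 throughout.

# Draws z ~ N(0,1) truncated to z >= a, vectorized and stable in the far
# tail (log-scale inverse CDF; finite for |a| of several tens).
rtnorm_above <- function(a) {
  lp <- pnorm(a, lower.tail = FALSE, log.p = TRUE)
  qnorm(lp + log(runif(length(a))), lower.tail = FALSE, log.p = TRUE)
}

# Michael-Schucany-Haas inverse-Gaussian sampler (mean mu, shape lam).
rinvgauss <- function(n, mu, lam) {
  nu <- rnorm(n)^2
  x <- mu + mu^2 * nu / (2 * lam) -
    mu / (2 * lam) * sqrt(4 * mu * lam * nu + mu^2 * nu^2)
  x <- pmax(x, .Machine$double.xmin)
  u <- runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

#' Sampler configuration
#'
#' @param n_iter total Gibbs iterations.
#' @param n_burnin discarded warm-up iterations (< `n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer RNG seed; fits are bit-reproducible given the seed.
#' @param beta_prior_var prior variance of each covariate effect
#'   (independent N(0, `beta_prior_var`); the large default is effectively
#'   flat).
#' @param lasso_prior shape and rate of the Gamma prior on the LASSO
#'   regularization parameter lambda^2.  The default `NULL` anchors the
#'   prior to the marker-variance budget at fitting time: prior mean
#'   `lambda2_0 = 2 * sum(var(x_j)) * (1 - R0) / R0` with `R0 = 0.1` (the
#'   prior guess of the liability variance fraction captured by SNPs) and
#'   shape 3.  With the residual variance fixed at 1, an unanchored weak
#'   hyperprior lets the latent scale inflate when many markers can
#'   separate the person-interval records; scaling the prior with the
#'   marker count prevents that.
#' @param gamma_prior_var prior variance of the interval cutoffs; `Inf`
#'   (default) is the flat prior.
#' @param store_chains keep the retained draws of every parameter block.
#' @return an `st_control` list.
#' @export
st_control <- function(n_iter = 20000, n_burnin = 5000, thin = 10,
                       seed = 1L, beta_prior_var = 1e6,
                       lasso_prior = NULL, gamma_prior_var = Inf,
                       store_chains = FALSE) {
  stopifnot(n_iter >= 1, n_burnin >= 0, n_burnin < n_iter, thin >= 1,
            beta_prior_var > 0, gamma_prior_var > 0)
  if (!is.null(lasso_prior))
    stopifnot(length(lasso_prior) == 2, all(lasso_prior > 0))
  structure(list(n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), beta_prior_var = beta_prior_var,
                 lasso_prior = lasso_prior,
                 gamma_prior_var = gamma_prior_var,
                 store_chains = isTRUE(store_chains)),
            class = "st_control")
}

#' Draw latent liabilities for the expanded records
#'
#' For each record draws `u` from N(eta, 1) truncated to `u < gamma_k` when
#' the record outcome is 0 (interval survived) and `u >= gamma_k` when it is
#' 1 (event in the interval).  Stable for truncation regions of negligible
#' mass: draws stay finite even when `|gamma_k - eta|` is large.
#'
#' @param expanded an `st_expanded` (or any data.frame with `patient`,
#'   `interval`, `outcome`).
#' @param gamma K-vector of cutoffs.
#' @param eta linear predictor, per patient (length max(patient)) or
#'   per record.
#' @return numeric vector of liabilities, one per record.
#' @export
sample_liabilities <- function(expanded, gamma, eta) {
  k <- expanded$interval
  y <- expanded$outcome
  n <- length(k)
  eta_r <- if (length(eta) == n) eta else eta[expanded$patient]
  draw_liabilities(y, gamma[k], eta_r)
}

# fast path: per-record outcome, cutoff and linear predictor
draw_liabilities <- function(y, gk, eta_r) {
  a <- gk - eta_r
  z <- numeric(length(a))
  up <- y == 1
  z[up] <- rtnorm_above(a[up])
  z[!up] <- -rtnorm_above(-a[!up])
  eta_r + z
}

#' Draw the interval cutoffs from their full conditional
#'
#' The cutoffs are unordered and act as interval-specific intercepts: with a
#' flat (or normal) prior, `gamma_k` is drawn from a normal centred at the
#' mean of the interval-k cutoff-scale pseudo-observations with variance
#' `1 / n_k`.
#'
#' @param latents per-record cutoff-scale pseudo-observations (for record r
#'   in interval k this is `eta_r - (u_r - gamma_k)`, i.e. the value whose
#'   interval mean centres the conditional).
#' @param record_interval interval index per record.
#' @param K number of intervals.
#' @param prior_mean,prior_var optional normal prior on each cutoff;
#'   `prior_var = Inf` is flat.
#' @param current current cutoff values, kept (with a warning) for
#'   intervals with no records.
#' @return K-vector of cutoff draws.
#' @export
sample_gamma <- function(latents, record_interval, K, prior_mean = 0,
                         prior_var = Inf, current = NULL) {
  gamma <- if (is.null(current)) rep(NA_real_, K) else current
  for (k in seq_len(K)) {
    idx <- record_interval == k
    n_k <- sum(idx)
    if (n_k == 0) {
      warning("interval ", k, " has no records; cutoff not updated")
      next
    }
    prec <- n_k + 1 / prior_var
    m <- (sum(latents[idx]) + prior_mean / prior_var) / prec
    gamma[k] <- rnorm(1, m, sqrt(1 / prec))
  }
  gamma
}

#' Draw covariate effects from their multivariate normal conditional
#'
#' Joint conjugate draw for the "Bayesian regression" block: residual
#' variance 1, independent N(0, `prior_var`) priors per coefficient.
#'
#' @param latents per-record response with all other linear-predictor parts
#'   (cutoff handled on the liability scale, SNP part) already removed.
#' @param X record-level covariate design matrix (no intercept column;
#'   interval cutoffs play that role).
#' @param prior_var scalar or per-coefficient prior variance.
#' @param check_rank verify full column rank and name collinear columns.
#' @return Q-vector draw.
#' @export
sample_beta <- function(latents, X, prior_var = 1e6, check_rank = TRUE) {
  q <- ncol(X)
  if (q == 0) return(numeric(0))
  if (check_rank) {
    qrx <- qr(X)
    if (qrx$rank < q) {
      bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):q]]
      stop("covariate matrix is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
  }
  pv <- rep_len(prior_var, q)
  prec <- crossprod(X) + diag(1 / pv, q)
  R <- chol(prec)
  m <- backsolve(R, forwardsolve(t(R), crossprod(X, latents)))
  drop(m + backsolve(R, rnorm(q)))
}

#' One Bayesian LASSO sweep over the SNP effects
#'
#' Single-site Gibbs update of each SNP effect in fixed marker order from
#' its scalar normal conditional with prior variance `sigma2 * tau2_j`,
#' followed by the Park-Casella hyperparameter updates: `1 / tau2_j` from
#' its inverse-Gaussian conditional and `lambda2` from its Gamma
#' conditional with prior `Gamma(lasso_prior[1], lasso_prior[2])`.
#'
#' @param latents per-record response with cutoff and covariate parts
#'   removed (still containing the SNP signal).
#' @param genotypes record-level centred dosage matrix.
#' @param effects current P-vector of SNP effects.
#' @param tau2 current per-SNP prior variance components.
#' @param lambda2 current squared regularization parameter.
#' @param lasso_prior Gamma shape/rate prior on lambda2.
#' @param sigma2 residual variance (1 in the threshold model; free in the
#'   Gaussian-response variant).
#' @param xtx precomputed `colSums(genotypes^2)` (optional).
#' @param update_lambda set FALSE to hold lambda2 fixed.
#' @return list with updated `effects`, `tau2`, `lambda2`.
#' @export
sample_snp_effects <- function(latents, genotypes, effects, tau2, lambda2,
                               lasso_prior = c(0.1, 0.1), sigma2 = 1,
                               xtx = NULL, update_lambda = TRUE) {
  p <- ncol(genotypes)
  if (is.null(xtx)) xtx <- colSums(genotypes^2)
  r <- latents - drop(genotypes %*% effects)
  for (j in seq_len(p)) {
    if (xtx[j] <= 0) {
      if (effects[j] != 0) {
        r <- r + genotypes[, j] * effects[j]
        effects[j] <- 0
      }
      next
    }
    xj <- genotypes[, j]
    r <- r + xj * effects[j]
    prec <- xtx[j] + 1 / tau2[j]
    m <- sum(xj * r) / prec
    effects[j] <- rnorm(1, m, sqrt(sigma2 / prec))
    r <- r - xj * effects[j]
  }
  # tau2_j: 1/tau2 ~ InvGauss(sqrt(lambda2 * sigma2 / b_j^2), lambda2)
  b2 <- pmax(effects^2, 1e-12)
  mu <- pmin(sqrt(lambda2 * sigma2 / b2), 1e8)
  tau2 <- 1 / rinvgauss(p, mu, lambda2)
  if (update_lambda)
    lambda2 <- rgamma(1, shape = p + lasso_prior[1],
                      rate = sum(tau2) / 2 + lasso_prior[2])
  list(effects = effects, tau2 = tau2, lambda2 = lambda2)
}

# One full Gibbs sweep over (liabilities, gamma, beta, SNP block) on the
# prepared record-level data.  `dat` holds y, k (interval per record), X, G,
# xtx, K; `state` holds gamma, beta, b, tau2, lambda2.  Shared by the model
# fit loop and by prior-invariance (Geweke-style) checks.
st_gibbs_sweep <- function(state, dat, control) {
  n <- length(dat$y)
  eta_r <- rep(0, n)
  if (!is.null(dat$X) && length(state$beta))
    eta_r <- eta_r + drop(dat$X %*% state$beta)
  if (!is.null(dat$G) && length(state$b))
    eta_r <- eta_r + drop(dat$G %*% state$b)

  u <- draw_liabilities(dat$y, state$gamma[dat$k], eta_r)
  z <- u - state$gamma[dat$k]
  state$gamma <- sample_gamma(eta_r - z, dat$k, dat$K,
                              prior_var = control$gamma_prior_var,
                              current = state$gamma)
  u <- z + state$gamma[dat$k]

  if (!is.null(dat$X) && ncol(dat$X) > 0) {
    resp <- u
    if (!is.null(dat$G) && length(state$b))
      resp <- resp - drop(dat$G %*% state$b)
    state$beta <- sample_beta(resp, dat$X, control$beta_prior_var,
                              check_rank = FALSE)
  }
  if (!is.null(dat$G) && ncol(dat$G) > 0) {
    resp <- u
    if (!is.null(dat$X) && length(state$beta))
      resp <- resp - drop(dat$X %*% state$beta)
    upd <- sample_snp_effects(resp, dat$G, state$b, state$tau2,
                              state$lambda2, control$lasso_prior,
                              xtx = dat$xtx)
    state$b <- upd$effects
    state$tau2 <- upd$tau2
    state$lambda2 <- upd$lambda2
  }
  state
}

# Gaussian-response Bayesian LASSO (identity link, free residual variance).
# Used to regress a continuous liability prediction on SNP dosages.
# lasso_prior = NULL anchors the lambda2 prior to the marker-variance
# budget, as in the threshold-model fit.
lasso_gaussian <- function(y, X, n_iter = 600, n_burnin = 200, thin = 1,
                           seed = 1L, lasso_prior = NULL) {
  set.seed(seed)
  n <- length(y)
  p <- ncol(X)
  xtx <- colSums(X^2)
  if (is.null(lasso_prior)) {
    R0 <- 0.1
    l0 <- max(2 * sum(xtx) / max(n - 1, 1) * (1 - R0) / R0, 1)
    lasso_prior <- c(3, 3 / l0)
  }
  lambda2 <- lasso_prior[1] / lasso_prior[2]
  b <- rep(0, p)
  tau2 <- rep(2 / lambda2, p)
  sigma2 <- max(stats::var(y), 1e-6)
  ybar <- mean(y)
  yc <- y - ybar
  keep <- seq(n_burnin + 1, n_iter, by = thin)
  b_sum <- rep(0, p)
  s2_sum <- 0
  for (i in seq_len(n_iter)) {
    upd <- sample_snp_effects(yc, X, b, tau2, lambda2, lasso_prior,
                              sigma2 = sigma2, xtx = xtx)
    b <- upd$effects; tau2 <- upd$tau2; lambda2 <- upd$lambda2
    r <- yc - drop(X %*% b)
    sigma2 <- 1 / rgamma(1, shape = (n - 1 + p) / 2,
                         rate = sum(r^2) / 2 + sum(b^2 / tau2) / 2)
    if (i %in% keep) {
      b_sum <- b_sum + b
      s2_sum <- s2_sum + sigma2
    }
  }
  list(effects = b_sum / length(keep), sigma2 = s2_sum / length(keep),
       intercept = ybar)
}
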