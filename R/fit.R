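# Model fitting: the cohort engine (seqthresh_fit) and the formula
# interface (seqthresh), plus the S3 methods of the fitted object.

#' Fit a sequential threshold model to a cohort
#'
#' Runs the full Gibbs sampler on the person-interval expansion of a cohort.
#' Three variants are available: `"cpp"` (clinical covariates only, vague
#' normal priors), `"snp"` (SNP dosages only, Bayesian LASSO prior), and
#' `"cpp_snp"` (both, additive on the liability scale).  The residual
#' variance is fixed at 1 for identifiability; the interval cutoffs are
#' unordered.  Genotypes must be complete (impute first) and are centred
#' per marker before fitting; covariates are centred as well (the cutoffs
#' absorb the location).
#'
#' @param cohort an `st_cohort`.
#' @param grid an `st_grid`, or `NULL` to build one from `K`.
#' @param K number of intervals when `grid` is `NULL` (9 is the
#'   recurrence-like convention, 4 the progression-like one).
#' @param model which linear-predictor blocks to include.
#' @param control an [st_control()] configuration.
#' @return an object of class `seqthresh` with posterior means `gamma`,
#'   `beta`, `snp_effects`, `lambda2`, fixed `sigma2_e = 1`, the training
#'   linear predictor `eta`, and (if requested) retained chains.
#' @export
seqthresh_fit <- function(cohort, grid = NULL, K = NULL,
                          model = c("cpp", "snp", "cpp_snp"),
                          control = st_control()) {
  stopifnot(inherits(cohort, "st_cohort"))
  model <- match.arg(model)
  if (is.null(grid)) {
    if (is.null(K)) stop("provide either a grid or K")
    grid <- build_grid(cohort$time, cohort$event, K)
  }
  expanded <- expand_cohort(cohort$time, cohort$event, grid)
  if (nrow(expanded) == 0) stop("expanded data is empty")
  Kk <- grid$K

  use_x <- model %in% c("cpp", "cpp_snp")
  use_g <- model %in% c("snp", "cpp_snp")
  X <- G <- NULL
  x_center <- g_center <- NULL
  if (use_x) {
    if (is.null(cohort$covariates) || ncol(cohort$covariates) == 0)
      stop("model '", model, "' needs covariates")
    Xp <- cohort$covariates
    x_center <- colMeans(Xp)
    Xp <- sweep(Xp, 2, x_center)
    qrx <- qr(Xp)
    if (qrx$rank < ncol(Xp)) {
      bad <- colnames(Xp)[qrx$pivot[(qrx$rank + 1):ncol(Xp)]]
      stop("covariate matrix is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
    X <- Xp[expanded$patient, , drop = FALSE]
  }
  if (use_g) {
    if (is.null(cohort$genotypes))
      stop("model '", model, "' needs genotypes")
    if (anyNA(cohort$genotypes))
      stop("genotypes contain missing calls; run impute_missing() first")
    Gp <- cohort$genotypes
    g_center <- colMeans(Gp)
    Gp <- sweep(Gp, 2, g_center)
    G <- Gp[expanded$patient, , drop = FALSE]
  }

  dat <- list(y = expanded$outcome, k = expanded$interval,
              X = X, G = G, K = Kk,
              xtx = if (use_g) colSums(G^2) else NULL)

  if (use_g && is.null(control$lasso_prior)) {
    # anchor the lambda2 prior to the marker-variance budget (prior guess
    # R0 of the liability variance fraction explained by SNPs)
    R0 <- 0.1
    sumvar <- sum(apply(Gp, 2, stats::var))
    l0 <- max(2 * sumvar * (1 - R0) / R0, 1)
    control$lasso_prior <- c(3, 3 / l0)
  } else if (is.null(control$lasso_prior)) {
    control$lasso_prior <- c(0.1, 0.1)
  }
  lambda2_init <- control$lasso_prior[1] / control$lasso_prior[2]

  set.seed(control$seed)
  # initial cutoffs from per-interval event rates
  rate <- vapply(seq_len(Kk), function(k) {
    y <- dat$y[dat$k == k]
    if (length(y) == 0) 0.5 else mean(y)
  }, 0)
  state <- list(gamma = qnorm(1 - pmin(pmax(rate, 0.02), 0.98)),
                beta = if (use_x) rep(0, ncol(X)) else numeric(0),
                b = if (use_g) rep(0, ncol(G)) else numeric(0),
                tau2 = if (use_g) rep(2 / lambda2_init, ncol(G))
                       else numeric(0),
                lambda2 = lambda2_init)

  keep <- seq(control$n_burnin + 1, control$n_iter, by = control$thin)
  n_keep <- length(keep)
  sums <- list(gamma = 0, beta = 0, b = 0, lambda2 = 0)
  sqs <- list(gamma = 0, beta = 0, lambda2 = 0)
  chains <- NULL
  if (control$store_chains)
    chains <- list(gamma = matrix(NA_real_, n_keep, Kk),
                   beta = if (use_x) matrix(NA_real_, n_keep, ncol(X)),
                   snp = if (use_g) matrix(NA_real_, n_keep, ncol(G)),
                   lambda2 = rep(NA_real_, n_keep))
  stored <- 0L
  for (i in seq_len(control$n_iter)) {
    state <- st_gibbs_sweep(state, dat, control)
    if (!all(is.finite(c(state$gamma, state$beta, state$lambda2))))
      stop("divergent chain: non-finite parameter at iteration ", i)
    if (i > control$n_burnin &&
        (i - control$n_burnin - 1L) %% control$thin == 0L) {
      stored <- stored + 1L
      sums$gamma <- sums$gamma + state$gamma
      sqs$gamma <- sqs$gamma + state$gamma^2
      sums$lambda2 <- sums$lambda2 + state$lambda2
      sqs$lambda2 <- sqs$lambda2 + state$lambda2^2
      if (use_x) {
        sums$beta <- sums$beta + state$beta
        sqs$beta <- sqs$beta + state$beta^2
      }
      if (use_g) sums$b <- sums$b + state$b
      if (control$store_chains) {
        chains$gamma[stored, ] <- state$gamma
        if (use_x) chains$beta[stored, ] <- state$beta
        if (use_g) chains$snp[stored, ] <- state$b
        chains$lambda2[stored] <- state$lambda2
      }
    }
  }

  gamma_mean <- sums$gamma / stored
  beta_mean <- if (use_x) setNames(sums$beta / stored, colnames(X)) else numeric(0)
  b_mean <- if (use_g) setNames(sums$b / stored, colnames(cohort$genotypes)) else numeric(0)
  lambda_mean <- if (use_g) sums$lambda2 / stored else NA_real_

  eta_cpp <- if (use_x)
    drop(sweep(cohort$covariates, 2, x_center) %*% beta_mean) else rep(0, length(cohort$time))
  eta_snp <- if (use_g)
    drop(sweep(cohort$genotypes, 2, g_center) %*% b_mean) else rep(0, length(cohort$time))

  post_sd <- function(s, s2) sqrt(pmax(s2 / stored - (s / stored)^2, 0))
  fit <- structure(list(
    call = match.call(), model = model, grid = grid,
    gamma = gamma_mean,
    gamma_sd = post_sd(sums$gamma, sqs$gamma),
    beta = beta_mean,
    beta_sd = if (use_x) setNames(post_sd(sums$beta, sqs$beta), colnames(X)) else numeric(0),
    snp_effects = b_mean,
    lambda2 = lambda_mean,
    lambda2_sd = if (use_g) post_sd(sums$lambda2, sqs$lambda2) else NA_real_,
    sigma2_e = 1,
    control = control, seed = control$seed,
    n_iter = control$n_iter, n_burnin = control$n_burnin,
    thin = control$thin, n_draws = stored,
    x_center = x_center, g_center = g_center,
    eta = eta_cpp + eta_snp, eta_cpp = eta_cpp, eta_snp = eta_snp,
    patient_ids = cohort$patient_ids,
    time = cohort$time, event = cohort$event,
    n = length(cohort$time), n_records = nrow(expanded),
    chains = chains), class = "seqthresh")
  fit
}

#' Sequential threshold model (formula interface)
#'
#' Formula front-end to [seqthresh_fit()].  The left-hand side is a
#' `survival::Surv(time, event)` object; the right-hand side gives the
#' clinical covariates (use `~ 1` for a SNP-only model).
#'
#' @param formula e.g. `Surv(time, event) ~ stage + grade + age`.
#' @param data data.frame holding the formula variables.
#' @param genotypes optional complete N x P dosage matrix, row-aligned with
#'   `data`.
#' @param grid,K interval grid or number of intervals.
#' @param model model variant; default `"cpp"` without genotypes,
#'   `"cpp_snp"` with genotypes (or `"snp"` when the formula has no
#'   covariates).
#' @param control an [st_control()].
#' @return a `seqthresh` fit (with the terms needed by `predict` on new
#'   data frames).
#' @examples
#' set.seed(1)
#' d <- data.frame(time = rexp(120, 1 / 24), stage = rbinom(120, 1, 0.3))
#' d$event <- rbinom(120, 1, 0.4)
#' f <- seqthresh(survival::Surv(time, event) ~ stage, d, K = 3,
#'                control = st_control(n_iter = 200, n_burnin = 50, thin = 1))
#' coef(f)
#' @export
seqthresh <- function(formula, data, genotypes = NULL, grid = NULL, K = NULL,
                      model = NULL, control = st_control()) {
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  if (!survival::is.Surv(y))
    stop("the formula response must be a survival::Surv(time, event) object")
  time <- as.numeric(y[, "time"])
  event <- as.integer(y[, "status"])
  tt <- terms(formula, data = data)
  X <- model.matrix(tt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (is.null(model))
    model <- if (is.null(genotypes)) "cpp"
             else if (ncol(X) == 0) "snp" else "cpp_snp"
  cohort <- make_cohort(time = time, event = event, genotypes = genotypes,
                        covariates = if (ncol(X) > 0) X else NULL)
  fit <- seqthresh_fit(cohort, grid = grid, K = K, model = model,
                       control = control)
  fit$call <- match.call()
  fit$terms <- tt
  fit$xlevels <- .getXlevels(tt, mf)
  fit
}

#' @export
print.seqthresh <- function(x, ...) {
  lab <- c(cpp = "clinical covariates (Bayesian regression)",
           snp = "SNPs (Bayesian LASSO)",
           cpp_snp = "clinical covariates + SNPs")
  cat("Sequential threshold model -", lab[[x$model]], "\n")
  cat("  patients:", x$n, " expanded records:", x$n_records,
      " intervals:", x$grid$K, "\n")
  cat("  Gibbs: ", x$n_iter, " iterations (burn-in ", x$n_burnin,
      ", thin ", x$thin, ", seed ", x$seed, "), residual variance fixed at 1\n",
      sep = "")
  cat("  cutoffs (posterior mean):",
      paste(sprintf("%.3f", x$gamma), collapse = ", "), "\n")
  if (length(x$beta)) {
    cat("  covariate effects:\n")
    print(round(x$beta, 4))
  }
  if (length(x$snp_effects))
    cat("  SNP effects: ", length(x$snp_effects),
        " markers, mean |effect| = ",
        signif(mean(abs(x$snp_effects)), 3),
        ", lambda^2 = ", signif(x$lambda2, 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.seqthresh <- function(object,
                           which = c("beta", "gamma", "snp", "all"), ...) {
  which <- match.arg(which)
  switch(which,
         beta = object$beta,
         gamma = setNames(object$gamma,
                          paste0("gamma", seq_along(object$gamma))),
         snp = object$snp_effects,
         all = list(gamma = object$gamma, beta = object$beta,
                    snp = object$snp_effects))
}

#' @export
summary.seqthresh <- function(object, n_top_snps = 10, ...) {
  out <- list(model = object$model, n = object$n,
              n_records = object$n_records, K = object$grid$K,
              n_draws = object$n_draws,
              gamma = data.frame(mean = object$gamma, sd = object$gamma_sd),
              lambda2 = object$lambda2, lambda2_sd = object$lambda2_sd,
              r2_probit_train = r2_probit(object$eta))
  if (length(object$beta))
    out$beta <- data.frame(mean = object$beta, sd = object$beta_sd,
                           row.names = names(object$beta))
  if (length(object$snp_effects)) {
    ord <- order(-abs(object$snp_effects))[seq_len(min(n_top_snps,
                                                length(object$snp_effects)))]
    out$top_snps <- data.frame(effect = object$snp_effects[ord],
                               row.names = names(object$snp_effects)[ord])
  }
  class(out) <- "summary.seqthresh"
  out
}

#' @export
print.summary.seqthresh <- function(x, ...) {
  cat("Sequential threshold model (", x$model, "), N = ", x$n,
      ", K = ", x$K, ", ", x$n_draws, " retained draws\n", sep = "")
  cat("Interval cutoffs (posterior mean, sd):\n")
  print(round(x$gamma, 4))
  if (!is.null(x$beta)) {
    cat("Covariate effects:\n")
    print(round(x$beta, 4))
  }
  if (!is.null(x$top_snps)) {
    cat("Largest SNP effects (posterior mean):\n")
    print(round(x$top_snps, 5))
    cat("lambda^2 =", signif(x$lambda2, 4), "\n")
  }
  cat("Training-set liability R2 =", round(x$r2_probit_train, 4), "\n")
  invisible(x)
}

# Build the centred design pieces for prediction.
predict_parts <- function(object, newdata = NULL, genotypes = NULL) {
  if (is.null(newdata) && is.null(genotypes))
    return(list(cpp = object$eta_cpp, snp = object$eta_snp))
  eta_cpp <- eta_snp <- NULL
  if (length(object$beta)) {
    if (inherits(newdata, "st_cohort")) {
      X <- newdata$covariates[, names(object$beta), drop = FALSE]
    } else if (!is.null(object$terms) && is.data.frame(newdata)) {
      tt <- delete.response(object$terms)
      mf <- model.frame(tt, newdata, xlev = object$xlevels)
      X <- model.matrix(tt, mf)
      X <- X[, names(object$beta), drop = FALSE]
    } else if (is.matrix(newdata)) {
      X <- newdata[, names(object$beta), drop = FALSE]
    } else stop("cannot build covariates from 'newdata'")
    eta_cpp <- drop(sweep(X, 2, object$x_center) %*% object$beta)
  }
  if (length(object$snp_effects)) {
    G <- if (inherits(newdata, "st_cohort")) newdata$genotypes else genotypes
    if (is.null(G)) stop("model includes SNP effects; supply genotypes")
    G <- G[, names(object$snp_effects), drop = FALSE]
    eta_snp <- drop(sweep(G, 2, object$g_center) %*% object$snp_effects)
  }
  n <- max(length(eta_cpp), length(eta_snp))
  if (is.null(eta_cpp)) eta_cpp <- rep(0, n)
  if (is.null(eta_snp)) eta_snp <- rep(0, n)
  list(cpp = eta_cpp, snp = eta_snp)
}

#' Predict from a sequential threshold model
#'
#' @param object a `seqthresh` fit.
#' @param newdata a data.frame (formula fits), covariate matrix, or
#'   `st_cohort`; `NULL` returns training-set predictions.
#' @param genotypes dosage matrix for SNP models when `newdata` is not a
#'   cohort.
#' @param type `"link"` for the liability-scale linear predictor eta,
#'   `"survival"` for the N x K matrix of cumulative event-free
#'   probabilities, `"risk"` for 1 minus the final survival probability.
#' @param parts return the additive covariate/SNP decomposition of eta.
#' @param ... unused.
#' @return vector, matrix, or (with `parts = TRUE`) a list `cpp`/`snp`.
#' @export
predict.seqthresh <- function(object, newdata = NULL, genotypes = NULL,
                              type = c("link", "survival", "risk"),
                              parts = FALSE, ...) {
  type <- match.arg(type)
  pp <- predict_parts(object, newdata, genotypes)
  if (parts) return(pp)
  eta <- pp$cpp + pp$snp
  if (type == "link") return(eta)
  surv <- t(vapply(eta, function(e)
    cumprod(pnorm(object$gamma - e)), numeric(object$grid$K)))
  colnames(surv) <- paste0("S", seq_len(object$grid$K))
  if (type == "survival") surv else 1 - surv[, object$grid$K]
}

#' @export
fitted.seqthresh <- function(object, ...) object$eta

#' Martingale-type residuals
#'
#' Observed event count minus the model-expected number of events over the
#' intervals each patient was actually observed in:
#' `event_i - sum_k (1 - pnorm(gamma_k - eta_i))`.
#'
#' @param object a `seqthresh` fit.
#' @param ... unused.
#' @export
residuals.seqthresh <- function(object, ...) {
  expanded <- expand_cohort(object$time, object$event, object$grid)
  haz <- 1 - pnorm(object$gamma[expanded$interval] - object$eta[expanded$patient])
  expected <- vapply(seq_len(object$n),
                     function(i) sum(haz[expanded$patient == i]), 0)
  object$event - expected
}

#' Simulate outcomes from the fitted model
#'
#' Posterior-mean parametric simulation: each patient walks the intervals,
#' failing interval k with probability `1 - pnorm(gamma_k - eta_i)` (no
#' censoring process).
#'
#' @param object a `seqthresh` fit.
#' @param nsim number of replicate outcome sets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame with `sim`, `patient`, `interval` (NA = survived all
#'   K intervals) and `event`.
#' @export
simulate.seqthresh <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  K <- object$grid$K
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    fail <- outer(object$eta, object$gamma,
                  function(e, g) runif(length(e)) >= pnorm(g - e))
    k_ev <- apply(fail, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
    out[[s]] <- data.frame(sim = s, patient = seq_len(object$n),
                           interval = k_ev, event = as.integer(!is.na(k_ev)))
  }
  do.call(rbind, out)
}

#' Plot a sequential threshold model fit
#'
#' `type = "survival"` (default) draws model-implied event-free survival
#' curves at the 10th/50th/90th percentiles of the training linear
#' predictor; `type = "trace"` draws retained-chain traces (requires
#' `store_chains = TRUE`).
#'
#' @param x a `seqthresh` fit.
#' @param type plot type.
#' @param ... passed to the underlying plot call.
#' @export
plot.seqthresh <- function(x, type = c("survival", "trace"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    if (is.null(x$chains))
      stop("no stored chains; refit with st_control(store_chains = TRUE)")
    oldpar <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(oldpar))
    plot(x$chains$gamma[, 1], type = "l", xlab = "retained draw",
         ylab = expression(gamma[1]), main = "Cutoff trace", ...)
    y2 <- if (length(x$snp_effects)) x$chains$lambda2 else x$chains$beta[, 1]
    plot(y2, type = "l", xlab = "retained draw",
         ylab = if (length(x$snp_effects)) expression(lambda^2) else "beta[1]",
         main = if (length(x$snp_effects)) "Regularization trace"
                else "Covariate-effect trace", ...)
    return(invisible(x))
  }
  qs <- quantile(x$eta, c(0.1, 0.5, 0.9))
  K <- x$grid$K
  surv <- vapply(qs, function(e) cumprod(pnorm(x$gamma - e)), numeric(K))
  plot(0:K, c(1, surv[, 1]), type = "s", ylim = c(0, 1),
       xlab = "interval", ylab = "event-free probability",
       main = "Model-implied survival", ...)
  lines(0:K, c(1, surv[, 2]), type = "s", lty = 2)
  lines(0:K, c(1, surv[, 3]), type = "s", lty = 3)
  legend("bottomleft", lty = 1:3, bty = "n",
         legend = paste0("eta @ ", c("10th", "50th", "90th"), " pctile"))
  invisible(x)
}
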