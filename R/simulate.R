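# Synthetic cohorts with the statistical structure the model assumes:
# Hardy-Weinberg genotypes with optional LD blocks, six prognosticator-like
# clinical covariates, and discrete-time outcomes generated from the
# sequential threshold model itself with heavy right-censoring.

#' Simulate biallelic SNP dosages
#'
#' MAFs are drawn uniformly from `maf_range`.  Within each LD block of
#' `ld_block_size` markers, a latent Gaussian copula with exchangeable
#' correlation `ld_rho` is applied to each of the two gametes and
#' thresholded at the allele frequency, giving Hardy-Weinberg dosages with
#' within-block LD.  Chromosome labels are assigned block-wise round-robin
#' over 1..22.
#'
#' @param n,p patients and markers.
#' @param maf_range minor allele frequency range, subset of (0, 0.5\].
#' @param ld_block_size markers per LD block (1 = independent markers).
#' @param ld_rho latent correlation within a block, in \[0, 1).
#' @param missing_rate fraction of calls set missing (for QC testing).
#' @return list with `genotypes` (N x P), `snp_ids`, `snp_chroms`, `maf`.
#' @export
simulate_genotypes <- function(n, p, maf_range = c(0.05, 0.5),
                               ld_block_size = 1, ld_rho = 0,
                               missing_rate = 0) {
  stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5)
  if (ld_rho >= 1 || ld_rho < 0) stop("ld_rho must be in [0, 1)")
  maf <- runif(p, maf_range[1], maf_range[2])
  thr <- qnorm(1 - maf)
  geno <- matrix(0L, n, p)
  starts <- seq(1, p, by = ld_block_size)
  gamete <- function(m) {
    # exchangeable copula: sqrt(rho) * shared + sqrt(1 - rho) * own
    shared <- rnorm(n)
    z <- sqrt(ld_rho) * shared +
      sqrt(1 - ld_rho) * matrix(rnorm(n * m), n, m)
    z
  }
  for (s in starts) {
    cols <- s:min(s + ld_block_size - 1, p)
    m <- length(cols)
    z1 <- gamete(m)
    z2 <- gamete(m)
    t_blk <- matrix(thr[cols], n, m, byrow = TRUE)
    geno[, cols] <- (z1 > t_blk) + (z2 > t_blk)
  }
  if (missing_rate > 0)
    geno[runif(n * p) < missing_rate] <- NA
  snp_ids <- sprintf("SNP%05d", seq_len(p))
  chroms <- as.character(rep(rep_len(1:22, length(starts)),
                             each = ld_block_size)[seq_len(p)])
  colnames(geno) <- snp_ids
  list(genotypes = geno, snp_ids = snp_ids, snp_chroms = chroms, maf = maf)
}

#' Simulate clinico-pathological covariates
#'
#' Six prognosticator-like columns in the mould of non-muscle invasive
#' bladder cancer staging: `stage` (T1-like vs Ta-like), `grade` (high),
#' `multiple` (more than one tumour), `size` (> 3 cm-like), `cis`
#' (concomitant carcinoma in situ, rare), and standardized `age`.
#'
#' @param n patients.
#' @param prevalence named binary-covariate prevalences.
#' @return N x 6 numeric matrix.
#' @export
simulate_covariates <- function(n, prevalence = c(stage = 0.3, grade = 0.25,
                                                  multiple = 0.35,
                                                  size = 0.25, cis = 0.05)) {
  m <- cbind(stage = rbinom(n, 1, prevalence[["stage"]]),
             grade = rbinom(n, 1, prevalence[["grade"]]),
             multiple = rbinom(n, 1, prevalence[["multiple"]]),
             size = rbinom(n, 1, prevalence[["size"]]),
             cis = rbinom(n, 1, prevalence[["cis"]]),
             age = rnorm(n))
  m
}

#' Simulate discrete-time outcomes from the sequential threshold model
#'
#' Builds the liability-scale linear predictor, then walks each patient
#' through intervals `k = 1..K`: independent censoring with probability
#' `censor_rate` is checked first, then the event occurs with probability
#' `1 - pnorm(gamma[k] - eta)`; survivors of all K intervals are censored
#' at the end of follow-up.  Causal SNP effects are rescaled so the
#' realized SNP variance hits the liability-scale target
#' `snp_h2 * (1 + var(X beta)) / (1 - snp_h2)` (residual variance 1).
#'
#' @param genotypes N x P dosage matrix (complete) or `NULL`.
#' @param covariates N x Q matrix or `NULL`.
#' @param gamma true K-vector of cutoffs.
#' @param cpp_effects true covariate effects (length Q) or `NULL`.
#' @param snp_h2 target liability-scale SNP variance fraction in \[0, 1).
#' @param n_causal number of causal markers.
#' @param censor_rate per-interval independent censoring probability.
#' @param boundaries finite time boundaries; default 12-unit spacing.
#' @return list with `time`, `event`, `truth` (true effects, causal
#'   indices, cutoffs, boundaries, per-patient event/censor interval).
#' @export
simulate_outcomes <- function(genotypes = NULL, covariates = NULL, gamma,
                              cpp_effects = NULL, snp_h2 = 0, n_causal = 0,
                              censor_rate = 0, boundaries = NULL) {
  K <- length(gamma)
  stopifnot(snp_h2 >= 0, snp_h2 < 1, censor_rate >= 0, censor_rate < 1)
  n <- if (!is.null(genotypes)) nrow(genotypes)
       else if (!is.null(covariates)) nrow(covariates)
       else stop("need genotypes or covariates to size the cohort")
  if (is.null(boundaries)) boundaries <- c(0, 12 * seq_len(K - 1), Inf)

  eta_cpp <- rep(0, n)
  if (!is.null(covariates) && !is.null(cpp_effects))
    eta_cpp <- drop(sweep(covariates, 2, colMeans(covariates)) %*% cpp_effects)

  snp_effects <- NULL
  causal <- integer(0)
  eta_snp <- rep(0, n)
  if (!is.null(genotypes) && n_causal > 0 && snp_h2 > 0) {
    p <- ncol(genotypes)
    causal <- sort(sample.int(p, n_causal))
    raw <- rnorm(n_causal)
    Gc <- sweep(genotypes[, causal, drop = FALSE], 2,
                colMeans(genotypes[, causal, drop = FALSE]))
    g <- drop(Gc %*% raw)
    target <- snp_h2 * (1 + var(eta_cpp)) / (1 - snp_h2)
    scl <- sqrt(target / max(var(g), 1e-12))
    snp_effects <- rep(0, p)
    snp_effects[causal] <- raw * scl
    eta_snp <- g * scl
  }
  eta <- eta_cpp + eta_snp

  surv_p <- outer(eta, gamma, function(e, g) pnorm(g - e))  # N x K
  event <- integer(n)
  time <- numeric(n)
  event_interval <- rep(NA_integer_, n)
  censor_interval <- rep(NA_integer_, n)
  b <- boundaries
  lower <- b[-length(b)]
  width <- pmin(b[-1], lower + 12) - lower  # open last interval: 12 units
  end_time <- b[K] + 12  # beyond the last finite boundary
  if (is.finite(b[K + 1])) end_time <- b[K + 1]
  for (i in seq_len(n)) {
    done <- FALSE
    for (k in seq_len(K)) {
      # a continuous time within the interval keeps event-time quantiles
      # tie-free, as in real follow-up data
      t_in <- lower[k] + runif(1, 0.05, 0.95) * width[k]
      if (censor_rate > 0 && runif(1) < censor_rate) {
        time[i] <- t_in; event[i] <- 0L
        censor_interval[i] <- k
        done <- TRUE; break
      }
      if (runif(1) >= surv_p[i, k]) {
        time[i] <- t_in; event[i] <- 1L
        event_interval[i] <- k
        done <- TRUE; break
      }
    }
    if (!done) { time[i] <- end_time; event[i] <- 0L }
  }
  list(time = time, event = event,
       truth = list(eta = eta, gamma = gamma, boundaries = boundaries,
                    cpp_effects = cpp_effects, snp_effects = snp_effects,
                    causal = causal, event_interval = event_interval,
                    censor_interval = censor_interval))
}

#' Simulate a full synthetic cohort
#'
#' One call producing genotypes, covariates and outcomes with preset
#' survival shapes: `"tfr"` emulates a recurrence-like outcome (K = 9
#' intervals, roughly a third of patients with an event, front-loaded
#' hazard, heavy censoring) and `"tp"` a progression-like outcome (K = 4,
#' under a tenth with an event).  All presets can be overridden.
#'
#' @param preset `"tfr"` or `"tp"`.
#' @param n,p patients and markers.
#' @param cpp_effects true covariate effects (length 6, see
#'   [simulate_covariates()]); 0 = null covariates.
#' @param snp_h2,n_causal SNP architecture on the liability scale.
#' @param gamma,boundaries override the preset cutoffs / time grid.
#' @param censor_rate per-interval loss-to-follow-up probability.
#' @param maf_range,ld_block_size,ld_rho,missing_rate genotype controls.
#' @param seed RNG seed; identical arguments give identical cohorts.
#' @return an `st_cohort`; `attr(, "truth")` holds the generating values.
#' @export
simulate_cohort <- function(preset = c("tfr", "tp"), n = 822, p = 2000,
                            cpp_effects = c(stage = 0.5, grade = 0.4,
                                            multiple = 0.3, size = 0.3,
                                            cis = 0.6, age = 0.2),
                            snp_h2 = 0.01, n_causal = 100,
                            gamma = NULL, boundaries = NULL,
                            censor_rate = 0.02,
                            maf_range = c(0.05, 0.5), ld_block_size = 1,
                            ld_rho = 0, missing_rate = 0, seed = 1L) {
  preset <- match.arg(preset)
  n_causal <- min(n_causal, p)
  set.seed(seed)
  if (is.null(gamma)) {
    gamma <- switch(preset,
      # per-interval event probabilities at eta = 0, calibrated so the
      # default cohort shows ~33% events / ~52% end-of-study censoring
      # (recurrence-like) and ~9% events (progression-like) once the
      # default covariate/SNP liability heterogeneity is accounted for
      tfr = qnorm(1 - c(0.112, 0.064, 0.048, 0.040, 0.032, 0.024,
                        0.020, 0.016, 0.016)),
      tp = qnorm(1 - c(0.026, 0.019, 0.015, 0.011)))
  }
  K <- length(gamma)
  if (is.null(boundaries)) {
    boundaries <- switch(preset,
      tfr = c(0, 3, 6, 12, 18, 24, 36, 48, 72, Inf),
      tp = c(0, 12, 24, 60, Inf))
    if (length(boundaries) != K + 1)
      boundaries <- c(0, 12 * seq_len(K - 1), Inf)
  }
  sg <- if (p > 0)
    simulate_genotypes(n, p, maf_range, ld_block_size, ld_rho, missing_rate)
  covs <- simulate_covariates(n)
  geno_complete <- if (p > 0 && missing_rate > 0)
    impute_missing(sg$genotypes, "mode") else if (p > 0) sg$genotypes
  out <- simulate_outcomes(genotypes = geno_complete, covariates = covs,
                           gamma = gamma, cpp_effects = cpp_effects,
                           snp_h2 = snp_h2, n_causal = n_causal,
                           censor_rate = censor_rate,
                           boundaries = boundaries)
  cohort <- make_cohort(time = out$time, event = out$event,
                        genotypes = if (p > 0) sg$genotypes,
                        covariates = covs,
                        snp_ids = if (p > 0) sg$snp_ids,
                        snp_chroms = if (p > 0) sg$snp_chroms)
  attr(cohort, "truth") <- c(out$truth, list(maf = if (p > 0) sg$maf,
                                             preset = preset, seed = seed))
  cohort
}
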