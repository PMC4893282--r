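# AUC, liability-scale R2, cross-validation, heritability, decomposition.

test_that("AUC handles perfect separation, ties and mixed cases", {
  expect_equal(auc_roc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc_roc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  # 4 event-censored pairs, 2 concordant
  expect_equal(auc_roc(c(3, 1, 2, 4), c(0, 1, 0, 1)), 0.5)
  expect_error(auc_roc(1:4, rep(1, 4)), "both")
})

test_that("AUC equals brute-force pair enumeration", {
  set.seed(14)
  for (i in 1:30) {
    n <- sample(5:200, 1)
    score <- sample(seq(-2, 2, by = 0.25), n, replace = TRUE)  # forces ties
    label <- rbinom(n, 1, 0.4)
    if (length(unique(label)) < 2) next
    expect_identical(auc_roc(score, label), brute_auc(score, label))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  score <- rnorm(80)
  label <- rbinom(80, 1, 0.5)
  expect_equal(auc_roc(score, label),
               as.numeric(pROC::auc(pROC::roc(label, score, quiet = TRUE))))
})

test_that("liability R2 follows var/(var+1) exactly", {
  expect_equal(r2_probit(c(0, 1, 2)), 0.5)      # sample var 1
  expect_equal(r2_probit(rep(3, 5)), 0)
  eta <- rnorm(50)
  expect_equal(r2_probit(eta), var(eta) / (var(eta) + 1))
  # location invariance and scale law
  expect_equal(r2_probit(eta + 100), r2_probit(eta))
  cc <- 2.5
  v <- var(eta)
  expect_equal(r2_probit(cc * eta), cc^2 * v / (cc^2 * v + 1))
})

test_that("cross-validation stratifies folds and reports per-fold results", {
  co <- tiny_cohort(n = 150, p = 20, seed = 2)
  cv <- cv_seqthresh(co, K = 2, model = "cpp", n_folds = 3,
                     control = quick_control(n_iter = 80, n_burnin = 30))
  expect_equal(nrow(cv$per_fold), 3)
  expect_true(all(cv$per_fold$auc >= 0 & cv$per_fold$auc <= 1,
                  na.rm = TRUE))
  expect_true(all(cv$per_fold$r2_probit >= 0 & cv$per_fold$r2_probit < 1))
  # stratification balances events across folds (folds are stored in
  # canonical id-sorted patient order)
  ev_sorted <- co$event[order(co$patient_ids)]
  ev_per_fold <- table(cv$folds[ev_sorted == 1])
  expect_lte(max(ev_per_fold) - min(ev_per_fold), 1)
})

test_that("fold assignment and CV results ignore patient row order", {
  co <- tiny_cohort(n = 120, p = 15, seed = 6)
  perm <- sample(seq_along(co$patient_ids))
  co_shuf <- seqthresh:::subset_cohort(co, perm)
  ctl <- quick_control(n_iter = 80, n_burnin = 30)
  g <- build_grid(co$time, co$event, 2)
  cv1 <- cv_seqthresh(co, grid = g, model = "cpp", n_folds = 2,
                      control = ctl)
  cv2 <- cv_seqthresh(co_shuf, grid = g, model = "cpp", n_folds = 2,
                      control = ctl)
  expect_identical(cv1$auc_mean, cv2$auc_mean)
  expect_identical(cv1$r2_mean, cv2$r2_mean)
})

test_that("heritability is the SNP-only cross-validated R2", {
  co <- tiny_cohort(n = 150, p = 25, seed = 3,
                    snp_h2 = 0.2, n_causal = 10)
  cv <- cv_seqthresh(co, K = 2, model = "snp", n_folds = 2,
                     control = quick_control(n_iter = 100, n_burnin = 40))
  expect_identical(heritability(cv), cv$r2_mean)
  expect_identical(cv$heritability_estimate, cv$r2_mean)
  cv_cpp <- cv_seqthresh(co, K = 2, model = "cpp", n_folds = 2,
                         control = quick_control(n_iter = 60,
                                                 n_burnin = 20))
  expect_error(heritability(cv_cpp), "SNP-only")
  # whole-sample variant from a fitted object
  f <- seqthresh_fit(co, K = 2, model = "snp",
                     control = quick_control(n_iter = 100, n_burnin = 40))
  expect_identical(heritability(f), r2_probit(f$eta))
})

test_that("decomposing the clinical prediction onto SNPs is deterministic
           and near its ceiling under constructed confounding", {
  # one covariate IS a SNP's dosage: the SNPs must explain most of the
  # clinical prediction
  set.seed(16)
  n <- 200
  sg <- simulate_genotypes(n, 25, maf_range = c(0.2, 0.5))
  covs <- cbind(conf = sg$genotypes[, 1], age = rnorm(n))
  out <- simulate_outcomes(covariates = covs, gamma = qnorm(1 - c(0.2, 0.15)),
                           cpp_effects = c(0.8, 0.3), censor_rate = 0.05)
  co <- make_cohort(out$time, out$event, genotypes = sg$genotypes,
                    covariates = covs)
  ctl <- quick_control(n_iter = 200, n_burnin = 80)
  fit <- seqthresh_fit(co, K = 2, model = "cpp", control = ctl)
  d1 <- decompose_cpp_prediction(co, fit, n_folds = 2, seed = 4)
  d2 <- decompose_cpp_prediction(co, fit, n_folds = 2, seed = 4)
  expect_identical(d1$r2_mean, d2$r2_mean)
  expect_gt(d1$r2_mean, 0.3)

  # independence: null covariate effects unrelated to the SNPs
  co_null <- tiny_cohort(n = 400, p = 30, seed = 17,
                         cpp_effects = c(0.8, 0.4, 0, 0, 0, 0.3),
                         snp_h2 = 0, n_causal = 0)
  fit_null <- seqthresh_fit(co_null, K = 2, model = "cpp", control = ctl)
  d_null <- decompose_cpp_prediction(co_null, fit_null, n_folds = 2,
                                     seed = 4)
  expect_lt(d_null$r2_mean, 0.1)
  expect_lt(d_null$r2_mean, d1$r2_mean)
})

test_that("a fold without both classes yields a missing AUC with warning", {
  # 2 events only -> with 4 folds some test sets lack events
  set.seed(18)
  n <- 40
  time <- runif(n, 1, 40)
  event <- c(1, 1, rep(0, n - 2))
  covs <- cbind(x = rnorm(n))
  co <- make_cohort(time, event, covariates = covs)
  g <- interval_grid(c(0, 20, Inf))
  w <- testthat::capture_warnings(
    cv <- cv_seqthresh(co, grid = g, model = "cpp", n_folds = 4,
                       control = quick_control(n_iter = 60, n_burnin = 20)))
  expect_true(any(grepl("single outcome class", w)))
  expect_true(any(is.na(cv$per_fold$auc)))
  expect_false(is.na(cv$auc_mean))
})
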