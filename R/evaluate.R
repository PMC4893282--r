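# Cross-validated predictive ability: AUC-ROC, liability-scale R2, the
# SNP-only heritability estimate, and the decomposition of the clinical
# prediction onto SNPs.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Patient-level discrimination of the ever-event indicator by a score:
#' the probability that a random event patient scores above a random
#' censored patient, counting ties as 1/2.
#'
#' @param score per-patient predictor (e.g. the linear predictor eta).
#' @param label per-patient 0/1 event indicator; both classes must be
#'   present.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(score, label) {
  stopifnot(length(score) == length(label))
  pos <- score[label == 1]
  neg <- score[label == 0]
  if (length(pos) == 0 || length(neg) == 0)
    stop("AUC undefined: both event and censored patients are required")
  # rank-sum form of the Mann-Whitney U statistic
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

#' Liability-scale determination coefficient
#'
#' Proportion of liability variance explained by the predictions in a test
#' set: `var(eta) / (var(eta) + sigma2_e)` with the residual variance fixed
#' at 1 and the sample variance using the n - 1 denominator.  Constant
#' predictions return 0.
#'
#' @param eta test-set linear predictors (>= 2 values).
#' @param sigma2_e residual variance; 1 in the threshold model.
#' @return value in \[0, 1).
#' @export
r2_probit <- function(eta, sigma2_e = 1) {
  stopifnot(length(eta) >= 2)
  v <- var(eta)
  if (!is.finite(v) || v == 0) return(0)
  v / (v + sigma2_e)
}

# Event-stratified fold assignment, reproducible given the seed and
# invariant to patient row order: within each class, patients are taken in
# canonical (id-sorted) order before the seeded shuffle, so the same
# patient lands in the same fold however the rows are arranged.
stratified_folds <- function(event, n_folds, seed, ids = NULL) {
  n <- length(event)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  folds <- integer(n)
  set.seed(seed)
  for (cls in c(1, 0)) {
    idx <- which(event == cls)
    idx <- idx[order(ids[idx])]
    folds[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Cross-validated predictive ability
#'
#' Partitions patients into event-stratified folds, refits the model on
#' each training set (the interval grid is fixed across folds), scores the
#' held-out patients with the posterior-mean linear predictor, and reports
#' per-fold and averaged AUC and liability-scale R2.  A fold whose test set
#' lacks one of the classes gets a missing AUC (excluded from the mean with
#' a warning).
#'
#' @param cohort an `st_cohort` (genotypes imputed for SNP models).
#' @param grid,K interval grid or number of intervals (grid is built once
#'   on the full cohort).
#' @param model `"cpp"`, `"snp"` or `"cpp_snp"`.
#' @param n_folds number of folds; 10 is the whole-cohort convention, 2 the
#'   low-event fallback.
#' @param control an [st_control()]; fold f is fitted with seed
#'   `control$seed + f`.
#' @param seed fold-assignment seed (default `control$seed`).
#' @return an `st_cv` report with `per_fold`, `auc_mean`, `auc_sd`,
#'   `r2_mean`, `r2_sd`, and for `model = "snp"` the `heritability_estimate`.
#' @export
cv_seqthresh <- function(cohort, grid = NULL, K = NULL,
                         model = c("cpp", "snp", "cpp_snp"),
                         n_folds = 10, control = st_control(),
                         seed = control$seed) {
  stopifnot(inherits(cohort, "st_cohort"), n_folds >= 2)
  model <- match.arg(model)
  # canonical (id-sorted) patient order: results are invariant to how the
  # cohort rows happen to be arranged
  ord <- order(cohort$patient_ids)
  cohort <- subset_cohort(cohort, ord)
  if (is.null(grid)) grid <- build_grid(cohort$time, cohort$event, K)
  folds <- stratified_folds(cohort$event, n_folds, seed, cohort$patient_ids)
  per_fold <- data.frame(fold = seq_len(n_folds), auc = NA_real_,
                         r2_probit = NA_real_)
  eta_all <- rep(NA_real_, length(cohort$time))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    train <- subset_cohort(cohort, tr)
    test <- subset_cohort(cohort, !tr)
    ctl <- control
    ctl$seed <- control$seed + f
    fit <- seqthresh_fit(train, grid = grid, model = model, control = ctl)
    eta <- predict(fit, newdata = test)
    eta_all[!tr] <- eta
    if (length(unique(test$event)) < 2) {
      warning("fold ", f, " has a single outcome class; AUC recorded ",
              "as missing")
    } else {
      per_fold$auc[f] <- auc_roc(eta, test$event)
    }
    per_fold$r2_probit[f] <- r2_probit(eta)
  }
  out <- structure(list(per_fold = per_fold,
                        auc_mean = mean(per_fold$auc, na.rm = TRUE),
                        auc_sd = sd(per_fold$auc, na.rm = TRUE),
                        r2_mean = mean(per_fold$r2_probit),
                        r2_sd = sd(per_fold$r2_probit),
                        model_label = model, n_folds = n_folds,
                        folds = folds, eta_test = eta_all,
                        heritability_estimate = NA_real_),
                   class = "st_cv")
  if (model == "snp") out$heritability_estimate <- out$r2_mean
  out
}

# Row subset of a cohort.
subset_cohort <- function(cohort, idx) {
  make_cohort(time = cohort$time[idx], event = cohort$event[idx],
              genotypes = if (!is.null(cohort$genotypes))
                cohort$genotypes[idx, , drop = FALSE],
              covariates = if (!is.null(cohort$covariates))
                cohort$covariates[idx, , drop = FALSE],
              patient_ids = cohort$patient_ids[idx],
              snp_ids = cohort$snp_ids, snp_chroms = cohort$snp_chroms)
}

#' @export
print.st_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, model = %s\n", x$n_folds,
              x$model_label))
  cat(sprintf("  AUC      = %.3f (%.3f)\n", x$auc_mean, x$auc_sd))
  cat(sprintf("  R2probit = %.4f (%.4f)\n", x$r2_mean, x$r2_sd))
  if (x$model_label == "snp")
    cat(sprintf("  heritability estimate h2 = %.4f\n",
                x$heritability_estimate))
  invisible(x)
}

#' SNP heritability on the liability scale
#'
#' The fraction of liability variance attributable to the modelled common
#' SNPs, estimated as the SNP-only model's liability-scale R2 — from the
#' cross-validated mean (default) or from the whole-sample fit.  A
#' lower-bound-style estimate: finite samples and shrinkage bias it
#' downward.
#'
#' @param x an `st_cv` from `model = "snp"`, or a `seqthresh` SNP-model fit
#'   (whole-sample variant).
#' @param ... unused.
#' @return heritability estimate in \[0, 1).
#' @export
heritability <- function(x, ...) UseMethod("heritability")

#' @rdname heritability
#' @export
heritability.st_cv <- function(x, ...) {
  if (x$model_label != "snp")
    stop("heritability is estimated from the SNP-only model; got '",
         x$model_label, "'")
  x$r2_mean
}

#' @rdname heritability
#' @export
heritability.seqthresh <- function(x, ...) {
  if (x$model != "snp")
    stop("heritability is estimated from the SNP-only model; got '",
         x$model, "'")
  r2_probit(x$eta)
}

#' How much of the clinical prediction do SNPs explain?
#'
#' Regresses the covariate-only liability prediction `X beta-hat` on the
#' SNP dosages with a Gaussian-response Bayesian LASSO (identity link,
#' residual variance free), under the same cross-validation scheme, and
#' reports `var(pred) / (var(pred) + sigma2-hat)` on the held-out patients.
#' Large values mean the SNPs track the clinical prediction itself, which
#' explains why adding them to the joint model can fail to help.
#'
#' @param cohort an `st_cohort` with complete genotypes.
#' @param cpp_fit a covariate-only `seqthresh` fit on the same cohort.
#' @param n_folds cross-validation folds.
#' @param n_iter,n_burnin Gaussian LASSO chain settings.
#' @param seed fold and chain seed.
#' @return an `st_decomp` list with `per_fold`, `r2_mean`, `r2_sd`.
#' @export
decompose_cpp_prediction <- function(cohort, cpp_fit, n_folds = 10,
                                     n_iter = 600, n_burnin = 200,
                                     seed = 1L) {
  stopifnot(inherits(cpp_fit, "seqthresh"))
  if (cpp_fit$model != "cpp")
    stop("cpp_fit must be a covariate-only ('cpp') model fit")
  if (!identical(cpp_fit$patient_ids, cohort$patient_ids))
    stop("patient ids of the fit and the cohort do not match")
  if (is.null(cohort$genotypes) || anyNA(cohort$genotypes))
    stop("complete (imputed) genotypes are required")
  y <- cpp_fit$eta
  G <- sweep(cohort$genotypes, 2, colMeans(cohort$genotypes))
  folds <- stratified_folds(cohort$event, n_folds, seed, cohort$patient_ids)
  r2 <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    mod <- lasso_gaussian(y[tr], G[tr, , drop = FALSE], n_iter = n_iter,
                          n_burnin = n_burnin, seed = seed + f)
    pred <- drop(G[!tr, , drop = FALSE] %*% mod$effects)
    v <- var(pred)
    r2[f] <- if (!is.finite(v) || v == 0) 0 else v / (v + mod$sigma2)
  }
  structure(list(per_fold = data.frame(fold = seq_len(n_folds), r2 = r2),
                 r2_mean = mean(r2), r2_sd = sd(r2), n_folds = n_folds),
            class = "st_decomp")
}

#' @export
print.st_decomp <- function(x, ...) {
  cat(sprintf(paste0("Clinical-prediction decomposition (%d-fold CV): ",
                     "R2 = %.4f (%.4f)\n"),
              x$n_folds, x$r2_mean, x$r2_sd))
  invisible(x)
}
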