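# Marker QC: sex-chromosome exclusion, call-rate and MAF filtering, greedy
# windowed LD pruning, and missing-genotype imputation.

#' Filter markers on chromosome, call rate and minor allele frequency
#'
#' Applies the three filters in a fixed order: (1) markers on sex
#' chromosomes, (2) call rate below `callrate_min`, (3) minor allele
#' frequency below `maf_min`.  MAF is computed on non-missing calls as
#' `min(p, 1 - p)` with `p = mean(dosage) / 2`; an all-missing marker has
#' call rate 0 and is removed at the call-rate stage.
#'
#' @param genotypes N x P dosage matrix in \{0, 1, 2, NA\}.
#' @param snp_chroms chromosome label per marker (optional; no
#'   sex-chromosome removal when absent).
#' @param callrate_min minimum fraction of non-missing calls, default 0.95.
#' @param maf_min minimum minor allele frequency, default 0.02.
#' @param sex_chroms chromosome labels treated as sex chromosomes.
#' @return list with the filtered `genotypes`, the logical `keep` vector
#'   over input columns, and an `st_qc_report` with per-stage counts.
#' @export
filter_markers <- function(genotypes, snp_chroms = NULL,
                           callrate_min = 0.95, maf_min = 0.02,
                           sex_chroms = c("X", "Y", "XY")) {
  stopifnot(callrate_min >= 0, callrate_min <= 1, maf_min >= 0, maf_min <= 1)
  genotypes <- as.matrix(genotypes)
  p_in <- ncol(genotypes)
  keep <- rep(TRUE, p_in)

  n_sex <- 0L
  if (!is.null(snp_chroms)) {
    drop_sex <- toupper(as.character(snp_chroms)) %in% toupper(sex_chroms)
    n_sex <- sum(drop_sex)
    keep[drop_sex] <- FALSE
  }

  callrate <- colMeans(!is.na(genotypes))
  drop_cr <- keep & callrate < callrate_min
  n_cr <- sum(drop_cr)
  keep[drop_cr] <- FALSE

  p_alt <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  drop_maf <- keep & (is.na(maf) | maf < maf_min)
  n_maf <- sum(drop_maf)
  keep[drop_maf] <- FALSE

  report <- structure(list(n_input_snps = p_in,
                           n_removed_sex_chrom = n_sex,
                           n_removed_callrate = n_cr,
                           n_removed_maf = n_maf,
                           n_removed_ld = 0L,
                           n_retained = sum(keep),
                           thresholds_used = list(callrate_min = callrate_min,
                                                  maf_min = maf_min,
                                                  ld_r2_max = NA_real_)),
                      class = "st_qc_report")
  list(genotypes = genotypes[, keep, drop = FALSE], keep = keep,
       report = report)
}

#' @export
print.st_qc_report <- function(x, ...) {
  cat("Marker QC report\n")
  cat("  input markers:        ", x$n_input_snps, "\n")
  cat("  removed sex chrom:    ", x$n_removed_sex_chrom, "\n")
  cat("  removed call rate <", x$thresholds_used$callrate_min, ":",
      x$n_removed_callrate, "\n")
  cat("  removed MAF <", x$thresholds_used$maf_min, ":", x$n_removed_maf, "\n")
  if (x$n_removed_ld > 0 || !is.na(x$thresholds_used$ld_r2_max))
    cat("  removed LD r2 >=", x$thresholds_used$ld_r2_max, ":",
        x$n_removed_ld, "\n")
  cat("  retained:             ", x$n_retained, "\n")
  invisible(x)
}

#' Greedy windowed LD pruning
#'
#' Visits markers in order of increasing missingness (ties broken by input
#' order) and retains a marker only if its squared Pearson correlation of
#' dosages (pairwise-complete observations) with every already-retained
#' marker within `window` input positions is below `r2_max`.  Keeping the
#' less-missing member of a correlated pair prioritizes markers with less
#' missing data.  Zero-variance markers are dropped with a warning
#' (correlation undefined).
#'
#' @param genotypes N x P dosage matrix (already call-rate/MAF filtered).
#' @param r2_max squared-correlation threshold, default 0.2: retained
#'   in-window pairs satisfy r2 < r2_max.
#' @param window maximum input-index distance at which pairs are compared;
#'   `Inf` compares all pairs.
#' @param step reserved for sliding-window schedules; the greedy pruner
#'   compares against all retained markers within `window`, so `step` is
#'   accepted for interface compatibility and ignored.
#' @return sorted integer vector of retained column indices.
#' @export
ld_prune <- function(genotypes, r2_max = 0.2, window = 250, step = NULL) {
  stopifnot(r2_max > 0, r2_max <= 1)
  genotypes <- as.matrix(genotypes)
  p <- ncol(genotypes)
  if (p == 0) return(integer(0))
  miss <- colMeans(is.na(genotypes))
  vars <- apply(genotypes, 2, function(x) stats::var(x, na.rm = TRUE))
  zerovar <- is.na(vars) | vars == 0
  if (any(zerovar))
    warning("dropping ", sum(zerovar),
            " zero-variance marker(s): LD undefined")
  ord <- order(miss, seq_len(p))
  ord <- ord[!zerovar[ord]]
  retained <- integer(0)
  for (cand in ord) {
    nb <- retained[abs(retained - cand) <= window]
    ok <- TRUE
    for (r in nb) {
      r2 <- stats::cor(genotypes[, cand], genotypes[, r],
                       use = "pairwise.complete.obs")^2
      if (!is.na(r2) && r2 >= r2_max) { ok <- FALSE; break }
    }
    if (ok) retained <- c(retained, cand)
  }
  sort(retained)
}

# Per-marker modal dosage; ties resolved toward the lower dosage.
dosage_mode <- function(x) {
  x <- x[!is.na(x)]
  counts <- tabulate(x + 1L, nbins = 3L)
  which.max(counts) - 1
}

#' Impute missing genotype calls
#'
#' Replaces every missing dosage so downstream sampling sees a complete
#' matrix.  Strategies: `"mode"` (most frequent dosage per marker, ties to
#' the lower dosage), `"mean_rounded"` (per-marker mean rounded to the
#' nearest of 0/1/2), `"forest"` (per-marker random forest trained on the
#' most-correlated neighbouring markers).
#'
#' @param genotypes N x P dosage matrix.
#' @param strategy imputation strategy.
#' @param n_neighbors,ntree forest strategy: number of predictor markers and
#'   trees.
#' @param seed optional RNG seed for the forest strategy.
#' @return complete dosage matrix; non-missing cells are never altered.
#' @export
impute_missing <- function(genotypes,
                           strategy = c("mode", "mean_rounded", "forest"),
                           n_neighbors = 5, ntree = 50, seed = NULL) {
  strategy <- match.arg(strategy)
  genotypes <- as.matrix(genotypes)
  all_miss <- colSums(!is.na(genotypes)) == 0
  if (any(all_miss))
    stop("marker(s) with all calls missing (column ",
         which(all_miss)[1], "); apply call-rate filtering first")
  miss_cols <- which(colSums(is.na(genotypes)) > 0)
  if (length(miss_cols) == 0) return(genotypes)

  if (strategy == "mode") {
    for (j in miss_cols) {
      x <- genotypes[, j]
      genotypes[is.na(x), j] <- dosage_mode(x)
    }
  } else if (strategy == "mean_rounded") {
    for (j in miss_cols) {
      x <- genotypes[, j]
      m <- pmin(pmax(round(mean(x, na.rm = TRUE)), 0), 2)
      genotypes[is.na(x), j] <- m
    }
  } else {
    if (!requireNamespace("randomForest", quietly = TRUE))
      stop("strategy 'forest' requires the randomForest package")
    if (!is.null(seed)) set.seed(seed)
    # mode-filled working copy supplies complete predictors
    filled <- genotypes
    for (j in which(colSums(is.na(filled)) > 0))
      filled[is.na(filled[, j]), j] <- dosage_mode(filled[, j])
    for (j in miss_cols) {
      x <- genotypes[, j]
      na_rows <- is.na(x)
      others <- setdiff(seq_len(ncol(filled)), j)
      if (length(others) == 0 || sum(!na_rows) < 3) {
        genotypes[na_rows, j] <- dosage_mode(x)
        next
      }
      cors <- abs(suppressWarnings(
        cor(filled[, others, drop = FALSE], filled[, j])))
      cors[is.na(cors)] <- 0
      nb <- others[order(-cors)][seq_len(min(n_neighbors, length(others)))]
      train_x <- filled[!na_rows, nb, drop = FALSE]
      if (length(unique(x[!na_rows])) < 2) {
        genotypes[na_rows, j] <- x[!na_rows][1]
        next
      }
      rf <- randomForest::randomForest(
        x = train_x, y = factor(x[!na_rows], levels = 0:2), ntree = ntree)
      pred <- predict(rf, filled[na_rows, nb, drop = FALSE])
      genotypes[na_rows, j] <- as.numeric(as.character(pred))
    }
  }
  genotypes
}

#' Run the full marker QC pipeline
#'
#' Convenience wrapper chaining [filter_markers()], [ld_prune()] and
#' [impute_missing()] on a cohort, returning the reduced cohort and a
#' combined QC report.
#'
#' @param cohort an `st_cohort` with genotypes.
#' @param callrate_min,maf_min,sex_chroms passed to [filter_markers()].
#' @param ld_r2_max,ld_window passed to [ld_prune()]; `ld_r2_max = NULL`
#'   skips pruning.
#' @param impute_strategy passed to [impute_missing()]; `NULL` skips
#'   imputation.
#' @param force_include marker ids re-added after pruning (e.g. markers from
#'   prior association evidence), if they survived the marker filters.
#' @param seed RNG seed for the forest imputation strategy.
#' @return list with the QC'd `cohort` and the `report`.
#' @export
qc_cohort <- function(cohort, callrate_min = 0.95, maf_min = 0.02,
                      sex_chroms = c("X", "Y", "XY"),
                      ld_r2_max = 0.2, ld_window = 250,
                      impute_strategy = "mode", force_include = NULL,
                      seed = NULL) {
  stopifnot(inherits(cohort, "st_cohort"), !is.null(cohort$genotypes))
  flt <- filter_markers(cohort$genotypes, cohort$snp_chroms,
                        callrate_min = callrate_min, maf_min = maf_min,
                        sex_chroms = sex_chroms)
  geno <- flt$genotypes
  report <- flt$report
  if (!is.null(ld_r2_max)) {
    kept <- ld_prune(geno, r2_max = ld_r2_max, window = ld_window)
    if (!is.null(force_include)) {
      forced <- which(colnames(geno) %in% force_include)
      kept <- sort(union(kept, forced))
    }
    report$n_removed_ld <- ncol(geno) - length(kept)
    report$thresholds_used$ld_r2_max <- ld_r2_max
    geno <- geno[, kept, drop = FALSE]
  }
  report$n_retained <- ncol(geno)
  if (!is.null(impute_strategy))
    geno <- impute_missing(geno, strategy = impute_strategy, seed = seed)
  chroms <- cohort$snp_chroms
  if (!is.null(chroms))
    chroms <- chroms[match(colnames(geno), cohort$snp_ids)]
  out <- make_cohort(time = cohort$time, event = cohort$event,
                     genotypes = geno, covariates = cohort$covariates,
                     patient_ids = cohort$patient_ids,
                     snp_ids = colnames(geno), snp_chroms = chroms)
  list(cohort = out, report = report)
}
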