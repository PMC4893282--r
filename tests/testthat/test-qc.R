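# Marker QC: filtering stages, LD pruning, imputation.

test_that("marker filters apply in order with correct stage counts", {
  set.seed(7)
  n <- 20
  g <- cbind(
    sexchrom = rbinom(n, 2, 0.3),
    lowcall = c(rep(NA, 3), rbinom(n - 3, 2, 0.3)),   # call rate 0.85
    mono = rep(0, n),                                  # MAF 0
    rare = c(1, rep(0, n - 1)),                        # MAF 1/40 = 0.025
    common = rbinom(n, 2, 0.4),
    allmiss = rep(NA_real_, n))
  g[1, "common"] <- 1  # guard against a monomorphic draw
  chroms <- c("X", "1", "1", "1", "1", "2")
  res <- filter_markers(g, chroms, callrate_min = 0.95, maf_min = 0.02)
  r <- res$report
  expect_equal(r$n_input_snps, 6)
  expect_equal(r$n_removed_sex_chrom, 1)
  expect_equal(r$n_removed_callrate, 2)   # lowcall + allmiss (rate 0)
  expect_equal(r$n_removed_maf, 1)        # mono
  expect_equal(r$n_input_snps,
               r$n_removed_sex_chrom + r$n_removed_callrate +
                 r$n_removed_maf + r$n_retained)
  expect_setequal(colnames(res$genotypes), c("rare", "common"))
})

test_that("hand-computed allele frequency decides MAF retention", {
  # 20 patients, dosage sum 4, no missing: p = 4/40 = 0.1 -> retained
  g <- matrix(c(rep(1, 4), rep(0, 16)), ncol = 1)
  res <- filter_markers(g, callrate_min = 0.95, maf_min = 0.02)
  expect_equal(res$report$n_retained, 1)
  res2 <- filter_markers(g, callrate_min = 0.95, maf_min = 0.15)
  expect_equal(res2$report$n_removed_maf, 1)
})

test_that("filtering is idempotent", {
  set.seed(11)
  sg <- simulate_genotypes(50, 40, maf_range = c(0.01, 0.5),
                           missing_rate = 0.03)
  r1 <- filter_markers(sg$genotypes, sg$snp_chroms)
  r2 <- filter_markers(r1$genotypes,
                       sg$snp_chroms[r1$keep])
  expect_equal(r2$report$n_retained, r1$report$n_retained)
  expect_equal(r2$report$n_removed_maf + r2$report$n_removed_callrate +
                 r2$report$n_removed_sex_chrom, 0)
})

test_that("LD pruning keeps the less-missing member of a perfect pair", {
  set.seed(3)
  x <- rbinom(40, 2, 0.4)
  g <- cbind(a = x, b = x)
  g[1:5, "b"] <- NA           # 'a' has less missing data
  kept <- suppressWarnings(ld_prune(g, r2_max = 0.2))
  expect_identical(kept, 1L)
})

test_that("greedy pruning matches the exhaustive pairwise oracle", {
  for (s in 1:12) {
    set.seed(s)
    sg <- simulate_genotypes(60, 8, ld_block_size = 4, ld_rho = 0.6,
                             missing_rate = 0.05)
    g <- sg$genotypes
    for (r2m in c(0.2, 0.5)) {
      kept <- suppressWarnings(ld_prune(g, r2_max = r2m, window = Inf))
      expect_identical(kept, suppressWarnings(brute_ld_prune(g, r2m)),
                       info = paste("seed", s, "r2max", r2m))
      # retained pairs always satisfy the threshold
      if (length(kept) > 1)
        for (i in seq_along(kept)[-1]) for (j in seq_len(i - 1)) {
          r2 <- cor(g[, kept[i]], g[, kept[j]],
                    use = "pairwise.complete.obs")^2
          if (!is.na(r2)) expect_lt(r2, r2m)
        }
    }
  }
})

test_that("zero-variance markers are dropped from pruning with a warning", {
  g <- cbind(a = rbinom(30, 2, 0.4), flat = rep(1, 30))
  expect_warning(kept <- ld_prune(g, r2_max = 0.2), "zero-variance")
  expect_identical(kept, 1L)
})

test_that("imputation strategies fill all and only the missing cells", {
  g <- cbind(a = c(0, 0, 1, NA, 0, 0),
             b = c(2, 2, 2, NA, 2, 2),
             c = c(0, 1, 2, 0, NA, 1))
  for (s in c("mode", "mean_rounded")) {
    out <- impute_missing(g, s)
    expect_false(anyNA(out))
    expect_true(all(out %in% 0:2))
    # never alters observed cells
    expect_equal(out[!is.na(g)], g[!is.na(g)])
  }
  expect_equal(unname(impute_missing(g, "mode")[4, "a"]), 0)   # majority
  expect_equal(unname(impute_missing(g, "mode")[4, "b"]), 2)   # unanimous
  expect_equal(unname(impute_missing(g, "mean_rounded")[4, "b"]), 2)
  # tie in (0,0,1,1) resolves to the lower dosage
  tie <- matrix(c(0, 0, 1, 1, NA), ncol = 1)
  expect_equal(impute_missing(tie, "mode")[5, 1], 0)
  expect_error(impute_missing(cbind(rep(NA_real_, 4)), "mode"),
               "call-rate")
})

test_that("forest imputation recovers a perfectly correlated neighbour", {
  skip_if_not_installed("randomForest")
  set.seed(5)
  x <- rbinom(80, 2, 0.5)
  g <- cbind(a = x, b = x, c = rbinom(80, 2, 0.3))
  g[c(3, 10), "a"] <- NA
  out <- impute_missing(g, "forest", seed = 9)
  expect_equal(out[c(3, 10), "a"], x[c(3, 10)])
  expect_equal(out[!is.na(g)], g[!is.na(g)])
})

test_that("qc_cohort chains the stages and keeps the report consistent", {
  co <- simulate_cohort("tp", n = 80, p = 60, ld_block_size = 3,
                        ld_rho = 0.9, missing_rate = 0.02, seed = 8,
                        maf_range = c(0.1, 0.5))
  res <- suppressWarnings(qc_cohort(co, ld_r2_max = 0.3, ld_window = 50))
  r <- res$report
  expect_equal(r$n_input_snps,
               r$n_removed_sex_chrom + r$n_removed_callrate +
                 r$n_removed_maf + r$n_removed_ld + r$n_retained)
  expect_false(anyNA(res$cohort$genotypes))
  expect_lt(r$n_retained, r$n_input_snps)  # high-LD blocks must shrink
})
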