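# Shared fixtures and independent oracles.

quick_control <- function(n_iter = 300, n_burnin = 100, thin = 2, seed = 1,
                          ...) {
  st_control(n_iter = n_iter, n_burnin = n_burnin, thin = thin, seed = seed,
             ...)
}

# Pairwise-enumeration AUC (Mann-Whitney with half-credit ties).
brute_auc <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Per-patient recount of expanded records, written independently of
# expand_cohort: literal walk over intervals.
brute_expand <- function(time, event, boundaries) {
  K <- length(boundaries) - 1
  rec <- list()
  for (i in seq_along(time)) {
    t <- time[i]
    for (k in seq_len(K)) {
      lo <- boundaries[k]; hi <- boundaries[k + 1]
      if (event[i] == 1 && t > lo && t <= hi) {
        rec[[length(rec) + 1]] <- c(i, k, 1); break
      }
      if (event[i] == 1 && t == 0 && k == 1) {
        rec[[length(rec) + 1]] <- c(i, k, 1); break
      }
      if (t >= hi && is.finite(hi)) {
        rec[[length(rec) + 1]] <- c(i, k, 0)   # fully survived interval k
      } else break                             # censored inside interval k
    }
  }
  m <- do.call(rbind, rec)
  if (is.null(m)) m <- matrix(numeric(0), ncol = 3)
  data.frame(patient = m[, 1], interval = m[, 2], outcome = m[, 3])
}

# Exhaustive greedy LD pruning without windowing: visit in missingness
# order, keep iff r2 with every kept marker < r2_max.
brute_ld_prune <- function(geno, r2_max) {
  p <- ncol(geno)
  miss <- colMeans(is.na(geno))
  vars <- apply(geno, 2, function(x) var(x, na.rm = TRUE))
  ord <- order(miss, seq_len(p))
  ord <- ord[!(is.na(vars[ord]) | vars[ord] == 0)]
  kept <- integer(0)
  for (cand in ord) {
    ok <- TRUE
    for (r in kept) {
      r2 <- cor(geno[, cand], geno[, r], use = "pairwise.complete.obs")^2
      if (!is.na(r2) && r2 >= r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, cand)
  }
  sort(kept)
}

# Small deterministic cohort for interface tests.
tiny_cohort <- function(n = 120, p = 30, seed = 42, ...) {
  simulate_cohort("tp", n = n, p = p, seed = seed, ...)
}
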