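# Follow-up time discretization and person-interval expansion.
#
# Interval k is the half-open-left slice (b[k-1], b[k]] of the boundary
# sequence 0 = b[0] < b[1] < ... < b[K] = Inf.  A patient reaches interval k
# only by surviving intervals 1..k-1, so expansion yields one binary record
# per interval reached; the interval in which censoring occurs contributes
# no record (partial exposure is not treated as survival).

#' Construct an interval grid
#'
#' @param boundaries strictly increasing time points starting at 0; a finite
#'   last boundary is extended with `Inf` so the final interval is open.
#' @return an `st_grid` with `boundaries` and `K = length(boundaries) - 1`.
#' @export
interval_grid <- function(boundaries) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2) stop("need at least two boundaries")
  if (boundaries[1] != 0) stop("boundaries must start at 0")
  if (is.finite(boundaries[length(boundaries)]))
    boundaries <- c(boundaries, Inf)
  if (any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing")
  structure(list(boundaries = boundaries, K = length(boundaries) - 1L),
            class = "st_grid")
}

#' @export
print.st_grid <- function(x, ...) {
  cat("Interval grid: K =", x$K, "\n  boundaries:",
      paste(signif(x$boundaries, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Build an interval grid from the observed survival pattern
#'
#' Places the K - 1 interior boundaries at empirical quantiles of the
#' observed event times, splitting the events as evenly as possible across
#' intervals — an automatic analogue of choosing cut-points from the
#' Kaplan-Meier curve.  Recurrence-like outcomes conventionally use K = 9,
#' progression-like outcomes K = 4.
#'
#' @param time follow-up durations.
#' @param event 0/1 indicators.
#' @param K number of intervals (>= 1); requires at least K observed events.
#' @return an `st_grid`; every interval contains at least one event.
#' @export
build_grid <- function(time, event, K) {
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  et <- time[event == 1]
  if (length(et) < K)
    stop("only ", length(et), " events observed but K = ", K,
         " intervals requested; use a smaller K")
  if (K == 1) return(interval_grid(c(0, Inf)))
  qs <- quantile(et, probs = seq_len(K - 1) / K, names = FALSE, type = 7)
  b <- c(0, qs, Inf)
  if (any(diff(b) <= 0))
    stop("tied event-time quantiles produce duplicate boundaries; ",
         "use a smaller K")
  grid <- interval_grid(b)
  counts <- tabulate(interval_index(et, grid$boundaries), nbins = grid$K)
  if (any(counts == 0))
    stop("interval(s) ", paste(which(counts == 0), collapse = ", "),
         " contain no events; use a smaller K")
  grid
}

# Index k of the interval (b[k-1], b[k]] containing t; t = 0 maps to 1.
interval_index <- function(t, boundaries) {
  pmax(1L, findInterval(t, boundaries, left.open = TRUE))
}

#' Expand a cohort into person-interval binary records
#'
#' Each patient contributes one record per interval fully or terminally
#' reached.  An event patient whose time falls in interval `k*` contributes
#' records for intervals `1..k*` with outcomes `0, ..., 0, 1`.  A censored
#' patient contributes a 0-outcome record for every fully survived interval
#' only (the partial interval in which censoring occurs is dropped); a
#' patient censored at or beyond an interval's upper boundary has fully
#' survived it.
#'
#' @param time,event per-patient follow-up and indicator (or an `st_cohort`
#'   as `time`, in which case `event` is taken from it).
#' @param grid an `st_grid` (or K, from which a grid is built).
#' @return an `st_expanded` data.frame with columns `patient` (row index),
#'   `interval`, `outcome`, and attributes `K` and `n_records`.
#' @export
expand_cohort <- function(time, event = NULL, grid = NULL) {
  if (inherits(time, "st_cohort")) {
    event <- time$event
    time <- time$time
  }
  if (!inherits(grid, "st_grid")) grid <- build_grid(time, event, grid)
  b <- grid$boundaries
  K <- grid$K
  upper <- b[-1]
  n <- length(time)
  # records contributed: events -> interval of the event time; censored ->
  # number of finite upper boundaries at or below the censoring time
  k_event <- interval_index(time, b)
  k_surv <- vapply(time, function(t) sum(upper[is.finite(upper)] <= t), 0L)
  n_rec <- ifelse(event == 1, k_event, k_surv)
  if (any(event == 0 & time == 0))
    message(sum(event == 0 & time == 0),
            " patient(s) censored at time 0 contribute no records")
  pat <- rep(seq_len(n), n_rec)
  interval <- unlist(lapply(seq_len(n), function(i) seq_len(n_rec[i])),
                     use.names = FALSE)
  if (length(interval) == 0) interval <- integer(0)
  outcome <- integer(length(pat))
  # an event patient's last record carries outcome 1
  last_idx <- cumsum(n_rec)[event == 1 & n_rec > 0]
  outcome[last_idx] <- 1L
  out <- data.frame(patient = pat, interval = interval, outcome = outcome)
  attr(out, "K") <- K
  attr(out, "n_records") <- nrow(out)
  class(out) <- c("st_expanded", "data.frame")
  out
}

#' Conditional probability of surviving one interval
#'
#' Probability of passing interval k event-free given that it was reached:
#' `pnorm(gamma_k - eta)` with residual standard deviation fixed at 1.
#' Larger linear predictors mean higher event risk.
#'
#' @param gamma_k interval cutoff(s).
#' @param eta liability-scale linear predictor value(s).
#' @return survival probability in (0, 1), strictly decreasing in `eta`.
#' @export
sequential_probability <- function(gamma_k, eta) {
  pnorm(gamma_k - eta)
}

#' Likelihood of a patient's full interval sequence
#'
#' For an event in interval k: survive intervals 1..k-1, fail interval k.
#' For a patient censored after m fully survived intervals: survive
#' intervals 1..m.  Equals the product of per-record Bernoulli likelihoods
#' of the patient's expanded records.
#'
#' @param gamma K-vector of cutoffs.
#' @param eta linear predictor value.
#' @param k event interval (1..K) if `event`, else the number of fully
#'   survived intervals (0..K).
#' @param event logical; TRUE if the event occurred in interval `k`.
#' @return the sequence probability.
#' @export
sequence_likelihood <- function(gamma, eta, k, event = TRUE) {
  K <- length(gamma)
  if (event) {
    if (k < 1 || k > K) stop("event interval k = ", k, " outside 1..", K)
    prod(pnorm(gamma[seq_len(k - 1)] - eta)) *
      (1 - pnorm(gamma[k] - eta))
  } else {
    if (k < 0 || k > K) stop("survived-interval count k = ", k,
                             " outside 0..", K)
    prod(pnorm(gamma[seq_len(k)] - eta))
  }
}
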