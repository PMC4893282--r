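---
title: "Sequential threshold models for censored prognosis: methods and design"
author: "seqthresh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential threshold models for censored prognosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Prognostic studies ask how well clinical covariates and, increasingly,
genome-wide common SNPs predict a censored time-to-event outcome — for
example, recurrence or progression in non-muscle invasive bladder cancer,
where a third of patients recur, under a tenth progress, and more than half
are censored before any event.  Two features make this awkward for the
standard whole-genome regression toolkit: the outcome is a *censored
duration*, not a continuous trait, and the number of markers dwarfs the
number of patients.  **seqthresh** addresses both by combining a
discrete-time sequential threshold (probit) survival model with Bayesian
regression for the clinical covariates and a Bayesian LASSO for the SNPs,
all fitted in one Gibbs sampler.

## The model

Follow-up time is divided into $K$ intervals by boundaries
$0 = b_0 < b_1 < \dots < b_K = \infty$.  A patient is present in interval
$k$ only after surviving intervals $1..k{-}1$; given presence, the
probability of passing interval $k$ event-free is

$$\Pr(\text{survive } k \mid \text{reached } k)
  = \Phi\!\left(\frac{\gamma_k - \mathbf{x}_i'\boldsymbol\beta -
  \mathbf{g}_i'\mathbf{b}}{\sigma_e}\right),$$

where $\gamma_k$ is an *unordered* interval cutoff, $\mathbf{x}_i$ the
encoded clinical covariates, $\mathbf{g}_i$ the centred SNP dosages, and
$\sigma_e^2 \equiv 1$ fixed for identifiability (only the signal-to-residual
ratio is identified from binary data).  Larger linear predictors mean higher
event risk.  Three variants are fitted: covariates only (`cpp`), SNPs only
(`snp`), and both (`cpp_snp`); the linear predictor of the joint model is
additive in the two blocks.

**Expansion and censoring.** Each patient becomes one binary record per
interval reached: an event in interval $k^*$ yields records
$0,\dots,0,1$ for intervals $1..k^*$; a censored patient contributes a
0-record for every *fully survived* interval and nothing for the interval
containing the censoring time.  Dropping the partial interval is the
conservative convention — partial exposure is not treated as survival.  A
consequence of the open last interval is that its records are all events,
so $\gamma_K$ is informed only weakly (its draws drift under the flat
prior); this leaves the linear predictor, discrimination and variance
statistics untouched.

**Priors and conditionals.** Inference uses probit data augmentation: each
record gets a latent liability $u \sim N(\eta_i, 1)$ truncated by
$\gamma_k$ according to its outcome, sampled with a tail-stable inverse-CDF
method (finite draws even for $|\gamma_k-\eta|$ of several tens).  Given
liabilities, the cutoffs act as interval-specific intercepts with flat
priors; covariate effects get independent $N(0, 10^6)$ priors and a joint
multivariate-normal update; SNP effects follow the Park–Casella Bayesian
LASSO: $b_j \sim N(0, \tau_j^2)$, $\tau_j^2 \sim \mathrm{Exp}(\lambda^2/2)$,
$\lambda^2 \sim \mathrm{Gamma}(a, b)$, updated by single-site Gibbs in fixed
marker order, inverse-Gaussian draws for $1/\tau_j^2$, and a Gamma draw for
$\lambda^2$.

**Anchoring the regularization prior.** With $\sigma_e^2$ fixed at 1 the
latent scale is constrained only by the binary records.  When many markers
can nearly separate those records, a vague $\mathrm{Gamma}(0.1, 0.1)$
hyperprior on $\lambda^2$ permits a self-reinforcing inflation of the
latent scale (cutoffs, effects and $\mathrm{var}(\mathbf{g}'\mathbf{b})$
all grow together), visible as null cohorts yielding large apparent
$R^2$.  The default prior is therefore anchored to the marker-variance
budget, as is conventional for whole-genome LASSO software: prior mean
$\lambda_0^2 = 2\sum_j \mathrm{var}(g_j)\,(1-R_0^2)/R_0^2$ with
$R_0^2 = 0.1$ (a modest prior guess of the SNP-explained liability
fraction) and shape 3, with the chain initialized at the prior mean.  Any
explicit prior, including $\mathrm{Gamma}(0.1, 0.1)$, can be set via
`st_control(lasso_prior = c(a, b))`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `K` / `boundaries` | 9 (recurrence-like), 4 (progression-like) | number of follow-up intervals; automatic boundaries at event-time quantiles, or user-supplied |
| `callrate_min` | 0.95 | minimum genotype call rate per marker |
| `maf_min` | 0.02 | minimum minor allele frequency |
| `ld_r2_max` | 0.2 | greedy LD-pruning threshold on squared dosage correlation |
| `beta_prior_var` | 1e6 | prior variance of each covariate effect (effectively flat) |
| `lasso_prior` | `NULL` (auto-anchored) | Gamma shape/rate for $\lambda^2$ |
| `n_iter`, `n_burnin`, `thin` | 20000 / 5000 / 10 | chain settings; reduced sizes are used throughout the tests |
| `n_folds` | 10 | cross-validation folds; 2 for low-event strata |

The interval grid is built once from the full cohort (boundaries at the
$K{-}1$ event-time quantiles so events spread evenly — the reproducible
analogue of reading cut-points off a Kaplan–Meier curve) and held fixed
across cross-validation folds.

## Quality control

`qc_cohort()` applies, in order: sex-chromosome exclusion (label-driven),
call-rate filtering (< 95% removed), MAF filtering (< 0.02 removed), greedy
LD pruning, and imputation.  Pruning visits markers by increasing
missingness (ties by input order) and keeps a marker only if its pairwise
$r^2$ (Pearson correlation of dosages on pairwise-complete observations,
squared) with every retained marker inside the comparison window stays
below the threshold — so the less-missing member of a correlated pair
survives.  The default imputation is the per-marker mode (ties toward the
lower dosage); `mean_rounded` and a random-forest strategy trained on the
most-correlated neighbouring markers are available behind the `strategy`
flag.  Mode rather than forest is the default because imputation here is
plumbing, not part of the contributed method, and the mode is deterministic
and fast.

## Evaluation

Predictive ability is assessed by event-stratified $k$-fold
cross-validation.  For each fold the model is refitted on the training
patients and the held-out patients are scored with the posterior-mean
linear predictor $\hat\eta$; stratification by event status prevents folds
without events, the reason low-event strata use 2 folds.  Two statistics
are reported per fold and averaged:

* **AUC** at the patient level — the Mann–Whitney probability that a random
  event patient outscores a random censored patient (ties count 1/2),
  using the ever-event indicator within follow-up as the label;
* **$R^2_{\text{probit}}$** — the liability-scale determination
  coefficient $\mathrm{var}(\hat\eta)/(\mathrm{var}(\hat\eta) + \sigma_e^2)$
  with $\sigma_e^2 = 1$ and the $n-1$ sample variance on the test set.

The SNP-only model's mean cross-validated $R^2_{\text{probit}}$ doubles as
the **heritability estimate** $\hat h^2$ for the outcome's liability — a
lower-bound-style figure, biased down by shrinkage and finite samples (a
whole-sample variant is available from a fitted object).
`decompose_cpp_prediction()` quantifies how much of the covariate-only
prediction the SNPs themselves can track: the covariate prediction
$\mathbf{X}\hat{\boldsymbol\beta}$ becomes the *response* of a
Gaussian-response Bayesian LASSO on the SNPs whose residual variance is
free (the response is continuous, so fixing it would be wrong), evaluated
under the same cross-validation scheme.

## The synthetic cohort generator

`simulate_cohort()` produces data with exactly the structure the model
assumes, so every stage is testable without the (non-deposited) real
cohort: Hardy–Weinberg biallelic dosages with MAF drawn uniformly from a
range, optional LD blocks via an exchangeable Gaussian copula on the two
gametes, optional uniform missingness; six prognosticator-like covariates
(stage, grade, multiplicity, size, carcinoma in situ at 5% prevalence,
standardized age); and outcomes generated by walking the intervals of the
threshold model itself, with independent per-interval censoring
(loss-to-follow-up) plus guaranteed end-of-study censoring.  Causal SNP
effects are rescaled against the *empirical* genotype variance so the
realized liability-scale SNP fraction hits `snp_h2` per realization.

The `tfr` preset (K = 9, front-loaded hazard, per-interval event
probabilities 0.112 down to 0.016, censor rate 0.02) yields roughly a third
of patients with an event and half censored at the end of follow-up; the
`tp` preset (K = 4, hazards 0.026–0.011) yields just under a tenth with an
event.  The default covariate effects (0.2–0.6 on the liability scale) and
`snp_h2 = 0.01` give the weak-signal regime typical of this setting.  What
the generator does **not** emulate: realistic human LD maps, population
stratification, genotyping error beyond uniform missingness, informative
censoring, or competing risks (death from other causes is censoring).
Passing tests therefore demonstrate correctness of the machinery and
calibration under the model's own assumptions, not performance on real
cohorts.

## Numerical choices and degenerate inputs

* Truncated-normal draws use `qnorm(log-p)` in the appropriate tail, exact
  and stable for truncation points beyond $\pm 8$.
* $1/\tau_j^2$ uses the Michael–Schucany–Haas inverse-Gaussian sampler with
  the mean capped at $10^8$ when an effect is numerically zero.
* Zero-variance markers: excluded from LD pruning (correlation undefined,
  warning), effect fixed at 0 in the sampler.
* All-missing markers: rejected by imputation with a pointer to call-rate
  filtering; call rate 0 removes them there without division by zero.
* A patient censored at time 0 contributes no records (message).
* Tied event-time quantiles or an interval without events abort grid
  construction with a suggestion to lower `K`.
* Collinear covariate columns abort the fit naming the offending columns.
* Fold seeds are `seed + fold`; cross-validation canonicalizes patient
  order (id-sorted) so results are invariant to row shuffling.
* Chains are bit-reproducible given `st_control(seed)`; divergence
  (non-finite parameters) aborts with the iteration index.

## Problem sizes used in the tests

The shipped tests run reduced problems chosen to exercise every code path
while keeping the default suite quick: sampler oracles at $n \le 30$,
calibration on 200 null cohorts of $N=300$, $P=200$, $K=3$ with 2-fold
cross-validation and 400-iteration chains, and recovery on one cohort of
$N=1000$, $P=1000$, 20 causal SNPs, `snp_h2 = 0.3`, $K=4$ (400–800
iteration chains).  Production analyses should use the full defaults
(`n_iter = 20000`, `n_burnin = 5000`, `thin = 10`) and inspect the stored
chains (`store_chains = TRUE`) for mixing of $\lambda^2$ and a few effects.

## Known limitations

* The last interval's cutoff is weakly identified under the flat prior
  (see above); use `gamma_prior_var` for a proper prior if its value
  matters.
* Single-site Gibbs over markers mixes slowly when LD is strong; stringent
  pruning (the r² < 0.2 default) is assumed.
* The heritability estimate inherits the downward biases of shrinkage and
  modest sample sizes; it is best read as a lower bound.
* Interval-censored ties sit at interval boundaries by the left-open
  convention; time units are opaque (only the grid interprets them).
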