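---
title: "Estimating survival under incremental propensity score interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating survival under incremental propensity score interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipsisurv)
```

## The estimand

Consider a longitudinal study over intervals $j = 0, \dots, J-1$ with
the within-interval ordering $(L_j, A_j, C_{j+1}, Y_{j+1})$: covariates
$L_j$ (containing an *indication* indicator $L^*_j$), a binary treatment
$A_j$, a censoring indicator $C_{j+1}$ and a survival indicator
$Y_{j+1}$, with $Y_0 = 1$, $C_0 = 0$, $\bar A_{-1} = 0$, and everything
after death or censoring undefined.  The target is the cumulative
probability of survival by $J$ had treatment been assigned, at every
interval and among survivors, as a random draw from an *intervention
treatment distribution* $q^g(a_j \mid Y_j = 1, \bar l_j, \bar a_{j-1})$
that may depend on the observed treatment process
$f(a_j \mid Y_j = 1, \bar l_j, \bar a_{j-1})$.  Under sequential
exchangeability, consistency and a generalized positivity condition,
this counterfactual survival equals the generalized g-formula

$$\psi^g = \sum_{\bar a} \sum_{\bar l} \Pr(Y_J = 1 \mid \cdot)
\prod_{j=0}^{J-1} \Pr(Y_j = 1 \mid \cdot)\,
f(l_j \mid \cdot)\, q^g(a_j \mid \cdot),$$

which `exact_gformula()` evaluates exactly on finite discrete laws.

Two shift families are built in.  The **multiplicative shift** with
$\delta \in [0,1]$ multiplies the probability of *not* initiating
treatment by $\delta$ among subjects with the indication:
$q^g(a \mid \cdot) = (1-\delta)\,l^* a + (l^*\delta + 1 - l^*) f(a \mid
\cdot)$.  $\delta = 1$ leaves the observed process untouched and
$\delta = 0$ always treats the indicated; $1 - \delta$ is a risk-ratio
style increase in uptake, which is easy to communicate.  The **odds
shift** with $\delta > 0$ multiplies the propensity odds:
$q^g(1 \mid \cdot) = \delta f_1 / (\delta f_1 + 1 - f_1)$.  Static and
dynamic deterministic regimes are special cases with a degenerate
$q^g$.

## Canonical form and the influence-function recursion

Every family except the odds shift can be written as

$$q^g(a_j \mid \cdot) = c_1 h_1 I(a_j = a^*) + c_2 h_2 f(a_j \mid
\cdot) + c_3 h_3\, p^*(a_j \mid \cdot),$$

with known constants $c_k$, known history functions $h_k$, and a known
distribution $p^*$.  For such interventions the efficient influence
function has the backward-recursive form

$$U = \sum_{j=1}^{J} (T_j - Q_{j-1}) \prod_{k=0}^{j-1}
\frac{q^g_k(A_k \mid \cdot)}{f_k(A_k \mid \cdot)} + T_0 - \psi^g,$$

where $T_J = Y_J$, $Q_j = E(T_{j+1} \mid \bar L_j, \bar A_j, Y_j = 1)$,
and $T_j = c_1 Q_j^{A_j = a^*} h_1 + c_2 Q_j h_2 + c_3 \{\sum_a p^*(a)
Q_j^{A_j=a}\} h_3$, with $T_j = 0$ for the dead.  Estimators built on
this recursion are $J+1$ multiply robust: consistent whenever the
outcome regressions are correct from some interval $k$ onward and the
treatment models are correct before $k$.  For the multiplicative shift
the update is simply
$T_j = (1-\delta) Q_j^{A_j=1} l^*_j + Q_j (l^*_j \delta + 1 - l^*_j)$.

The odds shift admits no such representation and its influence function
is not doubly robust, so the package deliberately restricts it to the
singly robust IPW and ICE estimators (`q_eval()` works for any family;
`wice()` and `tmle_crossfit()` raise an error).  This is a guard
against silently reporting a non-robust estimate, not a limitation of
the software plumbing.

## Estimators

All four estimators share the per-interval nuisance models: treatment
process $\pi_j$, censoring hazard, and outcome regressions $Q_j$, each
fit separately at every interval among subjects at risk (an unpooled
specification matching the per-interval parameter indexing; pooling is
a deliberate non-feature — risk sets in the built-in designs are large
enough).

* **ICE** (`ice()`): the backward recursion with unit weights.
  Consistent when every outcome regression is correct.
* **IPW** (`ipw()`): $\hat\psi = \prod_j \hat\Upsilon_j$ with
  $\hat\Upsilon_j$ the $\prod_{k\le j}(\hat q^g_k/\hat\pi_k)$-weighted
  mean of $Y_{j+1}$ among those at risk.  Algebraically identical to
  weighted ICE with intercept-only outcome models (the package tests
  enforce this identity to $10^{-10}$).
* **Weighted ICE** (`wice()`): at each interval the response
  $\hat T_{j+1}$ is regressed by *fractional logistic regression*
  (quasibinomial logit score equation) with the cumulative
  $\hat q^g/\hat\pi$ products as observation weights; multiply robust
  as above.  The default standard error is the empirical SD of the EIF
  values over $\sqrt n$; the percentile bootstrap is the alternative.
* **TMLE with cross-fitting** (`tmle_crossfit()`): the sample is split
  into $M$ near-equal random folds; nuisances and the recursion are fit
  on each complement (by formulas or learner stacks), and on the
  held-out fold an intercept-only logit fluctuation $\gamma_j$ solves
  the weighted score exactly, interval by interval.  Out-of-fold
  estimation removes empirical-process (Donsker) conditions, so any
  learner may be used.

ICE, weighted ICE and TMLE are sample bounded in $[0,1]$ by
construction: every $T_j$ is a convex combination of fitted
probabilities.

### Censoring

Censoring is handled as an implicit intervention that eliminates it:
each per-interval censoring hazard
$\Pr(C_{j+1} = 1 \mid C_j = 0, Y_j = 1, \bar A_j, \bar L_j)$ is fit on
the risk set, and the cumulative weights are multiplied by
$\prod_{k \le j} \{1 - \hat\lambda^c_{k+1}\}^{-1}$ for subjects still
uncensored, with weight zero from the censoring interval onward.  This
standard inverse-probability-of-censoring construction was adopted as
the package's design; it enters ICE only through the risk-set
restriction (sequential regressions are unweighted there).

### Reading of the cross-fitting recursion

The training-fold recursion serves exactly one purpose: it defines the
regression responses $\hat T_{j+1}$ and hence the fitted predictor
functions $\hat Q^{(-m)}_j$.  Targeting on the held-out fold consumes
only those predictor functions (evaluated at observed and
counterfactual treatments) together with out-of-fold treatment and
censoring predictions; no training-fold individual enters any held-out
quantity.  Where the recursion could be read as feeding anything more
into the held-out step, this package takes the narrower reading.

## Nuisance estimation

`frac_logit()` solves the weighted score equation by Newton iteration
with step-halving on the (concave) quasibinomial log-likelihood.
Numerical choices, all visible in the function signatures:

* target score tolerance `1e-12` (max-abs score scaled by total
  weight), hard failure above `1e-8`, at most 200 iterations.  The
  tight target keeps saturated-model fits within $10^{-10}$ of exact
  cell means, which the exact-oracle tests require; quasi-separated
  continuous designs may legitimately stop between the two tolerances.
* rank-deficient designs (empty cells in saturated models) fall back to
  a damped solve (ridge $10^{-10}\times$ mean curvature), which keeps
  boundary-cell coordinates moving where a pseudoinverse would freeze
  them.
* fitted treatment and censoring probabilities are clipped to
  $[10^{-6}, 1-10^{-6}]$ with the count surfaced in warnings and
  diagnostics, so near-positivity behaviour stays visible and is never
  silently truncated; there is no default weight capping.
* TMLE initial outcome predictions are bounded to
  $[10^{-3}, 1-10^{-3}]$ before the logit fluctuation so offsets stay
  within about $\pm 7$ and the fluctuation root is bracketed in the
  default $\gamma \in [-10, 10]$; the root is found by `uniroot` and
  polished by Newton to a residual score below $10^{-11}$.

The learner library (`default_learners()`) holds a main-effects
quasibinomial GLM, a GLM with all pairwise interactions, an additive
natural-cubic-spline logit model (df 4 per continuous predictor), a
random regression forest (100 trees), and a single-hidden-layer neural
network on standardized inputs — parametric-rate candidates, a smooth
candidate, a tree ensemble and an adaptive nonlinear candidate.
`cv_stack()` selects the convex combination minimizing $V$-fold
cross-validated squared error on the probability scale (nonnegative
least squares, weights renormalized; discrete selection available via
`method = "select"`), with $V = 5$ folds by default — the conventional
stacking fold count, which measurably reduces the small-sample
regularization bias of the singly robust estimators relative to a
two-fold stack.  Squared error on the probability scale was chosen
because every response (binary or iterated $T$ values) lives in
$[0,1]$ and the stack's output feeds logit-scale offsets downstream.

## The built-in data-generating processes

`simulate_study1()` is a fully discrete system (three binary
covariates, strong confounding, ~10%/interval informative censoring,
high mortality) on which *saturated* working models are exactly
correct — the testing ground for the multiple-robustness pattern:
misspecification is introduced by dropping the previous treatment from
the treatment model and all treatment-covariate interactions from the
outcome model (`misspecified_formulas()`).  The misspecified weighting
also ignores the censoring process entirely (no censoring model, no
censoring weights): a milder reading that only altered the treatment
formula produced an IPW bias too small to distinguish from Monte-Carlo
noise at the replication sizes used, i.e. it did not meaningfully
misspecify the weighting at all.
`simulate_study2()` mixes continuous covariates with absolute-value and
power nonlinearities in the hazards and an absorbing treatment — a
harder target no parametric candidate in the library spans, the
testing ground for the learner-based estimators.  Each hazard of the
second process is isolated in a single expression in the simulator, so
an alternate form of any of its absolute-value, power or interaction
terms is a one-line change.

What the generators emulate: confounding by time-varying covariates
that respond to past treatment, informative censoring through measured
history, monotone death and censoring, and (in the second process)
deterministic treatment continuation.  What they do not emulate:
unmeasured confounding, interval-censored event times, competing
risks, measurement error, or covariate-dependent visit processes — so
green tests say nothing about those features of real data.

`monte_carlo_truth()` computes intervention-world survival by
simulating the covariate/outcome laws with treatment drawn from $q^g$
built from the *true* propensities and censoring eliminated.  The
default $10^6$ draws give an MCSE around $5\times10^{-4}$, reported
alongside; the replication grids in the tests use 200 replications per
cell and $n$ of 250–2500, sizes chosen so every cell's Monte-Carlo
standard error is small against the effects being checked.

## Diagnostics

`positivity_check()` reports, per interval, the at-risk person-moments
where the intervention assigns strictly more probability than the
observed process to a treatment level whose estimated observational
probability is below $\varepsilon$ (default $10^{-3}$) — the practical
shadow of the generalized positivity condition.  Under $\delta = 1$
nothing can be flagged; under the multiplicative shift only indicated
person-moments can be.  The report never truncates anything.  The
cumulative weight products (max and quantiles) are part of every fit's
diagnostics; their growth as $\delta \to 0$ is the expected
near-positivity signature.

## Known limitations

Treatments are binary; continuous-valued treatments and policies that
depend on the natural value of treatment are out of scope.  The odds
shift is evaluate-only, as above.  One-step (non-targeted) estimation
from the EIF is not provided — `eif_values()` exposes the per-subject
values for variance estimation and score checks instead.  Bootstrap
confidence intervals resample subjects, not intervals, and assume the
panel rows are independent across subjects.
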