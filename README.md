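# ipsisurv

Causal survival analysis under **incremental propensity score
interventions** — stochastic treatment strategies whose assignment
distribution depends on the observed treatment process.

## The problem

In longitudinal observational studies, "always treat vs. never treat"
contrasts are often both unrealistic and unidentifiable: propensity
scores near zero make deterministic regimes collide with positivity.
A more answerable question is what happens under a *partial* increase
in treatment uptake.  With intervals $j = 0,\dots,J-1$, covariates
$L_j$ (including an indication indicator $L^*_j$), binary treatment
$A_j$, censoring $C_{j+1}$ and survival $Y_{j+1}$, the package
estimates the cumulative survival probability
$\psi^g = \Pr(Y_J^g = 1)$ under an intervention that draws treatment
from

$$q^g(a_j \mid \cdot) \;=\; (1-\delta)\,l^*_j a_j +
(l^*_j\delta + 1 - l^*_j)\, f(a_j \mid \cdot),
\qquad \delta \in [0,1],$$

the *multiplicative shift*: among subjects with the indication, the
probability of **not** initiating treatment is multiplied by $\delta$
($\delta = 1$: no intervention; $\delta = 0$: all indicated subjects
treated).  The odds-scale shift
$q^g(1\mid\cdot) = \delta f_1/(\delta f_1 + 1 - f_1)$ is also
available.  Identification is by the generalized g-formula; censoring
is handled by an implicit intervention that eliminates it
(inverse-probability-of-censoring weights).

Four estimators are provided:

| estimator | call | robustness |
|---|---|---|
| sequential regression (ICE) | `ice()` | outcome models correct |
| inverse probability weighting | `ipw()` | treatment/censoring models correct |
| weighted ICE (fractional logistic) | `wice()` | $J{+}1$ multiply robust |
| TMLE with sample splitting | `tmle_crossfit()` | multiply robust, admits machine learning |

`wice()` implements the weighted sequential-regression algorithm: the
iterated responses $\hat T_j$ follow the canonical backward update of
the intervention and the regressions are weighted by cumulative
$\hat q^g/\hat\pi$ products.  `tmle_crossfit()` fits nuisances on
training folds (parametric formulas or cross-validated learner stacks:
GLMs, spline models, random forests) and solves an intercept-only logit
fluctuation on held-out folds.  See `vignette("ipsisurv-methods")` for
the model, the influence-function recursion, and every numerical
choice.

## Worked example

```r
library(ipsisurv)

panel <- simulate_study1(1000, seed = 2024)   # built-in discrete DGP
panel
#> Longitudinal survival panel: n = 1000, J = 5 treatment intervals
#>   covariates: lstar, L1, L2 (indication: lstar)
#>   risk-set sizes: 1000, 560, 362, 241, 165
#>   deaths by end of follow-up: 729; censored: 163

spec  <- mult_shift(0.5)                      # halve non-initiation if L* = 1
forms <- misspecified_formulas("all_correct") # per-interval working models

fit <- wice(panel, spec, treatment = forms$treatment,
            outcome = forms$outcome, censoring = forms$censoring)
fit
#> WICE estimate of survival under the multiplicative_shift intervention (delta = 0.5)
#>   psi_hat = 0.2529  (SE 0.0245)  95% CI [0.2049, 0.301]

fit0 <- wice(panel, mult_shift(1), treatment = forms$treatment,
             outcome = forms$outcome, censoring = forms$censoring)
fit0$psi                                      # no-intervention reference
#> [1] 0.1548
```

Halving the per-interval probability of *not* starting treatment among
indicated subjects raises 5-interval survival from about 15.5% to about
25.3% in this cohort — close to the simulator's exact intervention-world
value, `monte_carlo_truth("study1", delta = 0.5, n_mc = 1e6, seed = 99)`
= 0.2628 (MCSE 0.0004).  Supporting tools:

```r
positivity_check(spec, panel, fit_treatment(panel, forms$treatment))
#> Generalized positivity diagnostic (epsilon = 0.001)
#>  interval flagged min_f_support
#>         0       0        0.0100
#>  ...                       (no near-positivity flags)

bootstrap_ci(fit, panel, B = 500, seed = 7)$ci
#> [1] 0.2015 0.2988
```

`ice()`, `ipw()` and `tmle_crossfit()` have the same interface;
learner-based nuisances are requested by passing a learner list (e.g.
`default_learners()`) instead of a formula.  Panels come from
`read_panel()`/`write_panel()` (long CSV, one row per subject-interval)
or the two simulators; `exact_gformula()` evaluates the estimand
exactly on finite discrete laws.  A thin command-line front end lives
in `inst/cli/ipsisurv.R` (`simulate`, `truth`, `estimate`,
`replicate`).

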