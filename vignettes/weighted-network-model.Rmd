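---
title: "The weighted network model of deficit accumulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The weighted network model of deficit accumulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agenet)
```

## The model

An individual carries $N$ binary health attributes ("deficits")
$d_i \in \{0, 1\}$ that can only damage ($0 \to 1$, never repaired) and a
competing mortality process. Interactions are a weighted directed network
$w_{ij}$: damage in node $j$ raises the *local frailty* of node $i$,

$$f_i(t, \{d_j\}) = \phi\Big(\sum_{j=1}^N w_{ij} d_j + \mu_i(t)\Big),
\qquad \mu_i(t) = \sum_{n=1}^{n_f} \mu_{i n}\, t^n,$$

where $\phi(x) = \max(x, 0)$ is the hinge (rectifier). The monotone age
series $\mu_i(t)$ absorbs the average effect of everything *not* observed as
a node — it is what lets a 10-node network stand in for the thousands of
interacting physiological variables actually aging underneath. The hinge
lets a rate stay at zero until the inner argument crosses zero, so damage
can effectively "turn on" late in life without any explicit change point.

Node $i$ damages with rate
$$\Gamma_i^{+} = \phi\Big(\sum_{n=0}^{n_+} \gamma^{+}_{i n} f_i^{\,n}\Big),$$
and death occurs with rate
$$\Gamma_D = \phi\Big(\sum_{n=0}^{n_{D_1}} \alpha_n x^n\Big), \qquad
x(t, \{d_j\}) = \phi\Big(\sum_j \beta_j d_j +
\sum_{n=0}^{n_{D_2}} \eta_n t^n\Big).$$

All order-$\ge 1$ series coefficients are constrained non-negative, which
makes $f_i$, $\Gamma_i^+$, $x$ and $\Gamma_D$ monotone non-decreasing in age
at fixed deficits and monotone in the quantities driving them. Weights
($w_{ij}$, $\beta_j$) and the zeroth-order coefficients may be negative; the
hinge keeps every rate non-negative.

### Parameter count and fixing conventions

Two written coefficients are not identifiable and are fixed at zero:

* the diagonal $w_{ii}$ — node $i$'s damage rate is only ever evaluated
  while $d_i = 0$, so $w_{ii} d_i$ never contributes;
* the constant term $\mu_{i 0}$ — a constant offset inside $f_i$ is
  redundant with the intercept $\gamma^+_{i 0}$ of the damage-rate series.

With those conventions the free-parameter count is exactly
$N(N + n_f + n_+ + 1) + n_{D_1} + n_{D_2} + 2$; at the default
hyperparameters ($N = 10$, $n_+ = 4$, $n_f = n_{D_1} = n_{D_2} = 3$) that is
188, and `count_parameters()` always equals the length of the flattened
free-coefficient vector the fitter varies:

```{r count}
h <- wnm_hyper(N = 10)
count_parameters(h)
length(flatten_params(wnm_params_zero(h)))
```

Ages are in years with age 0 at birth; power series are evaluated by
Horner's rule. Coefficient magnitudes stay well-conditioned because the
default bounds scale the order-$n$ age-series coefficients by
$100^{-n}$, which plays the role of an internal age rescale without
changing the parameterization the user sees.

## Exact event-driven simulation

Between damage events the deficit vector is frozen, so every hazard is a
*hinged polynomial in age*: the inner argument of $f_i$ is monotone
non-decreasing (its only time dependence is $\mu_i$), hence crosses zero at
most once, and the same holds for the outer series and for the mortality
channel through $x(t)$. Each hazard therefore has at most two hinge kinks
per inter-event interval, and between kinks the total hazard
$\Gamma_{\mathrm{tot}}(t)$ is exactly polynomial.

Waiting times are drawn by hazard inversion: draw $u \sim \mathrm{Exp}(1)$
and solve $\int_{t}^{t^*} \Gamma_{\mathrm{tot}}(s)\,ds = u$. Kink locations
are found by monotone bracketing (Illinois regula falsi, tolerance
$10^{-7}$ years); each kink-free segment is integrated by Gauss–Legendre
quadrature whose order is chosen from the actual polynomial degree
($n$-point rules are exact to degree $2n - 1$), so the cumulative hazard is
evaluated *exactly* up to floating point; and $t^*$ is located within its
segment to $10^{-9}$ years. The event identity is then drawn proportional
to the instantaneous rates at $t^*$, with mortality placed last and exact
floating-point ties resolved toward the lowest node index. After each event
all rates are recomputed. Simulation stops at death or at the horizon
(default 120 years); individuals alive at the horizon are flagged as
censored rather than killed.

Because the quadrature is exact for the polynomial segments, the only
approximations are the two root tolerances. The test suite verifies the
sampler against closed forms (exponential waiting times, a linear-in-age
hazard, and the full master equation of a two-node system solved by matrix
exponential) and against an independent thinning (rejection) implementation
of the same process, `simulate_individual_thinning()`, kept in the package
purely as a distributional cross-check.

Reproducibility: every simulated life consumes its own counter-derived RNG
stream (xoshiro256++ seeded by splitmix64 from a `(seed, stream)` pair), so
cohorts are deterministic, order-independent, and individual lives can be
re-simulated in isolation.

## The likelihood for cross-sectional, right-censored data

A cohort record is $(t^{(m)}, \{d_i\}^{(m)}, a^{(m)}, c^{(m)})$: baseline
age, baseline deficits (possibly partially missing), survival age, and a
censoring flag. The log-likelihood splits into a health part and a
mortality part:

$$L = \sum_{c^{(m)} = 0} \log \hat p\big(a^{(m)} \mid \{d_i\}^{(m)}, t^{(m)}\big)
    + \sum_m \log \hat p\big(\{d_i\}^{(m)} \mid t^{(m)}\big)
    + \sum_{c^{(m)} = 1} \log \hat S\big(a^{(m)} \mid \{d_i\}^{(m)}, t^{(m)}\big).$$

All three pieces are estimated by simulation:

* **Health terms** come from one shared birth-cohort pool (individuals
  started at age 0 with no deficits) tallied into an age-binned joint state
  distribution $\hat p(\{d_i\} \mid t)$ over all $2^N$ states. Defaults:
  1-year bins, additive smoothing of 0.5 pseudo-counts per state per bin
  (so no observed state ever has probability zero), pool size $10^4$. A bin
  with no simulated survivor is signalled distinctly (`NA`, with a warning)
  rather than silently smoothed.
* **Mortality terms** for fully observed records use dedicated forward
  simulations from the record's own baseline state. Censored records need
  $\hat S(a)$; uncensored records need a death density, estimated as the
  symmetric finite difference
  $[\hat S(a - \Delta/2) - \hat S(a + \Delta/2)]/\Delta$ with
  $\Delta = 1$ year and a hard floor of $10^{-10}$/year. The uncensored
  budget defaults to five times the censored one: a density estimated from
  counts inside a 1-year window needs a finer empirical survival step than
  a single survival probability does, and an under-resolved density floors
  to $\log 10^{-10}$ often enough to bias the whole surface toward
  higher-mortality parameters.
* **Missing deficits** are marginalized: the health term sums the smoothed
  distribution over all completions of the observed sub-vector, and the
  mortality term conditions on pool individuals that match the observed
  sub-vector in the record's baseline age bin.

Two plumbing choices matter for optimization. First, *common random
numbers*: the likelihood seed is fixed across evaluations at different
parameter values, so the objective surface seen by the optimizer is
deterministic. Second, each record's forward-simulation streams are derived
from a hash of the record's own fields rather than its row position, which
makes the likelihood exactly invariant to record order and exactly additive
over duplicated records.

The simulation-based estimator is biased at small budgets (Jensen's
inequality pushes $E[\log \hat p]$ below $\log p$, more strongly where
$\hat p$ is noisier), which is why the test suite checks convergence to a
closed-form likelihood on a one-node model (relative error under 2% at a
$10^5$ pool) and why budgets are exposed as configuration.

## Fitting

`fit()` maximizes the (optionally $L_1$-penalized) log-likelihood by
global-best particle swarm optimization with reflecting bound handling.
Defaults are the standard constriction-style values (swarm 50, 200
iterations, inertia 0.72, cognitive = social = 1.49). Box bounds encode the
monotonicity constraints: order-$\ge 1$ coefficients live in
$[0, \cdot\,]$, weights and zeroth-order terms in $[-10, 10]$.

Uniform initialization over such bounds starts the search many orders of
magnitude away from lifelike rates, so the swarm is seeded around a
method-of-moments warm start computed from the data: per-deficit constant
damage rates solved from marginal prevalences
($\hat\lambda_i = -\log(1 - \mathrm{prev}_i)/\bar t$), a mortality scale
from the person-years death rate, and age series started so the background
terms are $O(1)$ at the mean age. Half the swarm is log-normal jitter
around the warm start, the rest uniform in a shrunken initialization box;
velocity clamps follow the scale of plausible coefficients rather than the
full bound box. The regularization (off by default) is
$\lambda(\lVert W \rVert_1 + \lVert \beta \rVert_1)$, a sparsity-friendly
choice for a weight matrix that is typically not fully identified.

Network weights themselves are *not* expected to be recovered — materially
different networks can produce nearly identical cohort behaviour — so
recovery is asserted on model behaviour: deficit prevalence curves,
pairwise prevalences and population survival of the refit model against the
generator's.

## Validation battery

* `deficit_prevalence()` / `pairwise_prevalence()`: survivor-conditioned
  marginal and joint deficit prevalences along simulated trajectories, with
  binomial standard errors (pairwise prevalences respect the Fréchet
  bounds by construction).
* `fi_distribution()`: the frailty-index distribution
  ($F = \sum_i d_i / N$) among survivors at an age.
* `leftout_deficit_auc()`: missing-data imputation assessed as
  classification. For each test record the probability of a left-out
  deficit is estimated from birth-cohort simulations matched exactly on the
  observed sub-state in the record's 1-year age bin, widening symmetrically
  up to 5 years before dropping the record; scored by ROC AUC (Mann–Whitney
  with midrank ties) overall and per 5-year age stratum, percentile
  bootstrap CIs (default 1000 resamples).
* `kaplan_meier()`: product-limit estimate with Greenwood ("plain")
  confidence bands via the survival package, with optional delayed entry
  for age-scale cohorts.
* `mean_survival_curve()`: the average of per-record simulated survival
  functions, the model-side analogue of the population Kaplan–Meier.
* `td_c_index()`: the age-dependent concordance
  $C^{\mathrm{td}} = \Pr\big(\hat S^{(1)}(a^{(1)}) < \hat S^{(2)}(a^{(1)})
  \mid a^{(1)} < a^{(2)}, c^{(1)} = 0\big)$, with ties counted one half, and
  a stratified variant restricted to 5-year baseline-age bins — appropriate
  when survival curves may cross, which a Cox-style single ordering cannot
  represent.
* `brier_r2()`: $1 - \mathrm{BS}(\text{model})/\mathrm{BS}(\text{reference})$
  with inverse-probability-of-censoring weights from the Kaplan–Meier
  estimate of the censoring distribution and the population Kaplan–Meier
  curve as reference.
* `window_mortality_auc()`: dead/alive classification within a fixed window
  of baseline, scored by $1 - \hat S(t_0 + w)$; records censored inside the
  window are excluded as status-unknown.
* `conditional_damage_rate()`: the damage-propagation curve
  $\Gamma_{i \leftarrow j}(t)$, the mean damage rate of node $i$ among
  simulated survivors with $d_j = 1$, $d_i = 0$, averaged over the
  simulated distribution of the remaining deficits.

The pair-based metrics are verified against $O(M^2)$ brute-force
enumerations in the test suite, and the AUC against an independent rank
implementation.

## Synthetic cohorts

Restricted study data cannot ship with the package, so `synthetic_data`
provides structural stand-ins. `csha_preset()` emulates a cohort of 8547
individuals, baseline ages 65–99 (truncated normal, mean 76, SD 7), deaths
observed within a 6-year window, with the ten ADL/IADL difficulty items as
deficit labels; `nhanes_preset()` a cohort of 9504, ages 20–85 (mean 51,
SD 20), a 10-year window, and 10% per-deficit missingness (the source
surveys report substantial missingness; the exact mechanism is not public,
so missing-completely-at-random is used). These presets encode study
*structure* only — no study values are reproduced, and the published
censored fractions (~78% and ~88%) emerge from the interplay of the
generator's mortality with the window rather than being set directly.

`make_ground_truth()` draws a random sparse positive network, lifelike
series coefficients, and then calibrates a global mortality scale by
bisection on a short pilot simulation (400 lives) so the birth-cohort
median death age lands in [60, 100] — keeping every randomly drawn
generator demographically plausible. `sample_cross_sectional()` builds in
left truncation: a baseline age is drawn from the design distribution, a
full life is simulated from birth, and the draw is rejected if the
individual died before baseline — exactly the "sampled from the living"
selection a cross-sectional study performs. The sampler aborts with a
diagnostic if a design is infeasible under a model (bounded rejections).

What the generator deliberately does **not** emulate: survey stratification
weights, informative missingness, measurement error in the deficits,
cohort effects (everyone ages under one stationary model), and
covariates such as sex. Tests passing on these cohorts therefore
demonstrate the correctness of the machinery and the self-consistency of
the method, not fidelity to any particular human study.

## Problem sizes and numerical choices

The packaged checks run at sizes chosen to exercise every code path while
staying desk-scale: the master-equation and waiting-time oracles use
$10^5$ replicates; the closed-form likelihood comparison a $10^5$ pool; the
behavioural-recovery study uses a three-deficit generator with first-order
series (22 free parameters), a cohort of $M = 2000$ with the 65–99/6-year
design, and a PSO budget of swarm 30 × 100 iterations with per-evaluation
budgets of a 5000-individual pool and 80 (censored) / 400 (uncensored)
forward simulations per record; behavioural agreement is assessed where the
cohort carries information (the central 99% of baseline ages for the
prevalence curves). Key tolerances: quadrature exact by construction;
kink roots $10^{-7}$ y; event times $10^{-9}$ y; state-distribution rows
sum to 1 within $10^{-12}$; survival floors at half a count.

## Known limitations

* The likelihood estimator is consistent but biased at small simulation
  budgets; fitted rate scales inherit a slight upward pull when budgets are
  very tight. Increase `n_pool`/`n_per_record` when the fit, not the wall
  clock, is the priority.
* Joint-state tallies are dense over $2^N$ states; practical up to roughly
  $N \le 20$ (and `N <= 25` is enforced), which matches the model's own
  computational-demand ceiling on $N$.
* The network is generally non-identifiable from cross-sectional data;
  report and compare model behaviour, not individual $w_{ij}$.
* No repair transitions: deficits here are binary and irreversible by
  design, so the model is inappropriate for attributes that remit.
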