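# agenet

Stochastic network modelling of human aging from cross-sectional data.

## The problem

Aging studies such as CSHA and NHANES measure each participant once: a
baseline age, a handful of binary health deficits (difficulty walking,
showering, managing money, ...), and then only whether the participant was
still alive some years later — death ages are right-censored by a short
follow-up window. Clinicians and epidemiologists summarize such deficits
with the frailty index *F* = Σᵢ dᵢ / N, but a summary index cannot forecast
*which* deficits a person will acquire next, how deficits drive each other,
or an individual's survival curve. `agenet` is for researchers who want a
generative, individual-level model of deficit accumulation and mortality
that can be trained on exactly this kind of cross-sectional, censored data
and then interrogated: forecast prevalence trajectories, impute missing
deficits, predict survival, and quantify deficit-to-deficit damage
propagation.

## The model

Each of *N* binary deficits dᵢ ∈ {0, 1} damages irreversibly at a rate set
by its *local frailty* — a weighted sum over its damaged network neighbours
plus a monotone age series standing in for everything unobserved:

    fᵢ(t, {dⱼ}) = φ( Σⱼ wᵢⱼ dⱼ + μᵢ(t) ),     μᵢ(t) = Σₙ μᵢₙ tⁿ
    Γᵢ⁺        = φ( Σₙ γᵢₙ⁺ fᵢⁿ )

with φ(x) = max(x, 0) the hinge. Mortality is a competing hazard driven by
a weighted deficit load with its own age series:

    Γ_D = φ( Σₙ αₙ xⁿ ),      x(t, {dⱼ}) = φ( Σⱼ βⱼ dⱼ + Σₙ ηₙ tⁿ )

All order-≥1 coefficients are non-negative, so every rate is monotone in
age and in damage. With the identifiability conventions w_ii = 0 and
μ_i0 = 0 the model has N(N + n_f + n₊ + 1) + n_D1 + n_D2 + 2 free
parameters — 188 at the default N = 10, n₊ = 4, n_f = n_D1 = n_D2 = 3.

Individuals are simulated by an exact event-driven algorithm (kinetic Monte
Carlo with time-dependent hazards inverted segment-by-segment), the
censored likelihood of a cohort is estimated from those simulations
(including marginalization over missing deficits), and parameters are
fitted by particle swarm optimization. A validation battery covers deficit
and pairwise prevalence forecasts, frailty-index distributions,
left-out-deficit imputation AUC, Kaplan–Meier comparisons, time-dependent
concordance, censoring-weighted Brier R², windowed mortality AUC, and
conditional damage-propagation rates. Because the source studies are
restricted, a synthetic-cohort module reproduces their *structure* (entry
among the living, baseline age distributions, censoring windows,
missingness) from fully known ground-truth models.

## A worked example

```r
library(agenet)

# a three-deficit ground truth, calibrated so a birth cohort's median
# death age is demographically plausible
truth <- make_ground_truth(N = 3, seed = 42)

# an aging-study-like cross-sectional cohort: entrants 65-99, deaths
# observed within 6 years of baseline
design <- cohort_design(M = 800, age_range = c(65, 99), window = 6,
                        age_dist = "truncnorm", age_mean = 76, age_sd = 7)
cohort <- sample_cross_sectional(truth, design, seed = 7)
head(cohort, 3)
#>        age d1 d2 d3 surv_age censored
#> 1 92.01073  0  0  1 98.01073        1
#> 2 67.62260  0  0  1 73.62260        1
#> 3 71.13995  0  0  1 77.13995        1
mean(cohort$censored)
#> [1] 0.84125
```

84% of this synthetic cohort is right-censored, as in the study designs it
emulates. A single life simulated from birth:

```r
simulate_individual(truth, health_state(c(0, 0, 0), 0), seed = 1)
#> WNM trajectory: start age 0.0, 2 damage events, death at 75.68
```

How well does the model discriminate mortality risk between individuals of
its own cohort? Predict each individual's survival curve from their
baseline state and compute the age-dependent concordance index:

```r
parts <- cohort[complete.cases(cohort), ][1:300, ]
d <- as.matrix(parts[, c("d1", "d2", "d3")])
pred <- lapply(seq_len(nrow(parts)), function(m)
  survival_function(truth, d[m, ], parts$age[m], n_sim = 150,
                    seed = 41, stream = (m - 1) * 150))
td_c_index(pred, parts$surv_age, parts$censored,
           baseline_ages = parts$age, n_boot = 200, seed = 43)[1:3, ]
#>   stratum  estimate     lower     upper    n
#> 1     all 0.7688760 0.7038846 0.8309667 7589
#> 2 [65,70) 0.8000000 0.5767857 0.9611718  340
#> 3 [70,75) 0.5987569 0.4244376 0.7934371  724
```

A C^td of 0.77 (95% CI 0.70–0.83) means: for 77% of comparable pairs, the
individual who died first had the lower predicted survival at that death
age. The `[65,70)` row shows the same discrimination *within* an age band,
i.e. beyond what age alone explains. Fitting a model to a cohort uses
`fit(cohort, wnm_hyper(...), fit_config(...))`; see the vignette in
`vignettes/weighted-network-model.Rmd` for the likelihood construction,
optimizer design and validation methodology, and `inst/cli/agenet.R` for a
command-line front end (`synth` / `simulate` / `fit` / `validate`).

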