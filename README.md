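# ecoreact

Reactivity and stability analysis for complex ecological communities.

## The problem

Stability analysis asks whether a community returns to equilibrium after
a perturbation; it says nothing about the *short-term* response. A stable
community can still be **reactive**: some perturbations are amplified
before they decay, and under frequent perturbations this transient
amplification — not instability — is what drives species to extinction.

For gLV dynamics `dX_i/dt = X_i (r_i + Σ_j A_ij X_j)` linearised at a
feasible equilibrium `X*`, deviations follow `dx/dt = M x` with the
community matrix `M = diag(X*) A`. The two key quantities are

- **spectral abscissa** `max Re λ(M)` — negative means stable;
- **reactivity** `ℛ = max λ(H)` with `H = (M + Mᵀ)/2` — positive means
  some perturbations grow initially.

Since `max λ(H) ≥ max Re λ(M)`, every community is stable–non-reactive,
stable–reactive, or unstable. `ecoreact` provides:

- **Generators** for the standard random-community ensembles: single
  interaction types (random, exploitative, competitive, mutualistic),
  arbitrary mixtures `(P+/+, P−/−, P+/−)`, cascade and niche food webs,
  and homogeneous/heterogeneous/absent self-regulation
  (`ensemble_spec()`, `generate_community()`, `apply_self_regulation()`).
- **Exact spectra and analytic criteria**: `reactivity()` computes
  `ℛ` and the abscissa from any matrix; `predict_unstructured()`,
  `predict_mixed()` and `predict_heterogeneous()` give the
  random-matrix-theory predictions, e.g. `ℛ = −d + σ√(2SC)` for random
  communities and the support-edge formula for uniformly distributed
  self-regulation strengths.
- **Phase geometry**: critical `S–C` curves for both transitions, the
  normalised distance `ND = 1 − (1 + r)/2` between reactivity and
  instability (with `r = (ρ − E²)/V` the pairwise interaction
  correlation), its theory-free Monte-Carlo counterpart
  (`area_ratio_numeric()`), and critical interaction-strength estimation
  (`critical_sigma()`).
- **A gLV simulator** with pulse-perturbation schedules, event-detected
  extinctions at 1% of equilibrium abundance, and the
  frequent-perturbation species-loss experiment
  (`build_glv()`, `simulate_glv()`, `species_loss_experiment()`).
- **An empirical pipeline** from inferred `(A, r)` parameter files to
  equilibrium, community matrix, reactivity and interaction-type
  composition, plus a synthetic fixture generator for small test
  communities (`empirical_reactivity()`, `make_fixture()`).

## Worked example

```r
library(ecoreact)

spec <- ensemble_spec(S = 200, C = 0.3, sigma = 0.1, d = 1,
                      interaction_type = "cascade", seed = 101)
web <- generate_cascade(spec)
reactivity(web$values)
#> Reactivity -0.354016, spectral abscissa -0.7346 -> stable_nonreactive

# cascade webs share the unstructured exploitative prediction
predict_unstructured("exploitative", 200, 0.3, 0.1, 1)$R_pred
#> [1] -0.3396554

# how far is the reactivity transition from the instability transition?
nd <- normalized_distance(ensemble_moments(spec), d = 1)
c(r = nd$r_corr, ND = nd$nd)
#>          r         ND
#> -0.6366198  0.8183099

# embed as gLV dynamics and pulse 60 random species
sys <- build_glv(web, X_star = 2)
sched <- perturbation_schedule("single_pulse", times = 1, strength = 0.2,
                               n_targets = 60, target_seed = 1)
sim <- simulate_glv(sys, sched, horizon = 200)
c(recovered = sim$recovered, extinctions = nrow(sim$extinctions))
#> recovered extinctions
#>         1           0
```

The generated food web is stable and non-reactive at this interaction
strength (`σ = 0.1` is below the critical `σ ≈ 0.151` for `S = 200`,
`C = 0.3`): its exact reactivity `−0.354` sits close to the analytic
segment-edge prediction `−0.340`, the normalised distance `0.818`
(`= 1/2 + 1/π`, from the half-normal pair correlation `r = −2/π`) says
reactive exploitative webs are typically far from instability, and a
single moderate pulse is absorbed without species loss.

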