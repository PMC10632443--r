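---
title: "Reactivity theory for complex ecological communities"
author: "ecoreact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reactivity theory for complex ecological communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoreact)
```

## The model

A community of $S$ species with abundances $X(t)$ is modelled by
generalized Lotka-Volterra (gLV) dynamics,
$\mathrm{d}X_i/\mathrm{d}t = X_i\,(r_i + \sum_j A_{ij} X_j)$,
with intrinsic growth rates $r$ and per-capita interaction matrix $A$.
Around a feasible equilibrium $X^* > 0$ the deviation $x = X - X^*$
follows $\mathrm{d}x/\mathrm{d}t = M x$ with the community matrix
$M = \operatorname{diag}(X^*) A$, whose entry $M_{ij}$ is the effect of
species $j$ on species $i$.

Two complementary one-number summaries of $M$ matter here:

* **Stability** is governed by the *spectral abscissa*
  $\max_k \operatorname{Re} \lambda_k(M)$: negative means perturbations
  decay asymptotically.
* **Reactivity** is the maximum instantaneous growth rate of the
  perturbation norm,
  $\mathcal{R} = \max_{x_0 \ne 0} \left.\tfrac{\mathrm{d}\,\log \lVert x
  \rVert_2}{\mathrm{d}t}\right|_{t=0}$, and equals the largest eigenvalue
  of the symmetric part $H = (M + M^{\mathsf T})/2$ (the numerical
  abscissa). Since the numerical abscissa dominates the spectral
  abscissa, communities are either stable and non-reactive, stable but
  reactive (perturbations grow before decaying), or unstable.

`reactivity()` computes both quantities exactly: a symmetric eigensolver
for $H$ (guaranteeing real eigenvalues) and a general one for $M$. The
three-region classification uses the tolerance
$10^{-9}\max(1, \lVert M\rVert_\infty)$; values inside it raise a
boundary flag.

## Random community ensembles

All generators share the same notion of *connectance*: each unordered
species pair interacts independently with probability $C$ (expected, not
exact, link counts), so `ensemble_spec(S, C, sigma, d, type)` fully
determines an ensemble, and a spec plus its seed reproduces a matrix
bit-identically (member $k$ of an ensemble uses `seed + k`). Interaction
magnitudes come from a base variable $Z$ with mean zero and variance
$\sigma^2$; the default is normal, so $|Z|$ is half-normal with
$\mathbb{E}(|Z|) = \sigma\sqrt{2/\pi}$. A gamma family (`z_gamma()`) with
the same variance but a smaller $\mathbb{E}(|Z|)$ lets you make weak
interactions more common without touching $\sigma$. The diagonal
(self-regulation) is $-d$ unless a scheme below replaces it.

The pairwise sign structures are:

* *random*: both directions are independent draws of $Z$;
* *exploitative* (+/-): one direction $+|Z|$, the other $-|Z|$, the
  beneficiary chosen by a fair coin per pair (the coin is irrelevant to
  $H$ but fixed for reproducibility);
* *competitive* (-/-) and *mutualistic* (+/+): both directions $-|Z|$ or
  $+|Z|$;
* *mixed*: each connected pair is first assigned a type with
  probabilities $(P_{+/+}, P_{-/-}, P_{+/-})$.

The off-diagonal moments of a mixed ensemble have the closed forms
returned by `ensemble_moments()`:
$E = C\,\mathbb{E}(|Z|)(P_{+/+} - P_{-/-})$, $V = C\sigma^2 - E^2$, and
$\rho = \mathbb{E}(M_{ij}M_{ji}) = C\,\mathbb{E}^2(|Z|)
(P_{+/+} + P_{-/-} - P_{+/-})$; `empirical_moments()` measures the same
statistics on a realised matrix, together with the induced statistics of
$H$.

### Structured food webs

The *cascade* web puts species on a strict trophic hierarchy (species
index = trophic rank, low index = prey end, recorded in the object's
metadata): every lower-triangular position is filled with probability
$C$ by a $+|Z|$ entry (prey helps predator), its transpose partner with
$-|Z|$. Because transposition only swaps the signs that $H$ symmetrises
away, cascade webs share the symmetric-part statistics of exploitative
unstructured webs — the basis for their identical reactivity behaviour.

The *niche* web gives each species a niche value $\eta_i \sim U[0,1]$
(sorted), a feeding radius $r_i = \eta_i \mathcal{B}_i$ with
$\mathcal{B}_i \sim \mathrm{Beta}(1, 1/C - 1)$, and a centre
$c_i \sim U[r_i/2, \min(\eta_i, 1 - r_i/2)]$; species $i$ is prey of $j$
when $\eta_i$ lies in $j$'s feeding interval, giving interval (contiguous)
diets and a broad degree distribution. The sign matrix
$P = -A + A^{\mathsf T}$ cancels mutual predation and cannibalism.
Two numerical notes:

* the centre interval is provably non-empty (since
  $\mathcal{B}_i \le 1$), but a defensive re-draw (100 tries, then
  $r_i = 0$) guards it, and exact $\eta$ ties are re-drawn;
* with this Beta shape the *directed* link density converges to $C/2$,
  while the probability that an unordered pair interacts is $\approx C$
  — the quantity that matches the other generators' definition of
  connectance. The tests assert both values; comparisons across
  generators at equal $C$ are comparisons at equal pair connectance.

### Self-regulation schemes

`apply_self_regulation()` rewrites only the diagonal. Strengths can be
homogeneous ($-d$), heterogeneous uniform on
$[d_{\mathrm{mean}} - \sqrt3\sigma_d,\, d_{\mathrm{mean}} + \sqrt3\sigma_d]$
(rejected if the lower bound is negative, since self-regulation
strengths must be non-negative), optionally sorted so that higher
trophic ranks regulate more (`"positive"`) or less (`"negative"`), or a
subset of $S_n$ species can stop regulating entirely (zero diagonal),
placed at random or at the top/bottom trophic ranks. `"top_trophic"`
places the zeros at the $S_n$ highest ranks. Trophic orderings require a
cascade or niche matrix, whose index is a trophic rank.

## Analytic predictions

For large single-type communities the eigenvalues of $H$ concentrate on
a segment, possibly with one rank-one outlier
(`predict_unstructured()`):

* random: segment of half-length $\sigma\sqrt{2SC}$ centred at $-d$, so
  $\mathcal{R} = -d + \sigma\sqrt{2SC}$;
* exploitative: half-length
  $\sqrt{2SC(\sigma^2 - \mathbb{E}^2(|Z|))}$ — the negative pairwise
  feedback narrows the support;
* competitive: centre $-d + C\mathbb{E}(|Z|)$, half-length
  $\sqrt{2\sigma^2 SC + 2\mathbb{E}^2(|Z|)SC(1 - 2C)}$, and an outlier
  (approximately the row sum of $H$) to the *left*, which is reported
  but never sets $\mathcal{R}$;
* mutualistic: the outlier sits to the *right* at
  $-d + (S-1)C\mathbb{E}(|Z|)$ and determines $\mathcal{R}$.

At fixed parameters this orders predicted reactivity strictly:
exploitative < random < competitive < mutualistic. Shrinking
$\mathbb{E}(|Z|)$ at fixed $\sigma^2$ (weak interactions common) makes
exploitative communities *more* reactive, competitive and mutualistic
ones less, and leaves random ones unchanged — visible directly in the
closed forms.

For mixed ensembles `predict_mixed()` works from $(E, V, \rho)$: the
segment has half-length $\sqrt{2S(V + \rho - E^2)}$ centred at $-d - E$,
and when $|E| > \sqrt{(V + \rho - E^2)/(2S)}$ an outlier
$-d + (S-1)E$ competes; $\mathcal{R}$ is the larger candidate and the
branch is recorded. The two branches join continuously at the threshold.

With heterogeneous self-regulation (`predict_heterogeneous()`), the
uniform diagonal convolves with the interaction bulk. Writing
$\omega = \sqrt{S(V + \rho - E^2)/2}$ and rescaled support endpoints
$d_{1,2} = (-d_{\mathrm{mean}} \mp \sqrt3\sigma_d)/\omega$, the right
support edge is
$\omega\left(\tfrac{d_1 + d_2}{2} +
\sqrt{\left(\tfrac{d_2 - d_1}{2}\right)^2 + 1} +
\tfrac{2}{d_2 - d_1}\tanh^{-1}\tfrac{d_2 - d_1}
{\sqrt{(d_2 - d_1)^2 + 4}}\right) - E$.
The $\tanh^{-1}$ form is evaluated as written for
$|d_2 - d_1| \ge 10^{-8}$ and by the series $1 - u^2/24$ below it, which
avoids the $0/0$ cancellation; at $\sigma_d = 0$ the function returns the
homogeneous formulas exactly. On the outlier branch the candidate
$-d_{\mathrm{mean}} + (S-1)E + (V + \rho - E^2)/(2E) + \sigma_d^2/(SE)$
competes with the edge. Reactivity increases monotonically with
$\sigma_d$: heterogeneity in self-regulation is destabilising in the
transient sense, and even one non-regulating species pushes
$\max \lambda(H)$ above the zero diagonal entry, making the community
reactive regardless of how strongly everyone else regulates.

These support-edge formulas are asymptotic in $S$. The ensemble maximum
eigenvalue converges to the edge from below with the usual slow
edge-fluctuation scaling, so at moderate $S$ (a few hundred) a visible
finite-size gap remains, largest when the support edge approaches zero
(strong heterogeneity). The test suite measures this sweep explicitly at
$S = 200$ rather than hiding it; the gap closes by $S \approx 2000$.
Non-uniform self-regulation distributions and non-self-regulating
species have no closed forms here and are handled through the exact
numerical path (generate, then `reactivity()`).

## Phase geometry: how far is reactivity from instability?

On the segment branch the critical species counts at connectance $C$ are
$S_{\mathrm{react}} = (d + E)^2 / (2(V + \rho - E^2))$ and
$S_{\mathrm{stab}} = V (d + E)^2 / (V + \rho - E^2)^2$
(`critical_curves()`); when $E > 0$ the rank-one outlier can govern both
transitions at $S = d/E + 1$, and each curve takes the smaller value —
for mutualistic-dominant mixes the curves coincide, so a reactive
mutualistic community is always unstable.

The *normalised distance* (ND) between the two transitions is the area
of the reactive-stable region divided by the area of the whole stable
region. Because both segment-branch curves scale the same way with $C$,
the ratio collapses to $\mathrm{ND} = 1 - (1 + r)/2$ with the pairwise
correlation $r = (\rho - E^2)/V$: $1/2$ for random ensembles,
$1/2 + 1/\pi \approx 0.818$ for exploitative half-normal ensembles, $0$
when the outlier governs. ND falls as $P_{+/+}$ or $P_{-/-}$ grows and
rises with $P_{+/-}$.

`area_ratio_numeric()` re-derives ND with no theory: it classifies each
cell of an $(S, C)$ grid by the majority state of freshly generated
matrices (ties broken toward the less reactive state, a conservative
boundary placement) and takes the stable-reactive to stable area ratio.
Numerical design: cell widths live on the log-$C$ axis; cell heights are
linear in $S$ with geometric-midpoint boundaries, and the bottom cell
extends to $S = 0$ so the thin always-stable strip below the smallest
grid size is not lost. The window must contain the full stable region —
truncating the stability curve at the top of the grid was measured to
bias ND down by far more than the Monte-Carlo noise, which is why the
desk-scale defaults in the tests use $C \in [0.35, 0.8]$, $S \le 90$ for
random ensembles and $C \in [0.4, 0.9]$, $S \le 450$ for exploitative
ones (whose stable region reaches roughly $S \approx 470$).

`critical_sigma()` estimates a transition point the way the simulation
protocol defines it: $\sigma_1$ is the largest grid value where 100% of
replicates are still pre-transition, $\sigma_2$ the smallest where 100%
have crossed, and $\sigma_r = (\sigma_1 + \sigma_2)/2$; an unbracketed
transition is an error that reports the observed fractions. The 100%
rule is deliberately literal; it makes $\sigma_r$ a grid-resolution
quantity, which is how the tests compare cascade, niche and unstructured
webs ($S = 500$, $C = 0.3$, $d = 1$, 50 replicates per grid point, grid
step 0.005): cascade webs share the unstructured exploitative
$\sigma_r$, niche webs turn reactive at a strictly lower interaction
strength.

## Simulating perturbations and extinctions

`build_glv(M, X_star)` embeds any community matrix as a gLV system with
the chosen equilibrium ($A = \operatorname{diag}(X^*)^{-1} M$,
$r = -A X^*$), so the Jacobian at $X^*$ is exactly $M$.
`simulate_glv()` integrates with a stiff-capable adaptive solver
(relative tolerance $10^{-8}$, absolute $10^{-10}$), piecewise between
pulse instants. Extinction is an integration *event*: the solver locates
the downward crossing of $X_i$ through
`extinction_fraction` $\times X_i^*$ (default 1%) by root finding and
sets the species to zero, which the gLV flow then preserves; post-hoc
thresholding of stored output would miss rebounds between output points.
Pulses add `strength` to `n_targets` randomly picked species — a fresh
subset each pulse (the fixed-subset variant is an option), driven by a
dedicated seed so schedules are reproducible; a pulse that pushes a
species below its threshold registers an extinction at the pulse time.
Abundances are never clipped silently.

`initial_amplification()` closes the loop between theory and dynamics:
the instantaneous growth rate of a pulse in direction $x$ is the
Rayleigh quotient $x^{\mathsf T} H x / x^{\mathsf T} x$, maximised at
$\mathcal{R}$ by the leading eigenvector of $H$, and the nonlinear
short-time trajectory matches it for small pulses.

### The frequent-perturbation species-loss experiment

`species_loss_experiment()` generates stable unstructured food webs
($S = 50$, $C = 0.2$, $\sigma = 0.05$; unstable draws are discarded and
counted), embeds them with $X^* = 1$ and per-capita self-regulation $s$,
and measures the percentage of communities losing at least one species
under periodic pulses over a horizon of 500 time units, with 30 species
pulsed per event. The interaction type matters: at these parameters an
exploitative web with $s = 0.1$ is reactive yet stable (elliptic-law
abscissa $-s + (1 - 2/\pi)\,\sigma\sqrt{SC} \approx -0.043$, reactivity
$-s + \sigma\sqrt{2SC(1 - 2/\pi)} \approx +0.035$), whereas a
sign-unconstrained random matrix would already be unstable at $s = 0.1$
— there is no reactive-stable regime to probe there, which is why the
food-web type is the default. With $s = 1$ the same webs are stable and
non-reactive.

Pulse strength is measured in units of the equilibrium abundance and the
frequency in pulses per time unit; the default grids
($\{0.25, 0.5, 1, 2\}\times\{0, 0.25, 0.5\}$, frequency 0 meaning a
single pulse) span the transition from no species loss to full loss in
the reactive regime. The headline contrast — computed by the tests and
the acceptance script — is that single small pulses are harmless in both
regimes, while frequent mid-strength pulses drive extinctions in the
reactive regime and none in the non-reactive one, although both are
asymptotically stable. Single-trajectory demonstrations use $X^* = 2$;
the loss maps use $X^* = 1$.

## The empirical-community pipeline and synthetic fixtures

`empirical_reactivity(A, r)` runs the pipeline used for communities with
independently inferred gLV parameters: solve $A X^* + r = 0$, require
feasibility (infeasible equilibria abort with the offending species
listed — projecting onto a feasible subcommunity is out of scope),
form $M_e = \operatorname{diag}(X^*) A$ and report the reactivity of
$H_e$ plus the interaction-type composition.
`interaction_proportions()` classifies unordered pairs by the signs of
the two directed effects; pairs with only one direction above the
threshold (default 0) go into a separate commensal/amensal bin rather
than being forced into the three-way split. Note that abundance scaling
matters: a non-reactive $A$ can still yield a reactive $M_e$ under
uneven $X^*$, so reactivity is always computed from $M_e$.

`make_fixture()` produces small (4-5 taxa) *synthetic* parameter sets in
the same file format — a positive $X^*$ is drawn first and $r = -AX^*$
set afterwards, so feasibility is guaranteed, with a requested pair-sign
composition and coupling scale. These emulate the shape of inferred
microbial-community parameters for pipeline testing only; they are not
fits to any data, and nothing in the package infers $A$ or $r$ from
abundance time series.

## What the synthetic ensembles do and do not show

The generators realise the idealised ensembles the theory is derived
for: independent Bernoulli links, a single strength scale, at most
block-level structure (trophic hierarchy or niche intervals), and exact
self-regulation schemes. Real interaction networks have degree
correlations, modularity, abundance heterogeneity and measurement noise
that these ensembles deliberately lack, so green tests here validate the
mathematics and the implementation, not the claim that any particular
real community is reactive. The problem sizes used throughout the tests
($S$ from 50 to 500, ensembles of 20-50, a 500-time-unit horizon) are
desk-scale choices that keep every experiment re-runnable in minutes
while staying inside the asymptotic regime of the formulas, except where
the tests intentionally measure the finite-size gap.

## Known limitations

* Support endpoints and outliers only — no full eigenvalue densities,
  pseudospectra or transient envelopes.
* Closed forms for heterogeneous self-regulation assume the uniform
  distribution; other distributions go through the numerical path.
* The rank-one outlier location ignores higher-order corrections, which
  makes sparse mutualistic-dominant communities turn reactive slightly
  before the predicted threshold.
* White-noise (stochastic) forcing, demographic noise and spatial
  structure are out of scope; perturbations are instantaneous abundance
  pulses.
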