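---
title: "Modeling proto-community formation through emotional contagion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling proto-community formation through emotional contagion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protocontagion)
```

## The model

This package studies how a population of individuals, each occupying
one of two emotional attractor states — positive (PEA, +1) or negative
(NEA, −1) — can synchronize into an ordered, persistent group state.
Three layers are implemented, from micro to macro.

**Substrate.** In the absence of interaction, states are independent
Bernoulli draws: PEA with probability `p_pea`. The order parameter
ξ = (#PEA − #NEA)/N is exactly the mean of the ±1 encoding, so
E[ξ] = 2·p_pea − 1 and the default `p_pea = 0.5` normalizes the
substrate mean to 0. Transitional states between the two attractors are
treated as noise: an individual is always exactly PEA or NEA.

**Contagion.** The engine follows the generalized contagion scheme of
dose, memory and threshold. Per step, each individual contacts one
uniformly random other (self-contact excluded, sampling with
replacement across individuals); a contact with an infected individual
delivers a dose from `dose_model` with probability `p_exposure`. Each
individual keeps the doses of the last `T_mem` steps; a susceptible
whose window sum *strictly* exceeds its threshold becomes infected.
Infected individuals whose window sum has dropped to or below the
threshold recover with probability `r`; removed individuals become
susceptible again with probability `rho`. All transitions in a step are
evaluated synchronously against the time-t state, which is what makes
the mean-field comparison below well-posed. With the defaults
`r = rho = 1` recovery goes straight back to susceptibility, the
removed class is empty at every step, and N = S + I.

**Aggregate dynamics.** At the macro level the order parameter relaxes
under the cusp normal form dξ/dt = c_int + c_ext·ξ − ξ³, the gradient
flow of V(ξ) = ξ⁴/4 − c_ext·ξ²/2 − c_int·ξ. The theory this package
implements invokes "the canonical model" for one order parameter and
two controls without printing an equation; the normal form above is the
canonical choice, oriented so that (a) the c_int = 0 section undergoes
a pitchfork at c_ext = 0 (one stable state for c_ext < 0, two at
±√c_ext beyond it) and (b) for c_ext > 0 bi-stability holds exactly
for |c_int| < a. The constant a is not free: setting the cubic
discriminant 4c_ext³ − 27c_int² to zero gives a = 2(c_ext/3)^{3/2},
which `fold_thresholds()` computes rather than assumes.

## Parameters that matter

| parameter | meaning | default | rationale |
|---|---|---|---|
| `p_pea` | substrate PEA probability | 0.5 | normalizes E[ξ] to 0 |
| `p_exposure` | dose delivery probability per infected contact | — | the main contagion dial; named to avoid the substrate/contagion symbol collision on "p" |
| `T_mem` | memory length (steps) | — | couples reinforcement to time; P_k is defined for k = 1..T |
| `r`, `rho` | recovery / re-susceptibility probabilities | 1, 1 | the analytically solvable case; R stays empty |
| `dosing_mode` | who receives doses | `"susceptible_only"` | see "Two dosing readings" below |
| `contagious_state` | which state spreads | `"PEA"` | NEA contagion is configuration, not a separate mechanism; lower NEA thresholds are expressed by passing a different threshold model |
| `c_ext`, `c_int` | cusp controls | — | opportunity/risk tension; proto-community potential |

Doses and thresholds support `delta`, `uniform` and `lognormal`
families, all with nonnegative support.

## Two dosing readings

The source model description contains a genuine ambiguity: it states
that non-susceptible individuals receive zero dose, yet recovery is
narrated as an infected individual's dosing "dropping below" its
threshold. Neither reading is privileged, so both are implemented:

- `"susceptible_only"` (default): only susceptibles receive doses. Infected
  memories drain passively and recovery follows within at most `T_mem`
  dose-free steps.
- `"all"`: every individual receives doses and compartment status is a
  pure function of the memory window.

The mean-field map is derived for `"all"` dosing, which is therefore the
mode used in all analytic-agreement experiments. Whether removed
individuals (when `rho < 1`) keep their memory is likewise unspecified;
memory is retained and keeps sliding.

## The mean-field map and P_k

P_k = E_g[Pr(sum of k doses > d*)] is the probability that k doses
infect. Under `"all"` dosing with r = ρ = 1, each of the `T_mem` window
slots was dosed independently with probability p·φ, so the next
expected infected fraction is the binomial mixture
φ′ = Σₖ C(T,k)(pφ)ᵏ(1−pφ)^{T−k} P_k. The map is not printed in the
source theory (only its solvability is asserted); it is derived here
and validated against the agent simulation: at n = 10⁴ the simulated
steady infected fraction lies within binomial noise of a stable fixed
point of the map on both shipped scenarios (the test suite runs this at
10 seeds).

Numerical notes:

- P_k is exact (closed form) for delta doses and for uniform doses
  against a delta threshold (Irwin–Hall); otherwise the survival
  function of the dose sum is built by discretized convolution
  (2¹³-cell grid) and integrated against the threshold distribution by
  cell masses rather than adaptive quadrature — the integrand is
  step-like and defeats adaptive rules. Monte Carlo estimation is also
  available and is cross-checked against quadrature in the tests.
- Tiny non-monotonicities of numerical P_k in k are smoothed by a
  running maximum; the exact P_k is provably non-decreasing because
  doses are nonnegative.
- `steady_states()` iterates the map from a grid of starts
  (convergence |Δφ| < 10⁻¹⁰), merges limits within 10⁻⁶, classifies
  stability by a centered numerical derivative with step 10⁻⁵, and
  locates unstable separatrices by bisection on initial conditions —
  valid because the map is monotone in φ, so basin boundaries are
  themselves fixed points.

## Regime classification

Single-encounter contagion holds when P₁ ≥ P₂/2 *and* P₁ > 0;
otherwise reinforcement is required. The P₁ > 0 qualifier covers the
degenerate case P₁ = P₂ = 0 (e.g. unit doses against a threshold of
3.5), where the bare inequality is satisfied vacuously although no
first encounter can ever infect — calling that "single-encounter" would
be meaningless. The secondary inequality P₂ > P₁/2 ≥ 1/T that
accompanies the published two-regime split is internally inconsistent
with the prose around it; it is computed and reported as a diagnostic
flag but never gates the label.

## Thresholds, ties and seeding

- Infection requires *strict* exceedance: a cumulative dose exactly
  equal to the threshold never infects (tested explicitly).
- Initially infected individuals get a single pre-loaded memory entry
  of d\*·(1 + 10⁻⁶) in the newest slot, so "status follows memory"
  holds from the first step.
- Thresholds are drawn once at initialization;
  `redraw_threshold_on_resusceptibility = TRUE` optionally re-draws on
  return to susceptibility.
- Replacement in `turnover_run()` draws Binomial(n, rate) newcomers per
  step: susceptible, zero memory, fresh threshold. With rate 0 the
  trajectory is bit-identical to `run_contagion()` under the same seed
  (the binomial draw is skipped so the RNG streams coincide).

## Cusp numerics

- Equilibria come from `polyroot()` away from the fold set; when the
  discriminant is (numerically) zero the double and simple roots are
  taken in closed form, so folds are exact (e.g. c_ext = 3, c_int = 2
  gives the marginal root −1 and the stable root 2).
- Stability is the sign of the flow derivative c_ext − 3ξ²; double
  roots are reported as `marginal`, never silently merged.
- `hysteresis_sweep()` relaxes by explicit Euler (default h = 0.01, 500
  steps per path value) and flags a jump when |Δξ| between consecutive
  path values exceeds 0.5 — above relaxation noise, below the
  inter-branch gap near folds for c_ext ≥ 1. Passage through a fold is
  slow, so one physical jump can spread over consecutive path values;
  runs of flagged values are merged into a single jump event. The
  bifurcation tests use 2000 relaxation steps per value so the jump
  completes within one path step of the fold.
- Divergence (|ξ| > 10) aborts with an error rather than returning
  nonsense.

## Detecting transitions and scoring persistence

"Changes from nearly −1 to nearly 1 and remains stable for a time" is
operationalized with three constants: a jump threshold of 1.0 in ξ, a
window of 20 steps, and a stability tolerance of 0.2 (window standard
deviation). The published description names no duration, so the window
is a declared convention; all three are arguments. The persistence
score is the fraction of post-burn-in steps (default burn-in: first
25%) at which ξ keeps the target sign and stays within `tol` of its
trailing-window mean.

## The control-parameter mapping

The theory assigns c_ext and c_int roles but no functional link to the
micro-model. `scenario_mapping()` makes that link explicit and
overridable, keeping the contagion core mapping-free: by default
`p_exposure = logistic(c_int)` (anchor: 0.5 at c_int = 0, monotone
increasing) and the threshold-model mean is rescaled to
`softplus(1 − c_ext)` (monotone decreasing in tension). These are
modeling conveniences, not claims about the theory.

## What the fixtures emulate — and what they do not

The shipped presets are chosen for clean oracles, not as empirical
calibrations (the source theory prints no simulation settings):

- `fire_in_theater` — one unit dose beats the 0.5 threshold (P₁ = 1,
  T = 1): single-encounter contagion. Its exposure probability is fixed
  at 0.9, making the mean-field map a strict contraction to 0 — a clean
  analytic target.
- `bistable_syndicate` — unit doses against a 3.5 threshold with
  T = 12 make P_k a step at k = 4; at p_exposure = 0.6 the map is
  bi-stable (stable 0 and ≈ 0.981, separatrix ≈ 0.491).
- `turnover_community` — the bi-stable scenario at n = 2000 with 1%
  turnover per step.

Synthetic populations here are well-mixed (every pair equally likely to
meet), memoryless beyond the dose window, and free of external shocks.
Passing tests therefore demonstrate internal consistency of the
implementation and the predicted regime behavior under random mixing —
not that real populations follow these dynamics: contact networks,
heterogeneous susceptibility, competing simultaneous contagions and
time-varying substrates are all outside the model class.

## Problem sizes

The test suite runs the mean-field agreement experiments at n = 10⁴
individuals for 300 steps (10 seeds per scenario), the turnover
persistence experiment at n = 2000 for 300 steps (20 seeds), and the
bifurcation property checks on 10³ random control-parameter pairs;
these sizes hold every Monte-Carlo error bound used in the assertions
well below the effect sizes being checked while keeping the whole suite
inside a couple of minutes on one CPU.

## Known limitations

- The mean-field map assumes `"all"` dosing; no analytic layer is
  provided for `"susceptible_only"` dosing or for r, ρ < 1 (simulation only).
- Only the two-regime split printed in the main text of the source
  theory is implemented; the full three-class taxonomy of the cited
  contagion model (referenced there only via an unavailable footnote)
  is not.
- The cusp layer is deterministic; stochastic (noise-driven) switching
  between attractors, and fitting cusp parameters to data, are out of
  scope.
- A time-varying substrate probability ("leaning" with macro
  conditions) is not implemented; no drift process is specified in the
  source theory.
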