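# protocontagion

Simulation and analysis tools for **proto-community formation through
emotional contagion**: how shared emotional states spread through a
population of individuals and stabilize into an ordered, persistent
group state before any deliberate organizing takes place.

The package is aimed at researchers in computational social science,
organizational theory and mathematical epidemiology who want a
reproducible, seeded implementation of three coupled layers:

1. **A bi-state population substrate.** Every individual occupies one of
   two emotional attractor states — a positive one (PEA, encoded +1) or
   a negative one (NEA, encoded −1). The population-level *order
   parameter*

   ξ = (#PEA − #NEA) / N ∈ [−1, 1]

   is the mean of the encoding: ξ = +1 for an all-PEA population, −1
   for all-NEA, 0 for an independent 50/50 mix. A sudden, stable change
   of ξ from one extreme toward the other is a *phase transition*.

2. **A generalized dose–memory–threshold contagion engine.** The
   population splits into susceptible / infected / removed compartments
   (S + I + R = N). Each step every individual contacts one random
   other; contact with an infected individual delivers an emotional
   "dose" d ~ f(d) with probability p. Individuals remember doses over
   the last T steps and become infected when the cumulative dose
   strictly exceeds their personal threshold d\* ~ g(d\*). With removal
   rate r = 1 and re-susceptibility rate ρ = 1 the removed class stays
   empty and the dynamics admit a mean-field description: writing φ for
   the infected fraction, the expected update under dosing of all
   individuals is

   φ′ = Σₖ C(T,k) (pφ)ᵏ (1 − pφ)^(T−k) · P_k,

   where P_k is the probability that k doses beat a random threshold.
   Comparing P₁ with P₂/2 separates *single-encounter* contagion (one
   interaction suffices) from *reinforcement-required* contagion
   (repeated exposures needed), the regime in which the map can be
   bi-stable.

3. **The cusp-of-change model.** At the aggregate level the order
   parameter relaxes under the cusp normal form dξ/dt = c_int +
   c_ext·ξ − ξ³, with c_ext the *opportunity/risk tension* and c_int
   the *proto-community potential*. The c_int = 0 section shows a
   pitchfork bifurcation at c_ext = 0; for c_ext > 0 the system is
   bi-stable for |c_int| < a = 2(c_ext/3)^(3/2) and jumps branches at
   the folds c_int = ±a (hysteresis, "tipping points").

A *proto-community* is an aggregate whose order parameter stays stable
while members leave and newcomers join; the package scores this
directly via turnover experiments.

## Worked example

The "syndicate" scenario needs four unit doses inside a 12-step memory
(threshold 3.5), with exposure probability 0.6 — a reinforcement-required
configuration whose mean-field map is bi-stable:

```r
library(protocontagion)

P <- infection_probabilities(dose_model("delta", value = 1),
                             threshold_model("delta", value = 3.5),
                             T_mem = 12)
P
#> <infection_probabilities> T = 12
#>  [1] 0 0 0 1 1 1 1 1 1 1 1 1
classify_regime(P)
#> <regime_label> reinforcement_required (P1 = 0.0000, P2/2 = 0.0000)
steady_states(0.6, P)
#>         phi stability
#> 1 0.0000000    stable
#> 2 0.4912531  unstable
#> 3 0.9813151    stable
```

No single encounter can infect (P₁ = 0), and the mean-field map has two
stable states — extinction at φ = 0 and an ordered state at φ ≈ 0.981 —
separated by an unstable point at φ ≈ 0.491. A seeded agent-based run
with 1% membership turnover per step stays on the high branch, i.e. the
ordered state is a persistent proto-community:

```r
fx <- generate_fixture("turnover_community", seed = 1)
tr <- turnover_run(fx$contagion, n = 2000, t_max = 300,
                   init_infected_fraction = 0.9,
                   replacement_rate = 0.01, seed = 1)
summary(tr)
#> contagion trajectory: n = 2000, 300 steps
#>   final infected fraction: 0.8980
#>   tail mean infected fraction: 0.8818 (xi = 0.7637)
#>   max R over run: 0
proto_community_persistence(tr, target_xi_sign = 1, burn_in = 1/3)
#> [1] 1
```

The simulated infected fraction sits near the stable mean-field state
(the gap to 0.981 reflects the 1% of members replaced by fresh,
not-yet-infected newcomers each step), R stays empty because r = ρ = 1,
and the persistence score of 1 says ξ kept its sign and level through
the turnover. On the aggregate side, the cusp layer gives the
bifurcation structure directly:

```r
cusp_equilibria(cusp_params(c_ext = 1, c_int = 0))
#> <cusp_equilibria> c_ext = 1, c_int = 0
#>   xi stability
#> 1 -1    stable
#> 2  0  unstable
#> 3  1    stable
fold_thresholds(3)
#> [1] 2
```

A command-line wrapper over the same functions is installed under
`inst/cli/protocontagion.R` (subcommands `simulate`, `meanfield`,
`phase-diagram`, `cusp`, `detect`, `fixtures`), reading YAML configs and
writing CSV outputs with JSON sidecars.

## Package layout

- `R/population.R` — substrate generation, order parameter, sampling
- `R/contagion.R`, `R/trajectory.R` — agent-based engine, turnover runs
- `R/dose-models.R`, `R/meanfield.R` — f/g distributions, P_k, the
  mean-field map, fixed points, regime classification, phase diagrams
- `R/cusp.R` — cusp equilibria, bifurcations, hysteresis
- `R/scenarios.R` — control-parameter mapping, transition detection,
  persistence scoring
- `R/fixtures.R`, `R/config.R`, `R/cli.R` — seeded scenario presets,
  YAML configuration, command-line interface
- `vignettes/proto-community-dynamics.Rmd` — the methods vignette
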