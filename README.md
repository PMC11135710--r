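# diauxie

Event-driven simulation of microbial (and other boom-and-bust)
communities whose members use resources **sequentially** — diauxie —
under periodic cycles of resource pulse, growth to depletion, and
mortality.  The package is for ecologists and modellers studying how
temporal niches arise from sequential resource utilization and how
environmental fluctuations let many more species than resources coexist
("competitive exclusion violations").

## The model

Species μ has growth rates *g<sub>μi</sub>* (hr⁻¹, one per resource
R<sub>i</sub>) and a preference permutation; at any moment it consumes
only its top-ranked not-yet-depleted resource and grows exponentially on
it, with yield 1:

```
dn_μ/dt = g_{μ r_μ({c})} n_μ        dc_i/dt = − Σ_{μ eating R_i} g_{μi} n_μ
```

Each growth cycle starts with a resource pulse *c<sub>i</sub> →
s<sub>i</sub>* (Σ s = 1), runs until every supplied resource is
depleted, and ends with mortality *n<sub>μ</sub> → n<sub>μ</sub>/10*;
species whose population fraction drops below 10⁻¹² go extinct.  Because
within a phase all growth is exponential, depletion events are found by
root-finding on sums of exponentials (no ODE integration), making runs
of 10⁵–10⁶ cycles cheap and exact.

Between consecutive depletions the community sits in a **temporal
niche** — a period with a particular subset of resources available.  At
most 2<sup>N</sup>−1 niches exist for N resources, and that number — not
N — bounds diversity when the depletion order varies from cycle to
cycle.  The package provides the simulator plus:

- random species pools under the L2 metabolic constraint
  Σ g² = 1 hr⁻² (`sample_pool`, `pool_size`);
- supply schedules: constant, uniform on the simplex, single random
  resource, seasonal sinusoids, and a calibrated stochastic family
  parameterised by the fluctuation magnitude
  σ_RS = √⟨(s_i − 1/3)²⟩ ∈ [0, 0.471] (`supply_sampler`,
  `seasonal_supply`);
- temporal-niche extraction, the 2^N−1 bound, time-on-preference
  statistics, and constrained-optimal strategies g* = τ/‖τ‖₂
  (`tally_niches`, `time_on_preferences`, `optimal_allocation`,
  `optimal_strategy_set`);
- experiment drivers: the 5+3-repetition survivor protocol with a
  declining-trend filter, competitive-exclusion sweeps over σ_RS,
  diversity-versus-resources scaling with linear/monomial/exponential
  fits, seasonal assembly, and dynamics classification
  (`survivor_protocol`, `ce_violation_sweep`, `diversity_scaling`,
  `fit_diversity_law`, `seasonal_assembly`, `classify_dynamics`).

## Worked example

Assemble a random 300-species community on three resources under a
fluctuating supply (σ_RS = 0.15):

```r
library(diauxie)
pool <- sample_pool(3, 300, seed = 11)
set.seed(99)
sim <- run_serial_dilution(pool, supply_sampler(0.15), 10000)
summary(sim)
#> 5 of 300 species survive on 3 resources after 10000 cycles
#>   competitive exclusion violated: TRUE
#>   distinct temporal niches observed: 7 (max 7 )
#>   mean cycle length: 2.833 hr
```

Five species stably coexist on three resources — a competitive-exclusion
violation — and all seven possible temporal niches occur.  (Two of the
five survivors happen to sit at very low fractions on the final cycle;
under a fluctuating supply abundances swing over orders of magnitude
without the species going extinct.)  The time species spend growing on
each preference rank predicts the optimal strategy:

```r
tau <- time_on_preferences(sim)
round(unclass(tau)[1:3], 3)
#> rank1 rank2 rank3
#> 2.266 0.392 0.187
round(optimal_allocation(tau), 3)
#> [1] 0.982 0.170 0.081
d <- survivor_strategy_distance(pool$growth_rates[sim$survivors, ],
                                optimal_strategy_set(tau))
round(attr(d, "mean"), 3)
#> [1] 0.05
```

Survivors invest most in their first preference (0.982 of their unit
growth-rate budget) and sit within 0.05 (Euclidean, in growth-rate
space) of the predicted optimal strategies — the clustering that makes
these communities predictable.

A thin command-line wrapper over the same functions ships at
`inst/cli/diauxie.R` (subcommands `pool-gen`, `supply-gen`, `simulate`,
`sweep`, `seasonal`, `fit`).

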