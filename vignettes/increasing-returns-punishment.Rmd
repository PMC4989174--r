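---
title: "Increasing returns to scale and the evolution of altruistic punishment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Increasing returns to scale and the evolution of altruistic punishment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pggirs)
```

## The model

`pggirs` studies a public goods game (PGG) among three behavioural types
in a well-mixed population of constant size $M$: cooperators ($C$)
contribute cost $c$ to a joint project; defectors ($D$) contribute
nothing; punishers ($P$) contribute *and* fine every defector in their
group by $\delta$, paying $\gamma$ per defector fined. Each period a
group of $N$ players is sampled without replacement. With $x + z$
contributors in the group, total production follows a Cobb–Douglas
technology with defector productivity fixed at zero,

$$ \Pi = c\,r\,(x+z)^{\alpha}, $$

shared equally among all $N$ members (defectors included). A member's
payoff is the equal share minus its own costs and fines:

$$ P_x = \frac{\Pi}{N} - c, \qquad
   P_y = \frac{\Pi}{N} - \delta z, \qquad
   P_z = \frac{\Pi}{N} - c - \gamma y. $$

Two identities organize everything that follows: $P_x - P_z = \gamma y$
(punishers pay only the punishment cost extra — cooperators are
*second-order free-riders*), and $P_x - P_y = \delta z - c$ (punishment
deters defection exactly when $\delta z > c$). For $\alpha > 1$
production is superlinear in the number of contributors — *increasing
returns to scale* — which is the lever this package exists to study: it
raises the value of one's own contribution until defection, and with it
the need for costly punishment, collapses.

Payoffs map to reproductive fitness exponentially, $F = e^{\omega P}$,
which is well-defined for payoffs of any sign and admits arbitrary
selection strengths $\omega$.

## Exact small-mutation analysis

When the mutation rate $\mu \to 0$, at most two types coexist at any
time, and the long-run dynamics reduce to a Markov chain over the three
homogeneous states. The building blocks:

1. **Hypergeometric group sampling.** With $m_i$ players of type $i$
   among $M$, the number of type-$i$ players among $N$ draws follows
   the hypergeometric law (`group_sampling_pmf()`, via `stats::dhyper`).
2. **Expected pairwise payoffs.** The expected payoff of a type-$i$
   player facing type $j$ is the payoff of a focal player whose $N-1$
   co-players contain $k \sim \mathrm{Hyper}(m_i, M-m_i, N-1)$ players
   of its own type (`expected_payoff_pair()`). The co-player pool uses
   the population composition itself — the same sampling law as the
   group draw. The alternative focal-conditioned convention (own-type
   pool $m_i - 1$ out of $M-1$) was implemented and compared during
   development: it shifts the cooperator/defector crossover of the
   analytic scan from grid point 1.3 to 1.4 (continuous crossing near
   1.30) and was rejected in favour of the form that derives directly
   from the group-sampling law; at $M = 100$ the two differ by $O(1/M)$.
3. **Moran rates.** Birth–death transition probabilities
   $T^{\pm}$ combine fitness-proportional birth with uniform death
   (`moran_transition_probs()`); their ratio is
   $\theta = T^-/T^+ = F_j/F_i$.
4. **Fixation probabilities.** The classical birth–death product
   formula
   $\rho_{ij} = \bigl(1 + \sum_{k=1}^{M-1}\prod_{l=1}^{k}\theta_l\bigr)^{-1}$
   (`fixation_probability()`). Products are accumulated as sums of
   $\log\theta$ with a log-sum-exp outer sum: at $\omega = 5$, $M = 1000$
   the products span hundreds of orders of magnitude, and the log-space
   path keeps every $\rho$ finite in $[0, 1]$.
5. **Embedded chain and stationary law.** Each of the two possible
   mutant types arises with probability $1/2$, giving off-diagonal
   entries $\rho_{ij}/2$ (`embedded_transition_matrix()`). The
   stationary distribution is computed twice — eigenvector of the
   transposed matrix, and direct solve of the homogeneous system with
   the normalization identity — and the call fails unless the two agree
   to $10^{-10}$ (`stationary_distribution()`). A unit eigenvalue that
   is numerically non-simple (reducible or periodic chain) is rejected
   rather than silently resolved.

`alpha_scan()` repeats the whole pipeline over a grid of $\alpha$
values; the default experiments use step 0.1, matching the granularity
at which threshold statements are made.

```{r scan}
scan <- alpha_scan(game_params(M = 100, N = 5, c = 1, r = 3,
                               delta = 1, gamma = 0.3, omega = 0.1),
                   alpha_grid = seq(1, 2, by = 0.1))
round(scan, 4)
```

The defector state's weight falls monotonically with $\alpha$;
cooperators and punishers both reach it by $\alpha = 1.3$ and defectors
hold under 5% of the time from $\alpha = 1.5$. At large $\alpha$ the
law converges to $(1/2, 0, 1/2)$: with defection extinct, punishment is
never exercised, $C$ and $P$ are payoff-identical, and they split the
time by neutral drift — the second-order dilemma has dissolved rather
than been won.

## Agent-based simulator

At finite mutation rates the package simulates the process literally
(`run_simulation()`): per period one group of $N$ plays the game
(nested hypergeometric draws); sampled members earn that game's payoff
and everyone else earns 0, so non-participants carry baseline fitness
$e^{0} = 1$; one uniformly chosen individual dies and is replaced by an
offspring drawn with probability proportional to each type's total
fitness mass (the *genetic pool* update — distributionally identical to
materializing $M$ fitness-chosen offspring and drawing one uniformly,
which is kept as a `pool = "literal"` verification mode); the newborn
mutates with probability $\mu$, uniformly to one of the two other
types. Mutation acts on the newborn only: a per-individual per-period
sweep would inflate the effective mutation rate $M$-fold.

The inner loop is compiled (Rcpp) but consumes R's RNG in exactly the
call order of the exported step functions `play_one_period()` and
`genetic_pool_update()`, so `engine = "r"` reproduces the compiled
trace bit for bit — this equivalence is a standing test, and seeded
runs are exactly reproducible anywhere.

```{r sim}
p <- game_params(M = 100, N = 5, c = 1, r = 3, alpha = 1.8,
                 delta = 1, gamma = 0.3, omega = 0.5, mu = 0.001)
cfg <- sim_config(periods = 20000, seed = 1,
                  initial_state = population_state(30, 40, 30),
                  burn_in = 0, record_every = 20000)
run_simulation(p, cfg)$mean_frequencies
```

`parameter_sweep()` replicates runs over a grid of any one parameter
(or the initial composition), deriving per-run seeds as
`seed + 10007 * (grid_index - 1) + (replicate - 1)` so replicates are
independent yet reproducible from the base seed.

## What the defaults emulate, and what they do not

The canned recipes (`run_recipe()`, `list_recipes()`) fix the headline
parameter sets: the analytic scan at $M = 100$, $N = 5$, $c = 1$,
$r = 3$, $\delta = 1$, $\gamma = 0.3$, $\omega = 0.1$; the simulation
experiments at $\omega = 0.5$, $\mu = 0.001$, start $(30, 40, 30)$,
100{,}000 periods, 20 replicates, with time averages taken over the
full run (`burn_in = 0`). Sweep grids are package choices: the $\alpha$
panels use 1.0–1.5 by 0.1 (bracketing the simulated crossover), and the
remaining panels bracket their default value both ways. Where the
figure-caption defaults for the non-swept $\alpha$ are ambiguous, the
$r$ panel uses $\alpha = 1$ (constant returns) and the cost/strength
panels use $\alpha = 1.8$ (strong increasing returns); every recipe
accepts overrides.

Two caveats frame what passing experiments show. First, the simulated
strategy frequencies at these horizons are dominated by long-lived
monomorphic regimes: single-run averages (and even 20-replicate means
near the threshold) carry large regime-level noise, which is why the
crossover of punisher over defector frequency is reported on a 0.1 grid
and not finer. Second, in defector-free states $C$ and $P$ are exactly
payoff-identical, so which of the two heads the surviving regime in any
single strong-returns run is a drift coin flip; claims about punishers
specifically are only meaningful where defectors still circulate, or as
statements about the $C$/$P$-symmetric stationary law.

The model is deliberately minimal: well-mixed population (no space or
network), three fixed strategies (no loners, pool punishers, or
anti-social punishment), binary contribution, and one sampled game per
period. Real populations violate most of these; the package
characterizes the mechanism, not any empirical dataset.

## Numerical choices

* $0^\alpha = 0$ for all $\alpha > 0$: the all-defector group produces
  nothing and no domain error is raised.
* Payoffs are never clamped; the exponential fitness map absorbs
  negative payoffs (e.g. heavily fined defectors).
* Counterfactual payoffs: `group_payoffs()` always returns all three
  entries, including types absent from the composition — the
  focal-player construction requires them.
* All $\prod \theta_l$ products live in log space; the stationary
  distribution requires eigen/direct-solve agreement to $10^{-10}$ and
  rejects non-unique solutions instead of picking one.
* Eigenvector selection: eigenvalue nearest 1, normalized by component
  sum, rejected if any component is below $-10^{-9}$ after
  normalization.
* Problem sizes in the shipped tests: analytic cross-checks use
  $M \le 20$ (where the absorbing-chain linear solve is exact and
  cheap) plus $M = 1000$ stress points; simulator invariants use runs
  from $10^3$ to $4 \times 10^7$ periods and replicate counts up to
  2000, sized so the full suite completes in well under a minute.

## Known limitations

* The $\mu \to 0$ analysis is hard-sized to three strategies; the
  simulator likewise.
* Finite-$\mu$ stationary behaviour is available only by simulation; no
  perturbative corrections are computed.
* Near the simulated threshold the punisher-vs-defector crossover has
  one-grid-step uncertainty by construction (regime noise); treat
  single-seed thresholds accordingly.
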