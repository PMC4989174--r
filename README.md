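# pggirs

Evolutionary dynamics of public goods games with **increasing returns to
scale** and **altruistic punishment**.

## The problem

In a standard public goods game, defectors out-earn cooperators
(first-order social dilemma), and because punishing defectors is costly,
cooperators who don't punish out-earn the punishers who protect them
(second-order social dilemma). `pggirs` implements a minimal resolution
of the second-order dilemma that adds no new strategies or rules:
production with increasing returns to scale. With $x + z$ contributors
in a group of $N$, total production is Cobb–Douglas,

$$\Pi = c\,r\,(x+z)^{\alpha},$$

shared equally among all $N$ members, with per-member payoffs

$$P_x = \tfrac{\Pi}{N} - c,\qquad P_y = \tfrac{\Pi}{N} - \delta z,\qquad
  P_z = \tfrac{\Pi}{N} - c - \gamma y,$$

for cooperators, defectors and punishers respectively
($\delta$ = punishment strength, $\gamma$ = punishment cost, both per
punisher–defector pair). Fitness is $F = e^{\omega P}$. When the scale
coefficient $\alpha$ exceeds 1, one's own contribution becomes valuable
enough that defection — and with it the need for costly punishment —
collapses.

The package provides, for a finite population of size $M$ under
frequency-dependent Moran dynamics:

* the **exact small-mutation analysis**: hypergeometric expected
  payoffs, birth–death fixation probabilities
  $\rho_{ij} = (1 + \sum_{k=1}^{M-1}\prod_{l=1}^k \theta_l)^{-1}$
  computed in log space, the embedded 3-state Markov chain over
  homogeneous states, and its stationary distribution (cross-validated
  eigenvector vs direct linear solve);
* a fast **agent-based simulator** (compiled inner loop, bit-identical
  to the exported R step functions on the same seed) with genetic-pool
  reproduction and newborn mutation;
* replicated **parameter sweeps**, canned **experiment recipes**, and a
  **command-line front end**.

## Worked example

Stationary distribution of the homogeneous states ("relative time" in
the all-C, all-D, all-P states) as returns to scale increase, at
$M = 100$, $N = 5$, $c = 1$, $r = 3$, $\delta = 1$, $\gamma = 0.3$,
$\omega = 0.1$:

```r
library(pggirs)
scan <- alpha_scan(game_params(M = 100, N = 5, c = 1, r = 3,
                               delta = 1, gamma = 0.3, omega = 0.1),
                   alpha_grid = c(1.0, 1.3, 1.6))
round(scan, 4)
#>   alpha   pi_C   pi_D   pi_P
#> 1   1.0 0.0600 0.6934 0.2466
#> 2   1.3 0.3309 0.2363 0.4328
#> 3   1.6 0.4990 0.0012 0.4998
```

At constant returns ($\alpha = 1$) the population sits in the
all-defector state 69% of the time. By $\alpha = 1.3$ cooperators and
punishers each hold at least the defectors' share, and by $\alpha = 1.6$
defection is essentially extinct, with cooperators and punishers
splitting the time evenly — they are payoff-identical once there is
nobody left to punish.

A single agent-based run at strong increasing returns:

```r
p <- game_params(M = 100, N = 5, c = 1, r = 3, alpha = 1.8,
                 delta = 1, gamma = 0.3, omega = 0.5, mu = 0.001)
cfg <- sim_config(periods = 20000, seed = 1,
                  initial_state = population_state(30, 40, 30),
                  burn_in = 0, record_every = 20000)
run_simulation(p, cfg)$mean_frequencies
#>         C         D         P
#> 0.9503435 0.0076815 0.0419750
```

Defectors collapse within the first few hundred periods and a
contributor regime holds for the rest of the run (here the cooperators
head it; across seeds the C/P winner is a drift coin flip, as the
stationary analysis above predicts).

From the shell:

```sh
inst/cli/pggirs recipe fig2 --out results/
inst/cli/pggirs sweep --param alpha --grid 1.0,1.1,1.2,1.3,1.4,1.5 \
    --set omega=0.5 --set mu=0.001 --seed 1 --out results/
```

Every run writes CSV output plus a JSON manifest that can be re-fed via
`--config` to reproduce it exactly.

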