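# tritroph

Stochastic and deterministic dynamics of a trophically transmitted
parasite in a predator–prey system.

## The problem

Parasites with complex life cycles must cross two trophic levels: a
free-living stage infects an intermediate host (here: the prey), and the
parasite matures and reproduces only after an infected prey is eaten by
the definitive host (the predator), which then releases new free-living
parasites.  Whether such a parasite persists — and whether it drags the
predator down with it — depends on how efficiently it infects each host
(probabilities `Qx`, `Qy`) and on the reproductive costs it imposes on
them (factors `rx` for infected prey, `rp` for infected predators,
`re` for predators that fought off an exposure; 1 = no cost, 0 = full
sterilisation).

`tritroph` is for modellers who want to ask those questions
quantitatively: it implements the individual-level reaction network of the
five interacting populations (uninfected/infected prey `xU`, `xI`,
uninfected/infected predators `yU`, `yI`, free-living parasites `z`) and
derives *both* dynamical views from it —

* an **exact Gillespie simulation** (compiled, seeded, ensemble-ready),
  where demographic noise can absorb small populations at zero, and
* the **mean-field rate equations**

  $$\dot x_I = -\tfrac{(x_I+x_U)x_I}{K} - d_x x_I + Q_x S\,x_U z - f_y x_I y,\qquad
    \dot y_I = -d_y y_I + Q_y f_y x_I y_U,\ \ldots$$

  (all five printed in `?ode_rhs`), integrated with a stiff-capable
  adaptive solver,

plus an equilibrium module (closed-form parasite-free point, interior
equilibria via a polynomial condition on `xI` with back-substitution, and
a numerical parasite-invasion growth rate) and a phase module that
classifies long-run outcomes — which species coexist, and whether infected
or uninfected subtypes dominate each host — across parameter planes, with
bisection refinement of region boundaries.

## Worked example

```r
library(tritroph)
p <- make_params()        # reference set: no costs, Qx = Qy = 1

parasite_free_equilibrium(p)$state
#>  xU  xI  yU  yI   z
#> 500   0 165   0   0

solve_interior_equilibria(p)[[1]]$state
#>       xU       xI       yU       yI        z
#>    45.57   454.43    29.76   135.24 39888.89

invasion_growth_rate(p)
#> [1] 0.609
```

Without the parasite, 500 prey support 165 predators.  The invasion rate
is positive, so a rare parasite invades this community; the interior
equilibrium shows where it settles: most hosts end up infected (454 of 500
prey, 135 of 165 predators) on top of a large free-living parasite pool.
The integrated dynamics land on the same point, and classification agrees:

```r
tr <- ode_run(reference_state(), p, t_max = 2000, sample_dt = 0.5)
round(long_run_summary(tr)$mean, 2)
#>       xU       xI       yU       yI        z
#>    45.57   454.43    29.76   135.24 39888.89

run_outcome(p)
#> <tri_outcome> all_three:both_infected_dominant
```

A stochastic replicate fluctuates around that deterministic path:

```r
tail(as.data.frame(gillespie_run(reference_state(), p, t_max = 5, seed = 1)), 2)
#>      t  xU  xI yU yI    z
#> 50 4.9 323 401 30 68 5162
#> 51 5.0 331 433 34 73 5282
```

How weak may predator infection get before the parasite dies out?  Bisect
the three-species boundary along `Qy`:

```r
find_threshold(p, "Qy", "all_three", bracket = c(0.05, 0.9))
#> [1] 0.2708008
```

i.e. below a predator-infection probability of about 0.27 the parasite
cannot persist at the reference parameters, and only prey and predator
remain.

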