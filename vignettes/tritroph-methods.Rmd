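---
title: "Methods: a trophically transmitted parasite in a stochastic predator-prey system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a trophically transmitted parasite in a stochastic predator-prey system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tritroph)
```

## The model

Many parasites have complex life cycles: a free-living stage infects an
intermediate host, and the parasite only matures and reproduces after the
intermediate host is eaten by the definitive host.  `tritroph` models the
minimal such system — prey $X$ (intermediate host), predator $Y$ (definitive
host) and free-living parasite $Z$ — with two subtypes of each host,
infected ($X_I$, $Y_I$) and uninfected ($X_U$, $Y_U$).

All dynamics derive from one individual-level reaction network
(`reaction_network()`), with 24 state-changing channels:

* **Prey reproduction.** Uninfected prey reproduce at rate $g_x$; infected
  prey at $g_x r_x$, where $r_x \in [0,1]$ is the reproductive cost of
  infection (1 = no cost).  Offspring are always uninfected: there is no
  vertical transmission.
* **Prey competition.** Any prey pair competes at rate $1/K$, killing one
  of the two; infection does not change competitive ability.
* **Prey infection.** An uninfected prey meets a free-living parasite at
  rate $S$ per pair and is infected with probability $Q_x$; a successful
  infection removes the parasite from the free-living pool.
* **Predation and trophic transmission.** A predator eats any prey at rate
  $f_y$ per pair, and converts the meal into (at most one) offspring with
  efficiency $k_y$.  Eating an *infected* prey infects the predator with
  probability $Q_y$; a successful infection converts $Y_U \to Y_I$ and
  releases $n_z$ new free-living parasites (the parasite reproduces only in
  the definitive host, so release is coupled to predation).  Reproduction of
  infected predators is discounted by $r_p$; a predator that was exposed but
  not infected pays the (milder) immune-response cost $r_e$ in that
  encounter only, so $r_p \le r_e$ is enforced.  An already-infected
  predator can be re-infected by another infected prey: the newly arrived
  parasite still reproduces ($+n_z$), the predator stays $Y_I$ (no
  "doubly infected" type exists), and its reproduction in that encounter is
  discounted by $r_p^2$.
* **Deaths.** Intrinsic death rates $d_x$, $d_y$, $d_z$, identical for
  infected and uninfected individuals — virulence here is purely a
  *reproductive* cost.

Reactions whose product equals their reactant (failed prey infection, a
predation outcome that only removes the prey) carry no dynamics; they are
folded into the remaining channels as the complementary probability
factors.  Same-type competition uses the ordered-pair count $n(n-1)/K$, so
a lone individual never competes with itself; the mean-field equations use
$n^2/K$, and the two agree to $O(1/K)$ (an exact identity checked
componentwise in the test suite).

## The two engines

**Stochastic.** `gillespie_run()` simulates the network exactly (classic
Gillespie algorithm in compiled code): exponential waiting times at the
total propensity, channel choice proportional to propensity.  States are
recorded on a fixed grid (default $\Delta t = 0.1$) plus the final state,
because event counts at these abundances are millions per run.  One seeded
generator drives each trajectory; ensemble replicate $i$ uses seed
`base_seed + i - 1`, making ensembles reproducible replicate-by-replicate.
No tau-leaping or hybrid approximations are offered: exact stochasticity
near extinction boundaries is the point, and population sizes of a few
thousand keep exact simulation fast (about one second per thousand time
units at the reference parameters).

**Deterministic.** The mean-field limit is the five-equation system in
`ode_rhs()`:

$$\dot x_I = -\tfrac{(x_I+x_U)x_I}{K} - d_x x_I + Q_x S\, x_U z - f_y x_I (y_I+y_U)$$
$$\dot x_U = g_x (r_x x_I + x_U) - \tfrac{(x_I+x_U)x_U}{K} - d_x x_U - Q_x S\, x_U z - f_y x_U (y_I+y_U)$$
$$\dot y_I = -d_y y_I + Q_y f_y x_I y_U$$
$$\dot y_U = k_y f_y x_U (r_p y_I + y_U) + \big(r_e k_y (1-Q_y) - (1-r_p k_y) Q_y\big) f_y x_I y_U + \big(r_p r_e k_y (1-Q_y) + r_p^2 k_y Q_y\big) f_y x_I y_I - d_y y_U$$
$$\dot z = -Q_x S\, x_U z + n_z Q_y f_y x_I (y_I+y_U) - d_z z$$

`ode_run()` integrates it with `deSolve::lsoda` through a compiled
right-hand side.

## Reference conditions

The package defaults are the reference study conditions: parameters
$g_x=2$, $r_x=1$, $d_x=0.1$, $K=2000$, $S=5\times10^{-4}$, $n_z=6$,
$d_z=0.09$, $f_y=0.01$, $k_y=0.2$, $d_y=1$, $r_e=r_p=1$, $Q_x=Q_y=1$
(`make_params()`), and the initial condition of 800 uninfected prey, 100
uninfected predators and 1000 free-living parasites (`reference_state()`).
Under these conditions all three species coexist; sweeps vary $Q_x$, $Q_y$,
$r_p$ (and $r_x$) around this set.

## Numerical choices

* **Integration tolerances** `rtol = 1e-8`, `atol = 1e-10`.  The
  classification below reads cyclic valleys where abundances fall far below
  one individual; loose tolerances visibly distort those valleys.
* **Nonnegativity** is enforced by clamping, not log-transforming, so the
  equations above are solved verbatim: tiny negative excursions are zeroed
  inside the derivative evaluation and in the output.
* **Step control.** The maximal internal step is left unconstrained.
  deSolve's default (the output spacing) triggers an lsoda interpolation
  fault in strongly cyclic regimes where subpopulations underflow below
  about $10^{-300}$; with unconstrained steps the same runs integrate
  cleanly and faster.  As a second line of defence `ode_run()` restarts
  from the last good state (components below $10^{-12}$ zeroed) if the
  solver still stalls, and errors with the last good time after five
  attempts.
* **Horizons.**  Default `t_max = 2000` (deterministic) and 1000
  (stochastic sweeps), with summaries over the final 20%
  (`tail_fraction = 0.2`).  Reference-condition dynamics converge well
  before $t = 2000$; border regions converge more slowly, which is one
  reason boundary estimates carry a few-percent uncertainty.

## Equilibria

Besides the closed-form parasite-free point
$x_U^* = d_y/(k_y f_y)$, $y_U^* = (g_x - d_x - x_U^*/K)/f_y$
(`parasite_free_equilibrium()`), interior equilibria come from a
one-dimensional condition on the infected-prey abundance: with
$\Phi = \lambda x_I + 1$,
$\Psi = (d_y - \epsilon x_I - \zeta\lambda x_I^2)/(\gamma\lambda x_I + \delta)$
and $\Theta = \alpha\Psi + d_z$ (compound coefficients in
`derived_coefficients()`), an interior steady state requires
`polynomial_residual(xI, p) == 0`.  `solve_interior_equilibria()` scans a
log-spaced 4000-point grid over $(0, K]$ for sign changes (prey cannot
exceed the carrying-capacity scale at equilibrium), polishes each bracket
with `uniroot`, and back-substitutes $x_U^* = \Psi$, $y_U^*$ (two
algebraically equivalent forms, both evaluated as a consistency check),
$y_I^* = \lambda x_I^* y_U^*$ and
$z^* = \eta x_I^* (y_I^* + y_U^*)/\Theta$.  Because clearing denominators
can introduce spurious roots, a candidate is accepted only if all five
components are strictly positive **and** the max-norm of the full
right-hand side is below $10^{-6}$ — the rate equations, not the
polynomial, are the authority.  A brute-force $10^5$-point scan in the test
suite confirms the production scan misses no sign change at the tested
parameter sets.

Whether a rare parasite can grow at all is answered numerically:
`invasion_growth_rate()` returns the dominant eigenvalue of the linearised
infected subsystem $(x_I, y_I, z)$ at the parasite-free equilibrium (the
full Jacobian is block-triangular there, so this block decides invasion).
A positive rate means invasion; severing either transmission link
($Q_x = 0$ or $Q_y = 0$) makes it nonpositive.  Invasion and long-run
persistence are deliberately kept as *separate* outputs: a parasite can
have a positive invasion rate and still be classified extinct in the
long-run map when its asymptotic abundance stays below the demographic
cutoff; the package does not force the two views to agree.

Stability is assessed only dynamically (convergence of integrated
trajectories), never by symbolic eigenvalue analysis of the full
five-dimensional Jacobian: the regimes of interest are distinguished by
behaviour (stationary vs cyclic), and a quantitative chaos criterion
(Lyapunov exponents) is out of scope — tail variability is the only
cyclicity measure used.

## Outcome classification

`classify_outcome()` reduces a run to two labels:

* **Coexistence** — which species persist.  Deterministically a species is
  extinct when its tail-mean total abundance is below **one individual**
  (the ODE state is strictly positive forever, so a sub-individual
  demographic cutoff is needed; one individual is the natural unit, and the
  cutoff is configurable).  Stochastically, extinction is an exact zero at
  the final state — absorbing states are exact in the jump process.  The
  parasite counts as present through any life stage ($z + x_I + y_I$).
* **Composition** — within each host, does the infected or the uninfected
  subtype dominate the tail mean?  Four combinations; exact ties (a
  measure-zero event) count as uninfected-dominant.

`sweep_plane()` classifies a parameter grid cell-by-cell (per-cell label
frequencies over seeded replicates for the stochastic engine);
`find_threshold()` bisects a single boundary to a parameter tolerance of
0.005; `find_region_edge()` first scans in fixed steps before bisecting,
because several composition regions are narrow *bands* that a two-point
bracket would miss; `find_region_min()` repeats the edge search along a
companion-parameter grid to find the minimal parameter at which a region
appears anywhere in a plane.  The acceptance script sharpens the last step
with a two-stage companion grid (coarse grid, then a 0.005-step local grid
around the coarse optimum).

## What the reference conditions do and do not probe

The study conditions are a single well-mixed community with fixed
demographic rates.  Tests built on them exercise the full machinery —
exact stochastic dynamics, stiff cyclic integration, root-finding,
classification — but say nothing about age or spatial structure, vertical
transmission, evolving traits, seasonal forcing, or observation noise;
none of those are modelled.  Stochastic conclusions are demographic only:
the sole noise source is the jump process itself.

## Known limitations

* Composition boundaries where the two predator subtypes are nearly equal
  are intrinsically ill-conditioned: at equilibrium
  $y_I^*/y_U^* = (Q_y f_y / d_y)\, x_I^*$, so the
  infected-prey/uninfected-predator region boundary moves a long way in
  $(r_p, Q_y)$ for a small change in $x_I^*$.  Estimates of that region's
  extent are therefore much more sensitive to the classification protocol
  (horizon, averaging window, cutoff) than the coexistence thresholds are.
* Deterministic classification at finite horizon labels very slowly
  invading parasites "extinct" (tail mean still below cutoff at
  $t = 2000$); boundary estimates shift by a few hundredths of a
  probability unit with the horizon.
* In strongly cyclic regimes subpopulation minima underflow double
  precision ($<10^{-308}$) and are clamped to zero; the true flow stays
  positive in exact arithmetic, but at that depth the mean-field model has
  no biological meaning anyway (the stochastic engine is the right tool
  there).

## Problem sizes used in the checks

The test suite and the acceptance script run entirely at desk scale:
deterministic runs to $t = 2000$ at output spacing 0.5; bisections to
0.005; region scans in steps of 0.01–0.05; stochastic ensembles of 100
replicates to $t = 1000$ for sweep-style cells, 100 replicates to $t = 5$
for mean-field agreement, 2000 tiny pure-death runs for the exact
waiting-time law, and 50 replicates to $t = 400$ for the
predator-collapse regime.
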