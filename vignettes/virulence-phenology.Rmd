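---
title: "Host phenology and optimal virulence: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host phenology and optimal virulence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenovir)
```

## The model and its assumptions

`phenovir` models a free-living, obligate-killer parasite of a seasonally
emerging host — the transmission ecology of, for example, univoltine
insects attacked by parasitoids or soil-borne pathogens of annual plants.
The assumptions that define the model:

* Hosts have non-overlapping generations and live at most one season. A
  cohort of `s_hat` hosts emerges with uniform density over `[0, t_l]`;
  the cohort size is the same every year (no demographic feedback from
  parasitism).
* Hosts are susceptible from emergence until infected, and die from
  background causes at rate `mu`. Infection occurs at rate `alpha` per
  free parasite; free parasites decay at rate `delta`, and losses of free
  parasites to transmission itself are neglected (the usual free-living
  parasite approximation, excellent when `alpha * s` is small relative to
  `delta`).
* The parasite is monocyclic: one round of infection per season. An
  infected host is killed exactly `tau` time units after infection and
  releases `beta` progeny — unless background mortality strikes first, or
  the season ends, in which case nothing is released. `tau` is therefore
  the inverse of virulence.
* Progeny present at the season end `T` overwinter and become next
  season's infecting population.

Within a season the state variables follow

$$
\begin{aligned}
\frac{ds}{dt} &= \hat{s}\, g(t, t_l) - \mu s(t) - \alpha s(t) v_1(t),\\
\frac{dv_1}{dt} &= -\delta v_1(t),\\
\frac{dv_2}{dt} &= \alpha \beta e^{-\mu\tau} s(t-\tau) v_1(t-\tau)
  - \delta v_2(t),
\end{aligned}
$$

with `s(0) = 0` and `v_1(0)` equal to the carried-over density `v_hat`.
The factor `exp(-mu * tau)` is the probability that an infected host
survives background mortality through the incubation period.

## Closed-form within-season solution

Because `v_1` is a known exponential, the host equation is linear and
solves by an integrating factor. With the cumulative hazard

$$
H(t) = \mu t + \sum_i \frac{a_i}{d_i}\left(1 - e^{-d_i t}\right),
$$

where each free-parasite population contributes one hazard component
`a_i exp(-d_i t)` (for the resident alone, `a = alpha * v_hat`,
`d = delta`),

$$
s(t) = \frac{\hat{s}}{t_l} e^{-H(t)} \int_0^{\min(t,\, t_l)} e^{H(x)}\,dx .
$$

Substituting into the progeny equation and integrating gives a single
expression valid in both release regimes,

$$
v_2(T) = \alpha \beta \hat{v}\, e^{-\mu\tau - \delta (T - \tau)}
  \int_0^{T-\tau} s(w)\, dw ,
$$

because `s(w) v_1(w) e^{\delta w} = s(w)\hat v`. The conventional
two-regime form — release window ending before versus after the end of
the emergence period — corresponds exactly to splitting the outer
integral at `t_l`, where the closed form of `s` changes branch; we
implement it that way, and continuity across the regime boundary
`tau = T - t_l` is automatic (a delay exactly at the boundary is
evaluated without special-casing, justified by that continuity, which the
test suite checks at offsets of `1e-4`). Delays with `tau >= T` release
nothing and have zero fitness by construction.

All expressions are computed on the products `alpha * v_hat` and
`alpha * s_hat`, which are order one for the default magnitudes
(`s_hat = 1e8`, `alpha = 1e-8`), so no catastrophic cancellation or
overflow arises in the scientifically relevant range.

## Parameters

| name    | meaning                                   | units               | default |
|---------|-------------------------------------------|---------------------|---------|
| `s_hat` | emerging host cohort size                 | hosts               | 1e8     |
| `t_l`   | emergence period length                   | time                | 1       |
| `mu`    | background host death rate                | 1/time              | 0.5     |
| `alpha` | transmission rate                         | 1/(parasite × time) | 1e-8    |
| `beta`  | progeny released at host death            | parasites           | 200     |
| `delta` | free-parasite environmental decay rate    | 1/time              | 2       |
| `tau`   | infection-to-kill delay (1/virulence)     | time                | 1.5     |
| `T`     | season length                             | time                | 3       |

Two defaults deserve comment. The decay rate is treated as a plain
per-capita rate (1/time) — the natural reading of exponential
environmental decay. The progeny number used in the no-trade-off
analyses, 200, sits in the middle of the range spanned by the two linear
trade-off functions `99(τ + 0.5)` and `99(−τ + 4)` over delays near the
optima (roughly 150–300), so that comparisons with and without a
trade-off are made at commensurate progeny numbers; it is configurable
everywhere.

## Between-season dynamics and equilibrium

The between-season map sends `v_hat` to `v2(T)`. A single introduced
parasite persists when `season_map(1) >= 1` (annual growth factor of
modulus at least one). The nontrivial fixed point is found by Brent's
method on `season_map(v) - v` over an automatically expanded bracket: the
map lies above the identity at small densities whenever the persistence
criterion holds (per-capita output declines with density, so no interior
fixed point can hide below 1) and falls below it at large densities
through host depletion, so a sign change is guaranteed. Brent on a
bracketed sign change is as robust as bisection and converges faster;
each map evaluation costs one quadrature, so the saving matters inside
the evolutionary root-finder. The fixed point is polished to a relative
residual below `1e-8` (typically `1e-14`), and `resident_equilibrium()`
reports the residual rather than asserting convergence silently. Local
stability of the annual dynamics is estimated from the map slope at the
fixed point; an unstable fixed point triggers a search for a period-2
cycle of the map, which is reported to the user instead of being averaged
away. Across the default parameter ranges the slope stays inside the unit
interval and no cycles arise.

## Invasion analysis

A rare mutant with delay `tau_m` experiences the season shaped by the
resident at equilibrium: the host hazard gains the resident's component
`alpha * v_star * exp(-delta * t)`. Its per-capita end-of-season output is

$$
w(\tau_m) = \alpha_m \beta(\tau_m)\,
  e^{-\mu\tau_m - \delta_m (T - \tau_m)}\, I(T - \tau_m),
\qquad I(u) = \int_0^u s_{\mathrm{env}}(w)\, dw .
$$

Because the environment `s_env` does not depend on `tau_m`, the selection
gradient has the exact form

$$
\frac{dw}{d\tau_m} = w \left[\delta_m - \mu
  + \frac{\beta'(\tau_m)}{\beta(\tau_m)}
  - \frac{s_{\mathrm{env}}(T-\tau_m)}{I(T-\tau_m)}\right],
$$

which reads as a balance of marginal costs and benefits: waiting longer
avoids progeny decay (`+delta`), risks host death (`-mu`), changes the
progeny payload (`beta'/beta` under a trade-off), and forfeits the
infections closest to the season end (the `s/I` term). Differentiating
once more (using `s'` from the host ODE itself) gives the second-order
condition in closed form. We use these analytic derivatives rather than
finite differences of the quadrature output: differencing amplifies
quadrature error by `1/h` (or `1/h^2`), which would cap the attainable
precision of `tau_star` far above the `1e-9` root tolerance used here,
and in particular would break the exact invariance of `tau_star` under
the population rescaling `(s_hat, alpha) -> (s_hat/c, c*alpha)`. A
central-finite-difference gradient remains available
(`selection_gradient(..., method = "fd")`) and the test suite checks the
two against each other.

Two further choices:

* **Vanishing-density limit.** The singular-strategy machinery evaluates
  the mutant per capita in the limit of vanishing mutant density, i.e.
  without the mutant's own depletion of hosts ("self-shading"). This is
  the standard invasion-fitness convention — a rare mutant is rare — and
  it makes resident-identical mutants exactly neutral at equilibrium
  (per-capita growth 1, verified to `1e-6`) and `tau_star` exactly
  invariant under the population rescaling. `mutant_v2_end()` retains the
  self-shading terms with an explicit initial density `v1m0` for users
  who want the finite-density expressions.
* **Environment recomputation.** The resident equilibrium `v_star` is
  recomputed for every candidate resident delay during root-finding
  (cached per delay, warm-started from the previous equilibrium), since
  the selective environment depends on the resident trait.

The default search bracket `[0.05 T, 0.98 T]` generally contains
non-persistent residents at both ends (very fast killers release progeny
that decay all season; very slow killers rarely release at all), so
`find_singular_strategy()` first restricts the bracket to the resident
persistence window by bisecting `season_map(1) - 1`, then requires a sign
change of the gradient inside that window. Without a sign change it
returns a boundary diagnosis naming the direction of selection; it never
fabricates a root. Convergence stability is classified from the gradient
sign on either side of the root (positive below, negative above).

## Numerical evaluation

The inner antiderivative `E(w) = int_0^w exp(H(x)) dx` is tabulated once
per environment on a 2001-point uniform grid over `[0, t_l]` (scaled by
`exp(-H(t_l))` so the integrand lies in `(0, 1]`), accumulated with a
Simpson-type rule of global order `h^4`, and interpolated with a monotone
(Hyman-filtered) cubic spline; host density at any time is then a closed
form. The outer integral `I(u)` uses composite 10-point Gauss–Legendre
quadrature on eight fixed panels per smooth segment, split at the
emergence kink `t_l`. Fixed panels keep the quadrature error a smooth
function of the parameters, which the analytic derivatives and the
rescaling invariance rely on. In the extreme-hazard regime
(`H(t_l) > 500`, far outside the model's equilibria but reachable when
probing the map at huge densities) the tabulation would underflow, and
the engine switches to per-point adaptive quadrature of
`exp(H(x) - H(w))`, whose integrand never exceeds one.

The independent oracle (`season_oracle()`) integrates the season system
directly with `deSolve`'s lsoda at `rtol = 1e-10`. The delayed
progeny-production term is handled exactly, not by history interpolation:
the lagged states `s(t - tau)` and `v1(t - tau)` are carried as companion
states obeying the time-shifted dynamics, and the integration is
restarted at each forcing discontinuity (`t_l`, the delays and their
sums), where the shifted free-parasite density is switched on. An
analogous
two-strain oracle validates the mutant expressions. Closed form and
oracle agree to better than `1e-5` relative error across a Latin
hypercube of 50 parameter sets spanning the default magnitudes (and to
`~1e-9` at baseline).

## The stochastic validator

`simulate_season_ibm()` is an event-level, seeded realisation of the same
assumptions at reduced scale: `n_hosts = s_hat / c` hosts with the
transmission rate scaled up to `c * alpha`, which leaves every per-capita
rate of the deterministic model unchanged. Each host draws a uniform
emergence time, an exponential background death time, and an infection
time from the inhomogeneous hazard `alpha_ibm * v_init_ibm * exp(-delta
t)` — sampled exactly by inverting the integrated hazard in closed form
(the hazard is a single decaying exponential, so inversion is available
and preferable to thinning: exact, loop-free and identically
distributed). Kills occur `tau` after infection when neither background
death nor season end intervenes; each of the `beta` released progeny
survives to `T` independently with probability `exp(-delta (T - t_rel))`.
Within a season the infection hazard uses the deterministic free-parasite
density, exactly matching the model's assumption that transmission losses
of free parasites are negligible.

Because hosts are independent and the hazard is deterministic, the
expected end-of-season progeny count equals the deterministic `v2(T)` at
the reduced scale, so the validator tests the deterministic pipeline
without any calibration: the replicate mean must sit within sampling
error of the closed-form value (checked at `n_hosts = 1e4`, 50
replicates, fixed seed; replicate `r` uses `seed + r`). What the
validator does **not** emulate: demographic stochasticity feeding back
into the free-parasite pool within a season, multi-season stochastic
dynamics or strain competition, and any process absent from the
deterministic model (aggregated exposure, non-exponential decay, host
heterogeneity). Agreement therefore validates the mathematics and the
implementation, not the model's fit to any real system. `beta` must be a
whole number here, since progeny are discrete.

## Experiments and problem sizes

`sweep_season_length()` (default `T` grid 2.8–4.0 by 0.2, emergence
period 1) and `sweep_emergence_period()` (default `t_l` grid 0.01–2.5,
season length 3) locate the singular strategy per cell, reporting
non-persistent cells as `NA`; `run_tradeoff_experiment()` compares optima
without a trade-off and under the two linear forms; `reproduce_all()`
runs everything, writes tidy CSVs with a JSON manifest, and evaluates the
headline qualitative claims as named logical checks (interior ESS for
every season length; optimum increasing with `T` with the kill-time
offset `T - tau_star` varying by well under 10%; the non-monotone
dependence on emergence synchrony with equilibrium density declining as
emergence spreads; opposite trade-off shifts; stochastic mean within
three standard errors). The grid anchors (`T` = 3.2 and 4.0, `t_l` = 1,
`T` = 3 for the emergence sweep) are the captioned comparison points; the
remaining grid density was chosen once for shape resolution. These sizes
keep a full sweep under a few seconds per cell on one core; the test
suite and the acceptance script use the same sizes (with a 4-point `T`
grid and a 20-set hypercube in the script).

## Known limitations

* One resident strain at a time; no coexistence, branching or
  multi-season stochastic evolution of competing strains.
* `tau` is the only evolving trait; `alpha`, `beta`, `delta` are fixed or
  tied to `tau` through the supplied trade-off.
* Uniform emergence and exponential decay are structural; other
  distributions would change the closed forms.
* The host cohort is constant across years — no feedback from parasitism
  on host demography.
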