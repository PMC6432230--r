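---
title: "Living filament bundles in an optical trap: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Living filament bundles in an optical trap: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinotrap)
```

## The physical system

`actinotrap` simulates a bundle of `Nf` actin-like filaments grafted to a
fixed wall, growing and shrinking by single-monomer reactions at their free
tips, and pressing against a mobile wall held by a harmonic restoring force
`-kappa_T L` — the particle-based analogue of an optical-trap experiment on
a polymerizing actin bundle.  The box has transverse area `A` with periodic
boundaries in `y` and `z`; free monomers are exchanged with a reservoir at
fixed effective chemical potential, so the statistical ensemble is a
reactive grand-canonical one.  The solution on the far side of the mobile
wall enters only through its mean ideal-gas pressure `p = kBT rho1`,
applied to the wall as the constant force `-p A`.

All quantities are in reduced units: monomer size `d`, thermal energy
`kBT`, and the wall diffusion time `tauD = zeta_w d^2/kBT` equal 1.  At
`d = 2.7 nm` and `T = 300 K` one force-constant unit is `0.57 pN/nm` and
`tauD` corresponds to about `3.5e-5 s` for a micron-sized trapped bead.

## Potentials

A filament of `j` monomers (the first two form a rigid, immobile seed)
carries `j - 2` harmonic bonds and `j - 2` bending terms:

* `U_b(r) = -eps0 + ks (r - d)^2 / 2`, with `ks = 4000 kBT/d^2`.  The
  constant `eps0 = 13.644143 kBT` is the free-energy gain of creating a
  bond; it sets the bulk reaction equilibrium constant.
* `U_bend(theta) = kappa (1 - cos theta)` on the angle between adjacent
  bonds, with `kappa = 5370 kBT`, giving persistence length
  `Lp = kappa d/kBT = 5370 d` (14.5 um for F-actin).  The triple that
  includes the seed pair anchors the filament normal to the grafting wall.
* every mobile monomer is repelled by both walls through a purely
  repulsive, truncated 9-3 potential
  `U_w(s) = eps_w ((3*sqrt(3)/2)((d/s)^9 - (d/s)^3) + 1)` for
  `s <= s_c = 3^(1/6) d`, zero beyond; `eps_w = 0.1 kBT`.  Solving
  `U_w(s*) = kBT` gives an effective core at `s* = 3^(-1/6) d = 0.833 d`.
  Seed monomers are part of the grafting wall and carry no wall energy
  (with staggered seeds some sit at `h_n < 0`, where the wall term would
  be undefined).

There are no monomer-monomer interactions (ideal conditions); the package
models the regime the reference theories address, where excluded volume is
switched off.

The bulk single-monomer equilibrium constant follows in closed form from
the bond-vector configurational integral,

```
K0 = exp(beta eps0) (2 pi d^4/Lp) sqrt(2 pi/(beta ks d^2)) (1 - exp(-2 Lp/d)),
```

evaluated by `bulk_equilibrium_constant()`: `K0 = 39.071 d^3`, critical
density `rho1c = 1/K0 = 0.02559 d^-3`, critical effective chemical
potential `mu1c* = -3.665 kBT`.  Runs impose a reduced density
`rho_hat1 = rho1/rho1c` (default 2.5, supercritical).

## Dynamics

Monomers follow 3D Langevin equations with mass `M = 3.556e-3` and
friction `zeta = 0.5`; the wall follows a 1D Langevin equation with mass
`Mw = 1.0667e-2` and friction `zeta_w = 1`, subject to the monomer
reaction forces, the trap load `-kappa_T L` and `-p A`.  Both are
integrated with the two-Gaussian stochastic velocity-Verlet scheme
(velocity half-kick with the `(1 - h gamma/4)` friction correction and
`O(h^{3/2})` noise terms, position update with an `h^{3/2}` displacement
noise, force recomputation, closing half-kick).  With `gamma = 0` and
`T = 0` the scheme reduces exactly to velocity Verlet; the test suite
verifies free flight, energy conservation of the bare wall oscillator
(relative drift below 1e-6 over 1e5 steps), per-degree-of-freedom
equipartition, and that the bare trapped wall samples a Gaussian of
variance `kBT/kappa_T`.

The time step `h = 5.33e-5 tauD` resolves the stiffest mode (bond
stretching, period `tau_s = 5.9e-3 tauD`, about 110 steps).  Transverse
coordinates are periodic; filament coordinates are kept unwrapped so bond
and bend terms never need minimum-image corrections (a monomer captured
from a periodic image is shifted onto the bonded image), while free
monomers are wrapped into `[0, L')`.  `x` is confined by the walls and
never wrapped; a monomer reaching `s <= 0` at a wall aborts the run with
a diagnostic, since it signals an unstable configuration.

## Reaction moves

Chemistry is Poisson-clocked: each filament has independent
polymerization and depolymerization clocks of rate `nu = 7.1e4/tauD`
each, and the reservoir has a clock of rate `nu_GC = 187.5/tauD`.
Events execute at the first integration-step boundary at or after their
scheduled time, in scheduled-time order; because the configuration is
frozen between boundaries, this is statistically identical to executing
at the exact Poisson times.

A polymerization attempt selects one of the `N_r` free monomers inside
the reaction sphere (radius `r_c = 1.5 d`) of the tip, uniformly, and
accepts the in-place capture with probability

```
a_poly = min(1, N_r exp(-beta E)),
```

where `E` is the elastic (spring plus bend) energy of the bond being
created.  A depolymerization attempt releases the tip monomer in place
(topology changes, positions and velocities are retained) with
probability

```
a_depol = exp(-beta eps0) min(1, exp(+beta E)/N_r'),
```

where `E` is now the elastic energy of the bond being removed and `N_r'`
counts the candidates around the surviving tip after the move (the freed
monomer included — a release whose reverse capture could not re-select
the monomer, i.e. with the bond stretched beyond `r_c`, is refused).  The
two probabilities satisfy `a_poly/a_depol = N_r exp(-beta dU)` with
`dU = -eps0 + E` in every branch of the `min`, which is exactly detailed
balance with respect to the Boltzmann measure combined with the
grand-canonical monomer statistics.  Consequences verified by the tests:

* an isolated filament-plus-monomer system reaches the occupancy ratio
  predicted by direct quadrature of the two configurational integrals;
* the stationary size distribution of a confined filament obeys
  `Q_{m+1}/Q_m = rho_hat1`;
* the bulk effective depolymerization rate is
  `W0 ~= nu exp(-beta eps0) = 0.084 tauD^-1` (the residual factor
  `<min(1, e^{beta E}/N_r')> ~= 0.9` brings the measured value to about
  0.075-0.082), and `U0/W0 = rho_hat1` exactly at equilibrium.

This acceptance pair was chosen over the plain Metropolis pair
`min(1, N_r e^{-beta dU})`/`min(1, e^{+beta dU}/N_r)` deliberately: both
satisfy detailed balance, but the plain pair lets rare stretched-bond
configurations dominate the depolymerization flux (acceptance
`e^{-beta(eps0 - E)}` grows with `E`), inflating both bulk rates by the
ratio of the reaction-sphere volume to the thermal bond volume (a factor
of order 30) and destroying the identification of `nu e^{-beta eps0}`
with the bulk depolymerization rate.  The damped pair keeps the absolute
rates at the intended scale while leaving every equilibrium property
unchanged.

Reservoir moves are standard ideal-gas grand-canonical insertions and
deletions (acceptance `min(1, rho1 V e^{-beta dU}/(N1+1))` and
`min(1, N1 e^{+beta dU}/(rho1 V))`, `V = A L` at the attempt, `dU` the
wall energy of the monomer), with one extra condition applied
symmetrically: a move that would insert or delete a *chemically
reactive* monomer (inside any tip's reaction sphere) is refused, so the
reservoir never interferes with the reaction moves' candidate counting.
At the defaults the measured acceptance is ~0.89, and the stationary
free-monomer density equals `rho1` in the bulk with the barometric
profile `rho1 e^{-beta U_w(s)}` in the wall skins.

## Measuring rates: equilibrium, not growth

The per-`m` estimators follow the residence-counter scheme: at every step
each filament's relative size `m = j_n - z_n`,
`z_n = 1 + floor((L - h_n)/d)`, increments a residence counter; attempts
and successes increment per-`m` counters tagged with the pre-event `m`.
Effective rates are successes per residence time, `U_m`, `W_m`; their
plateaus at sufficiently negative `m` (`m <= -2` for depolymerization,
`m <= -3` for polymerization, since the soft wall already interferes one
step higher) are the bulk rates.

An important subtlety found while validating the package: bulk rates must
be measured **at equilibrium** (filament confined by a parked wall or in
the trap), not on a freely growing filament.  Monomer diffusion in the
model is slow (`tau_fm = 0.58 tauD`), and the reservoir refuses
insertions inside the reaction sphere, so a *net-growing* tip depletes
the favorable bond shell faster than diffusion replenishes it;
polymerization then becomes partially diffusion-limited and `U_m` falls
about a factor two below its equilibrium plateau while `W_m` is
unaffected.  At equilibrium the net flux vanishes and detailed balance
guarantees `U0/W0 = rho_hat1` exactly; the measured values at the
defaults are `W0 ~= 0.075-0.082 tauD^-1` and `U0/W0 = 2.50 +- 0.05`.

## Observables and analysis

`run_segment()`/`ot_simulate()` record a uniform-stride trace of `t`,
`L`, `N1`, per-filament sizes and end-to-end components, energy terms and
the wall-force decomposition.  Analysis functions: `wall_histogram()`
(with the rigid-filament Gaussian reference `P(L) ~ exp(-beta(-F_H L +
kappa_T L^2/2))`), `rate_table()`/`plateau_rates()`/`qm_slope()` for the
chemistry, `acf_fluct()` plus `fit_exponentials()` (one or two
components, automatic fit window equal to three times a log-linear
initial estimate, iterated once) for relaxation times, and
`equilibrium_summary()` for the moment table with block-averaged errors
and the stationarity identity `kappa_T <L> = <F_bun> + <F_wm> - p A`.

Rigid-filament references: `hill_theory()` returns `F_H = Nf (kBT/d) ln
rho_hat1`, `L_H = F_H/kappa_T`, `sigma_H = sqrt(kBT/kappa_T)`;
`brownian_ratchet_velocity()` returns `v(F_L) = d(U0 e^{-beta d F_L} -
W0)`.

## Reproducibility

All randomness derives from one master seed through four labelled
xoshiro256++ streams (thermostat, reaction clocks, reservoir clocks,
initial placement), so a subsystem draws the same numbers whether or not
the others are active.  Normal deviates use a 128-layer ziggurat (the
thermostat consumes two Gaussians per degree of freedom per step, which
dominates the run-time budget).  The full state — coordinates,
velocities, topology, wall, pending event times and all stream states —
round-trips through a text checkpoint with `%.17g` precision, and a
resumed run reproduces the uninterrupted trajectory bit for bit.

## Scaled-down study sizes

The automated checks run equilibrium simulations far shorter than the
multi-million-`tauD` trajectory sets a production study would use; the
sizes were fixed at values giving each check a clear statistical verdict:

* bulk chemistry: a single filament confined at `L = 12 d` in an `A = 9
  d^2` box, three to six pooled replicas of 1800-3000 `tauD` each,
  giving several hundred reaction events (plateau-rate errors of a few
  percent).  Replicas are pooled because the deep residence tail mixes
  slowly: runs occasionally enter long episodes with a locally depleted
  reaction sphere, which makes single-trajectory tail statistics (and
  hence the fitted residence slope) scatter by roughly ten percent;
* the trap run: `Nf = 1`, `kappa_T = 0.019375`, initialized at the
  rigid-theory state (`j0 = 46`, `L0 = 47.29 d`) rather than grown from
  bare seeds (growth from a seed is diffusion-limited and would cost
  thousands of `tauD`), 500 `tauD` of equilibration and ~2200 `tauD` of
  production.  That is only about two wall relaxation times
  (`tau_L ~ 1e3 tauD`), so the mean trap length carries a statistical
  error of several `d` and the relaxation-time fit is an
  order-of-magnitude estimate; the force-balance identity and the
  chemistry estimators, which decorrelate much faster, are sharp.

What the synthetic conditions do *not* probe: excluded-volume
interactions, ATP/ADP monomer states, capping or branching, flexible
obstacles, and the escaping-filament regime at weak traps — all outside
the model's scope.  Passing tests therefore validate the model's
statistical mechanics and its agreement with rigid-filament theory in
the near-rigid regime, not those biological refinements.

## Known limitations

* Polymerization during net growth is partially diffusion-limited (see
  above); growth-phase kinetics should not be read as bulk rates.
* The `m` index uses the geometric wall position, while the wall is soft
  (`s_c = 1.2 d`), so `m = -1` already feels weak wall interference;
  a monomer arriving at a tip with `m = -2` lands in the skin; the
  clean plateau windows are `m <= -2` (depolymerization) and `m <= -3`
  (polymerization).
* At `A = 9` the reaction sphere radius (`1.5 d`) equals half the
  transverse box edge; reaction geometry is handled by minimum image and
  remains exact, but transverse density correlations wrap.
* The closed-form `K0` reproduces the quoted model constant to four
  significant figures (39.0698 vs 39.07144); the residual 4e-5 relative
  difference is inherited from the constants' printed precision.
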