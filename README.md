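# actinotrap

Particle-based simulation of a bundle of grafted, **living** (polymerizing
and depolymerizing) semi-flexible actin-like filaments pressing against a
mobile wall held in a harmonic trap — the computational analogue of an
optical-trap experiment measuring the polymerization force of an actin
bundle.

The package is aimed at biophysicists studying force generation by
cytoskeletal filaments: it lets you simulate the reactive grand-canonical
ensemble of a bundle in contact with a free-monomer reservoir, measure the
wall-position distribution, the relative-size-resolved reaction rates and
the slow Brownian-ratchet relaxation of the wall, and compare everything
against the rigid-filament (Hill) analytic theory.

## Model in brief

All quantities are in reduced units (`d = kBT = tauD = 1`). Each monomer is
a Langevin particle; a filament of `j` monomers carries `j - 2` harmonic
bonds `U_b(r) = -eps0 + ks (r-d)^2/2` and `j - 2` worm-like-chain bending
terms `kappa (1 - cos theta)` (persistence length `Lp = kappa d/kBT`).
Monomers are repelled by both walls through a truncated, purely repulsive
9-3 potential. The wall obeys a 1D Langevin equation under the filament and
gas forces, the trap load `-kappa_T L` and the mean pressure `-p A` of the
solution behind it. Tips gain or lose single monomers through
Poisson-clocked Monte Carlo moves satisfying detailed balance; a
grand-canonical process holds the free-monomer density at
`rho1 = rho_hat1 / K0`, where

    K0 = exp(beta eps0) (2 pi d^4/Lp) sqrt(2 pi/(beta ks d^2)) (1 - e^{-2 Lp/d})

is the bulk reaction equilibrium constant (`39.071 d^3` at the defaults,
critical density `1/K0`). The rigid-filament references are the Hill force
`F_H = Nf (kBT/d) ln rho_hat1`, the mean trap length `L_H = F_H/kappa_T`,
the wall width `sigma_H = sqrt(kBT/kappa_T)`, and the ratchet load-velocity
relation `v(F_L) = d (U0 e^{-beta d F_L} - W0)`.

See the vignette (`vignettes/living-filament-trap.Rmd`) for the full model,
the reaction-move acceptance rules and all numerical choices.

## Worked example

Analytic references for the single-filament trap setup:

```r
library(actinotrap)
p <- simulation_params(Nf = 1, kappa_T = 0.019375, seed = 1)
theory_report(p)
#> Analytic references (reduced units)
#>   K0 = 39.06983 d^3   rho1c = 0.025595 d^-3   mu1c* = -3.6654 kBT
#>   rho1 = 0.063988 d^-3   p = 0.063988 kBT/d^3   pA = 2.3036 kBT/d
#>   Hill: FH = 0.9163 kBT/d   LH = 47.292 d   sigma_H = 7.1842 d
#>   rates: W0 = 0.0843   U0 = 0.2107 per tauD   tau_chem = 11.87 tauD
#>   times: tau_s = 5.92e-03  tau_b = 3.62e-03  tau_win = 1.07e-02  tau_T = 4.66 tauD
#>   overdamped wall: TRUE
```

`L_H = 47.3 d` is the wall position at which the trap load balances the
mean polymerization force of one filament at reduced monomer density 2.5;
`W0 = nu exp(-beta eps0) = 0.084/tauD` is the bulk depolymerization rate
implied by the attempt frequency.

A short equilibrium run measuring the bulk chemistry (a single filament
confined by a parked wall; ~2 minutes):

```r
p    <- simulation_params(A = 9, seed = 12)
st   <- build_initial_state(p, L0 = 12, j0 = 11)
burn <- run_segment(st, p, duration = 100, mobile_wall = FALSE, counters = FALSE)
out  <- run_segment(burn$state, p, duration = 600, mobile_wall = FALSE)
plateau_rates(out$counters, p)
#> W0    = 0.0767 +- 0.0113 /tauD  (n = 46 events)
#> U0    = 0.2270 +- 0.0331 /tauD  (n = 47 events)
#> U0/W0 = 2.96 +- 0.61   (imposed rho_hat1 = 2.5)
```

The depolymerization plateau sits at the `nu exp(-beta eps0)` scale and the
rate ratio estimates the imposed reduced density; at this short length the
error bars are large — production-quality numbers use several thousand
`tauD` (see below). Full trap runs go through `ot_simulate()` (growth,
equilibration, production phases) and are summarized by
`equilibrium_summary()`, `wall_histogram()`, `rate_table()` and
`acf_fluct()`/`fit_exponentials()`.

A thin command-line front end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/actinotrap", package="actinotrap"))') theory
```

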