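#' Rigid-filament (Hill) trap theory
#'
#' Mean-field references for a bundle of `Nf` rigid living filaments in a
#' harmonic trap: the polymerization force `F_H = Nf (kBT/d) log
#' rho_hat1`, the mean trap length `L_H = F_H / kappa_T` and the wall
#' position standard deviation `sigma_H = sqrt(kBT / kappa_T)` of the
#' Gaussian equilibrium distribution `P(L) ~ exp(-beta(-F_H L + kappa_T
#' L^2/2))`.
#'
#' @param Nf Number of filaments.
#' @param kappa_T Trap strength, `kBT/d^2`.
#' @param rho_hat1 Reduced free monomer density.
#' @param d Monomer size.
#' @param kBT Thermal energy.
#' @return A list with `FH` (force), `LH` (length) and `sigma_H` (length).
#' @examples
#' hill_theory(1, 0.019375, 2.5)   # LH ~ 47.3 d
#' hill_theory(8, 0.275, 2.5)      # LH ~ 26.7 d, sigma_H ~ 1.91 d
#' @export
hill_theory <- function(Nf, kappa_T, rho_hat1, d = 1, kBT = 1) {
  stopifnot(rho_hat1 > 0, kappa_T > 0)
  FH <- Nf * (kBT / d) * log(rho_hat1)
  list(FH = FH, LH = FH / kappa_T, sigma_H = sqrt(kBT / kappa_T))
}

#' Brownian-ratchet load-velocity relation
#'
#' Stationary growth velocity of a rigid filament against a load `FL` in
#' the fast wall-diffusion limit: `v(FL) = d (U0 exp(-d FL / kBT) - W0)`,
#' where `U0`, `W0` are the bulk polymerization and depolymerization
#' rates.  The velocity vanishes at the stall force `(kBT/d) log(U0/W0)`.
#'
#' @param FL Load force(s), `kBT/d`.
#' @param U0,W0 Bulk polymerization/depolymerization rates, `1/tauD`.
#' @param d Monomer size.
#' @param kBT Thermal energy.
#' @return Velocity in `d/tauD`.
#' @examples
#' brownian_ratchet_velocity(0, U0 = 0.203, W0 = 0.080)
#' @export
brownian_ratchet_velocity <- function(FL, U0, W0, d = 1, kBT = 1) {
  stopifnot(U0 >= 0, W0 >= 0)
  d * (U0 * exp(-d * FL / kBT) - W0)
}

#' Bulk reaction rates implied by the attempt rate
#'
#' For the adopted reaction scheme the effective bulk depolymerization
#' rate is close to `W0 = nu exp(-beta eps0)` and the polymerization rate
#' is `U0 = rho_hat1 W0`; the chemical characteristic time is `tau_chem =
#' 1/W0`.
#'
#' @param params An [simulation_params()] object.
#' @return A list with `W0`, `U0` (rates, `1/tauD`) and `tau_chem`.
#' @examples
#' bulk_rates(simulation_params())   # W0 ~ 0.0844/tauD
#' @export
bulk_rates <- function(params) {
  W0 <- params$nu * exp(-params$eps0 / params$kBT)
  list(W0 = W0, U0 = params$rho_hat1 * W0, tau_chem = 1 / W0)
}

#' Characteristic time scales of the model
#'
#' Fast to slow: bond stretching `tau_s = 2 pi sqrt(M/ks)`, bond bending
#' `tau_b = 2 pi sqrt(M d^2 / (2 kappa))`, free-monomer inertial time
#' `M/zeta` and diffusion time `d^2 zeta / kBT`, wall inertial time
#' `Mw/zeta_w`, trap period `tau_T = 2 pi sqrt(Mw/kappa_T)`, wall
#' diffusion time `tau_D = zeta_w d^2/kBT` (the unit of time) and the
#' chemical time `tau_chem = 1/W0`.  The wall in the trap is overdamped
#' when `(Mw/zeta_w)^2 <= Mw / (4 kappa_T)`.
#'
#' @param params An [simulation_params()] object.
#' @return A list of times (in `tauD`) plus the logical `overdamped`.
#' @examples
#' timescales(simulation_params())
#' @export
timescales <- function(params) {
  w0 <- bulk_rates(params)$W0
  tau_win <- params$Mw / params$zeta_w
  list(
    tau_s = 2 * pi * sqrt(params$M / params$ks),
    tau_b = 2 * pi * sqrt(params$M * params$d^2 / (2 * params$kappa_bend)),
    tau_fm_in = params$M / params$zeta,
    tau_fm = params$d^2 * params$zeta / params$kBT,
    tau_win = tau_win,
    tau_T = 2 * pi * sqrt(params$Mw / params$kappa_T),
    tau_D = params$zeta_w * params$d^2 / params$kBT,
    tau_chem = 1 / w0,
    overdamped = tau_win^2 <= params$Mw / (4 * params$kappa_T))
}

#' Analytic report of all reference quantities
#'
#' Collects in one flat list the chemical constants (`K0`, `rho1c`,
#' `mu1c_star`, `rho1`, `p`), the rigid-filament trap references (`FH`,
#' `LH`, `sigma_H`), the bulk rates (`W0`, `U0`, `tau_chem`) and the
#' characteristic times, for the given parameter set.
#'
#' @param params An [simulation_params()] object.
#' @return A named list; printed nicely by [print.ot_theory()].
#' @export
theory_report <- function(params) {
  eq <- bulk_equilibrium_constant(params)
  hill <- hill_theory(params$Nf, params$kappa_T, params$rho_hat1,
                      params$d, params$kBT)
  rates <- bulk_rates(params)
  ts <- timescales(params)
  out <- c(eq,
           list(rho1 = params$rho1, p = chamber2_pressure(params)$p,
                pA = chamber2_pressure(params)$pA),
           hill, rates, ts)
  class(out) <- "ot_theory"
  out
}

#' @export
print.ot_theory <- function(x, ...) {
  cat("Analytic references (reduced units)\n")
  cat(sprintf("  K0 = %.5f d^3   rho1c = %.6f d^-3   mu1c* = %.4f kBT\n",
              x$K0, x$rho1c, x$mu1c_star))
  cat(sprintf("  rho1 = %.6f d^-3   p = %.6f kBT/d^3   pA = %.4f kBT/d\n",
              x$rho1, x$p, x$pA))
  cat(sprintf("  Hill: FH = %.4f kBT/d   LH = %.3f d   sigma_H = %.4f d\n",
              x$FH, x$LH, x$sigma_H))
  cat(sprintf("  rates: W0 = %.4f   U0 = %.4f per tauD   tau_chem = %.2f tauD\n",
              x$W0, x$U0, x$tau_chem))
  cat(sprintf("  times: tau_s = %.2e  tau_b = %.2e  tau_win = %.2e  tau_T = %.3g tauD\n",
              x$tau_s, x$tau_b, x$tau_win, x$tau_T))
  cat(sprintf("  overdamped wall: %s\n", x$overdamped))
  invisible(x)
}
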