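#' Simulation parameters in reduced units
#'
#' Collects and validates every model constant and run control of the
#' living-bundle/optical-trap model.  Reduced units are used throughout:
#' the monomer size `d`, the thermal energy `kBT` and the wall diffusion
#' time `tauD = zeta_w d^2 / kBT` all equal 1 at the defaults, so masses
#' are in `tauD^2 kBT/d^2`, frictions in `tauD kBT/d^2`, spring constants
#' in `kBT/d^2` and rates in `1/tauD`.
#'
#' The defaults are the model calibration for an F-actin bundle pressing
#' on a trapped micron-scale bead: persistence length `Lp = kappa_bend d /
#' kBT = 5370 d` (14.5 um at d = 2.7 nm), bond stiffness `ks = 4000
#' kBT/d^2`, bond formation energy `eps0 = 13.644143 kBT` (which fixes the
#' bulk equilibrium constant `K0 = 39.071 d^3`), wall softness `eps_w =
#' 0.1 kBT`, reaction attempt rate `nu = 7.1e4/tauD` and reservoir
#' exchange attempt rate `nu_GC = 187.5/tauD`.
#'
#' @param d Monomer size (unit of length).
#' @param kBT Thermal energy (unit of energy).  `kBT = 0` is accepted as a
#'   deterministic test mode (no thermostat noise, zero initial velocities).
#' @param M,Mw Monomer and wall masses.
#' @param zeta,zeta_w Monomer and wall solvent friction coefficients.
#' @param ks Bond spring constant.
#' @param kappa_bend Bending stiffness `kappa` of the `kappa (1 - cos
#'   theta)` three-body term; equals `Lp kBT / d`.
#' @param eps0 Bond formation energy gained when a bond is created.
#' @param eps_w Strength of the repulsive 9-3 monomer-wall potential.
#' @param kappa_T Trap strength of the harmonic load `-kappa_T L` on the
#'   mobile wall.
#' @param A Transverse area of the box; the transverse edge is `L' =
#'   sqrt(A)` with periodic boundaries.
#' @param Nf Number of grafted filaments; must be 1 or `2 l^2` for an
#'   integer `l` (body-centered square seed lattice).
#' @param rho_hat1 Reduced free monomer density `rho1 / rho1c`; values
#'   above 1 are supercritical (filaments tend to grow).
#' @param nu Reaction attempt rate, per filament and per direction.
#' @param nu_GC Reservoir insertion/deletion attempt rate.
#' @param h Integration time step.
#' @param r_c Reaction-region radius around each filament tip.
#' @param seed Master RNG seed; all subsystem streams derive from it.
#' @param L_R Optional total two-chamber box length (documentation only;
#'   the second chamber enters the dynamics only through its mean pressure,
#'   see [chamber2_pressure()]).
#'
#' @return An object of class `ot_params`: a list with the arguments plus
#'   the derived quantities `Lp` (persistence length), `s_c` (wall cutoff
#'   `3^(1/6) d`), `K0`, `rho1c`, `mu1c_star`, `rho1 = rho_hat1 * rho1c`,
#'   `mu1_star` and `p` (reservoir pressure `kBT rho1`).
#'
#' @examples
#' p <- simulation_params(Nf = 1, kappa_T = 0.019375)
#' p$rho1          # supercritical free monomer density
#' p$s_c           # wall cutoff 3^(1/6)
#' @export
simulation_params <- function(d = 1, kBT = 1, M = 3.556e-3, Mw = 1.0667e-2,
                              zeta = 0.5, zeta_w = 1, ks = 4000,
                              kappa_bend = 5370, eps0 = 13.644143,
                              eps_w = 0.1, kappa_T = 0.019375, A = 36,
                              Nf = 1, rho_hat1 = 2.5, nu = 7.1e4,
                              nu_GC = 187.5, h = 5.33e-5, r_c = 1.5,
                              seed = 1L, L_R = NULL) {
  # zeta = 0 and kBT = 0 are accepted as deterministic test modes
  stopifnot(d > 0, kBT >= 0, M > 0, Mw > 0, zeta >= 0, zeta_w >= 0, ks > 0,
            kappa_bend > 0, eps0 > 0, eps_w >= 0, kappa_T >= 0, A > 0,
            rho_hat1 > 0, nu > 0, nu_GC > 0, h > 0, r_c > 0)
  Nf <- as.integer(Nf)
  l <- sqrt(Nf / 2)
  if (!(Nf == 1L || (Nf >= 2L && abs(l - round(l)) < 1e-9))) {
    stop("Nf must be 1 or 2*l^2 for an integer l (body-centered square ",
         "seed lattice); got Nf = ", Nf)
  }
  p <- list(d = d, kBT = kBT, M = M, Mw = Mw, zeta = zeta, zeta_w = zeta_w,
            ks = ks, kappa_bend = kappa_bend, eps0 = eps0, eps_w = eps_w,
            kappa_T = kappa_T, A = A, Nf = Nf, rho_hat1 = rho_hat1,
            nu = nu, nu_GC = nu_GC, h = h, r_c = r_c,
            seed = as.integer(seed), L_R = L_R)
  p$s_c <- 3^(1 / 6) * d
  if (kBT > 0) {
    p$Lp <- kappa_bend * d / kBT
    eq <- bulk_equilibrium_constant(p)
    p$K0 <- eq$K0
    p$rho1c <- eq$rho1c
    p$mu1c_star <- eq$mu1c_star
    p$rho1 <- rho_hat1 * eq$rho1c
    p$mu1_star <- eq$mu1c_star + kBT * log(rho_hat1)
    p$p <- kBT * p$rho1
  } else {
    # deterministic test mode: chemistry is meaningless at kBT = 0
    p$Lp <- Inf
    p$K0 <- p$rho1c <- p$mu1c_star <- p$mu1_star <- NA_real_
    p$rho1 <- 0
    p$p <- 0
  }
  class(p) <- "ot_params"
  p
}

#' @export
print.ot_params <- function(x, ...) {
  cat("Living-bundle optical-trap parameters (reduced units)\n")
  cat(sprintf("  bundle: Nf = %d, A = %g d^2 (L' = %g d), kappa_T = %g kBT/d^2\n",
              x$Nf, x$A, sqrt(x$A), x$kappa_T))
  cat(sprintf("  filament: ks = %g, kappa = %g (Lp = %g d), eps0 = %g kBT\n",
              x$ks, x$kappa_bend, x$Lp, x$eps0))
  cat(sprintf("  wall: eps_w = %g kBT, cutoff s_c = %.6g d\n", x$eps_w, x$s_c))
  if (is.finite(x$K0)) {
    cat(sprintf("  chemistry: K0 = %.5f d^3, rho1c = %.6f, rho_hat1 = %g (rho1 = %.6f)\n",
                x$K0, x$rho1c, x$rho_hat1, x$rho1))
    cat(sprintf("  rates: nu = %g, nu_GC = %g per tauD; h = %g tauD\n",
                x$nu, x$nu_GC, x$h))
  } else {
    cat("  kBT = 0: deterministic test mode (no chemistry)\n")
  }
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a new validated `ot_params` with the given fields replaced.
#' Derived quantities (`K0`, `rho1`, ...) are recomputed.
#'
#' @param params An `ot_params` object.
#' @param ... Named fields accepted by [simulation_params()].
#' @export
update_params <- function(params, ...) {
  keep <- c("d", "kBT", "M", "Mw", "zeta", "zeta_w", "ks", "kappa_bend",
            "eps0", "eps_w", "kappa_T", "A", "Nf", "rho_hat1", "nu",
            "nu_GC", "h", "r_c", "seed", "L_R")
  args <- modifyList(params[keep], list(...))
  do.call(simulation_params, args)
}
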