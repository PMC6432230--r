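#' Bond stretching potential
#'
#' Harmonic bond of rest length `d` with formation energy `-eps0`:
#' `U_b(r) = -eps0 + ks (r - d)^2 / 2`.  Every non-seed bond of a
#' filament carries one such term; the grafted seed bond is rigid and
#' contributes no energy.
#'
#' @param r Bond length(s), `r > 0`.
#' @param params An [simulation_params()] object.
#' @return Energy in `kBT`.
#' @examples
#' p <- simulation_params()
#' bond_energy(1, p)      # -eps0
#' bond_energy(1.1, p)    # -eps0 + 20
#' @export
bond_energy <- function(r, params) {
  stopifnot(all(r > 0))
  -params$eps0 + 0.5 * params$ks * (r - params$d)^2
}

#' Bending potential
#'
#' Worm-like-chain bending term `U_bend(theta) = kappa (1 - cos theta)`
#' on the angle between adjacent bond vectors (`theta = 0` is a straight
#' continuation).  With `kappa = Lp kBT / d` this imposes persistence
#' length `Lp`.
#'
#' @param theta Bending angle(s) in radians, in `[0, pi]`.
#' @param params An [simulation_params()] object.
#' @return Energy in `kBT`.
#' @examples
#' p <- simulation_params()
#' bend_energy(0, p)        # 0
#' bend_energy(pi / 2, p)   # kappa
#' @export
bend_energy <- function(theta, params) {
  stopifnot(all(theta >= 0), all(theta <= pi))
  params$kappa_bend * (1 - cos(theta))
}

#' Repulsive 9-3 wall potential
#'
#' Purely repulsive wall-monomer potential
#' `U_w(s) = eps_w ( (3 sqrt(3)/2) ((d/s)^9 - (d/s)^3) + 1 )` for `s <=
#' s_c`, zero beyond, where `s` is the distance from the wall plane.  The
#' cutoff `s_c = 3^(1/6) d` is the location of the (shifted) minimum, so
#' the potential is continuous and vanishes there.
#'
#' @param s Distance(s) from the wall plane; must be positive (a
#'   non-positive distance means a monomer has crossed a wall, which is an
#'   integration failure).
#' @param params An [simulation_params()] object.
#' @return Energy in `kBT`.
#' @examples
#' p <- simulation_params()
#' wall_energy(p$s_c, p)   # 0 at the cutoff
#' wall_energy(1, p)       # eps_w
#' @export
wall_energy <- function(s, params) {
  if (any(s <= 0)) {
    stop("wall_energy: s <= 0 (a monomer has crossed a wall; ",
         "the time step is too large)")
  }
  q3 <- (params$d / s)^3
  ifelse(s > params$s_c, 0,
         params$eps_w * (1.5 * sqrt(3) * (q3^3 - q3) + 1))
}

#' @rdname wall_energy
#' @return `wall_force(s, params)`: the force `-dU_w/ds` on a monomer at
#'   distance `s` (positive = pushed away from the wall).
#' @export
wall_force <- function(s, params) {
  if (any(s <= 0)) {
    stop("wall_force: s <= 0 (a monomer has crossed a wall)")
  }
  q3 <- (params$d / s)^3
  ifelse(s > params$s_c, 0,
         -params$eps_w * 1.5 * sqrt(3) * (-9 * q3^3 + 3 * q3) / s)
}

#' Bulk equilibrium constant of the (de)polymerization reaction
#'
#' Closed form of the size-independent equilibrium constant `K0` of
#' single-monomer addition for the discrete worm-like chain with harmonic
#' bonds (spring `ks`, rest length `d`, formation energy `eps0`) and
#' `kappa (1 - cos theta)` bending (persistence length `Lp`):
#'
#' `K0 = exp(beta eps0) (2 pi d^4 / Lp) sqrt(2 pi /(beta ks d^2))
#'       (1 - exp(-2 Lp / d))`
#'
#' i.e. the configurational integral of one added bond vector times the
#' bond Boltzmann factor.  The critical free-monomer density is `rho1c =
#' 1/K0` and the critical effective chemical potential `mu1c* = kBT
#' log(rho1c d^3)`.  At the default calibration `K0 = 39.071 d^3`,
#' `rho1c = 0.0256 d^-3`, `mu1c* = -3.665 kBT`.
#'
#' @param params An [simulation_params()] object (or any list with
#'   `eps0`, `ks`, `kappa_bend`, `d`, `kBT`).
#' @return A list with `K0` (volume, `d^3`), `rho1c` (density, `d^-3`)
#'   and `mu1c_star` (energy, `kBT`).
#' @examples
#' bulk_equilibrium_constant(simulation_params())
#' @export
bulk_equilibrium_constant <- function(params) {
  d <- params$d
  beta <- 1 / params$kBT
  Lp <- params$kappa_bend * d / params$kBT
  K0 <- exp(beta * params$eps0) * (2 * pi * d^4 / Lp) *
    sqrt(2 * pi / (beta * params$ks * d^2)) * (1 - exp(-2 * Lp / d))
  rho1c <- 1 / K0
  list(K0 = K0, rho1c = rho1c,
       mu1c_star = params$kBT * log(rho1c * d^3))
}

#' Forces and energy breakdown of a configuration
#'
#' Evaluates all analytic forces of the model for a static configuration:
#' intrafilament bond and bend forces (computed for every monomer; seed
#' monomers are immobile so forces on them are never integrated), wall
#' forces from the fixed wall at `x = 0` and the mobile wall at `x = L`
#' on every mobile monomer, and the total force on the mobile wall
#' (monomer reaction forces plus the trap load `-kappa_T L` and, if
#' requested, the second-chamber mean pressure force `-p A`).
#'
#' @param state An `ot_state`.
#' @param params An `ot_params`.
#' @param include_pA Include the `-p A` term in the reported wall force.
#' @return A list: `forces` (matrix, one row per monomer), `F_wall`
#'   (total force on the mobile wall), `F_w_bun` and `F_w_m` (wall force
#'   from filament and from free monomers), `U_bond`, `U_bend`, `U_wall`.
#' @export
compute_forces <- function(state, params, include_pA = FALSE) {
  cpp_forces(unclass(state), unclass(params), include_pA)
}
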