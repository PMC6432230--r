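#' Seed layout of the grafted bundle
#'
#' Places the `Nf` filament seeds in the grafting plane and assigns their
#' longitudinal offsets.  For `Nf = 1` the single seed sits at the center
#' of the transverse box with offset `h_n = 0`.  For `Nf = 2 l^2` the
#' seeds occupy a planar body-centered square lattice of unit cell `a =
#' L'/l` (`l^2` corner plus `l^2` center sites), and the bundle is made
#' "homogeneous" (staggered) by giving the seeds `Nf` equally spaced
#' longitudinal offsets with step `d/Nf`, symmetric about zero:
#' `h_n = (n - Nf/2 - 1/2) d/Nf`, `n = 1..Nf`.  This uniform sub-monomer
#' staggering dephases the wall contacts of the filaments, which is what
#' produces a smooth wall-position distribution for a bundle.
#'
#' @param params An [simulation_params()] object.
#' @return A data.frame with one row per filament: `n`, `h_n` (longitudinal
#'   seed offset), `y`, `z` (transverse seed coordinates).
#' @examples
#' build_seed_layout(simulation_params(Nf = 8))
#' @export
build_seed_layout <- function(params) {
  stopifnot(inherits(params, "ot_params"))
  Nf <- params$Nf
  Lprime <- sqrt(params$A)
  if (Nf == 1L) {
    return(data.frame(n = 1L, h_n = 0, y = Lprime / 2, z = Lprime / 2))
  }
  l <- as.integer(round(sqrt(Nf / 2)))
  a <- Lprime / l
  corners <- expand.grid(y = a * (seq_len(l) - 1), z = a * (seq_len(l) - 1))
  centers <- expand.grid(y = a * (seq_len(l) - 1) + a / 2,
                         z = a * (seq_len(l) - 1) + a / 2)
  sites <- rbind(corners, centers)
  n <- seq_len(Nf)
  h_n <- (n - Nf / 2 - 0.5) * params$d / Nf
  data.frame(n = n, h_n = h_n, y = sites$y, z = sites$z)
}

#' Initial system state
#'
#' Builds the starting configuration of a run: each filament is a bare
#' seed (two immobile monomers at `(h_n, y_n, z_n)` and `(h_n + d, y_n,
#' z_n)`), free monomers are placed as a spatial Poisson process at
#' density `rho1 = rho_hat1 * rho1c` in the slab `0 < x < L0`, thinned by
#' the wall Boltzmann weight (the equilibrium barometric profile, so no
#' monomer starts inside a strongly repulsive wall core), velocities are
#' Maxwell-Boltzmann at `kBT` (all zero when `kBT = 0`), and the wall
#' starts at rest at `L0`.
#'
#' @param params An [simulation_params()] object.
#' @param L0 Initial wall position; must exceed `2 d + s_c` plus the
#'   largest seed offset so the box can contain the seeds.
#' @param rho1 Free-monomer placement density; defaults to the reservoir
#'   density `params$rho1`.  Set to 0 for a monomer-free box.
#' @param j0 Initial filament size(s) (scalar or one value per filament,
#'   default 2 = bare seeds).  Sizes above 2 build straight filaments of
#'   equally spaced monomers along `x`, a standard shortcut to start a
#'   run near its expected equilibrium length instead of growing the
#'   filament from the seed.
#' @return An object of class `ot_state`: a list with `pos`, `vel`
#'   (matrices, one row per monomer), the topological indices `n_idx`,
#'   `k_idx` (filament id and rank; 0 marks free monomers), the seed
#'   geometry `hn`, `seed_y`, `seed_z`, the wall coordinates `L`, `L_dot`,
#'   the clock `t`, the RNG state and the pending Poisson event times.
#' @examples
#' p <- simulation_params(Nf = 1)
#' s <- build_initial_state(p, L0 = 20)
#' sum(s$n_idx == 0)   # number of free monomers
#' @export
build_initial_state <- function(params, L0, rho1 = params$rho1, j0 = 2L) {
  stopifnot(inherits(params, "ot_params"), L0 > 0)
  layout <- build_seed_layout(params)
  Nf <- params$Nf
  j0 <- rep(as.integer(j0), length.out = Nf)
  stopifnot(all(j0 >= 2L))
  if (L0 <= max(layout$h_n + (j0 - 1) * params$d) + params$s_c) {
    stop("L0 = ", L0, " is too small to contain the grafted filaments")
  }
  rng <- cpp_rng_new(params$seed)

  # straight filaments of j0 monomers along x (j0 = 2: bare seeds)
  pos <- do.call(rbind, lapply(seq_len(Nf), function(n) {
    cbind(layout$h_n[n] + (seq_len(j0[n]) - 1) * params$d,
          layout$y[n], layout$z[n])
  }))
  n_idx <- rep(seq_len(Nf), times = j0)
  k_idx <- unlist(lapply(j0, seq_len))

  # Free-monomer gas: homogeneous Poisson process in the slab, thinned by
  # the wall Boltzmann factor exp(-beta Uw) so that no monomer starts deep
  # inside a repulsive core (the thinned process is the equilibrium
  # barometric profile of the ideal gas between the two walls)
  if (rho1 > 0) {
    dr <- cpp_rng_draw(rng, 3L, 1L, "uniform")
    rng <- dr$rng
    lambda <- rho1 * params$A * L0
    N1 <- stats::qpois(dr$values, lambda)
    if (N1 > 0) {
      dr <- cpp_rng_draw(rng, 3L, 4L * N1, "uniform")
      rng <- dr$rng
      u <- matrix(dr$values, ncol = 4)
      xs <- u[, 1] * L0
      w <- exp(-(wall_energy(xs, params) + wall_energy(L0 - xs, params)) /
                 max(params$kBT, .Machine$double.eps))
      keep <- u[, 4] < w
      N1 <- sum(keep)
      if (N1 > 0) {
        Lprime <- sqrt(params$A)
        pos <- rbind(pos, cbind(xs[keep], u[keep, 2] * Lprime,
                                u[keep, 3] * Lprime))
        n_idx <- c(n_idx, rep(0L, N1))
        k_idx <- c(k_idx, rep(0L, N1))
      }
    }
  }

  ntot <- nrow(pos)
  vel <- matrix(0, ntot, 3)
  if (params$kBT > 0) {
    mobile <- n_idx == 0L | k_idx >= 3L  # seeds stay at rest
    nmob <- sum(mobile)
    if (nmob > 0) {
      dr <- cpp_rng_draw(rng, 3L, 3L * nmob, "normal")
      rng <- dr$rng
      vel[mobile, ] <- sqrt(params$kBT / params$M) *
        matrix(dr$values, ncol = 3)
    }
  }
  dimnames(pos) <- NULL

  state <- list(pos = pos, vel = vel, n_idx = as.integer(n_idx),
                k_idx = as.integer(k_idx), hn = layout$h_n,
                seed_y = layout$y, seed_z = layout$z,
                L = L0, L_dot = 0, t = 0, rng = rng,
                next_reaction = rep(NA_real_, 2 * Nf),
                next_gc = NA_real_)
  class(state) <- "ot_state"
  state
}

#' @export
print.ot_state <- function(x, ...) {
  j <- filament_sizes(x)
  cat(sprintf("ot_state: t = %.4g tauD, wall L = %.4g d, %d monomers\n",
              x$t, x$L, nrow(x$pos)))
  cat(sprintf("  filaments (j_n): %s;  free monomers N1 = %d\n",
              paste(j, collapse = " "), sum(x$n_idx == 0L)))
  invisible(x)
}

#' Filament sizes of a state
#'
#' @param state An `ot_state`.
#' @return Integer vector `j_n` (monomer count per filament, seeds included).
#' @export
filament_sizes <- function(state) {
  Nf <- length(state$hn)
  vapply(seq_len(Nf), function(n) sum(state$n_idx == n), integer(1))
}

#' Chemically reactive free monomers
#'
#' A free monomer is reactive when it lies within the reaction radius
#' `r_c` of any filament tip (transverse distances folded into the
#' periodic box).  Reservoir insertions and deletions of reactive monomers
#' are automatically refused, which keeps the reservoir moves from
#' interfering with the detailed balance of the reaction moves.
#'
#' @param state An `ot_state`.
#' @param params An `ot_params`.
#' @param ids Monomer row indices to query; defaults to all free monomers.
#' @return Logical vector, one entry per queried monomer.
#' @export
is_reactive <- function(state, params, ids = which(state$n_idx == 0L)) {
  if (any(state$n_idx[ids] != 0L)) {
    stop("is_reactive() is defined for free monomers only")
  }
  Nf <- length(state$hn)
  Lprime <- sqrt(params$A)
  tips <- vapply(seq_len(Nf), function(n) {
    j <- sum(state$n_idx == n)
    which(state$n_idx == n & state$k_idx == j)
  }, integer(1))
  fold <- function(dv) dv - Lprime * round(dv / Lprime)
  out <- rep(FALSE, length(ids))
  for (tp in tips) {
    dx <- state$pos[ids, 1] - state$pos[tp, 1]
    dy <- fold(state$pos[ids, 2] - state$pos[tp, 2])
    dz <- fold(state$pos[ids, 3] - state$pos[tp, 3])
    out <- out | (dx^2 + dy^2 + dz^2 < params$r_c^2)
  }
  out
}
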