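p <- simulation_params()

test_that("bond potential matches its closed form", {
  expect_equal(bond_energy(1, p), -13.644143)
  expect_equal(bond_energy(1.1, p), -13.644143 + 20)
  # even spring: symmetric about the rest length
  expect_equal(bond_energy(1 + 0.03, p), bond_energy(1 - 0.03, p))
})

test_that("bending potential matches kappa(1 - cos theta)", {
  expect_equal(bend_energy(0, p), 0)
  expect_equal(bend_energy(pi / 2, p), 5370)
  th <- seq(0.01, 0.1, by = 0.01)
  expect_true(all(abs(bend_energy(th, p) / (5370 * th^2 / 2) - 1) < 0.01))
})

test_that("9-3 wall potential is continuous, repulsive and correctly scaled", {
  expect_equal(wall_energy(p$s_c, p), 0)
  expect_equal(wall_energy(1, p), 0.1)          # eps_w at s = d
  expect_equal(wall_energy(2, p), 0)            # beyond cutoff
  s <- seq(0.4, p$s_c, by = 0.01)
  expect_true(all(diff(wall_energy(s, p)) < 0)) # strictly decreasing
  expect_error(wall_energy(-0.1, p), "crossed")
  # effective core: solving Uw(s*) = kBT gives s* = 3^(-1/6) d
  root <- uniroot(function(s) wall_energy(s, p) - 1, c(0.5, 1),
                  tol = 1e-12)$root
  expect_equal(root, 3^(-1 / 6), tolerance = 1e-6)
  # wall force at s = d: eps_w * (3 sqrt(3)/2) * 6
  expect_equal(wall_force(1, p), 0.1 * 1.5 * sqrt(3) * 6)
})

test_that("bulk equilibrium constant and critical state match the model", {
  eq <- bulk_equilibrium_constant(p)
  expect_equal(eq$K0, 39.07144, tolerance = 1e-4)
  expect_equal(eq$rho1c, 0.025594, tolerance = 1e-4)
  expect_equal(eq$mu1c_star, -3.6654, tolerance = 1e-4)
  # stiff-limit: the finite-Lp correction bracket tends to 1
  pinf <- update_params(p, kappa_bend = 1e9)
  ratio <- bulk_equilibrium_constant(pinf)$K0 / eq$K0
  expect_equal(ratio * 1e9 / 5370, 1, tolerance = 1e-6)
})

test_that("forces on a straight relaxed filament vanish", {
  st <- make_filament_state(simulation_params(A = 9), j = 6, L0 = 30)
  f <- compute_forces(st, simulation_params(A = 9))
  expect_lt(max(abs(f$forces)), 1e-10)
  expect_equal(f$U_bond, -4 * 13.644143)
  expect_equal(f$U_bend, 0)
})

test_that("wall forces obey Newton's third law and the no-contact limit", {
  pp <- simulation_params(A = 9, kappa_T = 0.275)
  st <- make_filament_state(pp, j = 2, L0 = 20, extra = c(19, 1, 1))
  f <- compute_forces(st, pp, include_pA = TRUE)
  # single free monomer at s = d from the mobile wall
  expect_equal(f$F_w_m, 0.1 * 1.5 * sqrt(3) * 6)
  expect_equal(f$forces[3, 1], -f$F_w_m)
  expect_equal(f$F_wall, f$F_w_m - 0.275 * 20 - chamber2_pressure(pp)$pA)
  # nothing near the wall: pure trap plus chamber-2 load
  st2 <- make_filament_state(pp, j = 2, L0 = 20)
  f2 <- compute_forces(st2, pp, include_pA = TRUE)
  expect_equal(f2$F_wall, -0.275 * 20 - chamber2_pressure(pp)$pA)
})

test_that("analytic forces equal minus the numerical gradient", {
  pp <- simulation_params(A = 9)
  set.seed(11)
  for (rep in 1:3) {
    j <- sample(4:7, 1)
    st <- make_filament_state(pp, j = j, L0 = 12)
    mob <- which(st$k_idx >= 3 | st$n_idx == 0L)
    st$pos[mob, ] <- st$pos[mob, ] + matrix(rnorm(3 * length(mob), 0, 0.01),
                                            ncol = 3)
    st$pos <- rbind(st$pos, c(11.2, 1, 1))  # free monomer in the wall skin
    st$vel <- rbind(st$vel, c(0, 0, 0))
    st$n_idx <- c(st$n_idx, 0L); st$k_idx <- c(st$k_idx, 0L)
    f0 <- compute_forces(st, pp)
    U_of <- function(s) {
      ff <- compute_forces(s, pp)
      ff$U_bond + ff$U_bend + ff$U_wall
    }
    hh <- 1e-6
    for (i in c(sample(3:j, 2), nrow(st$pos))) {
      for (dim in 1:3) {
        sp <- st; sp$pos[i, dim] <- sp$pos[i, dim] + hh
        sm <- st; sm$pos[i, dim] <- sm$pos[i, dim] - hh
        fd <- -(U_of(sp) - U_of(sm)) / (2 * hh)
        expect_equal(f0$forces[i, dim], fd,
                     tolerance = 1e-6 * max(1, abs(fd)))
      }
    }
    # wall coordinate: dU/dL = -(monomeric force on the wall)
    sp <- st; sp$L <- st$L + hh
    sm <- st; sm$L <- st$L - hh
    fdL <- -(U_of(sp) - U_of(sm)) / (2 * hh)
    expect_equal(f0$F_w_bun + f0$F_w_m, fdL, tolerance = 1e-6 * max(1, abs(fdL)))
  }
})
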