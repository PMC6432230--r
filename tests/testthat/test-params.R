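test_that("seed layout places single and bundled seeds correctly", {
  p1 <- simulation_params(Nf = 1)
  l1 <- build_seed_layout(p1)
  expect_equal(l1$h_n, 0)
  expect_equal(nrow(l1), 1L)

  p8 <- simulation_params(Nf = 8, A = 36)
  l8 <- build_seed_layout(p8)
  expect_equal(nrow(l8), 8L)
  # l = 2, a = 3: four corner sites and four cell centers
  sites <- paste(l8$y, l8$z)
  expect_setequal(sites, c("0 0", "0 3", "3 0", "3 3",
                           "1.5 1.5", "1.5 4.5", "4.5 1.5", "4.5 4.5"))
  # homogeneous staggering: equally spaced offsets, step d/Nf, centered on 0
  expect_equal(diff(sort(l8$h_n)), rep(1 / 8, 7))
  expect_equal(mean(l8$h_n), 0)
  expect_lt(diff(range(l8$h_n)), 1)
})

test_that("invalid filament numbers are rejected with the 2l^2 rule", {
  expect_error(simulation_params(Nf = 3), "2\\*l\\^2")
  expect_error(simulation_params(Nf = 6), "2\\*l\\^2")
  expect_silent(simulation_params(Nf = 2))
  expect_silent(simulation_params(Nf = 18))
})

test_that("initial state geometry and velocities are as specified", {
  p <- simulation_params(Nf = 1, kBT = 0, seed = 3)
  s <- build_initial_state(p, L0 = 20)
  # seeds immobile at (h, y, z) and (h + d, y, z)
  expect_equal(s$pos[1, ], c(0, 3, 3))
  expect_equal(s$pos[2, ], c(1, 3, 3))
  expect_true(all(s$vel == 0))  # kBT = 0 draws zero velocities
  expect_error(build_initial_state(p, L0 = 2), "too small")

  # pre-grown straight filament
  s2 <- build_initial_state(simulation_params(seed = 1), L0 = 30, j0 = 10)
  expect_equal(filament_sizes(s2), 10L)
  expect_equal(s2$pos[s2$n_idx == 1L, 1], 0:9)
})

test_that("free monomer count follows the thinned Poisson law across seeds", {
  p0 <- simulation_params(Nf = 1, A = 9)
  leff <- integrate(function(x) {
    exp(-(wall_energy(x, p0) + wall_energy(20 - x, p0)))
  }, 1e-9, 20 - 1e-9)$value
  lambda <- p0$rho1 * p0$A * leff
  counts <- vapply(1:60, function(sd) {
    s <- build_initial_state(update_params(p0, seed = sd), L0 = 20)
    sum(s$n_idx == 0L)
  }, integer(1))
  # mean within 4 sigma, variance ~ mean (Poisson)
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 60))
  expect_gt(var(counts), lambda / 3)
  expect_lt(var(counts), lambda * 3)
})

test_that("parameter updates recompute derived chemistry", {
  p <- simulation_params()
  p2 <- update_params(p, rho_hat1 = 1)
  expect_equal(p2$rho1, p2$rho1c)
  expect_equal(p2$mu1_star, p2$mu1c_star)
  expect_equal(p$K0, p2$K0)
})
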