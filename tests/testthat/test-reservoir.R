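test_that("chamber-2 pressure is the ideal-gas value at the imposed potential", {
  p <- simulation_params(A = 36, rho_hat1 = 2.5)
  c2 <- chamber2_pressure(p)
  expect_equal(c2$p, p$rho1)
  expect_equal(c2$pA, 2.3035, tolerance = 1e-3)
  expect_equal(c2$p, exp(p$mu1_star / p$kBT))  # p = (kBT/d^3) e^{mu1*/kBT}
  p0 <- update_params(p, rho_hat1 = 1e-9)
  expect_lt(chamber2_pressure(p0)$p, 1e-9)
})

test_that("wall-skin insertion is suppressed by the Boltzmann factor", {
  p <- simulation_params()
  # at s = 0.5 d the 9-3 wall costs ~131 kBT, making insertion hopeless
  expect_equal(wall_energy(0.5, p), 0.1 * (1.5 * sqrt(3) * (512 - 8) + 1),
               tolerance = 1e-12)
  expect_gt(wall_energy(0.5, p), 100)
})

test_that("reservoir holds the imposed density and exchanges at high acceptance", {
  p <- simulation_params(A = 36, seed = 8)
  s <- build_initial_state(p, L0 = 20)
  out <- run_segment(s, p, duration = 120, mobile_wall = FALSE,
                     reactions = FALSE, trace_stride = 2000,
                     xhist_stride = 2000, xhist_bin = 0.1)
  tr <- out$trace[out$trace$t > 30, ]
  leff <- integrate(function(x) {
    exp(-(wall_energy(x, p) + wall_energy(20 - x, p)))
  }, 1e-9, 20 - 1e-9)$value
  expected_N1 <- p$rho1 * p$A * leff
  se <- sd(tr$N1) / sqrt(nrow(tr) / 5)  # ~5 samples per N1 relaxation time
  expect_lt(abs(mean(tr$N1) - expected_N1), 3 * se)
  g <- gc_summary(out$gc)
  expect_gt(g$acceptance, 0.8)
  expect_lt(g$acceptance, 0.98)
})
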