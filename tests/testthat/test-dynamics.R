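test_that("deterministic limit reduces to free flight", {
  p <- simulation_params(kBT = 0, zeta = 0, zeta_w = 0)
  st <- make_filament_state(p, j = 2, L0 = 10, extra = c(5, 3, 3))
  st$vel[3, ] <- c(0.5, -0.2, 0.1)
  out <- run_segment(st, p, duration = 100 * p$h, reactions = FALSE,
                     reservoir = FALSE, include_pA = FALSE, counters = FALSE)
  expect_equal(out$state$pos[3, 1], 5 + 0.5 * 100 * p$h, tolerance = 1e-12)
  expect_equal(out$state$vel[3, ], c(0.5, -0.2, 0.1), tolerance = 1e-12)
})

test_that("gamma = T = 0 wall oscillator conserves energy to 1e-6", {
  p <- simulation_params(kBT = 0, zeta = 0, zeta_w = 0, kappa_T = 0.275)
  st <- build_initial_state(p, L0 = 10, rho1 = 0)
  st$L_dot <- 1
  E0 <- 0.5 * p$Mw * st$L_dot^2 + 0.5 * p$kappa_T * st$L^2
  out <- run_segment(st, p, duration = 1e5 * p$h, reactions = FALSE,
                     reservoir = FALSE, include_pA = FALSE, counters = FALSE)
  E1 <- 0.5 * p$Mw * out$state$L_dot^2 + 0.5 * p$kappa_T * out$state$L^2
  expect_lt(abs(E1 - E0) / E0, 1e-6)
})

test_that("thermostatted monomer satisfies equipartition", {
  p <- simulation_params(A = 9)
  st <- make_filament_state(p, j = 2, L0 = 10, extra = c(5, 1, 1))
  st$vel[3, ] <- 0
  # sample velocities along one long trajectory
  v2 <- numeric(0)
  for (k in 1:50) {
    out <- run_segment(st, p, duration = 20000 * p$h, reactions = FALSE,
                       reservoir = FALSE, include_pA = FALSE, counters = FALSE)
    st <- out$state
    v2 <- c(v2, st$vel[3, ]^2)
  }
  # <v^2> per component = kBT/M; SE from sample spread of v^2
  se <- sd(v2) / sqrt(length(v2))
  expect_lt(abs(mean(v2) - p$kBT / p$M), 3 * se)
})

test_that("seed monomers never move and topology invariants survive a fuzz run", {
  p <- simulation_params(Nf = 8, A = 36, kappa_T = 0.275, seed = 5)
  st <- build_initial_state(p, L0 = 8, j0 = 3)
  seeds0 <- st$pos[st$k_idx <= 2 & st$n_idx > 0, ]
  out <- run_segment(st, p, duration = 3, mobile_wall = TRUE,
                     trace_stride = 0)
  s1 <- out$state
  expect_equal(s1$pos[s1$k_idx <= 2 & s1$n_idx > 0, ], seeds0)
  expect_true(all(filament_sizes(s1) >= 2))
  # (n, k) pairs unique and ranks contiguous
  for (n in 1:8) {
    ks <- sort(s1$k_idx[s1$n_idx == n])
    expect_equal(ks, seq_along(ks))
  }
  # transverse coordinates of free monomers wrapped into [0, L')
  fr <- s1$n_idx == 0L
  expect_true(all(s1$pos[fr, 2:3] >= 0 & s1$pos[fr, 2:3] < 6))
  # x within the hard bounds
  expect_true(all(s1$pos[fr, 1] > -p$s_c & s1$pos[fr, 1] < s1$L + p$s_c))
})

test_that("event scheduling executes the expected number of attempts", {
  p <- simulation_params(A = 9, nu = 500, nu_GC = 50, seed = 2)
  st <- build_initial_state(p, L0 = 15)
  out <- run_segment(st, p, duration = 40, mobile_wall = FALSE)
  ct <- out$counters
  # one Poisson clock per direction per filament at rate nu
  expect_lt(abs(sum(ct$U_att) - 500 * 40), 4 * sqrt(500 * 40))
  expect_lt(abs(sum(ct$W_att) - 500 * 40), 4 * sqrt(500 * 40))
  g <- out$gc
  natt <- g$ins_att + g$del_att
  expect_lt(abs(natt - 50 * 40), 4 * sqrt(50 * 40))
})
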