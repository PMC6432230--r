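test_that("crossover and relative indices follow the floor definition", {
  expect_equal(crossover_index(47.0, 0), 48L)
  expect_equal(relative_index(48, 48), 0L)
  expect_equal(crossover_index(26.5, 0.4375), 27L)
  expect_equal(relative_index(26, crossover_index(26.5, 0.4375)), -1L)
  expect_equal(crossover_index(c(10.2, 10.9), 0), c(11L, 11L))
  expect_error(crossover_index(5, 6))
})

test_that("rate estimators reproduce hand-computed rates on a scripted log", {
  p <- simulation_params()
  # hand-built counters: residence (in steps), attempts, successes
  ct <- data.frame(m = c(-3, -2, -1),
                   Q = c(1000, 2000, 4000),
                   U_att = c(50, 100, 200), U_succ = c(2, 3, 0),
                   W_att = c(50, 100, 200), W_succ = c(1, 2, 4))
  rt <- rate_table(ct, p)
  expect_equal(sum(rt$Q), 1)
  expect_equal(rt$U[1], 2 / (1000 * p$h))
  expect_equal(rt$W[3], 4 / (4000 * p$h))
  expect_equal(rt$U_att[2], 100 / (2000 * p$h))
  pr <- plateau_rates(ct, p)          # plateau windows m <= -2 / m <= -3
  expect_equal(pr$W0, 3 / (3000 * p$h))
  expect_equal(pr$U0, 2 / (1000 * p$h))
  pr1 <- plateau_rates(ct, p, m_max_W = -1, m_max_U = -1)
  expect_equal(pr1$W0, 7 / (7000 * p$h))
  # single filament parked at one m with no events
  ct0 <- data.frame(m = -3, Q = 1000, U_att = 0, U_succ = 0,
                    W_att = 0, W_succ = 0)
  rt0 <- rate_table(ct0, p)
  expect_equal(rt0$U, 0)
  expect_equal(rt0$Q, 1)
})

test_that("Qm slope fit recovers a geometric residence distribution", {
  ct <- data.frame(m = -6:-1, Q = 1e5 * 2.5^(-6:-1),
                   U_att = 0, U_succ = 0, W_att = 0, W_succ = 0)
  qs <- qm_slope(ct)
  expect_equal(qs$rho_hat1_fit, 2.5, tolerance = 1e-10)
})

test_that("ACF of fluctuations matches variance at zero lag and OU theory", {
  x <- make_ou_series(60000, tau = 20, sigma = 1.5, dt = 1, seed = 3)
  a <- acf_fluct(x, dt = 1, lag_max = 200)
  expect_equal(a$acf[1], mean((x - mean(x))^2) * length(x) / (length(x)),
               tolerance = 1e-10)
  fit <- fit_exponentials(a, n_components = 1)
  expect_equal(fit$times, 20, tolerance = 0.1 * 20)
  expect_equal(fit$amplitudes, 1.5^2, tolerance = 0.15 * 1.5^2)
})

test_that("two-component fits separate well-spaced relaxation times", {
  set.seed(5)
  x1 <- make_ou_series(200000, tau = 4, sigma = 1, dt = 1, seed = 8)
  x2 <- make_ou_series(200000, tau = 80, sigma = 1, dt = 1, seed = 9)
  a <- acf_fluct(x1 + x2, dt = 1, lag_max = 400)
  fit <- fit_exponentials(a, n_components = 2)
  expect_equal(fit$times[1], 4, tolerance = 0.3 * 4)
  expect_equal(fit$times[2], 80, tolerance = 0.25 * 80)
})

test_that("non-decaying correlation functions are flagged instead of fitted", {
  a <- data.frame(lag = 0:100, acf = seq(1, 2, length.out = 101))  # growing
  expect_error(fit_exponentials(a), "cannot fit|does not decay")
  a0 <- data.frame(lag = 0:10, acf = c(-1, rep(0, 10)))
  expect_error(fit_exponentials(a0), "non-positive")
})

test_that("Hill theory and ratchet velocity give the rigid-filament references", {
  h1 <- hill_theory(1, 0.019375, 2.5)
  expect_equal(h1$LH, 47.3, tolerance = 0.01)
  h8 <- hill_theory(8, 0.275, 2.5)
  expect_equal(h8$LH, 26.6, tolerance = 0.01)
  expect_equal(h8$sigma_H, 1.9069, tolerance = 1e-4)
  expect_equal(hill_theory(4, 0.1, 1)$FH, 0)  # critical bath pushes nothing
  expect_equal(brownian_ratchet_velocity(0, 0.203, 0.080), 0.123)
  stall <- log(0.203 / 0.080)
  expect_equal(brownian_ratchet_velocity(stall, 0.203, 0.080), 0,
               tolerance = 1e-12)
})

test_that("wall histogram is normalized and carries the Gaussian reference", {
  p <- simulation_params(Nf = 8, kappa_T = 0.275)
  set.seed(2)
  L <- rnorm(5000, 26.6, 1.9)
  h <- wall_histogram(L, p, bin = 0.1)
  expect_equal(sum(h$density) * 0.1, 1, tolerance = 1e-6)
  expect_equal(h$L[which.max(h$gaussian)], 26.65, tolerance = 0.1)
  expect_error(wall_histogram(numeric(0), p), "empty")
})

test_that("equilibrium summary reports moments and the force identity inputs", {
  p <- simulation_params(Nf = 1, kappa_T = 0.019375)
  set.seed(9)
  n <- 400
  tr <- data.frame(t = seq_len(n), L = rnorm(n, 47, 2), L_dot = rnorm(n),
                   N1 = rpois(n, 100), U_bond = 0, U_bend = 0, U_wall = 0,
                   F_bun = rnorm(n, 0.91, 0.1), F_wm = rnorm(n, 2.3, 0.1),
                   j_1 = rpois(n, 46), X_1 = rnorm(n, 45, 2),
                   Rperp_1 = abs(rnorm(n, 3, 1)))
  s <- equilibrium_summary(tr, params = p)
  expect_equal(unname(s$L["mean"]), mean(tr$L))
  expect_equal(s$kT_L, 0.019375 * mean(tr$L))
  expect_equal(unname(s$I["mean"]), mean(tr$j_1))
  expect_false(s$drift)
  expect_error(equilibrium_summary(tr[1, ], params = p), "too short")
})
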