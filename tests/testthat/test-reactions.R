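test_that("reactive classification uses the tip reaction sphere", {
  p <- simulation_params(A = 36, seed = 1)
  st <- make_filament_state(p, j = 5, L0 = 20,
                            extra = rbind(c(4 + 0.99 * p$r_c, 3, 3),
                                          c(4, 3 + 1.01 * p$r_c, 3),
                                          c(12, 1, 1)))
  r <- is_reactive(st, p)
  expect_equal(unname(r), c(TRUE, FALSE, FALSE))
  expect_error(is_reactive(st, p, ids = 1), "free monomers only")
})

test_that("depolymerization never removes seed monomers", {
  # bare seed bombarded by depolymerization attempts only
  p <- simulation_params(A = 9, seed = 3, nu = 1e5)
  st <- build_initial_state(p, L0 = 10, rho1 = 0)
  out <- run_segment(st, p, duration = 2, mobile_wall = FALSE,
                     reservoir = FALSE)
  expect_equal(filament_sizes(out$state), 2L)
  expect_gt(sum(out$counters$W_att), 1e5)  # attempts happened, all refused
  expect_equal(sum(out$counters$W_succ), 0)
})

test_that("bulk depolymerization acceptance scale is nu*exp(-beta*eps0)", {
  p <- simulation_params()
  br <- bulk_rates(p)
  expect_equal(br$W0 / p$nu, 1.1876e-6, tolerance = 1e-3)
  expect_equal(br$U0 / br$W0, 2.5)
  expect_equal(br$tau_chem, 11.85, tolerance = 0.01)
})

test_that("event log and counters agree on a reactive run", {
  p <- simulation_params(A = 9, eps0 = 11, seed = 6)
  st <- build_initial_state(p, L0 = 12, j0 = 8)
  out <- run_segment(st, p, duration = 30, mobile_wall = FALSE)
  ev <- out$events
  ct <- out$counters
  expect_equal(sum(ev$dir == 1), sum(ct$U_succ))
  expect_equal(sum(ev$dir == -1), sum(ct$W_succ))
  # net size change equals the event balance
  expect_equal(filament_sizes(out$state) - 8L,
               as.integer(sum(ev$dir)))
  # events are time ordered and tagged with valid m indices
  expect_true(all(diff(ev$t) >= 0))
  expect_true(all(ev$m %in% ct$m))
  # success counts never exceed attempts
  expect_true(all(ct$U_succ <= ct$U_att))
  expect_true(all(ct$W_succ <= ct$W_att))
})
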