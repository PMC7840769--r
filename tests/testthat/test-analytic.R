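test_that("step probability follows the stay-on x catch-up form", {
  p <- analytic_params(tau_D = 60, tau_C = 3e-4, tau_Z = 0.2)
  expect_equal(step_probability(p), exp(-(0.2 / 60 + 3e-4 / 0.2)))
  expect_equal(step_probability(p), 0.99518, tolerance = 1e-4)
  # limits: vanishing loss rates give P -> 1
  expect_equal(step_probability(analytic_params(1e9, 1e-12, tau_Z = 1)),
               1, tolerance = 1e-6)
})

test_that("mean step count matches closed form, -1/log(P), and the
           discrete geometric oracle", {
  p <- analytic_params(60, 3e-4, tau_Z = 0.2)
  expect_equal(mean_steps(p), 60 * 0.2 / (0.04 + 3e-4 * 60))
  expect_equal(mean_steps(p), 206.9, tolerance = 1e-3)
  expect_equal(mean_steps(p), -1 / log(step_probability(p)),
               tolerance = 1e-12)
  # tau_C = 0 edge: N = tau_D / tau_Z
  p0 <- analytic_params(60, 1e-300, tau_Z = 0.2)
  expect_equal(mean_steps(p0), 300, tolerance = 1e-6)
  # brute-force geometric sum: the continuum limit exceeds the discrete
  # mean by exactly half a step for P near 1, and agrees to 1% once the
  # run is a few hundred steps long
  for (P in c(0.92, 0.97, 0.995)) {
    cont <- -1 / log(P)
    disc <- mean_steps_discrete_oracle(P)
    expect_close(cont - disc, 0.5, tol = 0.05)
  }
  expect_equal(-1 / log(0.995), mean_steps_discrete_oracle(0.995),
               tolerance = 0.01)
})

test_that("run length and duration scale as L0*N and N*tau_Z", {
  p <- analytic_params(60, 3e-4, v_z = 25)
  expect_equal(p$tau_Z, 0.2)
  expect_equal(mean_run_length(p), 1034, tolerance = 1e-3)
  expect_equal(mean_run_duration(p), 41.4, tolerance = 1e-3)
  # speed consistency: L / T = V_Z exactly
  expect_equal(mean_run_length(p) / mean_run_duration(p), 25)
  # duration decreases monotonically with treadmilling speed
  tab <- analytic_processivity(seq(10, 100, 10), 60, 3e-4)
  expect_true(all(diff(tab$mean_run_duration) < 0))
})

test_that("the run-length optimum sits at tau_Z = sqrt(tau_C tau_D)", {
  v_grid <- seq(5, 120, by = 0.05)
  tab <- analytic_processivity(v_grid, 60, 3e-4)
  v_num <- v_grid[which.max(tab$mean_run_length)]
  p <- analytic_params(60, 3e-4, v_z = 25)
  expect_equal(optimal_treadmill_speed(p), 37.3, tolerance = 1e-3)
  expect_equal(v_num, optimal_treadmill_speed(p), tolerance = 0.005)
  # P itself is also maximized there
  tz_grid <- seq(0.01, 1, by = 1e-4)
  P <- exp(-(tz_grid / 60 + 3e-4 / tz_grid))
  expect_equal(tz_grid[which.max(P)], sqrt(3e-4 * 60), tolerance = 0.01)
})

test_that("micro-simulations estimate tau_D and tau_C in the stated ranges", {
  est <- estimate_tau_d_tau_c(ratchet_params(D = 0.04, U0 = 10, v_z = 25),
                              n_traj = 60, seed = 14)
  expect_gt(est$tau_D, 10)
  expect_lt(est$tau_D, 400)
  expect_gt(est$tau_C, 1e-4)
  expect_lt(est$tau_C, 1e-2)
  # U0 = 0 dwell reduces to the flat-potential first-passage closed form
  p0 <- ratchet_params(D = 0.04, U0 = 0, v_z = 25)
  est0 <- estimate_tau_d_tau_c(p0, n_traj = 400, d_esc = 20,
                               t_max_dwell = 5, seed = 15)
  oracle <- mfpt_oracle(function(x) 0, p0$D_nm, 20)
  expect_equal(est0$tau_D, oracle, tolerance = 0.05)
})

test_that("deep-well dwell converges to the potential-theory oracle", {
  # closed-form double-integral MFPT through the truncated parabola;
  # compare at a fine step where the time discretization of the escape
  # flux is small
  p <- ratchet_params(D = 0.04, U0 = 8, v_z = 25, dt = 5e-7)
  est <- estimate_tau_d_tau_c(p, n_traj = 120, d_esc = 50,
                              t_max_dwell = 60, seed = 16)
  oracle <- mfpt_oracle(well_potential(8, p$a), p$D_nm, 50)
  expect_equal(est$tau_D, oracle, tolerance = 0.35)
})

test_that("simulated distance curve shape is reproduced by the theory
           with measured tau values", {
  p <- ratchet_params(D = 0.04, U0 = 10, v_z = 25)
  est <- estimate_tau_d_tau_c(p, n_traj = 60, seed = 17)
  v_z <- c(20, 40, 70, 100)
  sim <- run_length_duration_curves(v_z, p, n_traj = 25, seed = 18,
                                    n_boot = 50)
  th <- analytic_processivity(v_z, est$tau_D, est$tau_C)
  ok <- !is.na(sim$mean_distance)
  expect_gt(sum(ok), 2)
  ratio <- sim$mean_distance[ok] / th$mean_run_length[ok]
  # agreement within a factor of ~2 across the sweep (scaling theory)
  expect_true(all(ratio > 0.3 & ratio < 3))
})
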