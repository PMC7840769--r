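# Build a minimal hand-made trajectory for classifier unit tests
fake_traj <- function(t, x, x_S, v_z = 25, L0 = 5,
                      drop_times = numeric(0)) {
  p <- ratchet_params(v_z = v_z, L0 = L0, t_max = max(t) + 1)
  structure(tibble::tibble(t = t, x = x, x_S = x_S,
                           x_G = x_S + (p$n_fil - 1) * L0,
                           bound = TRUE),
            class = c("ratchet_trajectory", "tbl_df", "tbl", "data.frame"),
            params = p, scenario = ratchet_scenario(),
            drop_times = drop_times)
}

test_that("an enzyme riding the end for 10 s is one persistent run", {
  t <- seq(0, 10, 0.05)
  tr <- fake_traj(t, x = 25 * t, x_S = 25 * t)
  cl <- classify_end_tracking(tr)
  expect_true(cl$is_persistent)
  expect_equal(nrow(cl$runs), 1)
  expect_equal(cl$runs$duration, 10)
  expect_equal(cl$runs$speed, 25, tolerance = 1e-9)
})

test_that("a stationary enzyme left behind is not persistent", {
  t <- seq(0, 12, 0.05)
  # enzyme parked at 0 while the end advances at 25 nm/s; the gap crosses
  # 100 nm at t = 4 s and drop events fire every subunit period
  tr <- fake_traj(t, x = rep(0, length(t)), x_S = 25 * t,
                  drop_times = seq(0.2, 12, by = 0.2))
  cl <- classify_end_tracking(tr)
  expect_false(cl$is_persistent)
})

test_that("runs terminate when the gap exceeds 100 nm", {
  t <- seq(0, 20, 0.05)
  # tracks for 6 s, then stalls; gap reaches 100 nm 4 s later
  x <- ifelse(t <= 6, 25 * t, 150)
  tr <- fake_traj(t, x = x, x_S = 25 * t,
                  drop_times = seq(6.2, 20, by = 0.2))
  cl <- classify_end_tracking(tr)
  expect_true(cl$is_persistent)
  expect_lt(max(cl$runs$t_end), 10.1)
})

test_that("trajectories shorter than the minimum duration are not persistent", {
  t <- seq(0, 3, 0.05)
  tr <- fake_traj(t, x = 25 * t, x_S = 25 * t)
  expect_false(classify_end_tracking(tr)$is_persistent)
})

test_that("propensity counts persistent fractions and rejects empty input", {
  t <- seq(0, 10, 0.05)
  good <- fake_traj(t, 25 * t, 25 * t)
  bad <- fake_traj(t, rep(0, length(t)), 25 * t,
                   drop_times = seq(0.2, 10, 0.2))
  expect_equal(propensity(list(good, good)), 1)
  expect_equal(propensity(list(bad, bad)), 0)
  expect_equal(propensity(list(good, bad)), 0.5)
  expect_error(propensity(list()), "empty")
})

test_that("phase diagram covers the grid and handles degenerate cells", {
  pd <- phase_diagram(list(U0 = c(2, 10)), list(v_z = c(25)),
                      ratchet_params(D = 0.04, t_max = 30), n_traj = 6,
                      seed = 2)
  expect_equal(nrow(pd), 2)
  expect_true(all(pd$propensity >= 0 & pd$propensity <= 1))
  expect_lt(pd$propensity[pd$U0 == 2], 0.5)
  expect_gte(pd$propensity[pd$U0 == 10], 0.5)
  pd1 <- phase_diagram(list(U0 = 10), list(v_z = 25),
                       ratchet_params(t_max = 20), n_traj = 1, seed = 3)
  expect_true(pd1$propensity %in% c(0, 1))
  expect_error(phase_diagram(list(U0 = numeric(0)), list(v_z = 25),
                             ratchet_params()),
               "empty grid")
})

test_that("processivity curves report missing speeds as NA and keep
           the distance = speed x duration identity", {
  cur <- run_length_duration_curves(c(20, 40), ratchet_params(t_max = 60),
                                    n_traj = 12, seed = 8, n_boot = 100)
  expect_equal(nrow(cur), 2)
  expect_equal(sum(cur$relative_propensity), 1, tolerance = 1e-9)
  p <- ratchet_params(D = 0.04, U0 = 10, v_z = 30, t_max = 60)
  tr <- simulate_trajectory(p, seed = 21)
  runs <- classify_end_tracking(tr)$runs
  pers <- runs[runs$persistent, ]
  if (nrow(pers)) {
    expect_true(all(abs(pers$distance - pers$speed * pers$duration) <=
                      2 * 0.05 * abs(pers$speed) + 1e-6))
  }
})

test_that("bound lifetime matches the free-diffusion first-passage oracle", {
  # U0 = 0, V_Z = 0: escape from a 250 nm filament + 100 nm margins is
  # plain 1D first passage out of a 450 nm interval from uniform subunit
  # starts
  p <- ratchet_params(D = 0.04, U0 = 0, v_z = 0, t_max = 60)
  s <- mean_bound_lifetime(p, n_traj = 150, seed = 10)
  starts <- 100 + (0:49) * 5
  oracle <- mfpt_interval_uniform(p$D_nm, 450, starts)
  expect_equal(s$mean_lifetime, oracle, tolerance = 0.12)
  expect_equal(s$frac_censored, 0)
  expect_equal(s$km_mean, s$mean_lifetime, tolerance = 1e-9)
})

test_that("deeper wells give much longer bound lifetimes", {
  p0 <- ratchet_params(D = 0.04, U0 = 0, v_z = 0, t_max = 10)
  p6 <- ratchet_params(D = 0.04, U0 = 6, v_z = 0, t_max = 10)
  s0 <- mean_bound_lifetime(p0, n_traj = 40, seed = 11)
  s6 <- mean_bound_lifetime(p6, n_traj = 40, seed = 11)
  expect_gt(s6$mean_lifetime, 3 * s0$mean_lifetime)
})

test_that("slow-diffusing enzymes lose most of their bound lifetime when
           treadmilling accelerates", {
  vz <- c(8, 25)
  slow <- activity_curve(vz, ratchet_params(D = 0.005, U0 = 10, dt = 1e-5,
                                            t_max = 120),
                         n_traj = 60, seed = 13)
  expect_equal(slow$relative_off_rate[1], 1)
  # ~70% lifetime drop from 8 to 25 nm/s = off-rate up ~3x
  expect_gt(slow$relative_off_rate[2], 2)
  expect_lt(slow$relative_off_rate[2], 5)
  expect_false(any(slow$censored_dominated))
})

test_that("binding-potential bracketing recovers a known depth", {
  # generate noisy relative-activity data from the model at U0 = 9 and
  # check the recovered bracket contains it (self-consistency)
  base <- ratchet_params(D = 0.041, U0 = 9, dt = 2e-5, t_max = 40)
  vz <- c(8, 16, 25)
  truth <- activity_curve(vz, base, n_traj = 40, seed = 30)
  set.seed(31)
  dat <- tibble::tibble(
    v_z = vz,
    activity = truth$relative_off_rate * (1 + rnorm(3, 0, 0.1)))
  fit <- fit_binding_potential(dat, D = 0.041, U_grid = c(5, 7, 9, 11, 13),
                               params = ratchet_params(D = 0.041,
                                                       dt = 2e-5,
                                                       t_max = 40),
                               n_traj = 40, seed = 32)
  expect_lte(fit$u_low, 9)
  expect_gte(fit$u_high, 9)
  expect_s3_class(glance(fit), "tbl_df")
})
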