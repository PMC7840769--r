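p10 <- ratchet_params(D = 0.04, U0 = 10, v_z = 25)

test_that("binding potential has the stated depth, range and flat gap", {
  f <- filament_state(0, p10)
  expect_equal(binding_potential(0, f, p10), -10)
  expect_equal(binding_potential(2.5, f, p10), 0)
  expect_equal(binding_potential(5, f, p10), -10)      # next subunit center
  expect_equal(binding_potential(-10, f, p10), 0)       # off the end
  # after the end subunit departs, its former position sits in a flat
  # stretch: midway between old and new end centers is outside range a
  f2 <- filament_state(5, p10)
  expect_equal(binding_potential(0, f2, p10), 0)
  expect_true(all(binding_potential(seq(-1, 1, 0.25), f2, p10) == 0))
  expect_error(binding_potential(0, list(subunit_centers = numeric(0)),
                                 p10),
               "depolymerized")
})

test_that("binding force is -dU/dx of the quadratic and pulls inward", {
  f <- filament_state(0, p10)
  expect_equal(binding_force(0, f, p10), 0)
  # analytic derivative at x_c + a/2: -2 U0 (a/2) / a^2 = -U0/a
  expect_equal(binding_force(1.25, f, p10), -4)
  expect_equal(binding_force(300, f, p10), 0)
  # cross-check by central finite difference of the potential
  for (x in c(0.7, 1.9, 6.3, -1.2)) {
    h <- 1e-6
    num <- -(binding_potential(x + h, f, p10) -
               binding_potential(x - h, f, p10)) / (2 * h)
    expect_equal(binding_force(x, f, p10), num, tolerance = 1e-6)
  }
})

test_that("energy landscape is translation covariant", {
  shift <- 137.5
  f0 <- filament_state(0, p10)
  f1 <- filament_state(shift, p10)
  xs <- seq(-20, 270, by = 0.9)
  expect_equal(binding_potential(xs + shift, f1, p10),
               binding_potential(xs, f0, p10))
  expect_equal(binding_force(xs + shift, f1, p10),
               binding_force(xs, f0, p10))
})

test_that("single-step enzyme update has the stated drift and noise", {
  f <- filament_state(0, p10)
  # deterministic part: eta = 0 pulls toward the well center
  e <- enzyme_state(1, f, p10)
  e2 <- step_enzyme(e, f, p10, eta = 0)
  expect_lt(e2$x, 1)
  expect_gt(e2$x, 0)
  # D = 0 freezes the enzyme
  p0 <- ratchet_params(D = 1e-12, U0 = 0, v_z = 25)
  e3 <- step_enzyme(enzyme_state(3, f, p0), f, p0, eta = 1)
  expect_equal(e3$x, 3, tolerance = 1e-4)
  # free-diffusion step variance 2 D dt (std 0.632 nm at the defaults)
  pf <- ratchet_params(D = 0.04, U0 = 0, v_z = 25)
  set.seed(42)
  steps <- replicate(2e4, step_enzyme(enzyme_state(0, f, pf), f, pf)$x)
  expect_equal(sd(steps), sqrt(2 * pf$D_nm * pf$dt), tolerance = 0.02)
})

test_that("treadmilling clock fires at round(L0/(v_z dt)) and conserves subunits", {
  expect_equal(filament_state(0, p10)$steps_until_event, 40000)
  f <- filament_state(0, p10)
  n0 <- length(f$subunit_centers)
  for (i in 1:40000) f <- step_filament(f, p10)
  expect_equal(f$x_S, 5)
  expect_equal(f$x_G, 5 + (p10$n_fil - 1) * 5)
  expect_equal(length(f$subunit_centers), n0)
  expect_equal(diff(f$subunit_centers), rep(5, n0 - 1))
  # v_z = 0: static forever
  ps <- ratchet_params(v_z = 0)
  fs <- filament_state(0, ps)
  for (i in 1:100) fs <- step_filament(fs, ps)
  expect_equal(fs$x_S, 0)
})

test_that("boltzmann occupancy holds in a static well", {
  # V_Z = 0, deep well: sampled positions inside the well follow
  # exp(-U(x)); compare via the standard normal approximation of the
  # quadratic well (sd = a / sqrt(2 U0)) and a KS test
  # the enzyme hops between wells over 20 s; pool displacements relative
  # to the nearest subunit center, which share one Boltzmann shape
  p <- ratchet_params(D = 0.04, U0 = 10, v_z = 0, t_max = 20)
  tr <- simulate_trajectory(p, seed = 7)
  dx <- tr$x - p$L0 * round(tr$x / p$L0)
  xin <- dx[abs(dx) <= p$a & tr$t > 0.1]
  expect_gt(length(xin), 100)
  expect_equal(sd(xin), p$a / sqrt(2 * p$U0), tolerance = 0.1)
  # samples 0.05 s apart are effectively independent (in-well relaxation
  # time 1/(kD) ~ 8 us), so a direct KS comparison is valid
  ks <- suppressWarnings(
    stats::ks.test(xin, function(q) {
      stats::pnorm(q, 0, p$a / sqrt(2 * p$U0))
    }))
  expect_gt(ks$p.value, 0.01)
})

test_that("free enzyme shows 1D diffusive MSD 2 D t", {
  p <- ratchet_params(D = 0.04, U0 = 0, v_z = 0, t_max = 2)
  disp2 <- vapply(1:60, function(s) {
    tr <- simulate_trajectory(p, seed = 1000 + s)
    tr$x[tr$t == 1][1]^2
  }, numeric(1))
  expect_equal(mean(disp2), 2 * p$D_nm * 1, tolerance = 0.35)
})
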