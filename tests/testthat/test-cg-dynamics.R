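ring <- build_ideal_ring(seed = 1)
asg <- assign_domains(ring$structure, ring$topology)
sys <- build_cg(ring$structure, asg, ring$topology)

test_that("the reference state stays put at T = 0 with no damping", {
  tr <- run_langevin(sys, langevin_params(temperature = 0, damping = 0),
                     500, save_every = 100)
  expect_equal(max(abs(tr$x_final - sys$x0)), 0)
})

test_that("total energy is conserved in the symplectic limit", {
  set.seed(31)
  x0 <- sys$x0 + matrix(rnorm(18, 0, 0.5), ncol = 3)
  n_steps <- 50000
  tr <- run_langevin(sys, langevin_params(temperature = 0, damping = 0),
                     n_steps, save_every = 100, x0 = x0)
  drift <- diff(range(tr$e_tot))
  expect_lt(drift / n_steps, 1e-6)  # kcal/mol per step
})

test_that("identical seeds give bitwise-identical trajectories", {
  a <- run_langevin(sys, langevin_params(seed = 77), 5000, save_every = 500)
  b <- run_langevin(sys, langevin_params(seed = 77), 5000, save_every = 500)
  expect_identical(a$frames, b$frames)
  expect_identical(a$e_tot, b$e_tot)
  c <- run_langevin(sys, langevin_params(seed = 78), 5000, save_every = 500)
  expect_false(identical(a$frames, c$frames))
})

test_that("a restrained torsion equilibrates to variance kB*T / k", {
  # k = 50 kcal mol^-1 deg^-2 at 310 K -> var = 0.61603/50 = 0.012321 deg^2
  rs <- list(list(kind = "torsion",
                  participants = c("A1", "A2", "A3", "B1"),
                  k = 50, target_start = NA, target_velocity = 0,
                  duration_ps = 0, active_until_ps = Inf))
  tr <- run_langevin(sys, langevin_params(seed = 4), 1e6,
                     restraints = rs, save_every = 10)
  phi_deg <- tr$cv_value[, 1] * 180 / pi
  v <- stats::var(phi_deg[-(1:1000)])  # drop equilibration
  theory <- KB_TEST * 310 / 50
  expect_lt(abs(v - theory) / theory, 0.2)
})

test_that("steering work is non-negative on average across seeds", {
  proto <- make_protocol(1, ring$topology, steering_ps = 500,
                         post_steering_ps = 0)
  works <- vapply(1:4, function(sd) {
    tr <- run_steered(sys, proto, langevin_params(seed = sd),
                      save_every = 100)
    # energy stored in the restraint at the end of pulling is strictly
    # positive work done against the lagging colvar
    sum(tr$cv_energy[, 1])
  }, numeric(1))
  expect_gt(mean(works), 0)
})

test_that("a zero-duration protocol reduces to free dynamics", {
  proto <- make_protocol(2, ring$topology, steering_ps = 0,
                         post_steering_ps = 50)
  a <- run_steered(sys, proto, langevin_params(seed = 12), save_every = 100)
  b <- run_langevin(sys, langevin_params(seed = 12), 5000, save_every = 100)
  expect_identical(a$frames, b$frames)
})

test_that("type-1 steering separates the interface by 20 A", {
  proto <- make_protocol(1, ring$topology, steering_ps = 10000,
                         post_steering_ps = 0)
  tr <- run_steered(sys, proto, langevin_params(seed = 1), save_every = 1000)
  cv <- colvar_table(tr)
  final <- cv$value[cv$time_ps == 10000]
  d0 <- com_distance(sys$x0[ring$topology$open_interface[1], ],
                     sys$x0[ring$topology$open_interface[2], ])
  expect_equal(final - d0, 20, tolerance = 0.5)
})

test_that("type-2 steering drives each torsion down 20 deg (sum -60)", {
  proto <- make_protocol(2, ring$topology, steering_ps = 10000,
                         post_steering_ps = 0)
  tr <- run_steered(sys, proto, langevin_params(seed = 1), save_every = 1000)
  cv <- colvar_table(tr)
  fin <- cv[cv$time_ps == 10000, ]
  expect_equal(fin$value, rep(-20, 3), tolerance = 0.5)  # initial torsions 0
  hs <- cg_handedness_series(tr)
  expect_equal(hs$values[hs$time_ps == 10000], -60, tolerance = 1.5)
})

test_that("free relaxation reflects the reference geometry it was built with", {
  # equilibria from a right-handed spiral -> relaxes to positive handedness
  rh <- apply_deformation(ring$structure, ring$topology, "rh_spiral",
                          twist = 20)
  sys_rh <- build_cg(rh, asg, ring$topology)
  tr <- run_langevin(sys_rh, langevin_params(seed = 6), 50000,
                     save_every = 5000, x0 = sys_rh$x0)
  hs <- cg_handedness_series(tr)
  expect_gt(mean(tail(hs$values, 5)), 30)
  # planar equilibria -> stays near zero
  tr0 <- run_langevin(sys, langevin_params(seed = 6), 50000,
                      save_every = 5000)
  hs0 <- cg_handedness_series(tr0)
  expect_lt(abs(mean(tail(hs0$values, 5))), 15)
})

test_that("an unstable timestep is reported as an integration error", {
  bad <- langevin_params(temperature = 0, damping = 0, timestep = 5)
  set.seed(2)
  x0 <- sys$x0 + matrix(rnorm(18, 0, 1), ncol = 3)
  expect_error(run_langevin(sys, bad, 5000, save_every = 100, x0 = x0),
               "timestep|unstable")
})
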