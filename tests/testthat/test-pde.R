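test_that("non-dimensionalisation applies the stated scalings and inverts", {
  q <- nondimensionalise(D = 1, L = 1, gamma = 3, sigma = 0.2, m = 5,
                         a = c(1, 2), u = 4, t = 7)
  expect_equal(q$gamma, 3); expect_equal(q$sigma, 0.2); expect_equal(q$m, 5)
  expect_equal(nondimensionalise(D = 2, L = 1, gamma = 4)$gamma, 2)
  q2 <- nondimensionalise(D = 1.7, L = 0.3, gamma = 4, sigma = 0.06, m = 5,
                          a = c(1, 2), b = 0.5, u = 4, t = 7)
  back <- dimensionalise(q2)
  expect_equal(back$gamma, 4, tolerance = 1e-14)
  expect_equal(back$sigma, 0.06, tolerance = 1e-14)
  expect_equal(back$a, c(1, 2), tolerance = 1e-14)
  expect_equal(back$t, 7, tolerance = 1e-14)
  expect_error(nondimensionalise(D = -1, L = 1), class = "aggdiffenv_config_error")
})

test_that("grids are uniform with an integer cell count", {
  g <- make_grid(0.01)
  expect_equal(g$n, 200L)
  expect_equal(diff(range(diff(g$x))), 0)
  expect_equal(g$x[1], -1 + 0.005)
  expect_error(make_grid(0.013), class = "aggdiffenv_config_error")
})

test_that("initial-condition fixtures have the documented shapes and mass p", {
  g <- make_grid(0.01)
  u <- make_initial_condition("flat_min", g, p = 1, gamma = 2, sigma = 0.1)
  r0 <- r0_of(2, 0.1)
  expect_equal(total_mass(u, g$dx), 1, tolerance = 1e-12)
  expect_lt(max(abs(range(g$x[u > 0]) - c(-r0, r0))), 0.011)
  u6 <- make_initial_condition("cos6", g, p = 2)
  pk <- peak_stats(u6, g$x)
  expect_equal(pk$count, 3)
  expect_equal(sort(pk$locations), c(-1 / 3, 0, 1 / 3), tolerance = 0.01)
  expect_equal(total_mass(u6, g$dx), 2, tolerance = 1e-12)
  ug <- make_initial_condition("gaussian", g)
  expect_equal(g$x[which.max(ug)], 0.5, tolerance = 0.011)
  u4 <- make_initial_condition("cos4", g)
  expect_equal(peak_stats(u4, g$x)$count, 2)
  expect_error(make_initial_condition("bogus", g))
})

test_that("total mass is the midpoint-rule integral", {
  g <- make_grid(0.02)
  expect_equal(total_mass(numeric(g$n), g$dx), 0)
  u <- make_initial_condition("flat_min", g, p = 3, gamma = 2, sigma = 0.1)
  expect_equal(total_mass(2 * u, g$dx), 2 * total_mass(u, g$dx))
})

test_that("zero density is a fixed point and steps conserve mass", {
  g <- make_grid(0.02)
  cfg <- solver_config("quadratic_local4", gamma = 2, sigma = 0.1,
                       env = clump_env(1, 1), dt = 4e-7)
  sim <- step_solution(numeric(g$n), g, cfg, n_steps = 10L)
  expect_equal(sim$u, numeric(g$n))
  u0 <- make_initial_condition("flat_min", g, gamma = 2, sigma = 0.1)
  sim <- step_solution(u0, g, cfg, n_steps = 500L)
  expect_lt(sim$max_mass_err, 1e-12)
  expect_equal(total_mass(sim$u, g$dx), 1, tolerance = 1e-12)
})

test_that("the flat-landscape profile is numerically steady under local4", {
  g <- make_grid(0.01)
  u0 <- make_initial_condition("flat_min", g, gamma = 2, sigma = 0.1)
  cfg <- solver_config("quadratic_local4", gamma = 2, sigma = 0.1,
                       dt = 3e-8, tol = 1e-8, max_time = 0.05,
                       record_every = 10000L)
  sim <- run_to_steady(u0, g, cfg)
  expect_true(sim$converged)
  expect_lt(max(abs(sim$u - u0)), 1e-3)
  expect_gte(sim$min_u, -1e-12)
  expect_lt(sim$max_energy_increase, 1e-10)
})

test_that("an oversized step raises an instability error", {
  g <- make_grid(0.01)
  u0 <- make_initial_condition("flat_min", g, gamma = 2, sigma = 0.1)
  cfg <- solver_config("quadratic_local4", gamma = 2, sigma = 0.1,
                       env = clump_env(1, 1), dt = 1e-6, max_time = 0.01)
  expect_warning(check_stability(u0, g, cfg), "stability")
  expect_error(run_to_steady(u0, g, cfg), class = "aggdiffenv_instability_error")
})

test_that("the energy series is recorded and dissipates along a run", {
  g <- make_grid(0.02)
  u0 <- make_initial_condition("gaussian", g)
  cfg <- solver_config("linear_nonlocal", gamma = 2, kernel = tophat_kernel(0.1),
                       env = clump_env(1, 1), dt = 5e-6, tol = 1e-10,
                       max_time = 0.05, record_every = 100L)
  sim <- run_to_steady(u0, g, cfg)
  expect_gt(length(sim$energy), 10L)
  expect_true(all(diff(sim$energy) <= 1e-10))
  expect_equal(sim$energy_t[1], 0)
})
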