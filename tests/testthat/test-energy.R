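test_that("E2 quadrature on gridded densities matches analytic integrals", {
  g <- make_grid(0.002)
  flat <- fourier_env()
  expect_equal(energy_E2_quadrature(numeric(g$n), flat, 2, 0.1,
                                    x = g$x, dx = g$dx), 0)
  # u = 1 + cos(pi x), gamma = 0, A = 0: E2 = int u^2 = 3
  u <- 1 + cos(pi * g$x)
  expect_equal(energy_E2_quadrature(u, flat, 0, 0.1, x = g$x, dx = g$dx), 3,
               tolerance = 1e-4)
  # boundary-leak guard
  expect_error(energy_E2_quadrature(rep(1, g$n), flat, 2, 0.1,
                                    x = g$x, dx = g$dx),
               class = "aggdiffenv_boundary_leak_error")
})

test_that("E2 of the flat-landscape minimiser equals (1-gamma) p^2 / (2 r0)", {
  hm <- homogeneous_minimiser(params_default())
  expect_equal(energy_E2_closed(hm), -1 / (2 * pi * 0.1))          # -1.59155
  expect_equal(energy_E2_quadrature(hm), -1 / (2 * pi * 0.1), tolerance = 1e-9)
})

test_that("closed-form E2 agrees with quadrature across both branches", {
  for (sol in draw_candidates(50, seed = 11L))
    expect_lt(abs(energy_E2_closed(sol) - energy_E2_quadrature(sol)), 1e-6)
  # continuity across the r = 1/n branch split
  pp <- params_default()
  env <- clump_env(4, 1.5)
  e_lo <- energy_E2_closed(build_candidate(pp, env, 0.25 - 1e-9))
  e_hi <- energy_E2_closed(build_candidate(pp, env, 0.25 + 1e-9))
  e_at <- energy_E2_closed(build_candidate(pp, env, 0.25))
  expect_equal(e_lo, e_at, tolerance = 1e-6)
  expect_equal(e_hi, e_at, tolerance = 1e-6)
})

test_that("E1 quadrature drops the kernel term at gamma = 0 and is symmetric", {
  g <- make_grid(0.005)
  env <- clump_env(1, 1)
  u <- ifelse(abs(g$x) < 0.4, (1 + cos(pi * g$x / 0.4))^2, 0)
  A <- eval_environment(env, g$x)
  kn <- laplace_kernel(10)
  expect_equal(energy_E1_quadrature(u, env, 0, kn, g$x, g$dx),
               sum(u * (u - 2 * A)) * g$dx, tolerance = 1e-12)
  # even u, even A: invariant under grid reversal
  expect_equal(energy_E1_quadrature(u, env, 2, kn, g$x, g$dx),
               energy_E1_quadrature(rev(u), env, 2, kn, g$x, g$dx))
})

test_that("semi-analytic Laplace convolution matches direct integration", {
  sol <- build_candidate(params_laplace(), clump_env(1, 1), 0.25)
  xs <- c(-0.9, -0.3, 0, 0.17, 0.25, 0.6)
  oracle <- vapply(xs, function(x)
    stats::integrate(function(y) 5 * exp(-10 * abs(x - y)) * candidate_value(sol, y),
                     -0.25, 0.25, rel.tol = 1e-12)$value, numeric(1))
  expect_lt(max(abs(laplace_convolution(sol, xs) - oracle)), 1e-8)
})

test_that("semi-analytic E1 matches the grid-convolution quadrature route", {
  sol <- build_candidate(params_laplace(), clump_env(1, 1), 0.25)
  g <- make_grid(0.001)
  u <- candidate_value(sol, g$x)
  e_grid <- energy_E1_quadrature(u, sol$env, 2, laplace_kernel(10), g$x, g$dx)
  expect_equal(energy_E1_closed(sol), e_grid, tolerance = 1e-4)
})

test_that("minimisation recovers the flat-landscape solution", {
  fit <- minimise_energy(params_default(), clump_env(1, 0))
  r0 <- r0_of(2, 0.1)
  expect_equal(fit$r, r0, tolerance = 1e-6)
  expect_equal(fit$sol$alpha0, 1 / (2 * r0), tolerance = 1e-5)
  expect_equal(fit$sol$Q, fit$sol$alpha0, tolerance = 1e-5)
  expect_equal(fit$energy, -1 / (2 * r0), tolerance = 1e-6)
})

test_that("the energy curve is consistent with the minimiser", {
  pp <- params_default()
  env <- clump_env(1, 1)
  fit <- minimise_energy(pp, env)
  rg <- seq(0.05, 1, by = 0.005)
  curve <- energy_curve(pp, env, rg)
  expect_true(all(is.finite(curve$energy)))
  expect_lt(abs(attr(curve, "argmin_r") - fit$r), 0.005 + 1e-9)
  # inadmissible half-widths are absent: the curve stops short of r0
  expect_lt(max(curve$r), r0_of(2, 0.1))
  expect_gt(min(curve$r), 0.05 - 1e-9)
  # local-minimum certificate within the admissible family
  nb <- energy_curve(pp, env, fit$r + c(-1e-3, 1e-3))
  expect_true(all(fit$energy <= nb$energy + 1e-9))
})

test_that("Laplace-family minimisation returns an interior admissible optimum", {
  fit <- minimise_energy(params_laplace(), clump_env(1, 1))
  expect_gt(fit$r, 0.05)
  expect_lt(fit$r, 1)
  expect_true(is_admissible(fit$sol)$admissible)
  nb <- energy_curve(params_laplace(), clump_env(1, 1), fit$r + c(-1e-3, 1e-3))
  expect_true(all(fit$energy <= nb$energy + 1e-9))
})

test_that("gamma saturation: the minimiser half-width levels off", {
  pp <- params_default()
  rs <- vapply(c(2, 4, 8, 16), function(g)
    minimise_energy(model_params(g, sigma = 0.1), clump_env(1, 1))$r, numeric(1))
  steps <- abs(diff(rs))
  expect_true(all(diff(steps) < 0))
})
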