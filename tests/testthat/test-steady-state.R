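test_that("r0 follows the homogeneous half-width formula", {
  expect_equal(r0_of(2, 0.1), pi * 0.1)           # equals pi*sigma at gamma=2
  expect_equal(r0_of(1e6, 0.1), pi * 0.1 / sqrt(2), tolerance = 1e-5)
  expect_gt(r0_of(1.0001, 0.1), 20)               # diverges as gamma -> 1+
  expect_error(r0_of(0.9, 0.1), class = "aggdiffenv_regime_error")
  expect_error(r0_of(1, 0.1), class = "aggdiffenv_regime_error")
})

test_that("mode factors match both families and guard resonance", {
  expect_equal(mode_factor(params_default(gamma = 1e-12), 3), 1, tolerance = 1e-9)
  expect_equal(mode_factor(params_default(), 1),
               2 / (2 * (1 - 2) + 2 * 0.01 * pi^2))   # -1.10949...
  expect_equal(mode_factor(params_laplace(), 1),
               (pi^2 + 100) / (pi^2 - 100))           # -1.21902...
  # denominator 2(1-gamma) + gamma sigma^2 n^2 pi^2 = 0 at sigma = 1/pi, gamma = 2
  expect_error(mode_factor(model_params(2, sigma = 1 / pi), 1),
               class = "aggdiffenv_resonance_error")
})

test_that("the flat-landscape minimiser is recovered exactly", {
  pp <- params_default()
  hm <- homogeneous_minimiser(pp)
  r0 <- r0_of(2, 0.1)
  expect_equal(hm$r, r0)
  expect_equal(hm$alpha0, 1 / (2 * r0), tolerance = 1e-12)
  expect_equal(hm$Q, hm$alpha0, tolerance = 1e-12)
  expect_equal(candidate_value(hm, 0), 1 / r0, tolerance = 1e-12)  # peak p/r0
  expect_equal(candidate_value(hm, c(-r0, r0)), c(0, 0), tolerance = 1e-12)
  # mass by independent quadrature
  expect_equal(quad_simpson(function(z) candidate_value(hm, z), -r0, r0), 1,
               tolerance = 1e-10)
  expect_lt(steady_residual(hm), 1e-10)
  expect_true(is_admissible(hm)$admissible)
})

test_that("candidate constraints agree with an independent linear-solve oracle", {
  pp <- params_default()
  env <- clump_env(1, 1)
  r <- 0.25
  sol <- build_candidate(pp, env, r)
  # oracle: assemble mass and continuity constraints by quadrature/evaluation
  # of the three basis profiles, then solve the 2x2 system independently
  w2 <- pi / r0_of(2, 0.1)
  alpha_n <- mode_factor(pp, 1)
  basis <- list(function(z) rep(1, length(z)),             # alpha0
                function(z) cos(w2 * z))                   # Q
  fixed <- function(z) alpha_n * (1 + cos(pi * z))
  M <- vapply(basis, function(f) quad_simpson(f, -r, r), numeric(1))
  A <- rbind(M, vapply(basis, function(f) f(r), numeric(1)))
  b <- c(1 - quad_simpson(fixed, -r, r), -fixed(r))
  ab <- solve(A, b)
  expect_equal(sol$alpha0, ab[[1]], tolerance = 1e-8)
  expect_equal(sol$Q, ab[[2]], tolerance = 1e-8)
  # frozen regression values (computed from this oracle)
  expect_equal(sol$alpha0, 3.598962, tolerance = 1e-6)
  expect_equal(sol$Q, 2.128109, tolerance = 1e-6)
  expect_equal(sol$alpha_n, -1.109504, tolerance = 1e-6)
})

test_that("candidate profiles satisfy mass, continuity and the steady ODE", {
  sols <- draw_candidates(40)
  for (sol in sols) {
    expect_lt(steady_residual(sol), 1e-8)
    expect_lt(abs(candidate_mass(sol) - 1), 1e-10)
    expect_lt(abs(candidate_value(sol, sol$r)), 1e-10)
    expect_equal(candidate_value(sol, 1.5), 0)
    # symmetry and the value at the origin
    xs <- seq(0, sol$r, length.out = 50L)
    expect_equal(candidate_value(sol, xs), candidate_value(sol, -xs))
    expect_equal(candidate_value(sol, 0),
                 sol$alpha0 + 2 * sol$alpha_n + sol$Q)
  }
  # Laplace family analogue
  for (sol in draw_candidates(15, seed = 43L, family = "laplace"))
    expect_lt(steady_residual(sol), 1e-8)
})

test_that("the two branches join with continuous value and slope at 1/n", {
  pp <- params_default()
  sol <- build_candidate(pp, clump_env(4, 2), 0.4)   # r > 1/n
  edge <- 1 / 4
  expect_equal(candidate_value(sol, edge - 1e-12),
               candidate_value(sol, edge + 1e-12), tolerance = 1e-9)
  expect_equal(candidate_value(sol, edge - 1e-12, deriv = 1L),
               candidate_value(sol, edge + 1e-12, deriv = 1L), tolerance = 1e-6)
})

test_that("candidate frequency ties to r0 and perturbation breaks the ODE", {
  pp <- params_default(gamma = 3, sigma = 0.2)
  sol <- build_candidate(pp, clump_env(2, 1), 0.2)
  expect_equal(sol$w_hom, pi / r0_of(3, 0.2), tolerance = 1e-12)
  # +10% on alpha_n leaves a residual linear in the perturbation
  bad1 <- sol; bad1$alpha_n <- sol$alpha_n * 1.1
  bad2 <- sol; bad2$alpha_n <- sol$alpha_n * 1.2
  r1 <- steady_residual(bad1); r2 <- steady_residual(bad2)
  expect_gt(r1, 1e-3)
  expect_equal(r2 / r1, 2, tolerance = 0.05)
})

test_that("admissibility separates positive profiles from negative dips", {
  pp <- params_default()
  expect_true(is_admissible(homogeneous_minimiser(pp))$admissible)
  # past r0 the flat-landscape candidate dips negative at its interior trough
  sol <- build_candidate(pp, clump_env(1, 0), r0_of(2, 0.1) + 0.02)
  adm <- is_admissible(sol)
  expect_false(adm$admissible)
  expect_lt(adm$min_value, -1e-6)
})

test_that("build_candidate rejects bad regimes and singular systems", {
  expect_error(build_candidate(params_default(gamma = 0.5), clump_env(1, 1), 0.3),
               class = "aggdiffenv_regime_error")
  expect_error(build_candidate(params_default(), clump_env(1, 1), 1.5),
               class = "aggdiffenv_config_error")
})

test_that("the general family solves the steady ODE in both regimes", {
  # oscillatory (gamma > 1) and exponential (gamma < 1) homogeneous parts,
  # residual checked with finite differences (independent of the package's
  # analytic derivatives)
  env <- fourier_env(0.2, c(1, 0.4), c(0.3))
  for (fam in c("fourth_order", "laplace")) {
    for (gam in c(2.5, 0.5)) {
      pp <- if (fam == "fourth_order") model_params(gam, sigma = 0.15)
            else model_params(gam, m = 8, family = fam)
      f <- proposition_solution(pp, env, alpha0 = 0.7, P = 0.2, Q = 0.4)
      xs <- seq(-0.4, 0.4, length.out = 401L)
      h <- xs[2] - xs[1]
      u <- f(xs)
      d2u <- (u[1:399] - 2 * u[2:400] + u[3:401]) / h^2
      mid <- xs[2:400]
      A <- eval_environment(env, mid)
      lhs <- if (fam == "fourth_order") {
        (1 - gam) * u[2:400] - (gam * 0.15^2 / 2) * d2u - A
      } else {
        d2A <- (eval_environment(env, mid - h) - 2 * A +
                  eval_environment(env, mid + h)) / h^2
        (1 - gam) * u[2:400] - d2u / 64 - A + d2A / 64
      }
      expect_lt(diff(range(lhs)), 1e-4 * max(1, diff(range(u))))
    }
  }
})
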