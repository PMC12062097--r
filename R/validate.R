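#' Run the package's invariant checks
#'
#' Executes desk-scale versions of the analytic invariants (landscape
#' symmetry and smoothness, kernel normalisation and identities, candidate
#' fidelity to the steady-state ODE, energy closed-form/quadrature
#' agreement, minimiser optimality) and, optionally, scaled-down solver
#' contract checks (mass conservation, positivity, energy dissipation).
#' Failures are report rows, not errors.
#'
#' @param pde Include the scaled-down PDE checks (slower).
#' @param seed Seed for the randomised parameter draws.
#' @return Data frame of class \code{aggdiff_validation} with columns
#'   \code{check}, \code{tolerance}, \code{measured}, \code{pass}.
#' @export
validate_all <- function(pde = FALSE, seed = 1L) {
  set.seed(seed)
  rows <- list()
  add <- function(check, tolerance, measured)
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, tolerance = tolerance, measured = measured,
      pass = is.finite(measured) && measured <= tolerance)

  xg <- seq(-1, 1, length.out = 1001L)
  env4 <- clump_env(4, 1)
  add("landscape evenness", 1e-14,
      max(abs(eval_environment(env4, xg) - eval_environment(env4, -xg))))
  h <- 1e-6
  fd <- (eval_environment(env4, 0.25 + h) - eval_environment(env4, 0.25 - h)) / (2 * h)
  add("landscape C1 join", 1e-4,
      abs(fd - environment_gradient(env4, 0.25)))
  fe <- make_fourier(env4, 64)
  add("fourier round-trip", 1e-3,
      max(abs(eval_environment(fe, xg) - eval_environment(env4, xg))))

  dx <- 0.005
  for (kn in list(laplace_kernel(10), tophat_kernel(0.1))) {
    w <- kernel_weights(kn, dx)
    add(paste0("kernel mass (", class(kn)[1], ")"), 1e-12, abs(sum(w) - 1))
  }
  # Green's-function identity of the Laplace kernel on a smooth bump
  g <- make_grid(dx)
  u <- exp(-((g$x) / 0.15)^2)
  ku <- convolve_kernel(laplace_kernel(10), u, dx)
  lhs <- second_diff(ku, dx) - 100 * ku
  core <- abs(g$x) < 0.6
  add("laplace kernel identity", 0.05,
      max(abs(lhs[core] + 100 * u[core])) / max(100 * u))

  p4 <- model_params(gamma = 2, sigma = 0.1, p = 1)
  add("frequency identity", 1e-12,
      abs(intrinsic_freq(p4) - pi / r0_of(2, 0.1)))
  worst_res <- 0; worst_mass <- 0; worst_edge <- 0; worst_e <- 0
  for (i in 1:20) {
    gam <- stats::runif(1, 1.2, 5); sig <- stats::runif(1, 0.05, 0.3)
    nn <- sample(1:16, 1); amp <- stats::runif(1, 0, 10)
    pp <- model_params(gamma = gam, sigma = sig, p = 1)
    ok <- tryCatch({
      r <- stats::runif(1, 0.3, 1) * min(1, 1 / nn)
      sol <- build_candidate(pp, clump_env(nn, amp), r)
      worst_res <- max(worst_res, steady_residual(sol))
      worst_mass <- max(worst_mass, abs(candidate_mass(sol) - 1))
      worst_edge <- max(worst_edge, abs(candidate_value(sol, r)))
      worst_e <- max(worst_e, abs(energy_E2_closed(sol) - energy_E2_quadrature(sol)))
      TRUE
    }, aggdiffenv_error = function(e) FALSE)
  }
  add("candidate ODE residual", 1e-8, worst_res)
  add("candidate mass", 1e-10, worst_mass)
  add("candidate continuity at r", 1e-10, worst_edge)
  add("energy closed vs quadrature", 1e-6, worst_e)

  fit <- minimise_energy(p4, clump_env(1, 0))
  add("homogeneous recovery r*", 1e-6, abs(fit$r - r0_of(2, 0.1)))
  fit1 <- minimise_energy(p4, clump_env(1, 1))
  eps <- 1e-3
  nearby <- vapply(c(-eps, eps), function(d)
    energy_at_r(p4, clump_env(1, 1), fit1$r + d)$energy, numeric(1))
  add("minimiser optimality certificate", 1e-9,
      max(fit1$energy - nearby, 0))

  if (pde) {
    grid <- make_grid(0.02)
    u0 <- make_initial_condition("flat_min", grid, gamma = 2, sigma = 0.1)
    cfg <- solver_config("quadratic_local4", gamma = 2, sigma = 0.1,
                         env = clump_env(1, 1), dt = 5e-7,
                         max_time = 2e-3, record_every = 1L)
    sim <- step_solution(u0, grid, cfg, n_steps = 4000L)
    add("pde mass conservation", 1e-12, sim$max_mass_err)
    add("pde positivity", 1e-12, -min(sim$min_u, 0))
    add("pde energy dissipation", 1e-10, max(sim$max_energy_increase, 0))
  }

  out <- do.call(rbind, rows)
  class(out) <- c("aggdiff_validation", "data.frame")
  out
}
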