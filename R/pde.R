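#' Uniform cell-centred grid on [-1, 1]
#'
#' @param dx Cell width; \eqn{2/dx} must be an integer number of cells
#'   (default 0.01, the resolution used throughout the numerical
#'   experiments).
#' @return List with \code{x} (cell midpoints), \code{dx}, \code{n}.
#' @export
make_grid <- function(dx = 0.01) {
  stopifnot_scalar(dx, "dx", positive = TRUE)
  ncell <- 2 / dx
  if (abs(ncell - round(ncell)) > 1e-9)
    abort_config("(x_max - x_min)/dx must be an integer number of cells")
  ncell <- as.integer(round(ncell))
  if (ncell < 8L) abort_config("grid too coarse: need at least 8 cells")
  list(x = -1 + (seq_len(ncell) - 0.5) * dx, dx = dx, n = ncell)
}

#' Total mass of a gridded density
#'
#' Midpoint-rule mass \eqn{\sum_i u_i \Delta x} -- the exact invariant of the
#' conservative finite-volume scheme.
#'
#' @param u Density values on the cell midpoints.
#' @param dx Cell width.
#' @return The mass.
#' @export
total_mass <- function(u, dx) sum(u) * dx

#' Non-dimensionalisation of the model
#'
#' Maps dimensional inputs onto the unit half-period domain:
#' \eqn{\tilde x = x/L}, \eqn{\tilde\sigma = \sigma/L},
#' \eqn{\tilde\gamma = \gamma/D}, \eqn{\tilde a_n = L a_n / D},
#' \eqn{\tilde b_n = L b_n / D}, \eqn{\tilde t = t D / L^3},
#' \eqn{\tilde u = L u}, \eqn{\tilde m = m L}. `dimensionalise()` inverts the
#' map exactly.
#'
#' @param D Diffusion constant (\eqn{> 0}).
#' @param L Half-period of the landscape (\eqn{> 0}).
#' @param gamma,sigma,m,a,b,u,t Dimensional advection strength, kernel
#'   standard deviation, Laplace rate, landscape cosine/sine coefficients,
#'   density and time; any may be `NULL` to skip.
#' @return Named list of dimensionless quantities (with `D` and `L`
#'   retained for inversion).
#' @export
nondimensionalise <- function(D, L, gamma = NULL, sigma = NULL, m = NULL,
                              a = NULL, b = NULL, u = NULL, t = NULL) {
  stopifnot_scalar(D, "D", positive = TRUE)
  stopifnot_scalar(L, "L", positive = TRUE)
  sc <- function(z, f) if (is.null(z)) NULL else z * f
  list(D = D, L = L,
       gamma = sc(gamma, 1 / D), sigma = sc(sigma, 1 / L), m = sc(m, L),
       a = sc(a, L / D), b = sc(b, L / D), u = sc(u, L), t = sc(t, D / L^3))
}

#' @rdname nondimensionalise
#' @param q A list as returned by [nondimensionalise()].
#' @export
dimensionalise <- function(q) {
  D <- q$D; L <- q$L
  sc <- function(z, f) if (is.null(z)) NULL else z * f
  list(D = D, L = L,
       gamma = sc(q$gamma, D), sigma = sc(q$sigma, L), m = sc(q$m, 1 / L),
       a = sc(q$a, D / L), b = sc(q$b, D / L), u = sc(q$u, 1 / L),
       t = sc(q$t, L^3 / D))
}

#' Named initial-condition fixtures
#'
#' \describe{
#'   \item{\code{"flat_min"}}{the flat-landscape minimum-energy profile
#'     \eqn{(p/2r_0)[1+\cos(\pi x/r_0)]} on \eqn{|x| < r_0} (needs
#'     \code{gamma}, \code{sigma});}
#'   \item{\code{"gaussian"}}{a Gaussian bump offset from the origin (default
#'     mean 0.5, sd 0.05);}
#'   \item{\code{"cos4"}}{\eqn{1 - \cos(4\pi x)} on \eqn{|x| < 0.5}: two
#'     equal bumps either side of the origin;}
#'   \item{\code{"cos6"}}{\eqn{1 + \cos(6\pi x)} on \eqn{|x| < 0.5}: three
#'     local maxima at \eqn{x = 0, \pm 1/3}.}
#' }
#' All fixtures are normalised to total mass `p`.
#'
#' @param kind One of \code{"flat_min"}, \code{"gaussian"}, \code{"cos4"},
#'   \code{"cos6"}.
#' @param grid A [make_grid()] object.
#' @param p Total mass.
#' @param gamma,sigma Parameters of the \code{"flat_min"} profile.
#' @param mean,sd Parameters of the \code{"gaussian"} profile.
#' @return Density vector on the grid midpoints with mass `p`.
#' @export
make_initial_condition <- function(kind = c("flat_min", "gaussian", "cos4", "cos6"),
                                   grid, p = 1, gamma = NULL, sigma = NULL,
                                   mean = 0.5, sd = 0.05) {
  kind <- match.arg(kind)
  x <- grid$x
  u <- switch(kind,
    flat_min = {
      if (is.null(gamma) || is.null(sigma))
        abort_config("'flat_min' initial condition needs gamma and sigma")
      r0 <- r0_of(gamma, sigma)
      if (r0 >= 1) abort_config("flat_min profile does not fit inside [-1, 1]")
      ifelse(abs(x) < r0, (p / (2 * r0)) * (1 + cos(pi * x / r0)), 0)
    },
    gaussian = stats::dnorm(x, mean = mean, sd = sd),
    cos4 = ifelse(abs(x) < 0.5, 1 - cos(4 * pi * x), 0),
    cos6 = ifelse(abs(x) < 0.5, 1 + cos(6 * pi * x), 0))
  u * p / total_mass(u, grid$dx)
}

#' Solver configuration
#'
#' @param scheme \code{"quadratic_nonlocal"} (nonlocal advection, quadratic
#'   diffusion), \code{"quadratic_local4"} (fourth-order local approximation,
#'   quadratic diffusion) or \code{"linear_nonlocal"} (nonlocal advection,
#'   linear diffusion).
#' @param dt Time step. Defaults mirror the numerical experiments:
#'   \code{5e-6} for the quadratic schemes and \code{1e-5} for the linear
#'   one. The fourth-order scheme is explicit, so it typically needs
#'   \code{dt} of order \eqn{\Delta x^4/(4\gamma\sigma^2 \max u)}; see
#'   [check_stability()].
#' @param tol Steady-state threshold on the per-step sup-norm change
#'   (default 1e-8).
#' @param max_time Simulated-time cap.
#' @param gamma,sigma Model parameters (\code{sigma} used by
#'   \code{quadratic_local4} only).
#' @param kernel Kernel object for the nonlocal schemes.
#' @param env Landscape object (default: flat).
#' @param record_every Record the energy series every this many steps.
#' @return A \code{aggdiff_solver_config} list.
#' @export
solver_config <- function(scheme = c("quadratic_local4", "quadratic_nonlocal",
                                     "linear_nonlocal"),
                          gamma, sigma = NULL, kernel = NULL, env = NULL,
                          dt = NULL, tol = 1e-8, max_time = 10,
                          record_every = 1000L) {
  scheme <- match.arg(scheme)
  stopifnot_scalar(gamma, "gamma", positive = TRUE)
  stopifnot_scalar(tol, "tol", positive = TRUE)
  stopifnot_scalar(max_time, "max_time", positive = TRUE)
  if (is.null(dt)) dt <- if (scheme == "linear_nonlocal") 1e-5 else 5e-6
  stopifnot_scalar(dt, "dt", positive = TRUE)
  if (scheme == "quadratic_local4") {
    if (is.null(sigma)) abort_config("quadratic_local4 requires 'sigma'")
    stopifnot_scalar(sigma, "sigma", positive = TRUE)
  } else {
    if (is.null(kernel) || !inherits(kernel, "aggdiff_kernel"))
      abort_config("nonlocal schemes require a kernel object")
  }
  structure(list(scheme = scheme, gamma = gamma, sigma = sigma,
                 kernel = kernel, env = env, dt = dt, tol = tol,
                 max_time = max_time, record_every = as.integer(record_every)),
            class = "aggdiff_solver_config")
}

scheme_id <- function(scheme)
  switch(scheme, quadratic_nonlocal = 1L, quadratic_local4 = 2L,
         linear_nonlocal = 3L)

#' Explicit-step stability estimate
#'
#' Warns when the configured time step exceeds an explicit-scheme stability
#' estimate for the given state: advective CFL
#' \eqn{\Delta t \le 0.4 \Delta x^2 / \max|\xi'|\cdot\ldots} combined, for
#' the fourth-order scheme, with the biharmonic bound
#' \eqn{\Delta t \le \Delta x^4 / (4 \gamma\sigma^2 \max u)}. The bound is
#' heuristic -- the run itself still detects blow-up and raises an
#' instability error.
#'
#' @param u Initial density on the grid.
#' @param grid A [make_grid()] object.
#' @param config A [solver_config()].
#' @return The estimated maximum stable `dt`, invisibly; warns if
#'   `config$dt` exceeds it.
#' @export
check_stability <- function(u, grid, config) {
  dx <- grid$dx
  xi <- drift_potential(u, grid, config)
  vmax <- max(abs(diff(xi)) / dx, 1e-12)
  # quadratic mobility behaves like nonlinear diffusion with coefficient ~ u
  dt_est <- 0.4 * dx^2 / (max(u) + vmax * dx)
  if (config$scheme == "quadratic_local4") {
    dt_bih <- dx^4 / (4 * config$gamma * config$sigma^2 * max(max(u), 1e-12))
    dt_est <- min(dt_est, dt_bih)
  }
  if (config$dt > dt_est)
    warning(sprintf("dt = %.3g exceeds stability estimate %.3g; expect instability",
                    config$dt, dt_est), call. = FALSE)
  invisible(dt_est)
}

# the quantity whose gradient drives the motion (xi for quadratic schemes,
# the potential V for the linear one)
drift_potential <- function(u, grid, config) {
  A <- if (is.null(config$env)) numeric(grid$n) else eval_environment(config$env, grid$x)
  if (config$scheme == "quadratic_nonlocal") {
    u - config$gamma * convolve_kernel(config$kernel, u, grid$dx) - A
  } else if (config$scheme == "quadratic_local4") {
    (1 - config$gamma) * u -
      (config$gamma * config$sigma^2 / 2) * second_diff(u, grid$dx) - A
  } else {
    config$gamma * convolve_kernel(config$kernel, u, grid$dx) + A
  }
}

run_solver <- function(u, grid, config, max_time, tol) {
  A <- if (is.null(config$env)) numeric(grid$n) else eval_environment(config$env, grid$x)
  kw <- if (is.null(config$kernel)) 1.0 else kernel_weights(config$kernel, grid$dx)
  res <- fv_run_cpp(u, grid$dx, config$dt, max_time, tol,
                    scheme_id(config$scheme), config$gamma,
                    if (is.null(config$sigma)) 0 else config$sigma,
                    A, kw, total_mass(u, grid$dx), config$record_every)
  if (res$error_code == 1L)
    abort_instability("solver produced non-finite values; reduce dt")
  if (res$error_code == 2L)
    abort_instability("negative-density clipping exceeded 1e-8 of the total mass; reduce dt")
  res
}

#' Advance the solution by explicit steps
#'
#' Takes exactly `n_steps` conservative finite-volume steps (no convergence
#' test). Mass is conserved to round-off; the quadratic schemes preserve
#' positivity by upwinding.
#'
#' @param u Density on the grid midpoints.
#' @param grid A [make_grid()] object.
#' @param config A [solver_config()].
#' @param n_steps Number of steps to take.
#' @return A \code{aggdiff_sim} list: \code{u}, \code{t}, \code{steps},
#'   \code{converged}, diagnostics (\code{max_mass_err}, \code{min_u},
#'   \code{max_energy_increase}, \code{clipped_mass}) and the recorded
#'   \code{energy}/\code{energy_t} series.
#' @export
step_solution <- function(u, grid, config, n_steps = 1L) {
  res <- run_solver(u, grid, config, max_time = n_steps * config$dt, tol = -1)
  structure(res, class = "aggdiff_sim")
}

#' Run a model to its numerical steady state
#'
#' Iterates the explicit scheme until the per-step sup-norm change drops
#' below `config$tol` (the convergence rule
#' \eqn{|u(x, t+\Delta t) - u(x, t)| < 10^{-8}} for all \eqn{x}) or
#' `config$max_time` is reached, in which case the returned state is flagged
#' not-converged. Records the mass drift, the running minimum of the
#' density, and the discrete energy series, whose largest per-step increase
#' is reported for dissipation auditing.
#'
#' @inheritParams step_solution
#' @return A \code{aggdiff_sim} list (see [step_solution()]).
#' @export
run_to_steady <- function(u, grid, config) {
  res <- run_solver(u, grid, config, max_time = config$max_time, tol = config$tol)
  structure(res, class = "aggdiff_sim")
}
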