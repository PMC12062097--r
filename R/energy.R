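# Closed-form building blocks ------------------------------------------------

# int_{-s}^{s} cos(w x) dx
int_cos <- function(w, s) if (abs(w) < 1e-14) 2 * s else 2 * sin(w * s) / w

# int_{-s}^{s} cos(wa x) cos(wb x) dx
int_coscos <- function(wa, wb, s) {
  if (abs(wa - wb) < 1e-12 * max(abs(wa), abs(wb), 1)) {
    s + sin(2 * wa * s) / (2 * wa)
  } else {
    sin((wa - wb) * s) / (wa - wb) + sin((wa + wb) * s) / (wa + wb)
  }
}

# composite Simpson for already-evaluated values on an odd-length uniform grid
simpson_sum <- function(y, h) {
  n <- length(y)
  stopifnot(n %% 2L == 1L)
  idx <- seq_len(n)
  w <- rep(2, n); w[idx %% 2L == 0L] <- 4; w[c(1L, n)] <- 1
  h / 3 * sum(w * y)
}

# Simpson integral of f over [a, b] with n (even) intervals
simpson_fun <- function(f, a, b, n = 1024L) {
  if (b <= a) return(0)
  xs <- seq(a, b, length.out = n + 1L)
  simpson_sum(f(xs), (b - a) / n)
}

check_gridded <- function(u, dx, check_boundary = TRUE) {
  if (!is.numeric(u) || length(u) < 5L) abort_config("'u' must be a numeric grid vector")
  stopifnot_scalar(dx, "dx", positive = TRUE)
  if (check_boundary) {
    top <- max(abs(u))
    if (top > 0 && max(abs(u[1L]), abs(u[length(u)])) > 1e-3 * top)
      abort_boundary("density carries non-negligible mass at the grid edge")
  }
  invisible(u)
}

# centered second difference with one-sided closures at the ends
second_diff <- function(u, dx) {
  n <- length(u)
  d2 <- numeric(n)
  d2[2:(n - 1)] <- (u[1:(n - 2)] - 2 * u[2:(n - 1)] + u[3:n]) / dx^2
  d2[1] <- (2 * u[1] - 5 * u[2] + 4 * u[3] - u[4]) / dx^2
  d2[n] <- (2 * u[n] - 5 * u[n - 1] + 4 * u[n - 2] - u[n - 3]) / dx^2
  d2
}

# Energy functionals ----------------------------------------------------------

#' Energy of the fourth-order model by quadrature
#'
#' The Lyapunov functional of the fourth-order (Cahn--Hilliard-type) model,
#' \deqn{E_2[u] = \int u [(1-\gamma)u - 2A - (\gamma\sigma^2/2) u''] dx,}
#' which is non-increasing along non-negative solutions and stationary at
#' steady states. For a gridded density the second derivative is taken by
#' centered differences (one-sided at the ends) and the integral by the
#' midpoint rule on the cells; for a candidate profile the exact piecewise
#' cosine derivatives are used with composite Simpson split at the clump
#' edge, so no differencing error enters.
#'
#' @param u Either a numeric density on a uniform grid, or an
#'   \code{aggdiff_candidate}.
#' @param env Landscape object (ignored for candidates, which carry their
#'   own).
#' @param gamma,sigma Model parameters (ignored for candidates).
#' @param x Grid coordinates (gridded case).
#' @param dx Grid spacing (gridded case).
#' @param check_boundary Raise a boundary-leak error when the density does
#'   not vanish at the grid edge (default `TRUE`).
#' @return The energy value.
#' @export
energy_E2_quadrature <- function(u, env = NULL, gamma = NULL, sigma = NULL,
                                 x = NULL, dx = NULL, check_boundary = TRUE) {
  if (inherits(u, "aggdiff_candidate")) {
    sol <- u
    params <- sol$params
    g <- params$gamma; sg <- params$sigma
    w1 <- sol$w_env; w2 <- sol$w_hom
    a_n <- sol$env$amplitude
    # per-piece integrands with one-sided second derivatives at the clump
    # edge, where u'' (and A'') jump
    inner <- function(z) {
      uu <- sol$alpha0 + sol$alpha_n * (1 + cos(w1 * z)) + sol$Q * cos(w2 * z)
      u2 <- -sol$alpha_n * w1^2 * cos(w1 * z) - sol$Q * w2^2 * cos(w2 * z)
      A <- a_n * (1 + cos(w1 * z))
      uu * ((1 - g) * uu - 2 * A - (g * sg^2 / 2) * u2)
    }
    outer <- function(z) {
      uu <- sol$alpha0 + sol$Q * cos(w2 * z)
      u2 <- -sol$Q * w2^2 * cos(w2 * z)
      uu * ((1 - g) * uu - (g * sg^2 / 2) * u2)
    }
    s1 <- min(sol$r, 1 / sol$env$n)
    e <- simpson_fun(inner, -s1, s1)
    if (sol$r > s1)
      e <- e + simpson_fun(outer, -sol$r, -s1) + simpson_fun(outer, s1, sol$r)
    return(e)
  }
  check_gridded(u, dx, check_boundary)
  A <- eval_environment(env, x)
  d2 <- second_diff(u, dx)
  sum(u * ((1 - gamma) * u - 2 * A - (gamma * sigma^2 / 2) * d2)) * dx
}

#' Energy of the nonlocal model by quadrature
#'
#' The Lyapunov functional of the nonlocal quadratic-diffusion model,
#' \deqn{E_1[u] = \int u [u - 2A - \gamma K*u] dx,}
#' with the convolution evaluated by [convolve_kernel()]. This is the form
#' whose time derivative along solutions is
#' \eqn{-2\int u (\partial_x[u - A - \gamma K*u])^2 dx \le 0}; see the
#' package vignette for the derivation.
#'
#' @inheritParams energy_E2_quadrature
#' @param kernel A kernel object from [laplace_kernel()] or
#'   [tophat_kernel()].
#' @return The energy value.
#' @export
energy_E1_quadrature <- function(u, env, gamma, kernel, x, dx,
                                 check_boundary = TRUE) {
  check_gridded(u, dx, check_boundary)
  A <- eval_environment(env, x)
  Ku <- convolve_kernel(kernel, u, dx)
  sum(u * (u - 2 * A - gamma * Ku)) * dx
}

#' Closed-form energy of a single-aggregation candidate (fourth-order)
#'
#' On the candidate family the fourth-order energy collapses, via the
#' per-piece steady-state ODE, to
#' \deqn{E_2 = \int_{-s}^{s} u_* [(1-\gamma)(\alpha_0+\alpha_n) - 2a_n
#'   - a_n \cos(n\pi x)] dx \;(+\; 2(1-\gamma)\alpha_0 \int_{1/n}^{r} u_* dx
#'   \text{ when } r > 1/n),}
#' with \eqn{s = \min(r, 1/n)}; all trigonometric integrals are done in
#' closed form. Agrees with [energy_E2_quadrature()] on the same profile to
#' round-off.
#'
#' @param sol An \code{aggdiff_candidate} (fourth-order family).
#' @return The energy value.
#' @export
energy_E2_closed <- function(sol) {
  if (sol$params$family != "fourth_order")
    abort_config("energy_E2_closed applies to fourth-order candidates")
  g <- sol$params$gamma
  a_n <- sol$env$amplitude
  n <- sol$env$n
  w1 <- sol$w_env; w2 <- sol$w_hom
  c0 <- sol$alpha0 + sol$alpha_n; c1 <- sol$alpha_n; c2 <- sol$Q
  B <- (1 - g) * (sol$alpha0 + sol$alpha_n) - 2 * a_n
  s <- min(sol$r, 1 / n)
  # int_{-s}^{s} (c0 + c1 cos w1 x + c2 cos w2 x)(B - a_n cos w1 x) dx
  e <- B * (2 * s * c0 + c1 * int_cos(w1, s) + c2 * int_cos(w2, s)) -
    a_n * (c0 * int_cos(w1, s) + c1 * int_coscos(w1, w1, s) +
             c2 * int_coscos(w1, w2, s))
  if (sol$r > s) {
    tail_mass <- sol$alpha0 * (sol$r - s) + c2 * (sin(w2 * sol$r) - sin(w2 * s)) / w2
    e <- e + 2 * (1 - g) * sol$alpha0 * tail_mass
  }
  e
}

# Laplace-kernel convolution of a candidate, semi-analytically ----------------

# int_a^b e^{-m|x-y|} cos(w y) dy, vectorised over x; all exponents kept
# non-positive so large m cannot overflow.
laplace_seg_int <- function(m, w, a, b, x) {
  den <- m^2 + w^2
  gp <- function(y) m * cos(w * y) + w * sin(w * y)   # antiderivative pieces
  gm <- function(y) -m * cos(w * y) + w * sin(w * y)
  out <- numeric(length(x))
  right <- x >= b
  left <- x <= a
  mid <- !right & !left
  if (any(right)) {
    xr <- x[right]
    out[right] <- (exp(-m * (xr - b)) * gp(b) - exp(-m * (xr - a)) * gp(a)) / den
  }
  if (any(left)) {
    xl <- x[left]
    out[left] <- (exp(-m * (b - xl)) * gm(b) - exp(-m * (a - xl)) * gm(a)) / den
  }
  if (any(mid)) {
    xm <- x[mid]
    out[mid] <- (2 * m * cos(w * xm) -
                   exp(-m * (xm - a)) * gp(a) +
                   exp(-m * (b - xm)) * gm(b)) / den
  }
  out
}

#' Laplace-kernel convolution of a candidate profile
#'
#' \eqn{(K_m * u_*)(x)} with the exponential-against-cosine integrals done in
#' closed form on each piece of the support; matches the direct grid
#' convolution oracle to high accuracy.
#'
#' @param sol An \code{aggdiff_candidate} of the Laplace family.
#' @param x Evaluation points.
#' @return Numeric vector.
#' @export
laplace_convolution <- function(sol, x) {
  m <- sol$params$m
  r <- sol$r
  s1 <- min(r, 1 / sol$env$n)
  out <- sol$alpha0 * laplace_seg_int(m, 0, -r, r, x) +
    sol$Q * laplace_seg_int(m, sol$w_hom, -r, r, x)
  if (sol$alpha_n != 0)
    out <- out + sol$alpha_n * (laplace_seg_int(m, 0, -s1, s1, x) +
                                  laplace_seg_int(m, sol$w_env, -s1, s1, x))
  out * m / 2
}

#' Semi-analytic energy of a Laplace-family candidate
#'
#' \eqn{E_1} on a candidate profile: the convolution term is evaluated via
#' [laplace_convolution()] (closed-form exponential integrals) and the outer
#' integral by composite Simpson split at the clump edge.
#'
#' @param sol An \code{aggdiff_candidate} of the Laplace family.
#' @param n_grid Simpson intervals per smooth piece.
#' @return The energy value.
#' @export
energy_E1_closed <- function(sol, n_grid = 512L) {
  if (sol$params$family != "laplace")
    abort_config("energy_E1_closed applies to Laplace-family candidates")
  g <- sol$params$gamma
  integrand <- function(z) {
    uu <- candidate_value(sol, z)
    uu * (uu - 2 * eval_environment(sol$env, pmin(1, pmax(-1, z))) -
            g * laplace_convolution(sol, z))
  }
  s1 <- min(sol$r, 1 / sol$env$n)
  e <- simpson_fun(integrand, -s1, s1, n_grid)
  if (sol$r > s1)
    e <- e + simpson_fun(integrand, -sol$r, -s1, n_grid) +
      simpson_fun(integrand, s1, sol$r, n_grid)
  e
}

candidate_energy <- function(sol) {
  if (sol$params$family == "fourth_order") energy_E2_closed(sol)
  else energy_E1_closed(sol)
}

# Minimisation ----------------------------------------------------------------

# energy at half-width r, +Inf when no admissible candidate exists there
energy_at_r <- function(params, env, r, n_grid_adm = 2048L) {
  sol <- tryCatch(build_candidate(params, env, r),
                  aggdiffenv_error = function(e) NULL)
  if (is.null(sol)) return(list(energy = Inf, sol = NULL))
  adm <- is_admissible(sol, n_grid = n_grid_adm)
  if (!adm$admissible) return(list(energy = Inf, sol = sol))
  list(energy = candidate_energy(sol), sol = sol)
}

#' Minimum-energy single-aggregation solution
#'
#' Scans the aggregation half-width \eqn{r} over a uniform grid on
#' \eqn{(0, 1]}, discards half-widths with no admissible candidate (negative
#' densities or a singular constraint system), then refines around the best
#' grid point by golden-section search to \eqn{|\Delta r| < 10^{-6}}.
#' Deterministic. The energy is [energy_E2_closed()] for the fourth-order
#' family and [energy_E1_closed()] for the Laplace family.
#'
#' @param params A [model_params()] object with \eqn{\gamma > 1}.
#' @param env A [clump_env()] landscape.
#' @param r_steps Number of scan points (default 1000).
#' @return List with \code{r} (minimising half-width), \code{sol} (the
#'   candidate), \code{energy}, and \code{scan} (data frame of admissible
#'   grid energies).
#' @export
minimise_energy <- function(params, env, r_steps = 1000L) {
  if (params$gamma <= 1) abort_regime("energy minimisation requires gamma > 1")
  rs <- seq_len(r_steps) / r_steps
  es <- vapply(rs, function(r) energy_at_r(params, env, r)$energy, numeric(1))
  ok <- is.finite(es)
  if (!any(ok)) abort_minimiser("no admissible single-aggregation candidate at any half-width")
  k <- which.min(es)
  lo <- if (k > 1L) rs[k - 1L] else rs[k] / 2
  hi <- if (k < r_steps) rs[k + 1L] else 1
  f <- function(r) energy_at_r(params, env, r, n_grid_adm = 4096L)$energy
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  # strict comparison: when the energy is flat to round-off (e.g. near an
  # admissibility edge that is also the minimum) ties shrink from the left,
  # so the search settles at the upper admissible end rather than drifting
  while ((b - a) > 1e-8) {
    if (f1 < f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
  }
  r_star <- if (f1 < f2) x1 else x2
  best <- energy_at_r(params, env, r_star, n_grid_adm = 4096L)
  if (!is.finite(best$energy)) { # golden endpoint fell off the admissible set
    r_star <- rs[k]
    best <- energy_at_r(params, env, r_star, n_grid_adm = 4096L)
  }
  list(r = r_star, sol = best$sol, energy = best$energy,
       scan = data.frame(r = rs[ok], energy = es[ok]))
}

#' Energy as a function of the half-width
#'
#' Evaluates the candidate energy at each admissible half-width in `r_grid`;
#' inadmissible half-widths are absent from the result (the admissible range
#' typically stops short of both 0 and \eqn{r_0}).
#'
#' @param params A [model_params()] object with \eqn{\gamma > 1}.
#' @param env A [clump_env()] landscape.
#' @param r_grid Half-widths to evaluate.
#' @return A data frame of class \code{aggdiff_energy_curve} with columns
#'   \code{r}, \code{energy}; attributes \code{argmin_r} and
#'   \code{minimum_energy} (both `NA` when the curve is empty).
#' @export
energy_curve <- function(params, env, r_grid) {
  if (params$gamma <= 1) abort_regime("energy curves require gamma > 1")
  es <- vapply(r_grid, function(r) energy_at_r(params, env, r)$energy, numeric(1))
  ok <- is.finite(es)
  out <- data.frame(r = r_grid[ok], energy = es[ok])
  class(out) <- c("aggdiff_energy_curve", "data.frame")
  attr(out, "argmin_r") <- if (any(ok)) out$r[which.min(out$energy)] else NA_real_
  attr(out, "minimum_energy") <- if (any(ok)) min(out$energy) else NA_real_
  out
}
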