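#' Model parameters
#'
#' Bundles the dimensionless parameters of the two analytically tractable
#' quadratic-diffusion models:
#'
#' \describe{
#'   \item{\code{fourth_order}}{the local Cahn--Hilliard-type approximation,
#'     which needs the kernel standard deviation \code{sigma};}
#'   \item{\code{laplace}}{the nonlocal model with Laplace kernel, which needs
#'     the decay rate \code{m}.}
#' }
#'
#' \code{gamma} is the self-attraction strength relative to diffusion
#' (\eqn{\gamma = 1} is the Turing threshold for spontaneous aggregation) and
#' \code{p} the conserved total mass.
#'
#' @param gamma Self-attraction strength \eqn{\gamma > 0}.
#' @param sigma Kernel standard deviation \eqn{\sigma > 0} (fourth-order
#'   family).
#' @param m Laplace kernel rate \eqn{m > 0} (Laplace family).
#' @param p Total mass \eqn{p > 0}.
#' @param family \code{"fourth_order"} or \code{"laplace"}.
#' @return An object of class \code{aggdiff_params}.
#' @export
model_params <- function(gamma, sigma = NULL, m = NULL, p = 1,
                         family = c("fourth_order", "laplace")) {
  family <- match.arg(family)
  stopifnot_scalar(gamma, "gamma", positive = TRUE)
  stopifnot_scalar(p, "p", positive = TRUE)
  if (family == "fourth_order") {
    if (is.null(sigma)) abort_config("fourth_order family requires 'sigma'")
    stopifnot_scalar(sigma, "sigma", positive = TRUE)
  } else {
    if (is.null(m)) abort_config("laplace family requires 'm'")
    stopifnot_scalar(m, "m", positive = TRUE)
  }
  structure(list(gamma = gamma, sigma = sigma, m = m, p = p, family = family),
            class = "aggdiff_params")
}

#' Homogeneous-landscape minimiser half-width
#'
#' The half-width \eqn{r_0 = \pi \sqrt{\gamma\sigma^2 / (2(\gamma - 1))}} of
#' the minimum-energy aggregation of the fourth-order model on a flat
#' landscape. Requires \eqn{\gamma > 1} (above the Turing threshold); the
#' half-width diverges as \eqn{\gamma \to 1^+} and tends to
#' \eqn{\pi\sigma/\sqrt{2}} as \eqn{\gamma \to \infty}.
#'
#' @param gamma Self-attraction strength, \eqn{\gamma > 1}.
#' @param sigma Kernel standard deviation, \eqn{\sigma > 0}.
#' @return The half-width \eqn{r_0 > 0}.
#' @export
r0_of <- function(gamma, sigma) {
  stopifnot_scalar(gamma, "gamma", positive = TRUE)
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  if (gamma <= 1)
    abort_regime("r0 requires gamma > 1 (above the Turing threshold)")
  pi * sqrt(gamma * sigma^2 / (2 * (gamma - 1)))
}

# Intrinsic frequency of the oscillatory homogeneous solution component
# (gamma > 1): fourth-order sqrt(2(gamma-1)/(gamma sigma^2)) = pi/r0;
# Laplace m*sqrt(gamma-1).
intrinsic_freq <- function(params) {
  g <- params$gamma
  if (g <= 1)
    abort_regime("oscillatory homogeneous component requires gamma > 1")
  if (params$family == "fourth_order")
    sqrt(2 * (g - 1) / (g * params$sigma^2))
  else
    params$m * sqrt(g - 1)
}

# Decay rate of the exponential homogeneous component (gamma < 1).
intrinsic_decay <- function(params) {
  g <- params$gamma
  if (g >= 1) abort_regime("exponential homogeneous component requires gamma < 1")
  if (params$family == "fourth_order")
    sqrt(2 * (1 - g) / (g * params$sigma^2))
  else
    params$m * sqrt(1 - g)
}

#' Particular-solution mode factor
#'
#' The factor multiplying the landscape's mode-\eqn{n} Fourier coefficient in
#' the particular part of the steady state:
#' \eqn{2 / (2(1-\gamma) + \gamma\sigma^2 n^2\pi^2)} for the fourth-order
#' family, \eqn{(n^2\pi^2 + m^2) / (n^2\pi^2 + m^2(1-\gamma))} for the
#' Laplace family. With no self-attraction (\eqn{\gamma = 0}) the factor is 1
#' and the density simply tracks the landscape.
#'
#' At resonance -- when the landscape mode frequency \eqn{n\pi} matches the
#' intrinsic frequency of the homogeneous component -- the denominator
#' vanishes and the printed solution family degenerates; an error of class
#' \code{aggdiffenv_resonance_error} is raised rather than returning a
#' secular solution.
#'
#' @param params An [model_params()] object.
#' @param n Mode index (positive integer).
#' @return The scalar multiplier.
#' @export
mode_factor <- function(params, n) {
  stopifnot_scalar(n, "n", positive = TRUE)
  if (params$family == "fourth_order") {
    den <- 2 * (1 - params$gamma) + params$gamma * params$sigma^2 * n^2 * pi^2
    if (abs(den) < 1e-9)
      abort_resonance("mode factor denominator vanishes (resonant landscape mode)")
    2 / den
  } else {
    num <- n^2 * pi^2 + params$m^2
    den <- n^2 * pi^2 + params$m^2 * (1 - params$gamma)
    if (abs(den) < 1e-9 * num)
      abort_resonance("mode factor denominator vanishes (resonant landscape mode)")
    num / den
  }
}

#' General steady-state family on a connected support component
#'
#' Evaluates the full steady-state solution family
#' \eqn{u_*(x) = u_P(x) + u_I(x)} on a connected support component, for a
#' periodic (Fourier) landscape: the particular part applies
#' [mode_factor()] to each landscape mode, and the homogeneous part is
#' oscillatory (\eqn{P\sin + Q\cos} at the intrinsic frequency) for
#' \eqn{\gamma > 1} or exponential (\eqn{P e^{wx} + Q e^{-wx}}) for
#' \eqn{\gamma < 1}. The constants \eqn{\alpha_0, P, Q} are free.
#'
#' @param params An [model_params()] object (\eqn{\gamma \ne 1}).
#' @param env A [fourier_env()].
#' @param alpha0,P,Q Free constants of the family.
#' @return A function of `x` evaluating the profile.
#' @export
proposition_solution <- function(params, env, alpha0 = 0, P = 0, Q = 0) {
  if (!inherits(env, "fourier_env"))
    abort_config("proposition_solution requires a fourier_env landscape")
  if (params$gamma == 1) abort_regime("gamma = 1 singular case not supported")
  facs <- vapply(seq_along(env$cosine_coeffs),
                 function(k) mode_factor(params, k), numeric(1))
  facs_s <- vapply(seq_along(env$sine_coeffs),
                   function(k) mode_factor(params, k), numeric(1))
  oscillatory <- params$gamma > 1
  w <- if (oscillatory) intrinsic_freq(params) else intrinsic_decay(params)
  force(alpha0); force(P); force(Q)
  function(x) {
    u <- rep(alpha0, length(x))
    for (k in seq_along(env$cosine_coeffs))
      u <- u + facs[k] * env$cosine_coeffs[k] * cos(k * pi * x)
    for (k in seq_along(env$sine_coeffs))
      u <- u + facs_s[k] * env$sine_coeffs[k] * sin(k * pi * x)
    if (oscillatory) u + P * sin(w * x) + Q * cos(w * x)
    else u + P * exp(w * x) + Q * exp(-w * x)
  }
}

#' Constrained single-aggregation candidate
#'
#' Builds the symmetric single-aggregation steady-state candidate supported
#' on \eqn{[-r, r]} for a single-clump landscape:
#' \deqn{u_*(x) = \alpha_0 + \alpha_n [1 + \cos(n\pi x)]
#'       + Q \cos(w x), \quad |x| < \min(r, 1/n),}
#' with the clump term dropped on \eqn{1/n < |x| \le r} when \eqn{r > 1/n},
#' and \eqn{u_* = 0} outside. Here \eqn{w} is the intrinsic frequency
#' ([mode_factor()] resonance permitting), \eqn{\alpha_n} is the mode factor
#' times the clump amplitude, and \eqn{(\alpha_0, Q)} solve the simultaneous
#' pair of linear constraints: total mass equal to \eqn{p}, and continuity
#' \eqn{u_*(\pm r) = 0}. The odd amplitude \eqn{P} is fixed at 0 (the search
#' is restricted to profiles symmetric about the origin).
#'
#' @param params A [model_params()] object with \eqn{\gamma > 1}.
#' @param env A [clump_env()] landscape.
#' @param r Aggregation half-width, \eqn{0 < r \le 1}.
#' @return An object of class \code{aggdiff_candidate} with fields
#'   \code{r, alpha0, alpha_n, Q, P, env, params}.
#' @export
build_candidate <- function(params, env, r) {
  if (!inherits(env, "clump_env"))
    abort_config("build_candidate requires a clump_env landscape")
  stopifnot_scalar(r, "r", positive = TRUE)
  if (r > 1) abort_config("half-width r must lie in (0, 1]")
  if (params$gamma <= 1)
    abort_regime("single-aggregation candidates require gamma > 1")
  n <- env$n
  a_n <- env$amplitude
  alpha_n <- mode_factor(params, n) * a_n
  w1 <- n * pi
  w2 <- intrinsic_freq(params)
  p <- params$p

  # Linear system in (alpha0, Q):
  #   mass:      2r alpha0 + (2 sin(w2 r)/w2) Q = p - M_env
  #   continuity: alpha0 + cos(w2 r) Q          = -E_env
  if (r < 1 / n) {
    M_env <- alpha_n * (2 * r + 2 * sin(w1 * r) / w1)
    E_env <- alpha_n * (1 + cos(w1 * r))
  } else {
    M_env <- alpha_n * 2 / n
    E_env <- 0
  }
  Amat <- rbind(c(2 * r, 2 * sin(w2 * r) / w2),
                c(1, cos(w2 * r)))
  b <- c(p - M_env, -E_env)
  det <- Amat[1, 1] * Amat[2, 2] - Amat[1, 2] * Amat[2, 1]
  if (abs(det) < 1e-9 * max(abs(Amat)))
    abort_candidate("mass/continuity constraints are singular at this half-width")
  sol <- solve(Amat, b)
  structure(list(r = r, alpha0 = sol[1], alpha_n = alpha_n, Q = sol[2], P = 0,
                 w_env = w1, w_hom = w2, env = env, params = params),
            class = "aggdiff_candidate")
}

#' Evaluate a candidate profile
#'
#' Evaluates the piecewise candidate density; 0 outside \eqn{[-r, r]},
#' continuous everywhere (continuity at \eqn{\pm r} is enforced by
#' construction; the two interior branches join with matching value and
#' slope at \eqn{|x| = 1/n}).
#'
#' @param sol An \code{aggdiff_candidate}.
#' @param x Positions; vectorised (any real values; no domain restriction).
#' @param deriv 0, 1 or 2: the profile or its first/second piecewise
#'   derivative.
#' @return Numeric vector.
#' @export
candidate_value <- function(sol, x, deriv = 0L) {
  r <- sol$r; n <- sol$env$n
  w1 <- sol$w_env; w2 <- sol$w_hom
  inside <- abs(x) <= r + 1e-15
  clump <- inside & (abs(x) < 1 / n)
  out <- numeric(length(x))
  if (deriv == 0L) {
    out[inside] <- sol$alpha0 + sol$Q * cos(w2 * x[inside])
    out[clump] <- out[clump] + sol$alpha_n * (1 + cos(w1 * x[clump]))
  } else if (deriv == 1L) {
    out[inside] <- -sol$Q * w2 * sin(w2 * x[inside])
    out[clump] <- out[clump] - sol$alpha_n * w1 * sin(w1 * x[clump])
  } else if (deriv == 2L) {
    out[inside] <- -sol$Q * w2^2 * cos(w2 * x[inside])
    out[clump] <- out[clump] - sol$alpha_n * w1^2 * cos(w1 * x[clump])
  } else abort_config("deriv must be 0, 1 or 2")
  out
}

#' Minimum-energy profile on a flat landscape
#'
#' The minimum-energy steady state of the fourth-order model when
#' \eqn{A \equiv 0}: \eqn{u(x) = (p/2r_0)[1 + \cos(\pi x/r_0)]} on
#' \eqn{|x| < r_0}, zero outside, with \eqn{r_0} from [r0_of()]. Returned as
#' a candidate object (zero-amplitude clump), so all candidate tooling
#' applies.
#'
#' @param params A [model_params()] object with \eqn{\gamma > 1}.
#' @return An \code{aggdiff_candidate} with \eqn{r = r_0},
#'   \eqn{\alpha_0 = Q = p/2r_0}.
#' @export
homogeneous_minimiser <- function(params) {
  if (params$gamma <= 1) abort_regime("requires gamma > 1")
  r0 <- pi / intrinsic_freq(params)
  build_candidate(params, clump_env(1, 0), r0)
}

#' Positivity (admissibility) check
#'
#' A candidate is admissible iff its minimum over the support is
#' \eqn{\ge -10^{-12}} (the tolerance separates round-off from genuine
#' negativity). The minimum is located on a dense symmetric grid (4096
#' intervals) and polished by bracketed minimisation around every interior
#' local minimum of the two-cosine sum.
#'
#' @param sol An \code{aggdiff_candidate}.
#' @param n_grid Number of grid intervals for the scan.
#' @return List with elements \code{admissible} (logical) and
#'   \code{min_value}.
#' @export
is_admissible <- function(sol, n_grid = 4096L) {
  # even profile: scan [0, r]
  xs <- seq(0, sol$r, length.out = n_grid + 1L)
  us <- candidate_value(sol, xs)
  mn <- min(us)
  # interior critical points of the two-cosine sum: bracketed roots of u'
  dus <- candidate_value(sol, xs, deriv = 1L)
  sgn <- sign(dus)
  cross <- which(sgn[-length(sgn)] < 0 & sgn[-1L] >= 0) # minima: u' goes - to +
  for (i in cross) {
    root <- tryCatch(
      stats::uniroot(function(z) candidate_value(sol, z, deriv = 1L),
                     lower = xs[i], upper = xs[i + 1L], tol = 1e-14)$root,
      error = function(e) NULL)
    if (!is.null(root)) mn <- min(mn, candidate_value(sol, root))
  }
  list(admissible = mn >= -1e-12, min_value = mn)
}

#' Steady-state ODE residual of a candidate
#'
#' Measures how well a candidate satisfies the local steady-state ODE on its
#' support: \eqn{c + A = (1-\gamma)u - (\gamma\sigma^2/2)u''} (fourth-order
#' family) or, in the Laplace family, the equivalent scaled form
#' \eqn{c + A - A''/m^2 = (1-\gamma)u - u''/m^2}. Second derivatives are
#' taken from the exact piecewise cosine forms. The free constant \eqn{c} is
#' fitted by least squares on each smooth piece of the support (the pieces
#' are separated by the clump edge \eqn{|x| = 1/n}, where the landscape's
#' curvature jumps); see the package vignette for why the constant is fitted
#' per piece.
#'
#' @param sol An \code{aggdiff_candidate}.
#' @param n_grid Sample points per smooth piece.
#' @return Maximum absolute residual over the support interior.
#' @export
steady_residual <- function(sol, n_grid = 800L) {
  params <- sol$params
  pieces <- if (sol$r > 1 / sol$env$n)
    list(c(0, 1 / sol$env$n), c(1 / sol$env$n, sol$r))
  else
    list(c(0, sol$r))
  worst <- 0
  for (pc in pieces) {
    # open interval: stay off the piece edges where u'' is one-sided
    xs <- seq(pc[1], pc[2], length.out = n_grid + 2L)
    xs <- xs[-c(1L, length(xs))]
    u <- candidate_value(sol, xs)
    u2 <- candidate_value(sol, xs, deriv = 2L)
    A <- eval_environment(sol$env, xs)
    if (params$family == "fourth_order") {
      lhs <- (1 - params$gamma) * u - (params$gamma * params$sigma^2 / 2) * u2 - A
    } else {
      m <- params$m
      # A'' of the clump piece: -a_n w1^2 cos(w1 x) inside, 0 outside
      inside <- abs(xs) < 1 / sol$env$n
      A2 <- numeric(length(xs))
      A2[inside] <- -sol$env$amplitude * sol$w_env^2 * cos(sol$w_env * xs[inside])
      lhs <- (1 - params$gamma) * u - u2 / m^2 - A + A2 / m^2
    }
    cfit <- mean(lhs)
    worst <- max(worst, max(abs(lhs - cfit)))
  }
  worst
}

#' Mass of a candidate (closed form)
#'
#' \eqn{\int_{-r}^{r} u_*\, dx} from the trigonometric antiderivatives;
#' equals \eqn{p} for any [build_candidate()] output by construction.
#'
#' @param sol An \code{aggdiff_candidate}.
#' @return The total mass.
#' @export
candidate_mass <- function(sol) {
  r <- sol$r; n <- sol$env$n
  w1 <- sol$w_env; w2 <- sol$w_hom
  m <- 2 * r * sol$alpha0 + 2 * sol$Q * sin(w2 * r) / w2
  if (r < 1 / n)
    m + sol$alpha_n * (2 * r + 2 * sin(w1 * r) / w1)
  else
    m + sol$alpha_n * 2 / n
}
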