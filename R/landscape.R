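#' Environment (resource landscape) constructors
#'
#' The models live on the dimensionless domain \eqn{[-1, 1]} (half-period
#' \eqn{L = 1} after rescaling). Three landscape families are supported:
#'
#' \describe{
#'   \item{\code{fourier_env}}{a general period-2 landscape
#'     \eqn{A(x) = a_0 + \sum_n [a_n \cos(n\pi x) + b_n \sin(n\pi x)]}.}
#'   \item{\code{clump_env}}{a single clump of attractive resources,
#'     \eqn{A(x) = a_n [1 + \cos(n\pi x)]} for \eqn{|x| < 1/n}, 0 otherwise.
#'     The clump has width \eqn{2/n}, peak \eqn{2 a_n} at the origin, and is
#'     continuously differentiable at its edges.}
#'   \item{\code{two_clump_env}}{two clumps,
#'     \eqn{A(x) = a_4 [1 - \cos(4\pi x)]} for \eqn{|x| < 1/2}, 0 otherwise,
#'     with maxima \eqn{2 a_4} at \eqn{x = \pm 1/4} and a trough at 0.}
#' }
#'
#' All amplitudes are dimensionless (advection strength relative to
#' diffusion); see [nondimensionalise()] for the conversion from dimensional
#' inputs.
#'
#' @param a0 Constant (mean) term of the Fourier landscape.
#' @param cosine_coeffs,sine_coeffs Numeric vectors of cosine/sine
#'   coefficients \eqn{a_n}, \eqn{b_n}; position \code{n} is mode \code{n}.
#' @param n Positive integer mode index; the clump occupies \eqn{|x| < 1/n}.
#' @param amplitude Clump amplitude \eqn{a_n \ge 0}.
#' @return An environment object of class \code{aggdiff_env}.
#' @examples
#' env <- clump_env(n = 1, amplitude = 1)
#' eval_environment(env, 0)       # 2
#' environment_gradient(env, 0.5) # -pi
#' @name environments
NULL

#' @rdname environments
#' @export
fourier_env <- function(a0 = 0, cosine_coeffs = numeric(), sine_coeffs = numeric()) {
  stopifnot_scalar(a0, "a0")
  if (!is.numeric(cosine_coeffs) || !is.numeric(sine_coeffs))
    abort_config("Fourier coefficients must be numeric vectors")
  structure(list(a0 = a0,
                 cosine_coeffs = as.numeric(cosine_coeffs),
                 sine_coeffs = as.numeric(sine_coeffs)),
            class = c("fourier_env", "aggdiff_env"))
}

#' @rdname environments
#' @export
clump_env <- function(n, amplitude) {
  stopifnot_scalar(n, "n", positive = TRUE)
  if (n != round(n)) abort_config("clump mode index 'n' must be a positive integer")
  stopifnot_scalar(amplitude, "amplitude")
  if (amplitude < 0) abort_config("clump 'amplitude' must be non-negative")
  structure(list(n = as.integer(n), amplitude = amplitude),
            class = c("clump_env", "aggdiff_env"))
}

#' @rdname environments
#' @export
two_clump_env <- function(amplitude) {
  stopifnot_scalar(amplitude, "amplitude")
  if (amplitude < 0) abort_config("'amplitude' must be non-negative")
  structure(list(amplitude = amplitude),
            class = c("two_clump_env", "aggdiff_env"))
}

check_domain <- function(x) {
  if (!is.numeric(x)) abort_domain("positions must be numeric")
  if (any(!is.finite(x)) || any(x < -1 - 1e-12) || any(x > 1 + 1e-12))
    abort_domain("positions must lie in the dimensionless domain [-1, 1]")
  invisible(x)
}

#' Evaluate a landscape and its gradient
#'
#' `eval_environment()` returns the resource potential \eqn{A(x)};
#' `environment_gradient()` returns \eqn{dA/dx} from the closed-form
#' derivative of each piece (identically zero outside clump support, so the
#' advective forcing vanishes there exactly).
#'
#' @param env An environment from [clump_env()], [two_clump_env()] or
#'   [fourier_env()].
#' @param x Positions in \eqn{[-1, 1]}; vectorised.
#' @return Numeric vector of the same length as `x`.
#' @export
eval_environment <- function(env, x) {
  check_domain(x)
  UseMethod("eval_environment")
}

#' @export
eval_environment.fourier_env <- function(env, x) {
  out <- rep(env$a0, length(x))
  for (k in seq_along(env$cosine_coeffs))
    out <- out + env$cosine_coeffs[k] * cos(k * pi * x)
  for (k in seq_along(env$sine_coeffs))
    out <- out + env$sine_coeffs[k] * sin(k * pi * x)
  out
}

#' @export
eval_environment.clump_env <- function(env, x) {
  inside <- abs(x) < 1 / env$n
  out <- numeric(length(x))
  out[inside] <- env$amplitude * (1 + cos(env$n * pi * x[inside]))
  out
}

#' @export
eval_environment.two_clump_env <- function(env, x) {
  inside <- abs(x) < 0.5
  out <- numeric(length(x))
  out[inside] <- env$amplitude * (1 - cos(4 * pi * x[inside]))
  out
}

#' @rdname eval_environment
#' @export
environment_gradient <- function(env, x) {
  check_domain(x)
  UseMethod("environment_gradient")
}

#' @export
environment_gradient.fourier_env <- function(env, x) {
  out <- numeric(length(x))
  for (k in seq_along(env$cosine_coeffs))
    out <- out - env$cosine_coeffs[k] * k * pi * sin(k * pi * x)
  for (k in seq_along(env$sine_coeffs))
    out <- out + env$sine_coeffs[k] * k * pi * cos(k * pi * x)
  out
}

#' @export
environment_gradient.clump_env <- function(env, x) {
  inside <- abs(x) < 1 / env$n
  out <- numeric(length(x))
  out[inside] <- -env$amplitude * env$n * pi * sin(env$n * pi * x[inside])
  out
}

#' @export
environment_gradient.two_clump_env <- function(env, x) {
  inside <- abs(x) < 0.5
  out <- numeric(length(x))
  out[inside] <- env$amplitude * 4 * pi * sin(4 * pi * x[inside])
  out
}

#' Truncated Fourier projection of a landscape
#'
#' Projects any landscape onto its first `n_modes` Fourier modes on
#' \eqn{[-1, 1]} by periodic trapezoidal quadrature (spectrally accurate for
#' smooth pieces). Used for cross-checking the closed-form clump landscapes
#' against their series representation.
#'
#' @param env An environment object.
#' @param n_modes Number of modes to retain (\eqn{\ge 1}).
#' @param oversample Quadrature points per retained mode (at least 8).
#' @return A [fourier_env()] object.
#' @export
make_fourier <- function(env, n_modes, oversample = 8) {
  stopifnot_scalar(n_modes, "n_modes", positive = TRUE)
  if (n_modes < 1 || n_modes != round(n_modes))
    abort_config("'n_modes' must be a positive integer")
  oversample <- max(8, oversample)
  n_hi <- n_modes
  if (inherits(env, "clump_env")) n_hi <- max(n_hi, env$n)
  M <- as.integer(oversample * n_hi)
  # periodic rectangle rule on [-1, 1): exact for trig polynomials < M/2
  xj <- -1 + 2 * (seq_len(M) - 1) / M
  Aj <- eval_environment(env, xj)
  a0 <- sum(Aj) / M
  ks <- seq_len(n_modes)
  ac <- vapply(ks, function(k) 2 * sum(Aj * cos(k * pi * xj)) / M, numeric(1))
  bs <- vapply(ks, function(k) 2 * sum(Aj * sin(k * pi * xj)) / M, numeric(1))
  # clump landscapes are even; kill quadrature round-off in the odd part
  if (inherits(env, c("clump_env", "two_clump_env"))) bs[] <- 0
  fourier_env(a0 = a0, cosine_coeffs = ac, sine_coeffs = bs)
}
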