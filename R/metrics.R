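#' Aggregation width of a gridded density
#'
#' Two conventions:
#' \describe{
#'   \item{\code{"support"}}{the extent of \eqn{\{x : u > \epsilon\}}
#'     (\eqn{\epsilon} = 1e-6 by default, the solver round-off floor),
#'     quoted at cell resolution -- appropriate for compactly supported
#'     quadratic-diffusion states;}
#'   \item{\code{"at_height"}}{the extent of \eqn{\{x : u > h\}} with linear
#'     interpolation at the crossings -- used for linear-diffusion states,
#'     which are positive everywhere (the reference height is
#'     \eqn{u = 0.1}).}
#' }
#'
#' @param u Density values (non-negative).
#' @param x Grid coordinates.
#' @param mode \code{"support"} or \code{"at_height"}.
#' @param epsilon Support threshold.
#' @param h Reference height for \code{"at_height"}.
#' @return The width; 0 with attribute \code{empty = TRUE} when the density
#'   never exceeds the threshold.
#' @export
aggregation_width <- function(u, x, mode = c("support", "at_height"),
                              epsilon = 1e-6, h = 0.1) {
  mode <- match.arg(mode)
  thr <- if (mode == "support") epsilon else h
  above <- which(u > thr)
  if (!length(above)) return(structure(0, empty = TRUE))
  dx <- x[2] - x[1]
  if (mode == "support")
    return((above[length(above)] - above[1] + 1L) * dx)
  i0 <- above[1]; i1 <- above[length(above)]
  xl <- if (i0 > 1L)
    x[i0 - 1L] + dx * (thr - u[i0 - 1L]) / (u[i0] - u[i0 - 1L])
  else x[1]
  xr <- if (i1 < length(u))
    x[i1] + dx * (u[i1] - thr) / (u[i1] - u[i1 + 1L])
  else x[length(x)]
  xr - xl
}

#' Peaks of a gridded density
#'
#' Local maxima above a floor of \eqn{10^{-3} \max u}, with parabolic
#' sub-grid refinement of the positions.
#'
#' @param u Density values (non-negative).
#' @param x Grid coordinates.
#' @return List with \code{count}, \code{locations}, \code{heights}.
#' @export
peak_stats <- function(u, x) {
  n <- length(u)
  floor_h <- 1e-3 * max(u)
  idx <- which(u[2:(n - 1)] > u[1:(n - 2)] & u[2:(n - 1)] >= u[3:n]) + 1L
  idx <- idx[u[idx] > floor_h]
  # merge plateau neighbours
  if (length(idx) > 1L) idx <- idx[c(TRUE, diff(idx) > 1L)]
  dx <- x[2] - x[1]
  locs <- heights <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    den <- u[i - 1L] - 2 * u[i] + u[i + 1L]
    off <- if (den < 0) 0.5 * (u[i - 1L] - u[i + 1L]) / den else 0
    locs[j] <- x[i] + off * dx
    heights[j] <- u[i] - 0.25 * (u[i - 1L] - u[i + 1L]) * off
  }
  list(count = length(idx), locations = locs, heights = heights)
}

#' Parameter sweep of the minimum-energy aggregation
#'
#' For each value of the swept parameter, finds the minimum-energy
#' single-aggregation solution (analytic route, [minimise_energy()]) or the
#' converged PDE state (pde route, [run_to_steady()] from the flat-landscape
#' profile) and records the half-width, width, peak height and energy.
#' Entries where no admissible candidate exists (or a resonance is hit) are
#' recorded as `NA` without aborting the sweep.
#'
#' @param params Baseline [model_params()].
#' @param env Baseline [clump_env()] landscape.
#' @param parameter One of \code{"n"}, \code{"amplitude"}, \code{"gamma"},
#'   \code{"sigma"}, \code{"p"}.
#' @param values Values to sweep.
#' @param method \code{"analytic"} (seconds) or \code{"pde"} (minutes).
#' @param pde_control List of overrides for the pde route: \code{dx},
#'   \code{dt}, \code{tol}, \code{max_time}.
#' @return Data frame of class \code{aggdiff_sweep} with columns
#'   \code{value}, \code{r_star}, \code{width}, \code{peak_height},
#'   \code{energy}.
#' @export
sweep_parameter <- function(params, env, parameter, values,
                            method = c("analytic", "pde"),
                            pde_control = list()) {
  method <- match.arg(method)
  parameter <- match.arg(parameter, c("n", "amplitude", "gamma", "sigma", "p"))
  rows <- lapply(values, function(v) {
    pp <- params; ee <- env
    if (parameter == "n") ee <- clump_env(v, env$amplitude)
    else if (parameter == "amplitude") ee <- clump_env(env$n, v)
    else pp[[parameter]] <- v
    if (method == "analytic") {
      fit <- tryCatch(minimise_energy(pp, ee), aggdiffenv_error = function(e) NULL)
      if (is.null(fit))
        return(data.frame(value = v, r_star = NA_real_, width = NA_real_,
                          peak_height = NA_real_, energy = NA_real_))
      data.frame(value = v, r_star = fit$r, width = 2 * fit$r,
                 peak_height = candidate_value(fit$sol, 0), energy = fit$energy)
    } else {
      ctl <- utils::modifyList(list(dx = 0.01, dt = NULL, tol = 1e-8,
                                    max_time = 10), pde_control)
      grid <- make_grid(ctl$dx)
      cfg <- solver_config("quadratic_local4", gamma = pp$gamma,
                           sigma = pp$sigma, env = ee, dt = ctl$dt,
                           tol = ctl$tol, max_time = ctl$max_time)
      u0 <- make_initial_condition("flat_min", grid, p = pp$p,
                                   gamma = pp$gamma, sigma = pp$sigma)
      sim <- run_to_steady(u0, grid, cfg)
      w <- aggregation_width(sim$u, grid$x, "support")
      pk <- peak_stats(sim$u, grid$x)
      data.frame(value = v, r_star = w / 2, width = as.numeric(w),
                 peak_height = if (pk$count) max(pk$heights) else NA_real_,
                 energy = sim$energy[length(sim$energy)])
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- parameter
  attr(out, "method") <- method
  class(out) <- c("aggdiff_sweep", "data.frame")
  out
}
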